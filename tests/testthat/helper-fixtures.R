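# Shared, lazily built fixtures. Chemistry and model fitting are the slow
# parts, so anything reused across files is memoized here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# 200-molecule noiseless corpus (100 per class), with descriptors
corpus_200 <- function() {
  memo("corpus200", function() {
    rec <- generate_fixture(100, seed = 11, noise = 0)
    list(records = rec, descriptors = compute_descriptors(rec$smiles))
  })
}

# mock embeddings for the corpus
corpus_200_embeddings <- function() {
  memo("emb200", function() mock_encode(corpus_200()$records$smiles, d = 128))
}

# tuned similarity model + leaf embeddings over the corpus
corpus_200_leaves <- function() {
  memo("leaves200", function() {
    co <- corpus_200()
    emb <- corpus_200_embeddings()
    model <- fit_similarity_model(emb, co$records$label,
                                  search_space(n_trials = 12, nrounds_max = 40),
                                  seed = 5)
    list(model = model, leaves = leaf_embedding(model, emb),
         labels = co$records$label, ids = co$records$id)
  })
}

# 400-molecule noiseless fixture for the baseline bench
fixture_400 <- function() {
  memo("fix400", function() {
    rec <- generate_fixture(200, seed = 23, noise = 0)
    list(records = rec, descriptors = compute_descriptors(rec$smiles))
  })
}

# a compliant response for a given truth/score
compliant_response <- function(label = "approved", score = 0.9) {
  render_response("reasoning here", label, score)
}

# random tag-soup completions for fuzzing the reward grid
random_completion <- function() {
  pieces <- c("<think>", "</think>", "<label>", "</label>", "<score>", "</score>",
              "approved", "unapproved", "maybe", "0.9", "0.2", "1.7", "-1", "text ",
              "\n", " ", "<think>x</think>", "<label>approved</label>",
              "<score>0.5</score>")
  paste(sample(pieces, sample(0:12, 1), replace = TRUE), collapse = "")
}

# brute-force per-class neighbor scan with the ascending-position tie rule
brute_force_neighbors <- function(query, leaves, labels, ids, k = 5, exclude_id = NULL) {
  d <- apply(leaves, 1, function(r) sum(r != query))
  keep <- if (is.null(exclude_id)) rep(TRUE, length(ids)) else ids != exclude_id
  out <- lapply(c("approved", "unapproved"), function(lb) {
    idx <- which(keep & labels == lb)
    ord <- idx[order(d[idx], idx)][seq_len(k)]
    data.frame(id = ids[ord], distance = d[ord], stringsAsFactors = FALSE)
  })
  names(out) <- c("approved", "unapproved")
  out
}

# exhaustive pairwise AUC oracle (ties count one half)
brute_force_auc <- function(truth, prob) {
  pos <- prob[truth == "approved"]
  neg <- prob[truth == "unapproved"]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

softmax_test <- function(z) { e <- exp(z - max(z)); e / sum(e) }
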