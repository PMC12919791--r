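# Molecular-embedding contract: masked mean pooling over token hidden
# states, plus a deterministic mock encoder so the whole pipeline runs with
# no pretrained weights. A pretrained transformer encoder can be plugged in
# behind the same contract via `backend = list(encode = <function>)`.

EMBED_DIM_DEFAULT <- 768L
MOCK_ENCODER_SEED <- 760813L   # fixed projection seed, recorded in run manifests
MOCK_NGRAM_BUCKETS <- 1024L

#' Masked mean pooling over token hidden states
#'
#' Pools a `T x d` matrix of last hidden states into a length-`d` vector,
#' weighting each token row by its attention-mask entry:
#' `sum_t mask_t * hidden_t / sum_t mask_t`.
#'
#' @param hidden `T x d` numeric matrix.
#' @param mask Length-`T` vector of 0/1 attention-mask entries.
#' @return Length-`d` numeric vector.
#' @export
masked_mean_pool <- function(hidden, mask) {
  abort_if(!is.matrix(hidden) || !is.numeric(hidden), "`hidden` must be a numeric matrix")
  abort_if(length(mask) != nrow(hidden), "`mask` length must equal nrow(hidden)")
  abort_if(!all(mask %in% c(0, 1)), "`mask` entries must be 0 or 1")
  abort_if(sum(mask) == 0, "attention mask is all zero; nothing to pool")
  as.numeric(crossprod(hidden, mask) / sum(mask))
}

# polynomial rolling hash of a string into [1, buckets]
hash_ngram <- function(ngrams, buckets) {
  vapply(ngrams, function(g) {
    h <- 0
    for (cc in utf8ToInt(g)) h <- (h * 131 + cc) %% 1000003
    as.integer(h %% buckets) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

mock_projection <- function(d, buckets = MOCK_NGRAM_BUCKETS, seed = MOCK_ENCODER_SEED) {
  key <- sprintf("proj_%d_%d_%d", buckets, d, seed)
  if (is.null(.molapprove_env[[key]])) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    .molapprove_env[[key]] <- matrix(rnorm(buckets * d) / sqrt(d), nrow = buckets)
  }
  .molapprove_env[[key]]
}

#' Deterministic mock molecular encoder
#'
#' Embeds a SMILES string as the unit-normalized projection of its hashed
#' character 2- and 3-gram count vector through a fixed seeded random
#' Gaussian projection. Structure-aware only through the SMILES text, but
#' deterministic, dimension-correct and download-free, which is what the
#' retrieval and pipeline tests need.
#'
#' @param smiles Character vector of valid SMILES.
#' @param d Embedding dimension (default 768).
#' @return `length(smiles) x d` numeric matrix with unit-norm rows.
#' @export
mock_encode <- function(smiles, d = EMBED_DIM_DEFAULT) {
  can <- canonicalize_smiles(smiles)
  proj <- mock_projection(d)
  out <- matrix(0, nrow = length(can), ncol = d)
  for (i in seq_along(can)) {
    s <- can[i]
    grams <- c(substring(s, seq_len(max(nchar(s) - 1L, 0L)), seq_len(max(nchar(s) - 1L, 0L)) + 1L),
               substring(s, seq_len(max(nchar(s) - 2L, 0L)), seq_len(max(nchar(s) - 2L, 0L)) + 2L))
    grams <- grams[nchar(grams) > 1L]
    counts <- tabulate(hash_ngram(grams, nrow(proj)), nbins = nrow(proj))
    v <- as.numeric(crossprod(proj, counts))
    nv <- sqrt(sum(v^2))
    abort_if(nv == 0, "degenerate mock embedding for '", s, "'")
    out[i, ] <- v / nv
  }
  out
}

#' Encode a batch of molecules
#'
#' Applies the selected encoder backend in batches. The output is
#' independent of the batch partitioning and row order matches input order.
#'
#' @param smiles Character vector of valid SMILES.
#' @param backend `"mock"` (default) or a list with an `encode(smiles, d)`
#'   function wrapping a pretrained encoder.
#' @param d Embedding dimension.
#' @param batch_size Molecules per batch (default 64).
#' @return `n x d` matrix with `smiles` ids as rownames when named.
#' @export
encode_batch <- function(smiles, backend = "mock", d = EMBED_DIM_DEFAULT, batch_size = 64L) {
  abort_if(!is_count(batch_size) || batch_size < 1, "`batch_size` must be >= 1")
  enc <- if (is.list(backend) && is.function(backend$encode)) {
    backend$encode
  } else if (identical(backend, "mock")) {
    mock_encode
  } else {
    stop("encoder backend '", paste(backend, collapse = "/"),
         "' is not available; supply list(encode = <function>) or use 'mock'",
         call. = FALSE)
  }
  out <- matrix(0, nrow = length(smiles), ncol = d)
  starts <- seq(1L, length(smiles), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(smiles))
    block <- enc(smiles[idx], d)
    abort_if(!is.matrix(block) || nrow(block) != length(idx) || ncol(block) != d,
             "encoder backend returned a malformed block")
    out[idx, ] <- block
  }
  abort_if(any(!is.finite(out)), "non-finite entries in embedding matrix")
  if (!is.null(names(smiles))) rownames(out) <- names(smiles)
  out
}
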