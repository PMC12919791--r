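# Leaf-embedding similarity retrieval: a gradient-boosted-tree binary
# classifier (approved vs unapproved) is tuned on the molecular embeddings,
# every molecule is mapped to the vector of terminal-leaf indices it reaches
# (one per tree), and nearest neighbors are retrieved per class by Hamming
# distance in that leaf space.

#' Hyperparameter search space for the similarity model
#'
#' Ranges over learning rate, maximum tree depth, L1/L2 regularization and
#' the row/column subsampling ratios, searched by a tree-structured Parzen
#' estimator with median pruning. Desk-scale default is 25 trials; the
#' reference-scale 1000 trials remain a parameter away.
#'
#' @param eta_range Log-uniform learning-rate range.
#' @param max_depth_range Integer depth range.
#' @param alpha_range,lambda_range Log-uniform L1/L2 ranges.
#' @param subsample_range,colsample_range Subsampling-ratio ranges.
#' @param n_trials Search trials (default 25).
#' @param early_stopping_rounds Boosting early-stop patience (default 20).
#' @param nrounds_max Boosting-round budget per trial.
#' @return A `search_space` list.
#' @export
search_space <- function(eta_range = c(0.02, 0.3), max_depth_range = c(2L, 8L),
                         alpha_range = c(1e-8, 1), lambda_range = c(1e-8, 10),
                         subsample_range = c(0.6, 1), colsample_range = c(0.5, 1),
                         n_trials = 25L, early_stopping_rounds = 20L,
                         nrounds_max = 80L) {
  sp <- list(eta_range = eta_range, max_depth_range = as.integer(max_depth_range),
             alpha_range = alpha_range, lambda_range = lambda_range,
             subsample_range = subsample_range, colsample_range = colsample_range,
             n_trials = as.integer(n_trials),
             early_stopping_rounds = as.integer(early_stopping_rounds),
             nrounds_max = as.integer(nrounds_max))
  for (nm in grep("_range$", names(sp), value = TRUE)) {
    abort_if(length(sp[[nm]]) != 2L || sp[[nm]][1] > sp[[nm]][2],
             "empty range for ", nm)
  }
  abort_if(sp$n_trials < 1L, "`n_trials` must be >= 1")
  class(sp) <- "search_space"
  sp
}

# ---- univariate tree-structured Parzen estimator --------------------------

# After n_startup random trials, each parameter is proposed by splitting
# completed trials at the gamma-quantile of the loss, fitting Gaussian-kernel
# densities l(x) over the good trials and g(x) over the rest, and picking
# the candidate maximizing l/g. Log-scaled parameters are handled in log
# space, integers by rounding.
tpe_propose <- function(history, param, range, log_scale = FALSE, integer = FALSE,
                        gamma = 0.25, n_candidates = 24L, n_startup = 10L) {
  tx <- function(x) if (log_scale) log(x) else x
  itx <- function(x) if (log_scale) exp(x) else x
  lo <- tx(range[1]); hi <- tx(range[2])
  draw_uniform <- function() itx(runif(1, lo, hi))
  done <- history[!is.na(history$loss), , drop = FALSE]
  if (nrow(done) < n_startup) {
    x <- draw_uniform()
    return(if (integer) as.integer(round(x)) else x)
  }
  n_good <- max(1L, ceiling(gamma * nrow(done)))
  ord <- order(done$loss)
  good <- tx(done[[param]][ord[seq_len(n_good)]])
  bad <- tx(done[[param]][ord[-seq_len(n_good)]])
  if (!length(bad)) bad <- c(lo, hi)
  bw <- function(x) max((hi - lo) / 20, stats::sd(x), 1e-6)
  dens <- function(x, centers, h) rowMeans(outer(x, centers, function(a, b) stats::dnorm(a, b, h)))
  cand <- good[sample.int(length(good), n_candidates, replace = TRUE)] +
    rnorm(n_candidates, 0, bw(good))
  cand <- pmin(pmax(cand, lo), hi)
  score <- dens(cand, good, bw(good)) / pmax(dens(cand, bad, bw(bad)), 1e-12)
  x <- itx(cand[which.max(score)])
  if (integer) as.integer(round(x)) else x
}

logloss <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# incremental boosting with early stopping and rung-based median pruning
train_trial <- function(params, dtrain, x_tune, y_tune, space, rung_size = 10L,
                        rung_medians = NULL) {
  booster <- NULL
  best_loss <- Inf
  best_iter <- 0L
  since_best <- 0L
  losses <- numeric(0)
  pruned <- FALSE
  nrounds_done <- 0L
  while (nrounds_done < space$nrounds_max) {
    add <- min(rung_size, space$nrounds_max - nrounds_done)
    booster <- xgboost::xgb.train(params = params, data = dtrain, nrounds = add,
                                  xgb_model = booster, verbose = 0)
    nrounds_done <- nrounds_done + add
    p <- predict(booster, x_tune, iterationrange = c(1, nrounds_done))
    ll <- logloss(y_tune, p)
    losses <- c(losses, ll)
    rung <- length(losses)
    if (ll < best_loss - 1e-12) {
      best_loss <- ll; best_iter <- nrounds_done; since_best <- 0L
    } else {
      since_best <- since_best + add
    }
    if (!is.null(rung_medians) && rung <= length(rung_medians) &&
        is.finite(rung_medians[rung]) && ll > rung_medians[rung]) {
      pruned <- TRUE
      break
    }
    if (since_best >= space$early_stopping_rounds) break
  }
  list(loss = best_loss, best_iter = max(best_iter, 1L), losses = losses, pruned = pruned)
}

#' Fit the boosted-tree similarity model
#'
#' Tunes an XGBoost binary classifier (log-loss objective and evaluation)
#' over the [search_space()] with a tree-structured Parzen estimator and a
#' median pruner, evaluating trials on a stratified 10% tuning slice held
#' out of the training data, then refits the best configuration on the full
#' training set.
#'
#' @param embeddings `n x d` numeric matrix.
#' @param labels Character approval labels aligned with rows (approved = 1).
#' @param space A [search_space()].
#' @param seed Integer seed (single-threaded, deterministic).
#' @return A `similarity_model` list: `booster`, `n_trees`, `best_params`,
#'   `trials` data.frame, `feature_dim`.
#' @export
fit_similarity_model <- function(embeddings, labels, space = search_space(), seed = 1L) {
  abort_if(!is.matrix(embeddings), "`embeddings` must be a matrix")
  y <- as.integer(labels == "approved")
  abort_if(length(unique(y)) < 2L, "training data must contain both classes")
  abort_if(min(table(y)) < 2L, "need at least 2 examples per class")
  set.seed(as.integer(seed))
  # stratified 10% tuning slice (at least one per class)
  tune_idx <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(0.1 * length(idx))))
  }))
  x_tr <- embeddings[-tune_idx, , drop = FALSE]; y_tr <- y[-tune_idx]
  x_tu <- embeddings[tune_idx, , drop = FALSE]; y_tu <- y[tune_idx]
  dtrain <- xgboost::xgb.DMatrix(x_tr, label = y_tr, nthread = 1)
  history <- data.frame(eta = numeric(0), max_depth = integer(0), alpha = numeric(0),
                        lambda = numeric(0), subsample = numeric(0),
                        colsample_bytree = numeric(0), loss = numeric(0),
                        best_iter = integer(0), pruned = logical(0))
  rung_losses <- list()
  for (trial in seq_len(space$n_trials)) {
    par <- list(
      eta = tpe_propose(history, "eta", space$eta_range, log_scale = TRUE),
      max_depth = tpe_propose(history, "max_depth", space$max_depth_range, integer = TRUE),
      alpha = tpe_propose(history, "alpha", space$alpha_range, log_scale = TRUE),
      lambda = tpe_propose(history, "lambda", space$lambda_range, log_scale = TRUE),
      subsample = tpe_propose(history, "subsample", space$subsample_range),
      colsample_bytree = tpe_propose(history, "colsample_bytree", space$colsample_range))
    rung_medians <- if (length(rung_losses)) {
      n_rungs <- max(lengths(rung_losses))
      vapply(seq_len(n_rungs), function(r) {
        v <- unlist(lapply(rung_losses, function(l) if (length(l) >= r) l[r] else NULL))
        if (length(v) >= 3L) median(v) else NA_real_
      }, numeric(1))
    } else NULL
    fit <- train_trial(c(par, list(objective = "binary:logistic",
                                   eval_metric = "logloss", nthread = 1,
                                   seed = as.integer(seed))),
                       dtrain, x_tu, y_tu, space, rung_medians = rung_medians)
    rung_losses[[trial]] <- fit$losses
    history[trial, names(par)] <- par
    history$loss[trial] <- fit$loss
    history$best_iter[trial] <- fit$best_iter
    history$pruned[trial] <- fit$pruned
  }
  best <- history[which.min(history$loss), , drop = FALSE]
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 nthread = 1, seed = as.integer(seed),
                 eta = best$eta, max_depth = best$max_depth, alpha = best$alpha,
                 lambda = best$lambda, subsample = best$subsample,
                 colsample_bytree = best$colsample_bytree)
  dfull <- xgboost::xgb.DMatrix(embeddings, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dfull,
                                nrounds = best$best_iter, verbose = 0)
  structure(list(booster = booster, n_trees = best$best_iter,
                 best_params = params, trials = history,
                 feature_dim = ncol(embeddings)),
            class = "similarity_model")
}

#' Terminal-leaf embedding of one or more molecules
#'
#' Records, for each input vector, the index of the terminal leaf reached
#' in every tree of the fitted ensemble.
#'
#' @param model A `similarity_model`.
#' @param embeddings `n x d` matrix or a length-`d` vector.
#' @return `n x n_trees` integer matrix.
#' @export
leaf_embedding <- function(model, embeddings) {
  abort_if(!inherits(model, "similarity_model"), "`model` must be a similarity_model")
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1)
  abort_if(ncol(embeddings) != model$feature_dim,
           "embedding dimension ", ncol(embeddings),
           " does not match training dimension ", model$feature_dim)
  lv <- predict(model$booster, embeddings, predleaf = TRUE)
  if (is.null(dim(lv))) lv <- matrix(lv, nrow = nrow(embeddings))
  storage.mode(lv) <- "integer"
  abort_if(ncol(lv) != model$n_trees, "leaf matrix width does not match n_trees")
  lv
}

#' Hamming distance between leaf embeddings
#'
#' @param u,v Equal-length integer vectors of terminal-leaf indices.
#' @return Count of positions at which they differ.
#' @export
hamming <- function(u, v) {
  abort_if(length(u) != length(v), "leaf vectors must have equal length (",
           length(u), " vs ", length(v), ")")
  sum(u != v)
}

#' Top-k per-class neighbors in leaf space
#'
#' Retrieves the `k` nearest approved and `k` nearest unapproved corpus
#' molecules by Hamming distance on leaf embeddings. Distance ties are
#' broken by ascending corpus position. In self-comparison mode pass the
#' query's own id as `exclude_id`.
#'
#' @param query Length-`n_trees` leaf vector.
#' @param corpus_leaves `m x n_trees` integer matrix.
#' @param corpus_labels,corpus_ids Aligned labels and ids.
#' @param k Neighbors per class (default 5).
#' @param exclude_id Id excluded from the corpus (self-comparison mode).
#' @return List with `approved` and `unapproved` `data.frame`s
#'   (`id`, `distance`), each of exactly `k` rows sorted by distance.
#' @export
top_k_neighbors <- function(query, corpus_leaves, corpus_labels, corpus_ids,
                            k = 5L, exclude_id = NULL) {
  abort_if(length(query) != ncol(corpus_leaves),
           "query length must match corpus leaf width")
  keep <- rep(TRUE, nrow(corpus_leaves))
  if (!is.null(exclude_id)) keep <- corpus_ids != exclude_id
  d <- as.integer(colSums(t(corpus_leaves) != as.integer(query)))
  out <- lapply(APPROVAL_LABELS, function(lb) {
    idx <- which(keep & corpus_labels == lb)
    abort_if(length(idx) < k, "only ", length(idx), " '", lb,
             "' corpus entries available after exclusion; need k = ", k)
    ord <- idx[order(d[idx], idx)][seq_len(k)]
    data.frame(id = corpus_ids[ord], distance = d[ord], stringsAsFactors = FALSE)
  })
  names(out) <- APPROVAL_LABELS
  out
}

#' Neighbor sets for a batch of queries
#'
#' @param query_leaves `n x n_trees` matrix.
#' @param query_ids Query identifiers.
#' @param corpus_leaves,corpus_labels,corpus_ids Corpus leaf space.
#' @param k Neighbors per class.
#' @param mode `"query"` (no exclusion) or `"self"` (each query's id is
#'   excluded from its own corpus scan).
#' @return Named list of [top_k_neighbors()] results.
#' @export
neighbor_table <- function(query_leaves, query_ids, corpus_leaves, corpus_labels,
                           corpus_ids, k = 5L, mode = c("query", "self")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(query_leaves)), function(i) {
    top_k_neighbors(query_leaves[i, ], corpus_leaves, corpus_labels, corpus_ids,
                    k = k,
                    exclude_id = if (mode == "self") query_ids[i] else NULL)
  })
  names(out) <- query_ids
  out
}

#' Save / load a similarity model directory
#'
#' The booster is stored in xgboost's native format next to a JSON metadata
#' file (tree count, feature dimension, tuned parameters, trial log).
#'
#' @param model A `similarity_model`.
#' @param dir Target directory (created if needed).
#' @return `dir` (invisibly) / the restored `similarity_model`.
#' @export
save_similarity_model <- function(model, dir) {
  abort_if(!inherits(model, "similarity_model"), "`model` must be a similarity_model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.ubj"))
  meta <- list(n_trees = model$n_trees, feature_dim = model$feature_dim,
               best_params = model$best_params)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_similarity_model
#' @export
load_similarity_model <- function(dir) {
  abort_if(!file.exists(file.path(dir, "model.ubj")), "no model found in ", dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(list(booster = xgboost::xgb.load(file.path(dir, "model.ubj")),
                 n_trees = meta$n_trees, feature_dim = meta$feature_dim,
                 best_params = meta$best_params,
                 trials = utils::read.csv(file.path(dir, "trials.csv"))),
            class = "similarity_model")
}
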