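# Metrics, checkpoint selection, conventional baselines, and the ablation
# bench. The positive class throughout is "approved".

#' Confusion-matrix metrics
#'
#' Computes accuracy, recall (sensitivity), precision, specificity and F1
#' from truth/prediction label vectors, carrying the raw counts alongside.
#'
#' @param truth,predicted Character vectors of approval labels.
#' @param format_adherence Optional fraction in `[0, 1]` recorded in the
#'   report (defaults to `NA`).
#' @return An `eval_report` list with `tp, fn, tn, fp`, the five metrics,
#'   `n_pos`, `n_neg`, `auc` (NA until set) and `format_adherence`.
#' @export
confusion_metrics <- function(truth, predicted, format_adherence = NA_real_) {
  abort_if(length(truth) != length(predicted), "truth and predictions differ in length")
  abort_if(!length(truth), "empty input")
  abort_if(!all(truth %in% APPROVAL_LABELS) || !all(predicted %in% APPROVAL_LABELS),
           "labels must be approved/unapproved")
  abort_if(length(unique(truth)) < 2L,
           "single-class truth: recall/specificity undefined")
  tp <- sum(truth == "approved" & predicted == "approved")
  fn <- sum(truth == "approved" & predicted == "unapproved")
  tn <- sum(truth == "unapproved" & predicted == "unapproved")
  fp <- sum(truth == "unapproved" & predicted == "approved")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = (tp + tn) / length(truth),
                 recall = recall,
                 precision = precision,
                 specificity = tn / (tn + fp),
                 f1 = f1,
                 auc = NA_real_,
                 n_pos = tp + fn, n_neg = tn + fp,
                 format_adherence = format_adherence),
            class = "eval_report")
}

#' Rank-based AUC
#'
#' Probability that a random approved molecule receives a higher approval
#' probability than a random unapproved one, ties counted one half
#' (Mann-Whitney form with midranks).
#'
#' @param truth Character approval labels (both classes present).
#' @param prob Approval probabilities aligned with `truth`.
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_score <- function(truth, prob) {
  abort_if(length(truth) != length(prob), "lengths differ")
  y <- truth == "approved"
  abort_if(!any(y) || all(y), "single-class truth: AUC undefined")
  r <- rank(prob, ties.method = "average")
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Approval probability of a parsed response
#'
#' The package's convention for turning a label + confidence pair into a
#' probability of approval: `score` when the label is approved, `1 - score`
#' when unapproved, and an uninformative 0.5 when either field is absent.
#'
#' @param parsed A [parse_response()] result.
#' @return Scalar in `[0, 1]`.
#' @export
response_to_probability <- function(parsed) {
  if (!isTRUE(parsed$label_valid) || !isTRUE(parsed$score_valid)) return(0.5)
  if (parsed$label == "approved") parsed$score else 1 - parsed$score
}

#' Evaluate a set of raw completions against truth labels
#'
#' Parses each completion; invalid labels count as (wrong) unapproved
#' predictions; approval probabilities come from
#' [response_to_probability()]. Format adherence is the fraction of
#' completions earning the full strict XML-format reward.
#'
#' @param truth Character approval labels.
#' @param responses Character completions, aligned.
#' @return An `eval_report` with `auc` and `format_adherence` set.
#' @export
evaluate_responses <- function(truth, responses) {
  abort_if(length(truth) != length(responses), "lengths differ")
  parsed <- lapply(responses, parse_response)
  predicted <- vapply(parsed, function(p) {
    if (isTRUE(p$label_valid)) p$label else "unapproved"
  }, character(1))
  prob <- vapply(parsed, response_to_probability, numeric(1))
  adherence <- mean(vapply(responses, reward_xml_format, numeric(1)) == 0.75)
  rep <- confusion_metrics(truth, predicted, format_adherence = adherence)
  rep$auc <- auc_score(truth, prob)
  rep
}

#' Select the inference checkpoint
#'
#' Among checkpoints with complete (100%) format adherence, picks the step
#' with maximal AUC; AUC ties break by higher F1, then by later step. If no
#' checkpoint reaches full adherence, falls back to the maximal-AUC row
#' with a warning.
#'
#' @param table `data.frame` with columns `step`, `auc`, `f1`,
#'   `format_adherence` (steps strictly increasing).
#' @return The selected step.
#' @export
select_checkpoint <- function(table) {
  abort_if(!nrow(table), "empty checkpoint table")
  abort_if(any(diff(table$step) <= 0), "steps must be strictly increasing")
  pool <- table[table$format_adherence >= 1, , drop = FALSE]
  if (!nrow(pool)) {
    warning("no checkpoint reached full format adherence; falling back to max AUC")
    pool <- table
  }
  ord <- order(-pool$auc, -pool$f1, -pool$step)
  pool$step[ord[1]]
}

fit_predict_baseline <- function(name, x_tr, y_tr, x_ev, seed) {
  set.seed(as.integer(seed))
  y01 <- as.integer(y_tr == "approved")
  mu <- colMeans(x_tr); sg <- apply(x_tr, 2, stats::sd); sg[sg == 0] <- 1
  z_tr <- scale(x_tr, mu, sg); z_ev <- scale(x_ev, mu, sg)
  switch(name,
    logistic = {
      df <- data.frame(z_tr); df$.y <- y01
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      as.numeric(predict(fit, newdata = data.frame(z_ev), type = "response"))
    },
    svm = {
      fit <- e1071::svm(x = z_tr, y = factor(y01, levels = c(0, 1)),
                        kernel = "radial", probability = TRUE)
      pr <- attr(predict(fit, z_ev, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    knn = {
      k <- 5L
      pred <- class::knn(z_tr, z_ev, factor(y01), k = k, prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(x_tr), label = y01, nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              eval_metric = "logloss", max_depth = 4,
                                              eta = 0.2, nthread = 1,
                                              seed = as.integer(seed)),
                                data = dtr, nrounds = 60, verbose = 0)
      as.numeric(predict(fit, as.matrix(x_ev)))
    },
    stop("unknown baseline: ", name))
}

#' Run the four conventional baselines
#'
#' Logistic regression, radial SVM, 5-NN and XGBoost, trained on the given
#' feature matrix with fixed seeds, thresholded at probability 0.5.
#'
#' @param features Numeric feature matrix (rows = molecules). By default
#'   the 11-descriptor vectors; embeddings can be passed instead.
#' @param labels Approval labels aligned with rows.
#' @param train_idx,eval_idx Row indices of the training and evaluation
#'   splits.
#' @param seed Integer seed.
#' @return Named list of four `eval_report`s (with `auc` set).
#' @export
run_baselines <- function(features, labels, train_idx, eval_idx, seed = 1L) {
  features <- as.matrix(features)
  abort_if(any(!is.finite(features)), "non-finite feature values")
  abort_if(length(unique(labels[train_idx])) < 2L, "training split is single-class")
  keep <- apply(features[train_idx, , drop = FALSE], 2, function(col) stats::sd(col) > 0)
  abort_if(!any(keep), "degenerate features: no column varies on the training split")
  x_tr <- features[train_idx, keep, drop = FALSE]
  x_ev <- features[eval_idx, keep, drop = FALSE]
  out <- lapply(c(logistic = "logistic", svm = "svm", knn = "knn", xgboost = "xgboost"),
                function(nm) {
    prob <- fit_predict_baseline(nm, x_tr, labels[train_idx], x_ev, seed)
    pred <- ifelse(prob > 0.5, "approved", "unapproved")
    rep <- confusion_metrics(labels[eval_idx], pred)
    rep$auc <- auc_score(labels[eval_idx], prob)
    rep
  })
  out
}

#' Score the drug-likeness gates as classifiers
#'
#' Maps Ghose pass and QED > 0.5 to approved for metric computation.
#'
#' @param features Featurized table from [featurize_molecules()].
#' @param labels Approval labels aligned with rows.
#' @return List of two `eval_report`s (`ghose`, `qed`), AUC for QED from
#'   its continuous score, for Ghose from the binary gate.
#' @export
run_druglikeness_comparators <- function(features, labels) {
  ghose_pred <- ifelse(features$ghose_pass, "approved", "unapproved")
  qed_pred <- ifelse(qed_druglike(features$qed), "approved", "unapproved")
  ghose <- confusion_metrics(labels, ghose_pred)
  ghose$auc <- auc_score(labels, as.numeric(features$ghose_pass))
  qed <- confusion_metrics(labels, qed_pred)
  qed$auc <- auc_score(labels, features$qed)
  list(ghose = ghose, qed = qed)
}

#' Run one ablation configuration
#'
#' `no_neighbors` rebuilds the prompts without the comparative block and
#' evaluates the rule-based responder on them; `direct_gbt` classifies the
#' molecular embeddings directly with the boosted-tree ensemble (no
#' reasoning stage); `direct_logistic` does the same with an L2-regularized
#' linear logistic classifier.
#'
#' @param config One of `"no_neighbors"`, `"direct_gbt"`,
#'   `"direct_logistic"`.
#' @param data List of pipeline artifacts: `features`, `labels`,
#'   `train_idx`, `eval_idx`, and for the direct modes `embeddings`; for
#'   `no_neighbors` the featurized table and neighbor sets.
#' @param seed Integer seed.
#' @return List with `report` (an `eval_report`) and mode-specific
#'   artifacts (`prompts` for `no_neighbors`).
#' @export
run_ablation <- function(config = c("no_neighbors", "direct_gbt", "direct_logistic"),
                         data, seed = 1L) {
  config <- match.arg(config)
  if (config == "no_neighbors") {
    abort_if(is.null(data$features), "ablation 'no_neighbors': missing stage artifact 'features'")
    idx <- data$eval_idx
    prompts <- lapply(idx, function(i) {
      build_prompt(data$features[i, , drop = FALSE], ablate_neighbors = TRUE,
                   candidate_id = data$features$id[i])
    })
    responses <- vapply(idx, function(i) {
      heuristic_response(data$features[i, , drop = FALSE], neighbors = NULL)
    }, character(1))
    rep <- evaluate_responses(data$labels[idx], responses)
    return(list(report = rep, prompts = prompts, responses = responses))
  }
  abort_if(is.null(data$embeddings), "ablation '", config,
           "': missing stage artifact 'embeddings'")
  x <- data$embeddings
  y01 <- as.integer(data$labels == "approved")
  set.seed(as.integer(seed))
  prob <- if (config == "direct_gbt") {
    dtr <- xgboost::xgb.DMatrix(x[data$train_idx, , drop = FALSE],
                                label = y01[data$train_idx], nthread = 1)
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            eval_metric = "logloss", max_depth = 4,
                                            eta = 0.2, nthread = 1, seed = as.integer(seed)),
                              data = dtr, nrounds = 60, verbose = 0)
    as.numeric(predict(fit, x[data$eval_idx, , drop = FALSE]))
  } else {
    # ridge-logistic on embeddings: high-dimensional, so penalized for stability
    fit <- suppressWarnings(glm_ridge(x[data$train_idx, , drop = FALSE],
                                      y01[data$train_idx], lambda = 1e-2))
    glm_ridge_predict(fit, x[data$eval_idx, , drop = FALSE])
  }
  pred <- ifelse(prob > 0.5, "approved", "unapproved")
  rep <- confusion_metrics(data$labels[data$eval_idx], pred)
  rep$auc <- auc_score(data$labels[data$eval_idx], prob)
  list(report = rep)
}

# small ridge-penalized logistic regression via IRLS (closed-form inner solve)
glm_ridge <- function(x, y, lambda = 1e-2, maxit = 50L, tol = 1e-8) {
  x1 <- cbind(1, x)
  b <- numeric(ncol(x1))
  pen <- diag(c(0, rep(lambda, ncol(x))))
  for (it in seq_len(maxit)) {
    eta <- drop(x1 %*% b)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-8)
    z <- eta + (y - p) / w
    bn <- solve(crossprod(x1 * sqrt(w)) + pen, crossprod(x1, w * z))
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  list(coef = drop(b))
}

glm_ridge_predict <- function(fit, x) {
  1 / (1 + exp(-drop(cbind(1, x) %*% fit$coef)))
}
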