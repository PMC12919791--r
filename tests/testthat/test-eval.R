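test_that("confusion metrics reproduce the hand-computed oracle", {
  truth <- c(rep("approved", 10), rep("unapproved", 10))
  pred <- c(rep("approved", 7), rep("unapproved", 3),   # TP = 7, FN = 3
            rep("approved", 2), rep("unapproved", 8))   # FP = 2, TN = 8
  r <- confusion_metrics(truth, pred)
  expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(7, 3, 8, 2))
  expect_equal(r$recall, 0.700, tolerance = 5e-4)
  expect_equal(r$specificity, 0.800, tolerance = 5e-4)
  expect_equal(r$precision, 0.778, tolerance = 5e-4)
  expect_equal(r$accuracy, 0.750, tolerance = 5e-4)
  expect_equal(r$f1, 0.737, tolerance = 5e-4)
  expect_equal(r$n_pos, 10); expect_equal(r$n_neg, 10)
  # consistency with the stored counts
  expect_equal(r$accuracy, (r$tp + r$tn) / (r$n_pos + r$n_neg))
  # perfect and all-positive predictors
  p <- confusion_metrics(truth, truth)
  expect_equal(c(p$accuracy, p$recall, p$precision, p$specificity, p$f1),
               rep(1, 5))
  ap <- confusion_metrics(truth, rep("approved", 20))
  expect_equal(ap$specificity, 0)
  expect_equal(ap$recall, 1)
  expect_error(confusion_metrics(rep("approved", 5), rep("approved", 5)),
               "single-class")
})

test_that("rank AUC matches the exhaustive pairwise oracle up to n = 50", {
  expect_equal(auc_score(c("approved", "approved", "unapproved", "unapproved"),
                         c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auc_score(c("approved", "unapproved"), c(0.5, 0.5)), 0.5)
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    truth <- sample(c("approved", "unapproved"), n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("approved", "unapproved")
    prob <- round(runif(n), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    expect_equal(auc_score(truth, prob), brute_force_auc(truth, prob),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(rep("approved", 4), runif(4)), "single-class")
})

test_that("label + confidence map to an approval probability by convention", {
  expect_equal(response_to_probability(parse_response(compliant_response("approved", 0.9))), 0.9)
  expect_equal(response_to_probability(parse_response(compliant_response("unapproved", 0.9))), 0.1)
  expect_equal(response_to_probability(parse_response("garbled")), 0.5)
})

test_that("checkpoint selection gates on adherence before AUC, F1, recency", {
  tab <- data.frame(step = c(500, 1000), auc = c(0.7, 0.7),
                    f1 = c(0.6, 0.8), format_adherence = c(1, 1))
  expect_equal(select_checkpoint(tab), 1000)          # AUC tie -> higher F1
  one <- data.frame(step = 500, auc = 0.5, f1 = 0.4, format_adherence = 1)
  expect_equal(select_checkpoint(one), 500)
  gated <- data.frame(step = c(500, 1000), auc = c(0.6, 0.9),
                      f1 = c(0.6, 0.9), format_adherence = c(1, 0.9))
  expect_equal(select_checkpoint(gated), 500)         # full adherence wins
  none <- data.frame(step = c(500, 1000), auc = c(0.6, 0.9),
                     f1 = c(0.6, 0.9), format_adherence = c(0.8, 0.9))
  expect_warning(sel <- select_checkpoint(none), "adherence")
  expect_equal(sel, 1000)
  expect_error(select_checkpoint(none[0, ]), "empty")
})

test_that("all four baselines separate the planted noiseless fixture", {
  fx <- fixture_400()
  feats <- as.matrix(fx$descriptors[molapprove:::DESCRIPTOR_FIELDS])
  set.seed(1)
  idx <- sample(nrow(feats))
  tr <- idx[1:300]; ev <- idx[301:400]
  reps <- run_baselines(feats, fx$records$label, tr, ev, seed = 2)
  expect_named(reps, c("logistic", "svm", "knn", "xgboost"))
  for (nm in names(reps)) expect_gt(reps[[nm]]$auc, 0.9)
  # determinism
  reps2 <- run_baselines(feats, fx$records$label, tr, ev, seed = 2)
  expect_identical(reps, reps2)
})

test_that("label-permuted features score near chance", {
  fx <- fixture_400()
  feats <- as.matrix(fx$descriptors[molapprove:::DESCRIPTOR_FIELDS])
  set.seed(9)
  perm_labels <- sample(fx$records$label)
  idx <- sample(nrow(feats))
  reps <- run_baselines(feats, perm_labels, idx[1:300], idx[301:400], seed = 3)
  for (nm in names(reps)) {
    expect_gt(reps[[nm]]$auc, 0.35)
    expect_lt(reps[[nm]]$auc, 0.65)
  }
})

test_that("drug-likeness comparators produce reproducible classifier reports", {
  fx <- fixture_400()
  rec <- fx$records[c(1:60, 201:260), ]   # both classes represented
  feat <- memo("feat120", function() featurize_molecules(rec))
  r1 <- run_druglikeness_comparators(feat, rec$label)
  r2 <- run_druglikeness_comparators(feat, rec$label)
  expect_identical(r1, r2)
  expect_named(r1, c("ghose", "qed"))
  expect_true(all(c(r1$qed$auc, r1$ghose$auc) >= 0 & c(r1$qed$auc, r1$ghose$auc) <= 1))
})

test_that("ablation configurations are structurally distinct and complete", {
  fx <- fixture_400()
  rec <- fx$records[c(1:60, 201:260), ]
  feat <- memo("feat120", function() featurize_molecules(rec))
  emb <- mock_encode(rec$smiles, d = 64)
  set.seed(2)
  idx <- sample(120)
  data <- list(features = feat, labels = rec$label, embeddings = emb,
               train_idx = idx[1:90], eval_idx = idx[91:120])
  nn <- run_ablation("no_neighbors", data, seed = 1)
  expect_true(all(!vapply(nn$prompts, function(p) grepl("NEIGHBOR", p$user_text), TRUE)))
  expect_s3_class(nn$report, "eval_report")
  gbt <- run_ablation("direct_gbt", data, seed = 1)
  expect_gt(gbt$report$auc, 0.5)
  lg <- run_ablation("direct_logistic", data, seed = 1)
  for (f in c("accuracy", "recall", "precision", "specificity", "f1", "auc"))
    expect_true(is.finite(lg$report[[f]]), info = f)
  expect_error(run_ablation("direct_gbt", data[setdiff(names(data), "embeddings")]),
               "embeddings")
})
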