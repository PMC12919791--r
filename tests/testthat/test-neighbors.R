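test_that("Hamming distance satisfies the metric axioms on leaf vectors", {
  expect_equal(hamming(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(hamming(c(1, 2, 3), c(1, 5, 3)), 1)
  set.seed(2)
  for (i in 1:50) {
    u <- sample(10, 8, TRUE); v <- sample(10, 8, TRUE); w <- sample(10, 8, TRUE)
    expect_gte(hamming(u, v), 0)
    expect_equal(hamming(u, v), hamming(v, u))
    expect_equal(hamming(u, v) == 0, identical(u, v))
    expect_lte(hamming(u, w), hamming(u, v) + hamming(v, w))
  }
  expect_error(hamming(1:3, 1:4), "equal length")
})

test_that("similarity model training is deterministic and better than chance", {
  lv <- corpus_200_leaves()
  co <- corpus_200()
  emb <- corpus_200_embeddings()
  # training log-loss on the planted noiseless task beats an uninformed model
  p <- predict(lv$model$booster, emb)
  y <- as.integer(co$records$label == "approved")
  ll <- -mean(y * log(pmax(p, 1e-15)) + (1 - y) * log(pmax(1 - p, 1e-15)))
  expect_lt(ll, log(2))
  # same seed, same search trajectory
  m2 <- fit_similarity_model(emb, co$records$label,
                             search_space(n_trials = 12, nrounds_max = 40), seed = 5)
  expect_identical(m2$trials, lv$model$trials)
  expect_identical(leaf_embedding(m2, emb), lv$leaves)
})

test_that("a degenerate one-trial search still yields a valid model", {
  idx <- c(1:30, 101:130)  # 30 approved + 30 unapproved
  emb <- corpus_200_embeddings()[idx, ]
  lab <- corpus_200()$records$label[idx]
  m <- fit_similarity_model(emb, lab, search_space(n_trials = 1, nrounds_max = 20),
                            seed = 2)
  expect_equal(nrow(m$trials), 1)
  expect_s3_class(m$trials, "data.frame")
  p <- predict(m$booster, emb)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fit_similarity_model(emb, rep("approved", 60),
                                    search_space(n_trials = 1), 1),
               "both classes")
})

test_that("leaf embeddings are deterministic with one index per tree", {
  lv <- corpus_200_leaves()
  emb <- corpus_200_embeddings()
  l1 <- leaf_embedding(lv$model, emb[3, ])
  expect_identical(l1, leaf_embedding(lv$model, emb[3, ]))
  expect_equal(ncol(l1), lv$model$n_trees)
  # identical inputs land in identical leaves
  two <- leaf_embedding(lv$model, emb[c(3, 3), ])
  expect_equal(hamming(two[1, ], two[2, ]), 0)
  expect_error(leaf_embedding(lv$model, emb[1, 1:10]), "dimension")
})

test_that("top-k retrieval matches the brute-force scan with the same tie rule", {
  lv <- corpus_200_leaves()
  set.seed(31)
  for (qi in sample(nrow(lv$leaves), 15)) {
    got <- top_k_neighbors(lv$leaves[qi, ], lv$leaves, lv$labels, lv$ids,
                           k = 5, exclude_id = lv$ids[qi])
    want <- brute_force_neighbors(lv$leaves[qi, ], lv$leaves, lv$labels, lv$ids,
                                  k = 5, exclude_id = lv$ids[qi])
    expect_identical(got, want)
    expect_false(lv$ids[qi] %in% c(got$approved$id, got$unapproved$id))
  }
})

test_that("a corpus copy of the query is retrieved first at distance zero", {
  lv <- corpus_200_leaves()
  q <- lv$leaves[7, ]   # id not excluded: query mode
  got <- top_k_neighbors(q, lv$leaves, lv$labels, lv$ids, k = 5)
  lb <- lv$labels[7]
  expect_equal(got[[lb]]$distance[1], 0)
  expect_equal(got[[lb]]$id[1], lv$ids[7])
})

test_that("query mode and self mode agree when the query is absent", {
  lv <- corpus_200_leaves()
  keep <- 2:nrow(lv$leaves)
  q <- lv$leaves[1, ]
  a <- top_k_neighbors(q, lv$leaves[keep, ], lv$labels[keep], lv$ids[keep], k = 5)
  b <- top_k_neighbors(q, lv$leaves[keep, ], lv$labels[keep], lv$ids[keep], k = 5,
                       exclude_id = lv$ids[1])
  expect_identical(a, b)
})

test_that("insufficient per-class corpus is rejected with the class named", {
  lv <- corpus_200_leaves()
  few <- which(lv$labels == "approved")[1:3]
  idx <- c(few, which(lv$labels == "unapproved"))
  expect_error(
    top_k_neighbors(lv$leaves[1, ], lv$leaves[idx, ], lv$labels[idx], lv$ids[idx], k = 5),
    "approved")
})

test_that("similarity models survive a save/load round trip", {
  lv <- corpus_200_leaves()
  dir <- tempfile("simmodel_")
  save_similarity_model(lv$model, dir)
  back <- load_similarity_model(dir)
  emb <- corpus_200_embeddings()
  expect_identical(leaf_embedding(back, emb[1:10, ]),
                   leaf_embedding(lv$model, emb[1:10, ]))
})
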