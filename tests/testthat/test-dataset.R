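test_that("canonicalization is a fixed point and merges equivalent notations", {
  s <- c("C(C)O", "CCO", "c1ccccc1", "C1=CC=CC=C1")
  can <- canonicalize_smiles(s)
  expect_identical(canonicalize_smiles(can), can)
  expect_identical(can[1], can[2])
  expect_identical(can[3], can[4])
  expect_error(canonicalize_smiles("C1CC"), "C1CC")
  expect_error(canonicalize_smiles(c("CCO", "C1CC")), "C1CC")
})

test_that("undersampling balances to the minority count without duplicating ids", {
  rec <- molecule_records(sprintf("m%d", 1:35), sprintf("s%d", 1:35),
                          c(rep("approved", 10), rep("unapproved", 25)))
  bal <- balance_undersample(rec, seed = 7)
  expect_equal(as.integer(table(bal$label)["approved"]), 10)
  expect_equal(as.integer(table(bal$label)["unapproved"]), 10)
  expect_false(anyDuplicated(bal$id) > 0)
  # already balanced input: identical id multiset
  bal2 <- balance_undersample(bal, seed = 3)
  expect_setequal(bal2$id, bal$id)
  # determinism
  expect_identical(balance_undersample(rec, seed = 7)$id, bal$id)
  # single class rejected
  expect_error(balance_undersample(rec[rec$label == "unapproved", ], 1), "both classes")
})

test_that("stratified split is exact on divisible input and always a partition", {
  rec <- molecule_records(sprintf("m%d", 1:200), sprintf("s%d", 1:200),
                          rep(c("approved", "unapproved"), each = 100))
  sp <- stratified_split(rec, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(as.integer(table(sp$split)[c("train", "validation", "test")]),
               c(160L, 20L, 20L))
  tab <- table(sp$label, sp$split)
  expect_true(all(tab[, "train"] == 80), all(tab[, "validation"] == 10))
  # partition property across 100 seeds
  for (seed in 1:100) {
    s <- stratified_split(rec, seed = seed)
    expect_setequal(s$id, rec$id)
    expect_true(all(s$split %in% c("train", "validation", "test")))
    tab_s <- table(s$label, s$split)[, c("train", "validation", "test")]
    target <- matrix(rep(c(80, 10, 10), each = 2), nrow = 2)
    expect_true(all(abs(tab_s - target) <= 1))
  }
  # seed change: same sizes, different membership
  s2 <- stratified_split(rec, seed = 2)
  expect_equal(table(s2$split), table(sp$split))
  expect_false(identical(s2$split, sp$split))
  expect_error(stratified_split(rec, c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("external-overlap removal keys on canonical SMILES equality", {
  internal <- molecule_records(sprintf("i%d", 1:30), sprintf("CS%d", 1:30),
                               rep(c("approved", "unapproved"), 15))
  external <- molecule_records(sprintf("e%d", 1:20),
                               c(sprintf("CS%d", c(3, 11, 22)), sprintf("EX%d", 1:17)),
                               rep("approved", 20))
  kept <- remove_overlap(external, internal)
  expect_equal(nrow(kept), 17)
  expect_false(any(kept$smiles %in% internal$smiles))
  # disjoint sets unchanged; subset empties
  expect_equal(nrow(remove_overlap(external[4:20, ], internal)), 17)
  expect_equal(nrow(remove_overlap(internal[1:5, ], internal)), 0)
})

test_that("fixture generator is deterministic, parseable, and rule-faithful", {
  rec <- generate_fixture(25, seed = 3, noise = 0)
  rec2 <- generate_fixture(25, seed = 3, noise = 0)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_molecules(rec, f1); write_molecules(rec2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.integer(table(rec$label)), c(25L, 25L))
  expect_false(anyDuplicated(rec$smiles) > 0)
  # every emitted SMILES parses and is already canonical
  expect_identical(canonicalize_smiles(rec$smiles), rec$smiles)
  # noise 0: labels recoverable from the planted descriptor rule
  desc <- compute_descriptors(rec$smiles)
  expect_identical(molapprove:::fixture_rule_label(desc), rec$label)
})

test_that("fixture label flips hit the stated rate exactly", {
  rec <- generate_fixture(40, seed = 5, noise = 0.2)
  desc <- compute_descriptors(rec$smiles)
  agree <- mean(molapprove:::fixture_rule_label(desc) == rec$label)
  expect_equal(agree, 1 - 0.2, tolerance = 1e-12)
  expect_equal(as.integer(table(rec$label)), c(40L, 40L))
  expect_error(generate_fixture(10, noise = 0.5), "noise")
})

test_that("molecule CSV round-trips and drops duplicate structures on read", {
  rec <- generate_fixture(12, seed = 9, noise = 0)
  f <- tempfile(fileext = ".csv")
  write_molecules(rec, f)
  back <- read_molecules(f)
  expect_identical(back$smiles, rec$smiles)
  dup <- rbind(rec, within(rec[1, ], id <- "dup1"))
  write_molecules(dup, f)
  expect_warning(back2 <- read_molecules(f), "duplicate")
  expect_equal(nrow(back2), nrow(rec))
})
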