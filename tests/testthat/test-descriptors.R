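test_that("descriptor values match hand-counted anchors", {
  asp <- compute_descriptors("CC(=O)OC1=CC=CC=C1C(=O)O")
  expect_equal(asp$heavy_atoms, 13L)         # C9H8O4, non-hydrogen atoms
  expect_equal(asp$hbd, 1L)                  # one carboxylic OH
  expect_equal(asp$ring_count, 1L)
  expect_equal(asp$formal_charge, 0L)
  expect_equal(asp$chiral_centers, 0L)
  expect_equal(asp$molecular_weight, 180.157, tolerance = 1e-3)
  meth <- compute_descriptors("C")
  expect_equal(meth$ring_count, 0L)
  expect_equal(meth$rotatable_bonds, 0L)
  expect_equal(meth$formal_charge, 0L)
  # alanine has one stereocenter (unassigned included), a quaternary
  # ammonium carries +1
  expect_equal(compute_descriptors("CC(N)C(=O)O")$chiral_centers, 1L)
  expect_equal(compute_descriptors("C[N+](C)(C)C")$formal_charge, 1L)
  expect_equal(compute_descriptors("CC(=O)[O-]")$formal_charge, -1L)
  expect_error(compute_descriptors("C1CC"), "C1CC")
})

test_that("descriptor computation is deterministic", {
  smi <- corpus_200()$records$smiles[1:20]
  expect_identical(compute_descriptors(smi), compute_descriptors(smi))
})

test_that("structural invariants hold across the fixture corpus", {
  d <- corpus_200()$descriptors
  expect_true(all(d$molecular_weight > 0))
  counts <- c("hbd", "hba", "rotatable_bonds", "chiral_centers", "heavy_atoms",
              "ring_count")
  for (f in counts) expect_true(all(d[[f]] >= 0), info = f)
  expect_true(all(d$heavy_atoms >= d$ring_count))
})

test_that("alert screening flags known bad actors and keeps clean molecules clean", {
  al <- structural_alerts(c("CCO", "O=[N+]([O-])c1ccccc1", "O=C1C=CC(=O)C=C1"))
  expect_equal(al$pains_hits[1], 0L)
  expect_equal(al$brenk_hits[1], 0L)
  expect_true(al$brenk_flag[2])              # nitro group
  expect_true(al$pains_flag[3])              # quinone core
  expect_identical(al$pains_flag, al$pains_hits > 0L)
  expect_identical(al$brenk_flag, al$brenk_hits > 0L)
})

test_that("alert catalogs are installed in full", {
  expect_equal(nrow(load_alert_catalog("pains")), 480L)
  expect_equal(nrow(load_alert_catalog("brenk")), 116L)
})

test_that("the Ghose gate equals its four-condition conjunction", {
  asp <- compute_descriptors("CC(=O)OC1=CC=CC=C1C(=O)O")
  oracle <- function(d) {
    d$molecular_weight >= 160 & d$molecular_weight <= 480 &
      d$logp >= -0.4 & d$logp <= 5.6 &
      d$molar_refractivity >= 40 & d$molar_refractivity <= 130 &
      d$total_atoms >= 20 & d$total_atoms <= 70
  }
  expect_identical(ghose_filter(asp), oracle(asp))
  # out-of-range weight fails regardless of the rest
  big <- asp; big$molecular_weight <- 1000
  expect_false(ghose_filter(big))
  # inclusive endpoints
  edge <- data.frame(molecular_weight = 160, logp = -0.4,
                     molar_refractivity = 130, total_atoms = 70)
  expect_true(ghose_filter(edge))
  # oracle equivalence over 1000 random descriptor vectors
  set.seed(42)
  rnd <- data.frame(molecular_weight = runif(1000, 50, 900),
                    logp = runif(1000, -4, 9),
                    molar_refractivity = runif(1000, 10, 200),
                    total_atoms = sample(5:120, 1000, TRUE))
  expect_identical(ghose_filter(rnd), oracle(rnd))
})

test_that("the QED gate is strict at 0.5 and monotone", {
  expect_true(qed_druglike(0.51))
  expect_false(qed_druglike(0.50))
  expect_false(qed_druglike(0.0))
  expect_error(qed_druglike(1.2), "\\[0, 1\\]")
  s <- sort(runif(200))
  expect_true(all(diff(as.integer(qed_druglike(s))) >= 0))
})

test_that("QED scores live in [0,1] and penalize alert-laden molecules", {
  smi <- c("CC(=O)Oc1ccccc1C(=O)O",               # clean, drug-sized
           "O=[N+]([O-])c1ccc(N=Nc2ccccc2)cc1")   # nitro + azo alerts
  d <- compute_descriptors(smi)
  a <- structural_alerts(smi)
  q <- qed_score(d, a)
  expect_true(all(q >= 0 & q <= 1))
  expect_gt(q[1], q[2])
})

test_that("featurize emits one complete row per molecule", {
  rec <- corpus_200()$records[1:10, ]
  feat <- featurize_molecules(rec)
  expect_equal(nrow(feat), 10)
  expect_true(all(c(molapprove:::DESCRIPTOR_FIELDS, "pains_hits", "brenk_hits",
                    "qed", "ghose_pass") %in% names(feat)))
  expect_identical(feat$id, rec$id)
})
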