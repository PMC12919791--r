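test_that("correctness pays 2.0 only for a valid matching label", {
  expect_equal(reward_correctness(compliant_response("approved"), "approved"), 2.0)
  expect_equal(reward_correctness(compliant_response("unapproved"), "approved"), 0.0)
  expect_equal(reward_correctness(compliant_response("maybe"), "approved"), 0.0)
  expect_equal(reward_correctness("", "approved"), 0.0)
})

test_that("strict XML reward pays 0.125 per singular, ordered tag", {
  full <- compliant_response()
  expect_equal(reward_xml_format(full), 0.75)
  expect_equal(reward_xml_format(""), 0.0)
  # deleting </score> forfeits exactly one tag's credit
  expect_equal(reward_xml_format(sub("</score>", "", full, fixed = TRUE)), 0.625)
  # each single-tag deletion lowers the reward
  for (tag in molapprove:::XML_TAG_SEQUENCE) {
    expect_lt(reward_xml_format(sub(tag, "", full, fixed = TRUE)), 0.75)
  }
  # duplicated tags earn nothing for that tag
  expect_equal(reward_xml_format(paste0(full, "<score>")), 0.625)
  # out-of-order pairs lose their credit
  swapped <- "<label>approved</label><think>x</think><score>0.9</score>"
  expect_lt(reward_xml_format(swapped), 0.75)
})

test_that("soft format tolerates padding but requires all three pairs", {
  padded <- paste0("Sure! Here is my answer:\n", compliant_response(), "\n  \n")
  expect_equal(reward_soft_format(padded), 0.5)
  no_label <- "<think>x</think><score>0.9</score>"
  expect_equal(reward_soft_format(no_label), 0.0)
  expect_equal(reward_soft_format(""), 0.0)
  # reordered but complete pairs still pass the soft check
  reordered <- "<label>approved</label><think>x</think><score>0.9</score>"
  expect_equal(reward_soft_format(reordered), 0.5)
})

test_that("interpretability pays 0.5 for any semantically valid label", {
  expect_equal(reward_interpretability(compliant_response("approved")), 0.5)
  expect_equal(reward_interpretability(compliant_response("unapproved")), 0.5)
  expect_equal(reward_interpretability(compliant_response("maybe")), 0.0)
  expect_equal(reward_interpretability(""), 0.0)
})

test_that("confidence alignment follows the six-cell schedule with inclusive 0.7", {
  resp <- function(lb, sc) compliant_response(lb, sc)
  expect_equal(reward_confidence_alignment(resp("approved", 0.9), "approved"), 2.0)
  expect_equal(reward_confidence_alignment(resp("approved", 0.7), "approved"), 2.0)
  expect_equal(reward_confidence_alignment(resp("approved", 0.5), "approved"), 1.0)
  expect_equal(reward_confidence_alignment(resp("approved", 0.2), "approved"), 0.0)
  expect_equal(reward_confidence_alignment(resp("unapproved", 0.2), "approved"), 1.0)
  expect_equal(reward_confidence_alignment(resp("unapproved", 0.5), "approved"), 0.5)
  expect_equal(reward_confidence_alignment(resp("unapproved", 0.9), "approved"), 0.0)
  # absent score or invalid label: worst case
  expect_equal(reward_confidence_alignment("<label>approved</label>", "approved"), 0.0)
  expect_equal(reward_confidence_alignment(resp("maybe", 0.2), "approved"), 0.0)
})

test_that("the ideal completion totals 5.75 and components always sum", {
  ideal <- total_reward(compliant_response("approved", 0.9), "approved")
  expect_equal(ideal$total, 5.75)
  expect_equal(ideal$total, 2.0 + 0.75 + 0.5 + 0.5 + 2.0)
  expect_equal(total_reward("", "approved")$total, 0.0)
})

test_that("every component stays on its declared grid under fuzzing", {
  set.seed(123)
  grids <- list(correctness = c(0, 2), soft_format = c(0, 0.5),
                interpretability = c(0, 0.5),
                confidence_alignment = c(0, 0.5, 1, 2),
                xml_format = seq(0, 0.75, by = 0.125))
  scored <- do.call(rbind, lapply(1:10000, function(i) {
    total_reward(random_completion(), sample(c("approved", "unapproved"), 1))
  }))
  for (comp in names(grids)) {
    expect_true(all(scored[[comp]] %in% grids[[comp]]), info = comp)
  }
  expect_equal(scored$total,
               scored$correctness + scored$xml_format + scored$soft_format +
                 scored$interpretability + scored$confidence_alignment)
  expect_true(all(scored$total >= 0 & scored$total <= 5.75))
})

test_that("deleting an ordered singular tag lowers the strict XML reward by 0.125", {
  # schema-ordered responses with random tag subsets and filler: every
  # present tag is singular and correctly placed, so each deletion forfeits
  # exactly that tag's credit
  set.seed(5)
  for (i in 1:200) {
    present <- sort(sample(6, sample(1:6, 1)))
    filler <- function() paste(sample(c(letters, " "), sample(0:4, 1), TRUE), collapse = "")
    raw <- paste0(vapply(molapprove:::XML_TAG_SEQUENCE[present],
                         function(t) paste0(t, filler()), ""), collapse = "")
    base <- reward_xml_format(raw)
    expect_equal(base, 0.125 * length(present))
    for (tag in molapprove:::XML_TAG_SEQUENCE[present]) {
      expect_equal(reward_xml_format(sub(tag, "", raw, fixed = TRUE)),
                   base - 0.125)
    }
  }
})

test_that("batch scoring aligns completions with their truths", {
  out <- score_responses(c(compliant_response("approved", 0.9), ""),
                         c("approved", "unapproved"), ids = c("a", "b"))
  expect_equal(out$total, c(5.75, 0))
  expect_equal(out$id, c("a", "b"))
})
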