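# The five verifiable reward functions and their exact scalar schedule.
# Component maxima: correctness 2.0, XML format 0.75 (6 x 0.125), soft
# format 0.5, interpretability 0.5, confidence alignment 2.0 -> total 5.75.

REWARD_MAX_TOTAL <- 5.75

as_parsed <- function(x) {
  if (is.character(x)) parse_response(x) else x
}

#' Correctness reward
#'
#' 2.0 iff the parsed label is valid and equals the ground truth, else 0.0.
#'
#' @param response Raw completion text or a [parse_response()] result.
#' @param truth Ground-truth label, `"approved"` or `"unapproved"`.
#' @return Scalar in \{0, 2\}.
#' @export
reward_correctness <- function(response, truth) {
  abort_if(!truth %in% APPROVAL_LABELS, "`truth` must be approved/unapproved")
  p <- as_parsed(response)
  if (isTRUE(p$label_valid) && identical(p$label, truth)) 2.0 else 0.0
}

# positions of singular tags in schema order; a tag earns its 0.125 iff it
# occurs exactly once and sits after every singular schema predecessor and
# before every singular schema successor
XML_TAG_SEQUENCE <- c("<think>", "</think>", "<label>", "</label>", "<score>", "</score>")

#' Strict XML-format reward
#'
#' Each of the six schema tags (three opens, three closes) contributes 0.125
#' when present exactly once and correctly placed relative to the other
#' singular tags, for a maximum of 0.75. A tag appearing more than once
#' earns nothing for that tag.
#'
#' @param raw Completion text.
#' @return Scalar in \{0, 0.125, ..., 0.75\}.
#' @export
reward_xml_format <- function(raw) {
  abort_if(!is.character(raw) || length(raw) != 1L, "`raw` must be a single string")
  pos <- lapply(XML_TAG_SEQUENCE, function(tag) {
    m <- gregexpr(tag, raw, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  })
  # close tags also match inside open-tag scans? "<think>" never contains
  # "</think>"; but "</think>" contains "<think>"? No ("</" prefix differs).
  # "<think>" occurrences do count matches inside "</think>"? The substring
  # "<think>" is not part of "</think>" ("/t" breaks it), so counts are exact.
  singular <- vapply(pos, function(p) length(p) == 1L, logical(1))
  credit <- 0
  for (i in seq_along(XML_TAG_SEQUENCE)) {
    if (!singular[i]) next
    p <- pos[[i]][1]
    ok <- TRUE
    for (j in seq_along(XML_TAG_SEQUENCE)) {
      if (j == i || !singular[j]) next
      q <- pos[[j]][1]
      if (j < i && q > p) ok <- FALSE
      if (j > i && q < p) ok <- FALSE
    }
    if (ok) credit <- credit + 0.125
  }
  credit
}

#' Soft format-compliance reward
#'
#' 0.5 when the response approximately matches the expected structure: each
#' of the three tag pairs is present and internally well-formed (open before
#' close), tolerating surrounding prose, whitespace and reordering of the
#' pairs; 0.0 when any pair is missing.
#'
#' @param raw Completion text.
#' @return Scalar in \{0, 0.5\}.
#' @export
reward_soft_format <- function(raw) {
  abort_if(!is.character(raw) || length(raw) != 1L, "`raw` must be a single string")
  ok <- vapply(RESPONSE_TAGS, function(t) {
    grepl(sprintf("(?s)<%s>.*?</%s>", t, t), raw, perl = TRUE)
  }, logical(1))
  if (all(ok)) 0.5 else 0.0
}

#' Interpretability reward
#'
#' 0.5 iff the extracted label is semantically valid (approved/unapproved).
#'
#' @param response Raw completion text or a [parse_response()] result.
#' @return Scalar in \{0, 0.5\}.
#' @export
reward_interpretability <- function(response) {
  p <- as_parsed(response)
  if (isTRUE(p$label_valid)) 0.5 else 0.0
}

#' Confidence-alignment reward
#'
#' Scores the consistency of the confidence with the prediction outcome:
#' correct with score >= 0.7 -> 2.0; correct with 0.4 <= score < 0.7 -> 1.0;
#' correct with score < 0.4 -> 0.0; incorrect with score < 0.4 -> 1.0;
#' incorrect with 0.4 <= score < 0.7 -> 0.5; incorrect with score >= 0.7 ->
#' 0.0. An absent or unparseable score, or an invalid label, earns 0.0.
#'
#' @param response Raw completion text or a [parse_response()] result.
#' @param truth Ground-truth label.
#' @return Scalar in \{0, 0.5, 1, 2\}.
#' @export
reward_confidence_alignment <- function(response, truth) {
  abort_if(!truth %in% APPROVAL_LABELS, "`truth` must be approved/unapproved")
  p <- as_parsed(response)
  if (!isTRUE(p$score_valid) || !isTRUE(p$label_valid)) return(0.0)
  correct <- identical(p$label, truth)
  s <- p$score
  if (correct) {
    if (s >= 0.7) 2.0 else if (s >= 0.4) 1.0 else 0.0
  } else {
    if (s < 0.4) 1.0 else if (s < 0.7) 0.5 else 0.0
  }
}

#' Evaluate the full reward schedule on a completion
#'
#' Runs all five reward functions on the same completion and returns the
#' per-component breakdown plus their sum (maximum 5.75).
#'
#' @param raw Completion text.
#' @param truth Ground-truth label.
#' @return One-row `data.frame`: `correctness`, `xml_format`, `soft_format`,
#'   `interpretability`, `confidence_alignment`, `total`.
#' @export
total_reward <- function(raw, truth) {
  p <- parse_response(raw)
  out <- data.frame(
    correctness = reward_correctness(p, truth),
    xml_format = reward_xml_format(raw),
    soft_format = reward_soft_format(raw),
    interpretability = reward_interpretability(p),
    confidence_alignment = reward_confidence_alignment(p, truth))
  out$total <- rowSums(out)
  out
}

#' Score a table of completions
#'
#' @param responses Character vector of completions.
#' @param truth Ground-truth labels, recycled if length 1.
#' @param ids Optional identifiers.
#' @return `data.frame` with one row per completion.
#' @export
score_responses <- function(responses, truth, ids = NULL) {
  truth <- rep_len(truth, length(responses))
  rows <- lapply(seq_along(responses), function(i) total_reward(responses[i], truth[i]))
  out <- do.call(rbind, rows)
  if (!is.null(ids)) out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
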