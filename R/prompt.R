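# Structured comparative prompt construction and three-field XML response
# parsing. The response schema is:
#   <think> reasoning </think> <label> approved|unapproved </label>
#   <score> confidence in [0,1] </score>

RESPONSE_TAGS <- c("think", "label", "score")

# Default system prompt. The deployed model's verbatim instruction block is
# not redistributable; this default implements the same contract (expert
# persona, comparative reasoning over descriptor profiles, strict output
# schema) and can be replaced via `system_text`.
DEFAULT_SYSTEM_PROMPT <- paste(
  "You are an expert medicinal chemist assessing whether a small molecule",
  "is likely to achieve regulatory approval. You are given the computed",
  "physicochemical descriptors and structural-alert flags of a candidate",
  "molecule, together with the descriptors of its five most similar",
  "approved and five most similar unapproved reference molecules.",
  "Reason step by step, comparing the candidate against both reference",
  "groups, then answer using exactly this format:",
  "<think>your comparative reasoning</think>",
  "<label>approved or unapproved</label>",
  "<score>a confidence between 0.0 and 1.0</score>",
  sep = "\n")

PROMPT_DESCRIPTOR_ORDER <- c(
  "molecular_weight", "logp", "tpsa", "hbd", "hba", "rotatable_bonds",
  "molar_refractivity", "chiral_centers", "heavy_atoms", "ring_count",
  "formal_charge")
PROMPT_DESCRIPTOR_UNITS <- c(
  molecular_weight = "Da", logp = "", tpsa = "A^2", hbd = "", hba = "",
  rotatable_bonds = "", molar_refractivity = "", chiral_centers = "",
  heavy_atoms = "", ring_count = "", formal_charge = "")

render_descriptor_block <- function(row, header) {
  vals <- vapply(PROMPT_DESCRIPTOR_ORDER, function(f) {
    abort_if(is.null(row[[f]]), "descriptor field '", f, "' missing from prompt input")
    u <- PROMPT_DESCRIPTOR_UNITS[[f]]
    sprintf("  %s: %s%s", f, formatC(as.numeric(row[[f]]), format = "f", digits = 3),
            if (nzchar(u)) paste0(" ", u) else "")
  }, character(1))
  flags <- character(0)
  if (!is.null(row[["pains_flag"]]) && !is.null(row[["brenk_flag"]])) {
    flags <- c(sprintf("  pains_alert: %s", ifelse(isTRUE(as.logical(row[["pains_flag"]])), "yes", "no")),
               sprintf("  brenk_alert: %s", ifelse(isTRUE(as.logical(row[["brenk_flag"]])), "yes", "no")))
  }
  paste(c(header, vals, flags), collapse = "\n")
}

#' Build a comparative reasoning prompt
#'
#' Serializes the candidate descriptor profile and its five approved / five
#' unapproved neighbor profiles into a deterministic structured prompt.
#' Numeric values are rendered fixed-point with 3 decimals. With
#' `ablate_neighbors = TRUE` the comparative section is omitted entirely.
#'
#' @param candidate One-row descriptor `data.frame` (the 11 descriptors,
#'   optionally `pains_flag`/`brenk_flag`).
#' @param approved,unapproved Descriptor `data.frame`s of exactly 5 rows
#'   each (ignored when ablated).
#' @param ablate_neighbors Drop the comparative block (default `FALSE`).
#' @param candidate_id,approved_ids,unapproved_ids Optional identifiers for
#'   the metadata field.
#' @param system_text Override for the default system prompt.
#' @return List with `system_text`, `user_text`, `metadata`.
#' @export
build_prompt <- function(candidate, approved = NULL, unapproved = NULL,
                         ablate_neighbors = FALSE, candidate_id = NA_character_,
                         approved_ids = NULL, unapproved_ids = NULL,
                         system_text = DEFAULT_SYSTEM_PROMPT) {
  abort_if(nrow(candidate) != 1L, "`candidate` must be a single descriptor row")
  blocks <- render_descriptor_block(candidate[1, ], "[CANDIDATE]")
  if (!ablate_neighbors) {
    abort_if(is.null(approved) || nrow(approved) != 5L,
             "exactly 5 approved neighbors required (got ",
             if (is.null(approved)) 0L else nrow(approved), ")")
    abort_if(is.null(unapproved) || nrow(unapproved) != 5L,
             "exactly 5 unapproved neighbors required (got ",
             if (is.null(unapproved)) 0L else nrow(unapproved), ")")
    for (i in 1:5) blocks <- c(blocks, render_descriptor_block(approved[i, ],
                               sprintf("[APPROVED NEIGHBOR %d]", i)))
    for (i in 1:5) blocks <- c(blocks, render_descriptor_block(unapproved[i, ],
                               sprintf("[UNAPPROVED NEIGHBOR %d]", i)))
  }
  list(system_text = system_text,
       user_text = paste(blocks, collapse = "\n\n"),
       metadata = list(candidate_id = candidate_id,
                       approved_ids = approved_ids,
                       unapproved_ids = unapproved_ids,
                       ablate_neighbors = ablate_neighbors))
}

count_tag <- function(raw, tag) {
  lengths(regmatches(raw, gregexpr(tag, raw, fixed = TRUE)))
}

#' Parse a three-field XML response
#'
#' Total on arbitrary text: never raises. Extracts the first well-formed
#' `<think>`, `<label>` and `<score>` blocks; the label is normalized
#' case-insensitively to approved/unapproved (anything else is marked
#' invalid); the score is parsed as a decimal and marked absent (never
#' clamped) when unparseable or outside `[0, 1]`. Diagnostics record the
#' open/close count of every tag for the reward suite.
#'
#' @param raw Completion text.
#' @return List with `raw`, `think`, `label`, `label_valid`, `score`,
#'   `score_valid` and a `diagnostics` data.frame of tag counts.
#' @export
parse_response <- function(raw) {
  abort_if(!is.character(raw) || length(raw) != 1L, "`raw` must be a single string")
  # strip newlines inside tags is not needed: perl regex with (?s) dotall
  grab <- function(tag) {
    m <- regmatches(raw, regexpr(sprintf("(?s)<%s>(.*?)</%s>", tag, tag), raw, perl = TRUE))
    if (!length(m)) NA_character_
    else sub(sprintf("^<%s>", tag), "", sub(sprintf("</%s>$", tag), "", m))
  }
  think <- grab("think")
  label_raw <- grab("label")
  score_raw <- grab("score")
  label <- NA_character_
  label_valid <- FALSE
  if (!is.na(label_raw)) {
    lr <- tolower(trimws(label_raw))
    if (lr %in% APPROVAL_LABELS) { label <- lr; label_valid <- TRUE }
  }
  score <- NA_real_
  score_valid <- FALSE
  if (!is.na(score_raw)) {
    sv <- suppressWarnings(as.numeric(trimws(score_raw)))
    if (length(sv) == 1L && is.finite(sv) && sv >= 0 && sv <= 1) {
      score <- sv; score_valid <- TRUE
    }
  }
  diagnostics <- data.frame(
    tag = RESPONSE_TAGS,
    n_open = vapply(RESPONSE_TAGS, function(t) count_tag(raw, sprintf("<%s>", t)), integer(1)),
    n_close = vapply(RESPONSE_TAGS, function(t) count_tag(raw, sprintf("</%s>", t)), integer(1)),
    row.names = NULL)
  list(raw = raw, think = think, label = label, label_valid = label_valid,
       score = score, score_valid = score_valid, diagnostics = diagnostics)
}

#' Serialize a well-formed response
#'
#' Inverse of [parse_response()] for compliant responses; used by the toy
#' policy and the tests' round-trip checks.
#'
#' @param think,label,score The three fields.
#' @return A single response string in schema order.
#' @export
render_response <- function(think, label, score) {
  sprintf("<think>%s</think>\n<label>%s</label>\n<score>%s</score>",
          think, label, formatC(score, format = "f", digits = 2))
}
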