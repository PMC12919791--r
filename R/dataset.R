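# Molecule tables are plain data.frames with columns id, smiles, label
# (approved/unapproved) and split (train/validation/test/external/unassigned).

APPROVAL_LABELS <- c("approved", "unapproved")
SPLIT_LEVELS <- c("train", "validation", "test", "external", "unassigned")

#' Construct a molecule-record table
#'
#' @param id Character identifiers (unique).
#' @param smiles Canonical SMILES strings.
#' @param label Approval labels, `"approved"` or `"unapproved"`.
#' @param split Split tags; defaults to `"unassigned"`.
#' @return A `data.frame` with columns `id, smiles, label, split`.
#' @export
molecule_records <- function(id, smiles, label, split = "unassigned") {
  id <- as.character(id)
  label <- tolower(as.character(label))
  abort_if(anyDuplicated(id) > 0L, "duplicate ids in molecule records")
  abort_if(!all(label %in% APPROVAL_LABELS),
           "labels must be one of: ", paste(APPROVAL_LABELS, collapse = ", "))
  split <- rep_len(as.character(split), length(id))
  abort_if(!all(split %in% SPLIT_LEVELS),
           "split tags must be one of: ", paste(SPLIT_LEVELS, collapse = ", "))
  data.frame(id = id, smiles = as.character(smiles), label = label, split = split,
             stringsAsFactors = FALSE)
}

#' Read a molecule table from CSV
#'
#' Expects header `id,smiles,label[,split]`. Labels are case-insensitive on
#' read and lowercased. Duplicate canonical SMILES are dropped with a warning,
#' keeping the first occurrence (parent/child resolution is assumed done
#' upstream).
#'
#' @param path CSV file path.
#' @param canonicalize Re-canonicalize SMILES on read (default `TRUE`).
#' @return Molecule-record `data.frame`.
#' @export
read_molecules <- function(path, canonicalize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("id", "smiles", "label") %in% names(df)),
           "molecule CSV must have columns id, smiles, label")
  if (!"split" %in% names(df)) df$split <- "unassigned"
  if (canonicalize) df$smiles <- canonicalize_smiles(df$smiles)
  dup <- duplicated(df$smiles)
  if (any(dup)) {
    warning(sum(dup), " duplicate canonical SMILES dropped (kept first occurrence)")
    df <- df[!dup, , drop = FALSE]
  }
  molecule_records(df$id, df$smiles, df$label, df$split)
}

#' Write a molecule table to CSV
#'
#' @param records Molecule-record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(records, path) {
  utils::write.csv(records[, c("id", "smiles", "label", "split")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Balance classes by random undersampling
#'
#' Downsamples every class to the minority-class count, without replacement,
#' deterministically under `seed`.
#'
#' @param records Molecule-record `data.frame` with both labels present.
#' @param seed Integer seed.
#' @return Balanced record table (row order: input order of kept rows).
#' @export
balance_undersample <- function(records, seed) {
  tab <- table(factor(records$label, levels = APPROVAL_LABELS))
  abort_if(any(tab == 0L), "both classes must be present to balance")
  n_keep <- min(tab)
  keep <- logical(nrow(records))
  set.seed(as.integer(seed))
  for (lb in APPROVAL_LABELS) {
    idx <- which(records$label == lb)
    keep[sort(sample(idx, n_keep))] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Stratified train/validation/test split
#'
#' Partitions records into three disjoint, exhaustive splits preserving the
#' class distribution. Fractional per-class split sizes are resolved by
#' largest remainder, keeping each class's deviation from the target
#' proportions within one record.
#'
#' @param records Molecule-record `data.frame` (>= 10 records per class).
#' @param ratios Three non-negative proportions summing to 1 (default 8:1:1).
#' @param seed Integer seed.
#' @return The input table with `split` set to train/validation/test.
#' @export
stratified_split <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  abort_if(length(ratios) != 3L || any(ratios < 0), "`ratios` must be 3 non-negative numbers")
  abort_if(abs(sum(ratios) - 1) > 1e-9, "`ratios` must sum to 1")
  tab <- table(records$label)
  abort_if(any(tab < 10L), "need at least 10 records per class to split")
  set.seed(as.integer(seed))
  split <- rep(NA_character_, nrow(records))
  for (lb in names(tab)) {
    idx <- sample(which(records$label == lb))
    n <- length(idx)
    exact <- ratios * n
    sizes <- floor(exact)
    rem <- exact - sizes
    short <- n - sum(sizes)
    if (short > 0) {
      ord <- order(rem, decreasing = TRUE)
      sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1L
    }
    parts <- rep(c("train", "validation", "test"), times = sizes)
    split[idx] <- parts
  }
  records$split <- split
  records
}

#' Remove external records overlapping an internal set
#'
#' Drops every external record whose canonical SMILES occurs in the internal
#' set. Identity is canonical-SMILES string equality.
#'
#' @param external,internal Molecule-record `data.frame`s (canonicalized).
#' @return The retained external records (possibly zero rows).
#' @export
remove_overlap <- function(external, internal) {
  external[!(external$smiles %in% internal$smiles), , drop = FALSE]
}

# ---- synthetic fixture generator ------------------------------------------

# Small scaffold/substituent grammar: three 6-rings and twelve substituents
# give a valid, descriptor-diverse chemical space with no external data.
FIXTURE_SCAFFOLDS <- list(
  benzene     = list(atoms = c("c1", "c", "c", "c", "c", "c"), close = "1", sub_ok = rep(TRUE, 6)),
  cyclohexane = list(atoms = c("C1", "C", "C", "C", "C", "C"), close = "1", sub_ok = rep(TRUE, 6)),
  pyridine    = list(atoms = c("c1", "c", "c", "n", "c", "c"), close = "1",
                     sub_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
)

FIXTURE_SUBSTITUENTS <- c("C", "CC", "CCC", "O", "OC", "N", "NC",
                          "F", "Cl", "C(=O)O", "C(=O)OC", "C#N")

# Planted labelling rule: polar-surface-driven, thresholds fixed at design
# time near the grammar's descriptor median so both classes are well
# populated. approved <=> TPSA >= 30 and logP <= 1.9.
FIXTURE_RULE_TPSA_MIN <- 30
FIXTURE_RULE_LOGP_MAX <- 1.9

fixture_rule_label <- function(desc) {
  ifelse(desc$tpsa >= FIXTURE_RULE_TPSA_MIN & desc$logp <= FIXTURE_RULE_LOGP_MAX,
         "approved", "unapproved")
}

one_fixture_smiles <- function() {
  sc <- FIXTURE_SCAFFOLDS[[sample.int(length(FIXTURE_SCAFFOLDS), 1L)]]
  k <- sample(0:4, 1L)
  pos <- which(sc$sub_ok)
  sel <- if (k > 0) sort(sample(pos, min(k, length(pos)))) else integer(0)
  atoms <- sc$atoms
  for (p in sel) {
    atoms[p] <- paste0(atoms[p], "(", sample(FIXTURE_SUBSTITUENTS, 1L), ")")
  }
  paste0(paste(atoms, collapse = ""), sc$close)
}

#' Generate a labelled synthetic molecule fixture
#'
#' Emits `n_per_class` unique, canonical molecules per approval class from a
#' benzene/cyclohexane/pyridine scaffold grammar with 0-4 substituents drawn
#' from a fixed 12-element set. Labels are planted by a descriptor-threshold
#' rule (polar surface area and logP), then exactly `round(noise *
#' n_per_class)` labels per class are flipped so class counts stay exact and
#' the empirical label-descriptor agreement equals `1 - noise`.
#'
#' @param n_per_class Molecules per class (>= 1).
#' @param seed Integer seed; output is byte-identical for equal seeds.
#' @param noise Flip probability in `[0, 0.5)`.
#' @param max_draws Attempt budget before giving up on a class.
#' @return Molecule-record `data.frame` with `2 * n_per_class` rows.
#' @export
generate_fixture <- function(n_per_class, seed = 1L, noise = 0, max_draws = 400L * n_per_class) {
  abort_if(!is_count(n_per_class) || n_per_class < 1, "`n_per_class` must be >= 1")
  abort_if(!is.numeric(noise) || noise < 0 || noise >= 0.5, "`noise` must be in [0, 0.5)")
  set.seed(as.integer(seed))
  got <- list(approved = character(0), unapproved = character(0))
  seen <- character(0)
  draws <- 0L
  while ((length(got$approved) < n_per_class || length(got$unapproved) < n_per_class) &&
         draws < max_draws) {
    m <- 64L
    draws <- draws + m
    raw <- vapply(seq_len(m), function(i) one_fixture_smiles(), character(1))
    can <- canonicalize_smiles(raw)
    fresh <- !duplicated(can) & !(can %in% seen)
    can <- can[fresh]
    if (!length(can)) next
    seen <- c(seen, can)
    desc <- compute_descriptors(can)
    lab <- fixture_rule_label(desc)
    for (lb in APPROVAL_LABELS) {
      need <- n_per_class - length(got[[lb]])
      if (need > 0) got[[lb]] <- c(got[[lb]], can[lab == lb][seq_len(min(need, sum(lab == lb)))])
    }
  }
  short <- vapply(got, length, integer(1)) < n_per_class
  abort_if(any(short),
           "fixture grammar exhausted: achieved ",
           paste(sprintf("%s=%d", names(got), vapply(got, length, integer(1))), collapse = ", "),
           " of ", n_per_class, " per class")
  rec <- molecule_records(
    id = sprintf("fix%05d", seq_len(2L * n_per_class)),
    smiles = c(got$approved, got$unapproved),
    label = rep(APPROVAL_LABELS, each = n_per_class)
  )
  n_flip <- round(noise * n_per_class)
  if (n_flip > 0) {
    # choose flip sets from the pre-flip labels so swaps cannot cancel
    flips <- lapply(APPROVAL_LABELS, function(lb) sample(which(rec$label == lb), n_flip))
    for (j in seq_along(APPROVAL_LABELS)) {
      rec$label[flips[[j]]] <- setdiff(APPROVAL_LABELS, APPROVAL_LABELS[j])
    }
  }
  rec
}
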