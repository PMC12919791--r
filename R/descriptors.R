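# The 11 physicochemical/structural descriptors, structural-alert screening
# (PAINS + Brenk-type unwanted functionality), and the Ghose/QED gates.
# Descriptor semantics are those of the OpenBabel backend: logP and molar
# refractivity are Wildman-Crippen atom-contribution estimates, TPSA is the
# Ertl 2-D polar surface area, HBD/HBA follow OpenBabel's definitions.

DESCRIPTOR_FIELDS <- c("molecular_weight", "logp", "tpsa", "hbd", "hba",
                       "rotatable_bonds", "molar_refractivity", "chiral_centers",
                       "heavy_atoms", "ring_count", "formal_charge")

# single acyclic non-terminal sigma bond, triple-bond neighbours excluded
ROTOR_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

# ---- chiral centers --------------------------------------------------------

# Potential tetrahedral stereocenters from connectivity alone: a carbon with
# four sigma bonds (implicit H counted) whose four branches have pairwise
# distinct blocked-BFS signatures. An atom-ranking approximation of CIP
# perception: para/meso dependencies between centers are not resolved.
branch_signature <- function(start, blocked, adj, tokens, max_depth) {
  seen <- c(blocked, start)
  frontier <- start
  sig <- tokens[start]
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    sig <- paste(sig, paste(sort(tokens[nxt]), collapse = ","), sep = "|")
    frontier <- nxt
  }
  sig
}

count_chiral_centers_graph <- function(elements, bonds) {
  n <- length(elements)
  if (!n || !nrow(bonds)) return(0L)
  adj <- vector("list", n)
  orders <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1L]; b <- bonds[i, 2L]; o <- bonds[i, 3L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    orders[[a]] <- c(orders[[a]], o); orders[[b]] <- c(orders[[b]], o)
  }
  deg <- lengths(adj)
  tokens <- paste0(elements, deg, vapply(orders, function(o) paste(sort(o), collapse = ""), ""))
  n_centers <- 0L
  for (a in which(elements == "C")) {
    if (any(orders[[a]] != 1L)) next            # needs four sigma bonds
    n_h <- 4L - deg[a]
    if (n_h < 0L || n_h > 1L) next              # >= 3 heavy neighbours
    sigs <- vapply(adj[[a]], branch_signature, character(1),
                   blocked = a, adj = adj, tokens = tokens, max_depth = n)
    if (n_h == 1L) sigs <- c(sigs, "Himplicit")
    if (!anyDuplicated(sigs)) n_centers <- n_centers + 1L
  }
  n_centers
}

# ---- descriptor computation ------------------------------------------------

#' Compute the 11 molecular descriptors
#'
#' Returns one row per molecule with `molecular_weight` (Da), `logp`, `tpsa`
#' (A^2), `hbd`, `hba`, `rotatable_bonds`, `molar_refractivity`,
#' `chiral_centers`, `heavy_atoms`, `ring_count` (smallest-set ring count),
#' and `formal_charge`, plus the auxiliary columns `aromatic_rings` and
#' `total_atoms` (hydrogens included) consumed by the QED and Ghose gates.
#'
#' @param smiles Character vector of valid SMILES (canonicalized internally).
#' @return `data.frame`, rows aligned with `smiles`.
#' @export
compute_descriptors <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  ids <- sprintf("m%06d", seq_along(can))
  # properties and rotors on the hydrogen-implicit form
  refs <- ob_refs(can, ids)
  props <- ChemmineOB::prop_OB(refs)
  rot <- as.integer(smarts_counts(refs, ROTOR_SMARTS))
  # connectivity (and ring perception) on the explicit-hydrogen SDF, which
  # also carries single-heavy-atom molecules safely
  sdf <- smiles_to_sdf(can, ids, add_h = TRUE)
  ring_tab <- ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = TRUE)
  if (is.null(dim(ring_tab))) ring_tab <- matrix(ring_tab, nrow = 1,
                                                 dimnames = list(NULL, names(ring_tab)))
  heavy <- integer(length(can))
  total <- integer(length(can))
  chiral <- integer(length(can))
  for (i in seq_along(can)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    el <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf[[i]])
    bonds <- if (nrow(bb)) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                                 as.integer(bb[, 3]))
             else matrix(integer(0), ncol = 3)
    total[i] <- length(el)
    heavy[i] <- sum(el != "H")
    chiral[i] <- count_chiral_centers_graph(el, bonds)
  }
  out <- data.frame(
    molecular_weight  = as.numeric(props$MW),
    logp              = as.numeric(props$logP),
    tpsa              = as.numeric(props$TPSA),
    hbd               = as.integer(props$HBD),
    hba               = as.integer(props$HBA1),
    rotatable_bonds   = rot,
    molar_refractivity = as.numeric(props$MR),
    chiral_centers    = chiral,
    heavy_atoms       = heavy,
    ring_count        = as.integer(ring_tab[, "RINGS"]),
    formal_charge     = smiles_formal_charge(can),
    aromatic_rings    = as.integer(ring_tab[, "AROMATIC"]),
    total_atoms       = total,
    stringsAsFactors  = FALSE
  )
  rownames(out) <- NULL
  out
}

# ---- structural alerts -----------------------------------------------------

#' Load a structural-alert catalog
#'
#' @param which `"pains"` (480 pan-assay interference SMARTS, families
#'   A+B+C) or `"brenk"` (116 Brenk-type unwanted-functionality SMARTS).
#' @return `data.frame` with columns `name`, `smarts`.
#' @export
load_alert_catalog <- function(which = c("pains", "brenk")) {
  which <- match.arg(which)
  key <- paste0("catalog_", which)
  if (!is.null(.molapprove_env[[key]])) return(.molapprove_env[[key]])
  path <- system.file("extdata", paste0(which, if (which == "pains") "_smarts.tsv" else "_alerts.tsv"),
                      package = "molapprove")
  abort_if(!nzchar(path) || !file.exists(path),
           "alert catalog '", which, "' is not installed (configuration error)")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]  # SMARTS may contain '#'
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(name = vapply(parts, `[`, "", 1L),
                   smarts = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  abort_if(!nrow(df), "alert catalog '", which, "' is empty (configuration error)")
  .molapprove_env[[key]] <- df
  df
}

match_catalog <- function(refs_h, catalog) {
  hits <- integer(length(refs_h))
  multi <- grepl(".", catalog$smarts, fixed = TRUE)
  plain <- catalog$smarts[!multi]
  if (length(plain)) {
    cnt <- smarts_counts(refs_h, plain)
    hits <- hits + rowSums(cnt > 0L)
  }
  # multi-component patterns (identical components): require >= k matches
  for (p in catalog$smarts[multi]) {
    comps <- strsplit(p, ".", fixed = TRUE)[[1]]
    cnt <- smarts_counts(refs_h, comps[1])
    hits <- hits + as.integer(cnt[, 1] >= length(comps))
  }
  hits
}

#' Screen molecules against the PAINS and Brenk alert catalogs
#'
#' Hit counts are numbers of distinct catalog patterns matched. Matching is
#' done on explicit-hydrogen structures, as the catalogs constrain hydrogen
#' positions. A missing catalog raises a configuration error rather than
#' returning silent zeros.
#'
#' @param smiles Character vector of valid SMILES.
#' @return `data.frame` with `pains_hits`, `brenk_hits`, `pains_flag`,
#'   `brenk_flag`, rows aligned with `smiles`.
#' @export
structural_alerts <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  ids <- sprintf("m%06d", seq_along(can))
  pains <- load_alert_catalog("pains")
  brenk <- load_alert_catalog("brenk")
  refs_h <- ob_refs(can, ids, add_h = TRUE)
  ph <- match_catalog(refs_h, pains)
  bh <- match_catalog(refs_h, brenk)
  data.frame(pains_hits = ph, brenk_hits = bh,
             pains_flag = ph > 0L, brenk_flag = bh > 0L)
}

# ---- drug-likeness gates ---------------------------------------------------

GHOSE_RANGES <- list(molecular_weight = c(160, 480), logp = c(-0.4, 5.6),
                     molar_refractivity = c(40, 130), total_atoms = c(20, 70))

#' Ghose drug-likeness filter
#'
#' Passes a molecule iff all four criteria hold, endpoints inclusive:
#' molecular weight 160-480 Da, logP -0.4-5.6, molar refractivity 40-130,
#' and total atom count (hydrogens included) 20-70.
#'
#' @param descriptors Descriptor `data.frame` from [compute_descriptors()]
#'   (needs `molecular_weight`, `logp`, `molar_refractivity`, `total_atoms`).
#' @return Logical vector.
#' @export
ghose_filter <- function(descriptors) {
  ok <- rep(TRUE, nrow(descriptors))
  for (f in names(GHOSE_RANGES)) {
    abort_if(is.null(descriptors[[f]]), "descriptor column '", f, "' is required")
    r <- GHOSE_RANGES[[f]]
    ok <- ok & descriptors[[f]] >= r[1] & descriptors[[f]] <= r[2]
  }
  ok
}

# ADS (asymmetric double sigmoidal) desirability parameters and mean weights
# of the QED formulation (Bickerton et al. 2012, Nat Chem 4:90).
QED_ADS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 0.000000001,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.010000000, b = 272.4121427, c = 2.558379970, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939, d = 0.000000001,
             e = 1.317690384, f = 0.375760881, dmax = 312.3372610),
  ALERTS = c(a = 0.010000000, b = 1199.094025, c = -0.09002883, d = 0.000000001,
             e = 0.185904477, f = 0.875193782, dmax = 417.7253140)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])
  e2 <- 1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])
  unname((p["a"] + p["b"] / e1 * (1 - 1 / e2)) / p["dmax"])
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted-desirability QED: each of eight properties (molecular weight,
#' logP, acceptors, donors, polar surface area, rotatable bonds, aromatic
#' rings, structural alerts) is mapped through its asymmetric double
#' sigmoidal desirability function and combined as the weighted geometric
#' mean with the published mean weights. The alerts term counts Brenk-type
#' catalog hits.
#'
#' @param descriptors Descriptor `data.frame` from [compute_descriptors()].
#' @param alerts Alert `data.frame` from [structural_alerts()] (for
#'   `brenk_hits`); computed from `smiles` if omitted and available.
#' @return Numeric QED scores in `[0, 1]`.
#' @export
qed_score <- function(descriptors, alerts) {
  abort_if(missing(alerts) || is.null(alerts$brenk_hits),
           "`alerts` with a brenk_hits column is required")
  x <- cbind(MW = descriptors$molecular_weight, ALOGP = descriptors$logp,
             HBA = descriptors$hba, HBD = descriptors$hbd,
             PSA = descriptors$tpsa, ROTB = descriptors$rotatable_bonds,
             AROM = descriptors$aromatic_rings, ALERTS = alerts$brenk_hits)
  d <- vapply(names(QED_ADS), function(f) qed_ads(x[, f], QED_ADS[[f]]),
              numeric(nrow(x)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, names(QED_ADS)))
  w <- QED_WEIGHTS[colnames(d)]
  exp(as.numeric(log(pmax(d, 1e-12)) %*% w) / sum(w))
}

#' QED drug-likeness gate
#'
#' `TRUE` iff the QED score is strictly above 0.5.
#'
#' @param qed Numeric scores in `[0, 1]`.
#' @return Logical vector.
#' @export
qed_druglike <- function(qed) {
  abort_if(!is.numeric(qed) || any(!is.finite(qed)) || any(qed < 0 | qed > 1),
           "QED scores must lie in [0, 1]")
  qed > 0.5
}

#' Featurize a molecule table
#'
#' One row per molecule: the 11 descriptors plus `pains_hits`, `brenk_hits`,
#' `qed` and `ghose_pass`.
#'
#' @param records Molecule-record `data.frame`.
#' @return `data.frame` keyed by `id`.
#' @export
featurize_molecules <- function(records) {
  desc <- compute_descriptors(records$smiles)
  al <- structural_alerts(records$smiles)
  cbind(data.frame(id = records$id, stringsAsFactors = FALSE),
        desc[DESCRIPTOR_FIELDS],
        al[c("pains_hits", "brenk_hits", "pains_flag", "brenk_flag")],
        data.frame(qed = qed_score(desc, al), ghose_pass = ghose_filter(desc),
                   aromatic_rings = desc$aromatic_rings, total_atoms = desc$total_atoms))
}
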