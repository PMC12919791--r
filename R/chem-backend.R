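# OpenBabel-backed structure handling. Everything chemical in the package
# funnels through these helpers so the toolkit choice lives in one file.
# ChemmineOB::convertFormat() aborts a whole batch on the first bad SMILES,
# so batch calls fall back to per-molecule conversion to name the offender.

ob_available <- function() {
  requireNamespace("ChemmineOB", quietly = TRUE) &&
    requireNamespace("ChemmineR", quietly = TRUE)
}

assert_ob <- function() {
  abort_if(!ob_available(),
           "the OpenBabel backend (ChemmineOB/ChemmineR) is not available")
}

# one SMILES record per line: "<smiles><space><title>"
smi_block <- function(smiles, ids) paste0(paste(smiles, ids), "\n", collapse = "")

ob_convert <- function(smiles, ids, to = "CAN", add_h = FALSE) {
  assert_ob()
  txt <- smi_block(smiles, ids)
  suppressWarnings(
    if (add_h) {
      ChemmineOB::convertFormat("SMI", to, txt, options = data.frame(names = "h", args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", to, txt)
    }
  )
}

parse_can_output <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(smiles = character(), id = character()))
  sm <- sub("[ \t].*$", "", lines)
  id <- sub("^[^ \t]+[ \t]+", "", lines)
  id[id == lines] <- NA_character_
  data.frame(smiles = sm, id = id, stringsAsFactors = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit-canonical form. Canonicalization is a
#' fixed point: applying it twice returns the same string. Unparseable
#' inputs raise an error naming the offending string.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, same length and order.
#' @examples
#' \donttest{
#' canonicalize_smiles(c("C(C)O", "CCO"))  # both map to the same string
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  abort_if(!is.character(smiles) || !length(smiles), "`smiles` must be a non-empty character vector")
  abort_if(anyNA(smiles) || any(!nzchar(smiles)), "SMILES input contains NA or empty strings")
  ids <- sprintf("m%06d", seq_along(smiles))
  out <- parse_can_output(ob_convert(smiles, ids, "CAN"))
  if (nrow(out) == length(smiles) && identical(out$id, ids)) return(out$smiles)
  # batch aborted: find the offender(s) one molecule at a time
  res <- character(length(smiles))
  for (i in seq_along(smiles)) {
    o <- parse_can_output(ob_convert(smiles[i], ids[i], "CAN"))
    abort_if(nrow(o) != 1L, "unparseable SMILES: '", smiles[i], "'")
    res[i] <- o$smiles
  }
  res
}

# SDFset from SMILES (2D coords not generated; connectivity only is used)
smiles_to_sdf <- function(smiles, ids, add_h = FALSE) {
  assert_ob()
  txt <- ob_convert(smiles, ids, "SDF", add_h = add_h)
  sdf <- ChemmineR::read.SDFset(strsplit(txt, "\n", fixed = TRUE)[[1]])
  abort_if(length(sdf) != length(smiles),
           "SDF conversion dropped molecules (", length(sdf), "/", length(smiles), ")")
  ChemmineR::cid(sdf) <- as.character(ids)
  sdf
}

# OBMol references for property calculation and repeated SMARTS matching.
# With add_h the molecules go through an explicit-hydrogen SDF (the SMILES
# writer would fold hydrogens back in).
ob_refs <- function(smiles, ids, add_h = FALSE) {
  assert_ob()
  refs <- vector("list", 0L)
  if (add_h) {
    txt <- ob_convert(smiles, ids, "SDF", add_h = TRUE)
    invisible(ChemmineOB::forEachMol("SDF", txt, function(m) refs[[length(refs) + 1L]] <<- m))
  } else {
    invisible(ChemmineOB::forEachMol("SMILES", smi_block(smiles, ids),
                                     function(m) refs[[length(refs) + 1L]] <<- m))
  }
  abort_if(length(refs) != length(smiles), "OBMol conversion dropped molecules")
  refs
}

# match counts: molecules x patterns matrix
smarts_counts <- function(refs, patterns) {
  assert_ob()
  out <- matrix(0L, nrow = length(refs), ncol = length(patterns))
  for (j in seq_along(patterns)) {
    cnt <- try(ChemmineOB::smartsSearch_OB(refs, patterns[j], uniqueMatches = TRUE),
               silent = TRUE)
    abort_if(inherits(cnt, "try-error"),
             "SMARTS pattern rejected by the backend: '", patterns[j], "'")
    out[, j] <- as.integer(cnt)
  }
  out
}

# net formal charge read off bracket atoms of a canonical SMILES
smiles_formal_charge <- function(smiles) {
  vapply(smiles, function(s) {
    m <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (!length(m)) return(0L)
    chg <- 0L
    for (b in m) {
      body <- gsub("^\\[|\\]$", "", b)
      plus <- regmatches(body, regexpr("\\+\\+*[0-9]*", body))
      minus <- regmatches(body, regexpr("--*[0-9]*", body))
      if (length(plus) && nzchar(plus)) {
        n <- sub("^\\++", "", plus)
        chg <- chg + if (nzchar(n)) as.integer(n) else nchar(gsub("[^+]", "", plus))
      }
      if (length(minus) && nzchar(minus)) {
        n <- sub("^-+", "", minus)
        chg <- chg - if (nzchar(n)) as.integer(n) else nchar(gsub("[^-]", "", minus))
      }
    }
    chg
  }, integer(1), USE.NAMES = FALSE)
}
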