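#' Fingerprint configuration
#'
#' Circular (Morgan) fingerprint settings. The default radius 2 / 2048 bits
#' is the field-standard ECFP4-equivalent.
#'
#' @param radius Neighborhood radius (0-5); radius `r` corresponds to the
#'   ECFP\eqn{2r} circular fingerprint.
#' @param n_bits Folded fingerprint width (>= 64, <= 4096).
#' @return A `fingerprint_config` list.
#' @export
fingerprint_config <- function(radius = 2L, n_bits = 2048L) {
  stop_if_not(radius >= 0 && radius <= 5, "radius must be in 0..5")
  stop_if_not(n_bits >= 64, "n_bits must be >= 64")
  stop_if_not(n_bits <= 4096, "n_bits must be <= 4096")
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "fingerprint_config")
}

# OpenBabel repairs some malformed SMILES silently (e.g. "C(" parses as
# methane), so validity combines a syntactic balance check with
# canonicalization: a string is valid iff brackets/parentheses balance,
# every ring-closure label is paired, and OpenBabel produces a non-empty
# canonical SMILES.

#' Check SMILES validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector, `TRUE` where the string is a parseable,
#'   non-empty molecule.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    if (!smiles_balanced(s)) return(FALSE)
    can <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMILES", "CAN", s)),
      error = function(e) "")
    nzchar(trimws(can))
  }, logical(1L), USE.NAMES = FALSE)
}

# Balanced parentheses/brackets and paired ring-closure labels. Digits
# inside bracket atoms (isotopes, charges, H counts) are not ring labels.
smiles_balanced <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  depth_p <- 0L; depth_b <- 0L
  ring <- integer(100L)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (depth_b == 0L) {
      if (ch == "(") depth_p <- depth_p + 1L
      else if (ch == ")") { depth_p <- depth_p - 1L; if (depth_p < 0L) return(FALSE) }
      else if (ch == "[") depth_b <- depth_b + 1L
      else if (ch == "]") return(FALSE)
      else if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
          return(FALSE)
        lab <- as.integer(paste0(chars[i + 1L], chars[i + 2L])) + 1L
        ring[lab] <- ring[lab] + 1L
        i <- i + 2L
      } else if (grepl("[0-9]", ch)) {
        lab <- as.integer(ch) + 1L
        ring[lab] <- ring[lab] + 1L
      }
    } else {
      if (ch == "]") depth_b <- depth_b - 1L
      else if (ch == "[") return(FALSE)
    }
    i <- i + 1L
  }
  depth_p == 0L && depth_b == 0L && all(ring %% 2L == 0L)
}

#' Morgan (circular) fingerprints from SMILES
#'
#' Encodes each SMILES into a folded circular-substructure bit vector via
#' OpenBabel's extended-connectivity (ECFP) fingerprints; radius `r` uses
#' ECFP\eqn{2r}. Fingerprints are canonicalization-invariant: different
#' SMILES spellings of the same molecule give identical bit vectors.
#'
#' @param smiles Character vector of SMILES strings (all must be valid).
#' @param config A [fingerprint_config()].
#' @return A `length(smiles) x n_bits` 0/1 numeric matrix, one row per
#'   molecule, rownames taken from `names(smiles)` if set.
#' @export
morgan_fingerprint <- function(smiles, config = fingerprint_config()) {
  stop_if_not(inherits(config, "fingerprint_config"),
              "config must be a fingerprint_config")
  stop_if_not(length(smiles) > 0L, "no SMILES given")
  empty <- !nzchar(trimws(smiles))
  if (any(empty))
    stop("empty molecule: blank SMILES at position ",
         which(empty)[1L], call. = FALSE)
  ok <- is_valid_smiles(smiles)
  if (any(!ok))
    stop(sprintf("unparseable SMILES: '%s'", smiles[!ok][1L]), call. = FALSE)
  fptype <- paste0("ECFP", 2L * config$radius)
  raw <- ChemmineOB::forEachMol(
    "SMILES", paste(smiles, collapse = "\n"),
    function(m) ChemmineOB::fingerprint_OB(list(m), fptype))
  stop_if_not(length(raw) == length(smiles),
              "fingerprint backend returned wrong molecule count")
  out <- matrix(0, length(smiles), config$n_bits)
  for (i in seq_along(raw)) {
    on <- which(raw[[i]] > 0)
    if (length(on))
      out[i, unique((on - 1L) %% config$n_bits) + 1L] <- 1  # OR-fold
  }
  rownames(out) <- names(smiles)
  out
}

#' Fingerprint matrix for a drug table
#'
#' @param drugs Data frame with `drug_id` and `smiles` columns.
#' @param config A [fingerprint_config()].
#' @return Numeric 0/1 matrix, one row per drug, rownames = `drug_id`.
#' @export
drug_fingerprints <- function(drugs, config = fingerprint_config()) {
  smi <- drugs$smiles
  names(smi) <- drugs$drug_id
  morgan_fingerprint(smi, config)
}
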