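# Canonical amino-acid alphabet and coarse-grained side-chain geometry.

#' The 20 canonical amino acids (one-letter codes)
#'
#' The alphabet is strictly canonical: wildcard or ambiguity codes (B, J, O,
#' U, X, Z) are rejected everywhere, because the score is a residue-pair
#' potential and a silent substitution would corrupt energies.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Distance (Angstrom) from CA at which the side-chain centroid pseudo-atom is
# placed along the CA->CB direction.  Configuration data shipped with the
# tool: values scale with side-chain size within the coarse-grained regime
# 1.5-3.4 A.  Glycine has no side-chain point (CA stands in when scoring).
SC_DISTANCE <- c(
  A = 1.5, C = 2.1, D = 2.5, E = 3.0, F = 3.0, G = NA_real_, H = 2.8,
  I = 2.3, K = 3.3, L = 2.6, M = 2.9, N = 2.5, P = 1.9, Q = 3.0,
  R = 3.4, S = 1.9, T = 1.9, V = 2.0, W = 3.4, Y = 3.2
)

# Residue-type index 1..20 for potential-table lookups.
aa_index <- function(aa) {
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    stop_validation(
      "unknown residue type(s): ",
      paste(unique(aa[is.na(idx)]), collapse = ", ")
    )
  }
  idx
}

# Validate a sequence string against the canonical alphabet; returns the
# uppercased sequence or raises a validation error naming the offending
# record and position.
validate_seq <- function(seq, id = "<sequence>") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop_validation("sequence for record '", id, "' is empty")
  }
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop_validation(
      "non-canonical residue '", chars[bad[1L]], "' in record '", id,
      "' at position ", bad[1L]
    )
  }
  seq
}

#' Construct a peptide
#'
#' A peptide is a validated amino-acid sequence with an identifier; it is the
#' query unit of every prediction in the package.
#'
#' @param id Free-text identifier.
#' @param seq Sequence over the 20 canonical one-letter codes (case
#'   insensitive; stored uppercase).
#' @return An object of class `peptide` with fields `id`, `seq`, `length`.
#' @examples
#' peptide("p1", "NFGAIL")
#' @export
peptide <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop_validation("peptide id must be a nonempty string")
  }
  seq <- validate_seq(seq, id)
  structure(
    list(id = id, seq = seq, length = nchar(seq)),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d aa)\n  %s\n", x$id, x$length, x$seq))
  invisible(x)
}

# Split a peptide (or plain string) into a character vector of residues.
seq_chars <- function(x) {
  s <- if (inherits(x, "peptide")) x$seq else x
  strsplit(s, "", fixed = TRUE)[[1L]]
}

# Length window accepted by the threading engine (template-bound geometry).
THREAD_MIN_LEN <- 14L
THREAD_MAX_LEN <- 45L
MAX_OVERHANG <- 8L

check_threadable <- function(len, what = "query") {
  if (len < THREAD_MIN_LEN || len > THREAD_MAX_LEN) {
    stop_validation(
      what, " length ", len, " outside the threadable range [",
      THREAD_MIN_LEN, ", ", THREAD_MAX_LEN, "]"
    )
  }
  invisible(len)
}
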