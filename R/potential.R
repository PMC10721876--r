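# Distance-binned residue-pair statistical potential: the scoring knowledge
# base.  The table is pluggable; the packaged default is a coarse-grained
# contact potential favoring hydrophobic-hydrophobic and Q/N-Q/N packing.

#' Construct a potential table
#'
#' @param bin_edges Strictly increasing distance bin edges in Angstrom
#'   (first edge >= 0; the last edge is the cutoff).  Bins are half-open
#'   `[lo, hi)`; pairs at or beyond the cutoff contribute exactly 0.
#' @param energies Numeric array `[20, 20, n_bins]` indexed by
#'   [AA_ALPHABET] order; must be finite and symmetric in the residue pair.
#' @param min_seq_sep Minimum `|i - j|` within a chain for a pair to count
#'   (default 2: bonded/adjacent residues carry no packing signal).
#' @return Object of class `potential_table`.
#' @export
potential_table <- function(bin_edges, energies, min_seq_sep = 2L) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0) ||
      bin_edges[1] < 0) {
    stop_validation("bin_edges must be strictly increasing, first edge >= 0")
  }
  nb <- length(bin_edges) - 1L
  if (!is.array(energies) ||
      !identical(dim(energies), c(20L, 20L, nb))) {
    stop_validation("energies must be a 20 x 20 x n_bins array")
  }
  if (!all(is.finite(energies))) {
    stop_validation("potential energies must all be finite")
  }
  for (b in seq_len(nb)) {
    if (!isTRUE(all.equal(energies[, , b], t(energies[, , b]),
                          tolerance = 0))) {
      stop_validation("potential not symmetric in the residue pair (bin ",
                      b, ")")
    }
  }
  structure(
    list(
      bin_edges = bin_edges,
      energies = energies,
      cutoff = bin_edges[length(bin_edges)],
      min_seq_sep = as.integer(min_seq_sep)
    ),
    class = "potential_table"
  )
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf(
    "<potential_table> %d bins, cutoff %.1f A, min_seq_sep %d\n",
    length(x$bin_edges) - 1L, x$cutoff, x$min_seq_sep
  ))
  invisible(x)
}

#' Load a potential table from TSV
#'
#' Reads a table with columns `res_i`, `res_j`, `bin_lo`, `bin_hi`, `energy`.
#' Bins must tile a contiguous range; every unordered residue pair must be
#' covered in every bin (missing entries are reported as gaps).  A pair
#' given in both orders must carry equal energies (else a symmetry error).
#'
#' @param path TSV path.
#' @param min_seq_sep Passed to [potential_table()].
#' @return A `potential_table`.
#' @export
load_potential <- function(path, min_seq_sep = 2L) {
  if (!file.exists(path)) {
    stop("potential file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("res_i", "res_j", "bin_lo", "bin_hi", "energy")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("potential table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lo <- sort(unique(df$bin_lo))
  hi <- sort(unique(df$bin_hi))
  if (length(lo) != length(hi) || any(lo[-1] != hi[-length(hi)])) {
    stop_validation("potential bins are not contiguous")
  }
  bin_edges <- c(lo, hi[length(hi)])
  nb <- length(lo)
  bin_of <- match(df$bin_lo, lo)
  ii <- aa_index(df$res_i)
  jj <- aa_index(df$res_j)
  energies <- array(NA_real_, c(20L, 20L, nb))
  for (r in seq_len(nrow(df))) {
    i <- ii[r]; j <- jj[r]; b <- bin_of[r]; e <- df$energy[r]
    prev <- energies[i, j, b]
    if (!is.na(prev) && prev != e) {
      stop_validation(
        "asymmetric potential entries for pair (", df$res_i[r], ",",
        df$res_j[r], ") bin [", df$bin_lo[r], ",", df$bin_hi[r], ")"
      )
    }
    energies[i, j, b] <- e
    energies[j, i, b] <- e
  }
  if (anyNA(energies)) {
    gaps <- which(is.na(energies), arr.ind = TRUE)
    gaps <- gaps[gaps[, 1] <= gaps[, 2], , drop = FALSE]
    show <- utils::head(gaps, 3L)
    stop_validation(
      "potential table has ", nrow(gaps), " missing (pair, bin) entries, ",
      "first: ",
      paste(apply(show, 1, function(g) {
        sprintf("(%s,%s) bin %d", AA_ALPHABET[g[1]], AA_ALPHABET[g[2]], g[3])
      }), collapse = "; ")
    )
  }
  potential_table(bin_edges, energies, min_seq_sep = min_seq_sep)
}

#' Write a potential table as TSV
#'
#' One row per unordered residue pair and bin (the symmetric mate is implied
#' and accepted by [load_potential()]).
#'
#' @param table A `potential_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential <- function(table, path) {
  nb <- length(table$bin_edges) - 1L
  rows <- character()
  for (i in 1:20) {
    for (j in i:20) {
      for (b in seq_len(nb)) {
        rows <- c(rows, sprintf(
          "%s\t%s\t%g\t%g\t%g",
          AA_ALPHABET[i], AA_ALPHABET[j],
          table$bin_edges[b], table$bin_edges[b + 1L],
          table$energies[i, j, b]
        ))
      }
    }
  }
  atomic_write_lines(c("res_i\tres_j\tbin_lo\tbin_hi\tenergy", rows), path)
}

#' The packaged default potential
#'
#' Loads the potential TSV shipped with the package: 1 Angstrom bins to a
#' 10 Angstrom cutoff, minimum sequence separation 2, with favorable
#' energies for contacts among hydrophobic and Q/N residues and unfavorable
#' energies for like-charged contacts (see [make_potential()], style
#' `"hydrophobic"`, which generated it).
#'
#' @return A `potential_table`.
#' @export
default_potential <- function() {
  path <- system.file("extdata", "default_potential.tsv",
                      package = "fibrilthread", mustWork = TRUE)
  load_potential(path, min_seq_sep = 2L)
}

#' Look up the pair energy at a distance
#'
#' Bins are half-open `[lo, hi)`; distances at or beyond the cutoff (or
#' below the first edge) contribute 0.  Symmetric in the residue pair.
#'
#' @param table A `potential_table`.
#' @param t_i,t_j One-letter residue types.
#' @param d Distance(s) in Angstrom, `>= 0`.
#' @return Energy value(s).
#' @export
pair_energy <- function(table, t_i, t_j, d) {
  if (any(d < 0)) stop_validation("distance must be >= 0")
  i <- aa_index(t_i)
  j <- aa_index(t_j)
  b <- findInterval(d, table$bin_edges)
  nb <- length(table$bin_edges) - 1L
  out <- numeric(length(d))
  ok <- b >= 1L & b <= nb & d < table$cutoff
  if (any(ok)) {
    out[ok] <- table$energies[cbind(
      rep_len(i, length(d))[ok], rep_len(j, length(d))[ok], b[ok]
    )]
  }
  out
}
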