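# Model scoring: total statistical-potential energy and the
# length-normalized ndope score.

#' Length-normalized potential score
#'
#' The score of a model is its total potential energy divided by the average
#' length of the two sequences used to build it:
#' `ndope = raw / L`, `L = (len_a + len_b) / 2`.  For homoaggregation (both
#' peptides identical) `L` is the peptide length.  Lower values mean a more
#' stable model, hence a more likely interaction.
#'
#' @param raw Total model energy (dimensionless).
#' @param len_a,len_b Lengths of the two peptides in residues (each counted
#'   once per peptide, not per chain).
#' @return `raw / ((len_a + len_b)/2)`.
#' @examples
#' ndope(-5000, 20, 30) # -200
#' @export
ndope <- function(raw, len_a, len_b) {
  if (len_a < 1 || len_b < 1) {
    stop_validation("peptide lengths must be >= 1")
  }
  raw / ((len_a + len_b) / 2)
}

# Interaction points of a model: side-chain centroid per residue, CA for
# glycine.  Returns the coordinate matrix plus residue type / chain /
# within-chain index vectors used by the pair-inclusion rules.
model_points <- function(model) {
  pts <- NULL
  type <- character()
  chain <- integer()
  resi <- integer()
  for (k in seq_along(model$chains)) {
    ch <- model$chains[[k]]
    res <- seq_chars(ch$seq)
    p <- ch$sc
    gly <- is.na(p[, 1])
    p[gly, ] <- ch$ca[gly, , drop = FALSE]
    pts <- rbind(pts, p)
    type <- c(type, res)
    chain <- c(chain, rep.int(k, length(res)))
    resi <- c(resi, seq_along(res))
  }
  list(xyz = pts, type = type, chain = chain, resi = resi)
}

#' Score a threaded model with a potential table
#'
#' Sums [pair_energy()] over all unordered point pairs (points are
#' side-chain centroids, CA for glycine) whose residues sit in different
#' chains, or in the same chain at sequence separation
#' `|i - j| >= min_seq_sep`.  Pairs at or beyond the distance cutoff
#' contribute 0.  The normalized score divides by the average of the two
#' peptide lengths.
#'
#' @param model A `threaded_model` from [build_hetero_model()].
#' @param table A [potential_table].
#' @return Object of class `energy_score` with fields `raw`, `len_a`,
#'   `len_b`, `L`, `ndope`.
#' @export
evaluate_energy <- function(model, table) {
  stopifnot(inherits(model, "threaded_model"),
            inherits(table, "potential_table"))
  pts <- model_points(model)
  n <- nrow(pts$xyz)
  ti <- aa_index(pts$type)
  d <- as.matrix(stats::dist(pts$xyz))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  include <- pts$chain[i] != pts$chain[j] |
    abs(pts$resi[i] - pts$resi[j]) >= table$min_seq_sep
  dij <- d[pair]
  nb <- length(table$bin_edges) - 1L
  b <- findInterval(dij, table$bin_edges)
  keep <- include & b >= 1L & b <= nb & dij < table$cutoff
  raw <- if (any(keep)) {
    sum(table$energies[cbind(ti[i[keep]], ti[j[keep]], b[keep])])
  } else {
    0
  }
  len_a <- model$pep_a$length
  len_b <- model$pep_b$length
  structure(
    list(
      raw = raw, len_a = len_a, len_b = len_b,
      L = (len_a + len_b) / 2,
      ndope = ndope(raw, len_a, len_b)
    ),
    class = "energy_score"
  )
}

#' @export
print.energy_score <- function(x, ...) {
  cat(sprintf("<energy_score> raw %.3f, L %.1f, ndope %.3f\n",
              x$raw, x$L, x$ndope))
  invisible(x)
}
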