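# Fragment-pair interaction scanning: localize interacting regions between
# two longer proteins by scoring all fragment-pair combinations.

new_fragment_set <- function(parent, frag, scheme, width = NA_integer_,
                             step = NA_integer_) {
  structure(
    list(parent = parent, fragments = frag, scheme = scheme,
         width = width, step = step),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s: %d %s fragment(s)\n",
              x$parent$id, nrow(x$fragments), x$scheme))
  invisible(x)
}

#' Sliding-window fragments of a protein
#'
#' Overlapping subsequences of fixed width: starts 1, 1+step, ... while the
#' window fits, giving `floor((L - width)/step) + 1` fragments.  The default
#' width of 20 matches the length of curli (CsgA-like) repeat units; widths
#' below 14 are rejected because they cannot be threaded.
#'
#' @param p A [peptide()] (any length >= `width`).
#' @param width Window width in residues (>= 14; default 20).
#' @param step Start increment (default 1, the finest scan).
#' @return A `fragment_set` (scheme `"sliding"`).
#' @export
window_fragments <- function(p, width = 20L, step = 1L) {
  width <- as.integer(width)
  step <- as.integer(step)
  if (width < THREAD_MIN_LEN) {
    stop_validation("window width ", width, " below the threadable minimum ",
                    THREAD_MIN_LEN)
  }
  if (step < 1L) stop_validation("step must be >= 1")
  if (p$length < width) {
    stop_validation("protein '", p$id, "' (", p$length,
                    " aa) shorter than the window width ", width)
  }
  starts <- seq.int(1L, p$length - width + 1L, by = step)
  frag <- data.frame(
    name = sprintf("w%03d", starts),
    start = starts,
    end = starts + width - 1L,
    stringsAsFactors = FALSE
  )
  frag$seq <- substring(p$seq, frag$start, frag$end)
  new_fragment_set(p, frag, "sliding", width = width, step = step)
}

#' Explicit (repeat-unit) fragments of a protein
#'
#' Non-overlapping user-supplied fragments in increasing order, named
#' R1..Rn — the idiom for imperfect repeat units such as the five CsgA
#' repeats.
#'
#' @param p A [peptide()].
#' @param bounds Two-column matrix or list of `(start, end)` pairs, 1-based
#'   inclusive.
#' @return A `fragment_set` (scheme `"explicit"`).
#' @export
explicit_fragments <- function(p, bounds) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.integer(bounds), ncol = 2L)
  if (nrow(bounds) < 1L) stop_validation("no fragment bounds given")
  if (any(bounds[, 2] < bounds[, 1])) {
    stop_validation("fragment bound with end < start")
  }
  if (any(bounds < 1L) || any(bounds[, 2] > p$length)) {
    stop_validation("fragment bounds outside 1..", p$length,
                    " of '", p$id, "'")
  }
  if (nrow(bounds) > 1L) {
    if (any(diff(bounds[, 1]) <= 0) ||
        any(bounds[-1, 1] <= bounds[-nrow(bounds), 2])) {
      stop_validation("explicit fragments must be non-overlapping and in ",
                      "increasing order")
    }
  }
  frag <- data.frame(
    name = paste0("R", seq_len(nrow(bounds))),
    start = bounds[, 1],
    end = bounds[, 2],
    stringsAsFactors = FALSE
  )
  frag$seq <- substring(p$seq, frag$start, frag$end)
  new_fragment_set(p, frag, "explicit")
}

#' Score all fragment pairs of two proteins
#'
#' For every (row, col) fragment pair, builds a model ensemble
#' ([build_ensemble()]), scores the best model, and classifies it against
#' the threshold.  Each cell's ensemble is seeded deterministically from
#' `(seed, row, col)`, so any cell is reproducible in isolation and the
#' whole matrix is reproducible for a fixed seed.
#'
#' @param fa,fb `fragment_set`s for the two proteins (rows = `fa`).
#' @param template A [fibril_template()].
#' @param potential A [potential_table].
#' @param threshold Classification threshold on the ndope scale of
#'   `potential` (see [calibrate_threshold()]).
#' @param n_models Ensemble size per cell (default 10).
#' @param seed Integer seed.
#' @param sigma SC jitter in Angstrom.
#' @return Object of class `scan_result`: `scores` and `calls` matrices,
#'   fragment tables `rows`/`cols`, `best` (all cells sorted by ascending
#'   score), and the scan settings.
#' @export
scan_pair <- function(fa, fb, template, potential, threshold,
                      n_models = 10L, seed = 1L, sigma = 0.3) {
  stopifnot(inherits(fa, "fragment_set"), inherits(fb, "fragment_set"))
  for (fs in list(fa, fb)) {
    w <- nchar(fs$fragments$seq)
    bad <- which(w < THREAD_MIN_LEN | w > THREAD_MAX_LEN)
    if (length(bad)) {
      stop_validation(
        "fragment '", fs$fragments$name[bad[1]], "' of '", fs$parent$id,
        "' has unthreadable length ", w[bad[1]]
      )
    }
  }
  nr <- nrow(fa$fragments)
  nc <- nrow(fb$fragments)
  scores <- matrix(NA_real_, nr, nc,
                   dimnames = list(fa$fragments$name, fb$fragments$name))
  for (i in seq_len(nr)) {
    pep_i <- peptide(paste0(fa$parent$id, ":", fa$fragments$name[i]),
                     fa$fragments$seq[i])
    for (j in seq_len(nc)) {
      pep_j <- peptide(paste0(fb$parent$id, ":", fb$fragments$name[j]),
                       fb$fragments$seq[j])
      ens <- build_ensemble(
        pep_i, pep_j, template, potential,
        n_models = n_models, seed = mix_seed(seed, 1009L, i, j),
        sigma = sigma
      )
      scores[i, j] <- ens$best_score$ndope
    }
  }
  ord <- order(scores)
  cells <- arrayInd(ord, dim(scores))
  best <- data.frame(
    row = fa$fragments$name[cells[, 1]],
    col = fb$fragments$name[cells[, 2]],
    row_span = sprintf("%d-%d", fa$fragments$start[cells[, 1]],
                       fa$fragments$end[cells[, 1]]),
    col_span = sprintf("%d-%d", fb$fragments$start[cells[, 2]],
                       fb$fragments$end[cells[, 2]]),
    ndope = scores[ord],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      rows = fa, cols = fb,
      scores = scores,
      calls = matrix(as.integer(scores <= threshold), nr, nc,
                     dimnames = dimnames(scores)),
      best = best,
      threshold = threshold, n_models = n_models, seed = seed, sigma = sigma
    ),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d x %d cells, %d call(s) at threshold %.3f; best %.3f (%s x %s)\n",
    nrow(x$scores), ncol(x$scores), sum(x$calls), x$threshold,
    x$best$ndope[1], x$best$row[1], x$best$col[1]
  ))
  invisible(x)
}

# Merge runs of consecutively-started called windows of a sliding fragment
# set into maximal position ranges (union of the window spans).
merge_called_windows <- function(fs, called_idx) {
  if (length(called_idx) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  if (fs$scheme != "sliding") {
    f <- fs$fragments[called_idx, , drop = FALSE]
    return(data.frame(start = f$start, end = f$end, name = f$name))
  }
  starts <- fs$fragments$start[sort(called_idx)]
  run <- cumsum(c(1L, diff(starts) != fs$step))
  do.call(rbind, lapply(split(starts, run), function(s) {
    data.frame(start = min(s), end = max(s) + fs$width - 1L)
  }))
}

#' Top-scoring cells and merged interacting regions of a scan
#'
#' Reports the `k` lowest-scoring fragment pairs with their parent
#' coordinates, and — per protein — the called windows merged into maximal
#' runs of consecutive starts (sliding scheme; explicit fragments are
#' reported individually).
#'
#' @param r A [scan_pair()] result.
#' @param k Number of top cells to report.
#' @return List with `top` (data frame), `regions_a`, `regions_b`.
#' @export
best_regions <- function(r, k = 10L) {
  if (k < 1L) stop_validation("k must be >= 1")
  n_cells <- nrow(r$best)
  if (k > n_cells) {
    warning("k = ", k, " exceeds the ", n_cells,
            " scored cells; truncating", call. = FALSE)
    k <- n_cells
  }
  called <- which(r$calls == 1L, arr.ind = TRUE)
  list(
    top = r$best[seq_len(k), , drop = FALSE],
    regions_a = merge_called_windows(r$rows, unique(called[, 1])),
    regions_b = merge_called_windows(r$cols, unique(called[, 2]))
  )
}
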