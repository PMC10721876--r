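# Synthetic fixtures: idealized fibril templates, potential tables, and
# labeled benchmark pair sets with controlled score separation.  Everything
# the pipeline needs can be generated here, seeded, with no downloads.

# 37-residue human amylin (hIAPP) sequence: the default layer sequence of
# the synthetic template, matching the length regime of real cross-beta
# fibril templates.
AMYLIN_SEQ <- "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"

#' Generate an idealized cross-beta fibril template
#'
#' Builds a parallel, in-register stack of extended strands: within a layer,
#' CA positions advance by `strand_rise` (default 3.5 Angstrom, the
#' extended-strand repeat); layers are translated by `layer_spacing`
#' (default 4.8 Angstrom, the cross-beta stacking distance) along the
#' stacking axis.  An optional beta-arch turn at `arch_turn_at` folds the
#' strand back on itself (turn of three residues on a circular arc that
#' preserves the CA-CA spacing).  CB atoms alternate above/below the strand
#' plane; glycines get none.  The geometry is exact by construction and
#' passes every template invariant.
#'
#' @param n_layers Number of stacked chains (>= 4).
#' @param n_res Residues per layer (14..45).
#' @param layer_spacing Stacking translation in Angstrom (4.0..6.0).
#' @param strand_rise CA-CA rise within a strand, Angstrom.
#' @param arch_turn_at Residue index at which the beta-arch turn starts, or
#'   `NULL` for a straight strand.
#' @param template_seq Layer sequence; defaults to the 37-residue amylin
#'   sequence when `n_res` is 37, otherwise to a seeded random sequence.
#' @param seed Seed for the random sequence fallback.
#' @return A [fibril_template()].
#' @export
make_template <- function(n_layers = 4L, n_res = 37L, layer_spacing = 4.8,
                          strand_rise = 3.5, arch_turn_at = NULL,
                          template_seq = NULL, seed = 1L) {
  if (n_layers < 4L) stop_validation("n_layers must be >= 4")
  if (n_res < THREAD_MIN_LEN || n_res > THREAD_MAX_LEN) {
    stop_validation("n_res must be in [", THREAD_MIN_LEN, ", ",
                    THREAD_MAX_LEN, "]")
  }
  if (layer_spacing < 4.0 || layer_spacing > 6.0) {
    stop_validation("layer_spacing outside the cross-beta regime [4, 6]")
  }
  if (is.null(template_seq)) {
    template_seq <- if (n_res == 37L) {
      AMYLIN_SEQ
    } else {
      paste(with_seed(mix_seed(seed, 11L),
                      sample(AA_ALPHABET, n_res, replace = TRUE)),
            collapse = "")
    }
  }
  if (nchar(template_seq) != n_res) {
    stop_validation("template_seq length != n_res")
  }
  # Layer CA trace.
  ca1 <- matrix(NA_real_, n_res, 3)
  if (is.null(arch_turn_at)) {
    ca1[, 1] <- strand_rise * (seq_len(n_res) - 1L)
    ca1[, 2] <- 0
    ca1[, 3] <- 0
  } else {
    t0 <- as.integer(arch_turn_at)
    if (t0 < 4L || t0 > n_res - 6L) {
      stop_validation("arch_turn_at must leave >= 3 residues before and ",
                      ">= 3 after the 3-residue turn")
    }
    # Strand out (+x), 3-residue circular turn of radius = strand_rise
    # (60-degree steps keep the chord exactly strand_rise), strand back
    # (-x) displaced by 2*radius in y.
    r <- strand_rise
    pos <- matrix(NA_real_, n_res, 3)
    for (i in seq_len(t0)) pos[i, ] <- c(strand_rise * (i - 1L), 0, 0)
    # Arc in the xy-plane, centered one radius above the last strand point;
    # the entry point sits at -90 degrees, the turn sweeps to +90 in
    # 60-degree steps whose chord is exactly strand_rise.
    center <- pos[t0, ] + c(0, r, 0)
    for (k in 1:3) {
      ang <- -pi / 2 + k * pi / 3
      pos[t0 + k, ] <- center + c(r * cos(ang), r * sin(ang), 0)
    }
    for (i in seq.int(t0 + 4L, n_res)) {
      pos[i, ] <- pos[i - 1L, ] - c(strand_rise, 0, 0)
    }
    ca1 <- pos
  }
  # CB: alternate on either side of the sheet plane at the ideal CA-CB
  # length.  In a cross-beta stack the sheet plane contains the fibril
  # (stacking) axis, so side chains alternate perpendicular to it — here
  # +/- y, with strands along x and stacking along z.
  res <- seq_chars(template_seq)
  cb1 <- ca1
  cb1[, 2] <- ca1[, 2] + 1.53 * rep_len(c(1, -1), n_res)
  cb1[res == "G", ] <- NA_real_
  ca <- array(NA_real_, c(n_layers, n_res, 3L))
  cb <- array(NA_real_, c(n_layers, n_res, 3L))
  for (l in seq_len(n_layers)) {
    shift <- c(0, 0, (l - 1L) * layer_spacing)
    ca[l, , ] <- sweep(ca1, 2, shift, `+`)
    cb[l, , ] <- sweep(cb1, 2, shift, `+`)
  }
  fibril_template(
    id = sprintf("synthetic_fibril_%dx%d", n_layers, n_res),
    template_seq = template_seq, ca = ca, cb = cb
  )
}

# Residue classes used by the synthetic potential and sequence generators.
STICKY_RES <- c("A", "V", "L", "I", "F", "M", "W", "Y", "Q", "N")
POS_RES <- c("K", "R", "H")
NEG_RES <- c("D", "E")

#' Generate a synthetic potential table
#'
#' Three styles: `"uniform"` (every entry equal to `value`; control),
#' `"delta"` (a single (pair, bin) entry nonzero; locality tests), and
#' `"hydrophobic"` (contacts among hydrophobic and Q/N residues favorable,
#' like-charged contacts unfavorable, short-range clash penalty; a small
#' seeded per-entry jitter breaks exact degeneracy).  All styles are
#' symmetric with contiguous 1-Angstrom bins to a 10-Angstrom cutoff.
#'
#' @param style One of `"hydrophobic"`, `"uniform"`, `"delta"`.
#' @param seed Seed for the jitter (hydrophobic style).
#' @param value Entry value for the uniform style (default 0).
#' @param delta_pair,delta_bin,delta_value The single nonzero entry of the
#'   delta style.
#' @param cutoff,bin_width,min_seq_sep Table geometry.
#' @return A [potential_table].
#' @export
make_potential <- function(style = c("hydrophobic", "uniform", "delta"),
                           seed = 1L, value = 0,
                           delta_pair = c("F", "F"), delta_bin = c(4, 5),
                           delta_value = -1,
                           cutoff = 10, bin_width = 1, min_seq_sep = 2L) {
  style <- match.arg(style)
  bin_edges <- seq(0, cutoff, by = bin_width)
  nb <- length(bin_edges) - 1L
  energies <- array(0, c(20L, 20L, nb))
  if (style == "uniform") {
    energies[] <- value
  } else if (style == "delta") {
    i <- aa_index(delta_pair[1])
    j <- aa_index(delta_pair[2])
    b <- which(bin_edges[-length(bin_edges)] == delta_bin[1] &
                 bin_edges[-1] == delta_bin[2])
    if (length(b) != 1L) stop_validation("delta_bin must match a table bin")
    energies[i, j, b] <- delta_value
    energies[j, i, b] <- delta_value
  } else {
    centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
    depth <- function(a, b) {
      if (a %in% STICKY_RES && b %in% STICKY_RES) return(-1.0)
      same_charge <- (a %in% POS_RES && b %in% POS_RES) ||
        (a %in% NEG_RES && b %in% NEG_RES)
      if (same_charge) return(0.6)
      opp_charge <- (a %in% POS_RES && b %in% NEG_RES) ||
        (a %in% NEG_RES && b %in% POS_RES)
      if (opp_charge) return(-0.2)
      charged <- c(POS_RES, NEG_RES)
      if ((a %in% STICKY_RES && b %in% charged) ||
          (b %in% STICKY_RES && a %in% charged)) {
        return(0.1)
      }
      -0.05
    }
    for (i in 1:20) {
      for (j in i:20) {
        d <- depth(AA_ALPHABET[i], AA_ALPHABET[j])
        for (b in seq_len(nb)) {
          e <- if (centers[b] < 3) {
            1.5
          } else if (centers[b] < 7) {
            d
          } else {
            0.3 * d
          }
          e <- e + with_seed(mix_seed(seed, i, j, b),
                             stats::runif(1, -0.02, 0.02))
          energies[i, j, b] <- e
          energies[j, i, b] <- e
        }
      }
    }
  }
  potential_table(bin_edges, energies, min_seq_sep = min_seq_sep)
}

# Seeded residue-composition sampler.
sample_sequence <- function(len, weights, seed) {
  paste(with_seed(seed, sample(AA_ALPHABET, len, replace = TRUE,
                               prob = weights[AA_ALPHABET])),
        collapse = "")
}

# Composition profiles: aggregation-prone (hydrophobic / Q,N rich) versus
# beta-prone but charged/proline-punctuated non-amyloid sequences.
composition_weights <- function(kind = c("sticky", "charged")) {
  kind <- match.arg(kind)
  w <- stats::setNames(rep(0.5, 20), AA_ALPHABET)
  if (kind == "sticky") {
    w[STICKY_RES] <- 4
    w[c(POS_RES, NEG_RES)] <- 0.2
    w["P"] <- 0.1
  } else {
    w[c(POS_RES, NEG_RES)] <- 4
    w[c("P", "G", "S", "T")] <- 2
    w[STICKY_RES] <- 0.3
  }
  w
}

#' Generate a labeled benchmark pair set with controlled separation
#'
#' Emulates the structure of an interaction benchmark: positive pairs are
#' aggregation-prone sequences (hydrophobic / Q,N-rich composition,
#' alternately labeled `interact_faster` / `interact_slower`), negative
#' pairs are charged, proline-punctuated beta-prone sequences
#' (`non_interacting`).  Lengths are sampled uniformly from the threadable
#' range 14..45.  Every pair is scored through the full pipeline
#' (ensemble threading + potential scoring), and the achieved class means
#' and empirical AUC are reported.  With `signal = FALSE` the positives are
#' drawn from the negative generator (no-signal control).
#'
#' @param n_pos,n_neg Pairs per class.
#' @param template A [fibril_template()].
#' @param potential A [potential_table].
#' @param seed Integer seed (drives sequences, jitter, everything).
#' @param n_models Ensemble size per pair (default 3; the separation
#'   property does not need ensemble depth).
#' @param sigma SC jitter, Angstrom.
#' @param signal If `FALSE`, positives use the negative composition.
#' @return List: `records` (pair records), `scores` (data frame with id_a,
#'   id_b, label, positive, raw, L, ndope), `auc`, `mean_pos`, `mean_neg`.
#' @export
make_benchmark <- function(n_pos, n_neg, template, potential, seed = 1L,
                           n_models = 3L, sigma = 0.3, signal = TRUE) {
  if (n_pos < 1L || n_neg < 1L) stop_validation("n_pos, n_neg must be >= 1")
  w_pos <- composition_weights(if (signal) "sticky" else "charged")
  w_neg <- composition_weights("charged")
  gen_pair <- function(kind, idx, weights, label) {
    len_a <- with_seed(mix_seed(seed, 31L, idx, 1L),
                       sample(THREAD_MIN_LEN:THREAD_MAX_LEN, 1L))
    len_b <- with_seed(mix_seed(seed, 31L, idx, 2L),
                       sample(THREAD_MIN_LEN:THREAD_MAX_LEN, 1L))
    list(
      pep_a = peptide(sprintf("%s%03d_a", kind, idx),
                      sample_sequence(len_a, weights,
                                      mix_seed(seed, 37L, idx, 1L))),
      pep_b = peptide(sprintf("%s%03d_b", kind, idx),
                      sample_sequence(len_b, weights,
                                      mix_seed(seed, 37L, idx, 2L))),
      label = label
    )
  }
  records <- c(
    lapply(seq_len(n_pos), function(i) {
      gen_pair("pos", i, w_pos,
               if (i %% 2L == 1L) "interact_faster" else "interact_slower")
    }),
    lapply(seq_len(n_neg), function(i) {
      gen_pair("neg", n_pos + i, w_neg, "non_interacting")
    })
  )
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    ens <- build_ensemble(r$pep_a, r$pep_b, template, potential,
                          n_models = n_models,
                          seed = mix_seed(seed, 7L, i), sigma = sigma)
    s <- ens$best_score
    data.frame(
      id_a = r$pep_a$id, id_b = r$pep_b$id, label = r$label,
      positive = r$label %in% POSITIVE_LABELS,
      raw = s$raw, L = s$L, ndope = s$ndope,
      stringsAsFactors = FALSE
    )
  })
  scores <- do.call(rbind, rows)
  roc <- roc_curve(scores$ndope[scores$positive],
                   scores$ndope[!scores$positive])
  list(
    records = records,
    scores = scores,
    auc = roc$auc,
    mean_pos = mean(scores$ndope[scores$positive]),
    mean_neg = mean(scores$ndope[!scores$positive])
  )
}
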