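# Threading engine: map query peptides onto the fibril template and build
# coarse-grained 4-chain models (two chains of each peptide).

#' Center-align a query onto the template
#'
#' Queries shorter than the template are aligned to the middle of the
#' template sequence; queries longer than the template overhang both ends,
#' the overhang split evenly with the extra residue on the C-terminal side.
#' The convention is fixed: for `query_len <= template_len` the offset is
#' `floor((template_len - query_len)/2) + 1`, so an odd leftover leaves the
#' extra template residue on the C-terminal side.
#'
#' @param query_len Query length in residues (threadable range 14-45).
#' @param template_len Template layer length (>= 14).
#' @return Object of class `alignment_map` with fields `query_len`,
#'   `template_len`, `offset` (template index, 1-based, where query residue 1
#'   lands; <= 0 for overhanging queries), `covered` (two-column matrix of
#'   (query_idx, template_idx)), `overhang_n`, `overhang_c`.
#' @examples
#' center_align(20, 37) # query 1..20 maps to template 9..28
#' @export
center_align <- function(query_len, template_len) {
  query_len <- as.integer(query_len)
  template_len <- as.integer(template_len)
  check_threadable(query_len)
  if (template_len < THREAD_MIN_LEN) {
    stop_validation("template length ", template_len, " below ",
                    THREAD_MIN_LEN)
  }
  if (query_len <= template_len) {
    offset <- (template_len - query_len) %/% 2L + 1L
    overhang_n <- 0L
    overhang_c <- 0L
    covered <- cbind(
      query_idx = seq_len(query_len),
      template_idx = seq.int(offset, offset + query_len - 1L)
    )
  } else {
    extra <- query_len - template_len
    overhang_n <- extra %/% 2L
    overhang_c <- extra - overhang_n
    if (overhang_n > MAX_OVERHANG || overhang_c > MAX_OVERHANG) {
      stop_validation(
        "template too short: query overhangs by ", overhang_n, "/",
        overhang_c, " residues (max ", MAX_OVERHANG, " per terminus)"
      )
    }
    offset <- 1L - overhang_n
    covered <- cbind(
      query_idx = seq.int(overhang_n + 1L, overhang_n + template_len),
      template_idx = seq_len(template_len)
    )
  }
  structure(
    list(
      query_len = query_len, template_len = template_len,
      offset = offset, covered = covered,
      overhang_n = overhang_n, overhang_c = overhang_c
    ),
    class = "alignment_map"
  )
}

# Step length for CA extrapolation of residues overhanging the template ends
# (extended-strand rise).
OVERHANG_CA_STEP <- 3.8

#' Thread one peptide chain onto a template layer
#'
#' Covered residues inherit the template layer's CA coordinates exactly; the
#' side-chain centroid (SC) is placed along the template CA->CB direction at
#' a residue-specific distance (glycine gets none).  Residues overhanging the
#' template extend the terminal strand direction with 3.8 Angstrom CA steps.
#'
#' @param pep A [peptide()].
#' @param template A [fibril_template()].
#' @param layer Layer index (1..n_layers) to thread onto.
#' @param align An [center_align()] map consistent with `pep` and `template`.
#' @return List with `seq`, `ca` (query_len x 3), `sc` (query_len x 3; `NA`
#'   rows for glycine).
#' @export
thread_chain <- function(pep, template, layer, align) {
  stopifnot(inherits(pep, "peptide"), inherits(template, "fibril_template"))
  if (layer < 1L || layer > template$n_layers) {
    stop_validation("layer ", layer, " outside 1..", template$n_layers)
  }
  if (align$query_len != pep$length ||
      align$template_len != template$n_res) {
    stop_validation("alignment map inconsistent with peptide/template")
  }
  res <- seq_chars(pep)
  n <- pep$length
  ca <- matrix(NA_real_, n, 3)
  sc <- matrix(NA_real_, n, 3)
  t_ca <- template$ca[layer, , , drop = TRUE]
  t_cb <- template$cb[layer, , , drop = TRUE]
  qi <- align$covered[, "query_idx"]
  ti <- align$covered[, "template_idx"]
  ca[qi, ] <- t_ca[ti, ]
  # SC direction from the template CA->CB unit vector; for template glycines
  # (no CB) fall back to the mean CB direction of the layer's neighbors.
  dir_mat <- t_cb - t_ca
  for (k in seq_along(qi)) {
    aa <- res[qi[k]]
    if (aa == "G") next
    v <- dir_mat[ti[k], ]
    if (anyNA(v)) {
      ok <- which(!is.na(dir_mat[, 1]))
      j <- ok[which.min(abs(ok - ti[k]))]
      v <- dir_mat[j, ]
    }
    v <- v / sqrt(sum(v^2))
    sc[qi[k], ] <- ca[qi[k], ] + SC_DISTANCE[[aa]] * v
  }
  # Overhangs: continue the terminal strand direction.
  if (align$overhang_n > 0L) {
    d <- t_ca[1, ] - t_ca[2, ]
    d <- d / sqrt(sum(d^2))
    first_cov <- align$overhang_n + 1L
    for (i in seq.int(align$overhang_n, 1L)) {
      ca[i, ] <- ca[i + 1L, ] + OVERHANG_CA_STEP * d
      if (res[i] != "G") {
        v <- dir_mat[1, ]
        if (anyNA(v)) v <- c(0, 0, 1)
        v <- v / sqrt(sum(v^2))
        sc[i, ] <- ca[i, ] + SC_DISTANCE[[res[i]]] * v
      }
    }
    stopifnot(first_cov >= 1L)
  }
  if (align$overhang_c > 0L) {
    m <- template$n_res
    d <- t_ca[m, ] - t_ca[m - 1L, ]
    d <- d / sqrt(sum(d^2))
    last_cov <- n - align$overhang_c
    for (i in seq.int(last_cov + 1L, n)) {
      ca[i, ] <- ca[i - 1L, ] + OVERHANG_CA_STEP * d
      if (res[i] != "G") {
        v <- dir_mat[m, ]
        if (anyNA(v)) v <- c(0, 0, 1)
        v <- v / sqrt(sum(v^2))
        sc[i, ] <- ca[i, ] + SC_DISTANCE[[res[i]]] * v
      }
    }
  }
  list(seq = pep$seq, ca = ca, sc = sc)
}

#' Build a coarse-grained heterotetramer model
#'
#' Threads two peptides onto the first four template layers in the
#' alternating stacking pattern A,B,A,B (chains 1 and 3 carry `pep_a`,
#' chains 2 and 4 carry `pep_b`), maximizing A-B interfaces.  Each
#' side-chain centroid is perturbed by isotropic Gaussian noise of standard
#' deviation `sigma`; the generator for every point is seeded independently
#' from `(seed, model_index, chain, residue)`, so any model is reproducible
#' in isolation and `sigma = 0` is fully deterministic.
#'
#' @param pep_a,pep_b [peptide()] objects (homoaggregation: pass the same
#'   peptide twice).
#' @param template A [fibril_template()].
#' @param seed Integer seed.
#' @param sigma SC jitter standard deviation in Angstrom (default 0.3).
#' @param model_index Index of this model within an ensemble (default 1).
#' @return Object of class `threaded_model`.
#' @export
build_hetero_model <- function(pep_a, pep_b, template, seed = 1L,
                               sigma = 0.3, model_index = 1L) {
  check_threadable(pep_a$length, paste0("peptide '", pep_a$id, "'"))
  check_threadable(pep_b$length, paste0("peptide '", pep_b$id, "'"))
  align_a <- center_align(pep_a$length, template$n_res)
  align_b <- center_align(pep_b$length, template$n_res)
  pattern <- list(
    list(pep = pep_a, align = align_a),
    list(pep = pep_b, align = align_b),
    list(pep = pep_a, align = align_a),
    list(pep = pep_b, align = align_b)
  )
  if (sigma > 0) {
    # Counter-based jitter: an isolated RNG stream per SC point.  The
    # caller's RNG state is saved and restored so model building never
    # disturbs the session stream.
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    }, add = TRUE)
  }
  chains <- vector("list", 4L)
  for (k in 1:4) {
    ch <- thread_chain(pattern[[k]]$pep, template, k, pattern[[k]]$align)
    if (sigma > 0) {
      for (i in seq_len(nrow(ch$sc))) {
        if (is.na(ch$sc[i, 1])) next
        set.seed(mix_seed(seed, model_index, k, i))
        ch$sc[i, ] <- ch$sc[i, ] + stats::rnorm(3, 0, sigma)
      }
    }
    chains[[k]] <- ch
  }
  structure(
    list(
      chains = chains,
      pep_a = pep_a, pep_b = pep_b,
      template_id = template$id,
      align_a = align_a, align_b = align_b,
      seed = as.integer(seed), sigma = sigma,
      model_index = as.integer(model_index)
    ),
    class = "threaded_model"
  )
}

#' @export
print.threaded_model <- function(x, ...) {
  cat(sprintf(
    "<threaded_model> %s + %s on %s (A,B,A,B), seed %d, model %d\n",
    x$pep_a$id, x$pep_b$id, x$template_id, x$seed, x$model_index
  ))
  invisible(x)
}

#' Build a model ensemble and keep the lowest-energy model
#'
#' Builds `n_models` models with model indices 1..n_models and returns the
#' one with the lowest raw potential energy (ties broken by the lowest model
#' index), mirroring the build-10-keep-best modeling protocol.
#'
#' @inheritParams build_hetero_model
#' @param potential A [potential_table].
#' @param n_models Ensemble size (default 10).
#' @return List with `best` (a `threaded_model`), `best_score` (its
#'   [evaluate_energy()] result) and `energies` (raw energy per model).
#' @export
build_ensemble <- function(pep_a, pep_b, template, potential,
                           n_models = 10L, seed = 1L, sigma = 0.3) {
  if (n_models < 1L) {
    stop_validation("n_models must be >= 1")
  }
  energies <- numeric(n_models)
  best <- NULL
  best_score <- NULL
  for (m in seq_len(n_models)) {
    model <- build_hetero_model(pep_a, pep_b, template,
                                seed = seed, sigma = sigma, model_index = m)
    score <- evaluate_energy(model, potential)
    energies[m] <- score$raw
    if (is.null(best) || score$raw < best_score$raw) {
      best <- model
      best_score <- score
    }
  }
  list(best = best, best_score = best_score, energies = energies)
}
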