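# Shared fixtures and independent oracles.  The oracles are deliberately
# naive (double loops, exhaustive scans, enumeration) and written separately
# from the implementation paths they check.

fixture_template <- function(...) make_template(...)

# A random coarse-grained 4-chain toy model (not threaded from a template):
# chains of <= max_len residues with random coordinates in a box small
# enough that many pairs fall inside a 10 A cutoff.
random_toy_model <- function(seed, max_len = 30L, box = 15) {
  set.seed(seed)
  len_a <- sample(5:max_len, 1L)
  len_b <- sample(5:max_len, 1L)
  lens <- c(len_a, len_b, len_a, len_b)
  seqs <- c(
    paste(sample(AA_ALPHABET, len_a, replace = TRUE), collapse = ""),
    paste(sample(AA_ALPHABET, len_b, replace = TRUE), collapse = "")
  )[c(1, 2, 1, 2)]
  chains <- lapply(1:4, function(k) {
    n <- lens[k]
    ca <- matrix(runif(3 * n, 0, box), n, 3)
    sc <- ca + matrix(rnorm(3 * n, 0, 1), n, 3)
    res <- strsplit(seqs[k], "")[[1]]
    sc[res == "G", ] <- NA_real_
    list(seq = seqs[k], ca = ca, sc = sc)
  })
  structure(
    list(
      chains = chains,
      pep_a = peptide("toy_a", seqs[1]),
      pep_b = peptide("toy_b", seqs[2]),
      template_id = "toy", seed = seed, sigma = 0, model_index = 1L
    ),
    class = "threaded_model"
  )
}

# Independent total-energy oracle: explicit double loop over all point
# pairs, manual bin lookup (no calls into the vectorized scoring path).
brute_force_energy <- function(model, table) {
  pts <- list()
  for (k in seq_along(model$chains)) {
    ch <- model$chains[[k]]
    res <- strsplit(ch$seq, "")[[1]]
    for (i in seq_along(res)) {
      p <- ch$sc[i, ]
      if (anyNA(p)) p <- ch$ca[i, ]
      pts[[length(pts) + 1L]] <- list(xyz = p, type = res[i],
                                      chain = k, resi = i)
    }
  }
  lo <- table$bin_edges[-length(table$bin_edges)]
  hi <- table$bin_edges[-1]
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    for (j in seq.int(i + 1L, length(pts))) {
      a <- pts[[i]]; b <- pts[[j]]
      same_chain <- a$chain == b$chain
      if (same_chain && abs(a$resi - b$resi) < table$min_seq_sep) next
      d <- sqrt(sum((a$xyz - b$xyz)^2))
      if (d >= table$cutoff) next
      bin <- which(lo <= d & d < hi)
      if (length(bin) != 1L) next
      total <- total +
        table$energies[match(a$type, AA_ALPHABET),
                       match(b$type, AA_ALPHABET), bin]
    }
  }
  total
}

# Pair-counting AUC oracle: U / (n_pos * n_neg), positives counted when they
# score LOWER than negatives, ties 0.5.
auc_pair_count <- function(pos, neg) {
  u <- 0
  for (p in pos) {
    for (n in neg) {
      u <- u + if (p < n) 1 else if (p == n) 0.5 else 0
    }
  }
  u / (length(pos) * length(neg))
}

# Exhaustive threshold-selection oracle with the documented tie-breaks
# (lower FPR, then lower threshold).
select_threshold_oracle <- function(roc) {
  p <- roc$points
  best <- NULL
  for (i in seq_len(nrow(p))) {
    d <- sqrt(p$fpr[i]^2 + (1 - p$tpr[i])^2)
    if (is.null(best) || d < best$d ||
        (d == best$d && (p$fpr[i] < best$fpr ||
                         (p$fpr[i] == best$fpr &&
                            p$threshold[i] < best$thr)))) {
      best <- list(d = d, fpr = p$fpr[i], thr = p$threshold[i])
    }
  }
  best$thr
}

# Direct-formula metric oracle with explicit zero-denominator handling
# (F1 undefined when precision or recall is).
metrics_oracle <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    acc = div(tp + tn, tp + fp + tn + fn),
    sens = div(tp, tp + fn),
    spec = div(tn, tn + fp),
    f1 = if (tp + fp == 0 || tp + fn == 0) NA_real_
         else 2 * tp / (2 * tp + fp + fn),
    mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  )
}

# Exact two-sided Mann-Whitney p by enumeration over all assignments of the
# combined (tie-free) values to group a.
mwu_enum_p <- function(a, b) {
  comb <- c(a, b)
  n_a <- length(a)
  u_of <- function(av, bv) {
    u <- 0
    for (x in av) for (y in bv) u <- u + (x < y) + 0.5 * (x == y)
    u
  }
  obs <- u_of(a, b)
  idx <- utils::combn(length(comb), n_a)
  stats <- apply(idx, 2, function(ii) u_of(comb[ii], comb[-ii]))
  min(1, 2 * min(mean(stats <= obs), mean(stats >= obs)))
}

# Rigid-body transform of a model (random rotation + translation).
transform_model <- function(model, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  rot <- qr.Q(qr(m))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- runif(3, -50, 50)
  model$chains <- lapply(model$chains, function(ch) {
    ch$ca <- sweep(ch$ca %*% rot, 2, shift, `+`)
    ok <- !is.na(ch$sc[, 1])
    ch$sc[ok, ] <- sweep(ch$sc[ok, , drop = FALSE] %*% rot, 2, shift, `+`)
    ch
  })
  model
}

# Random scored-record frame with a given class separation.
random_scored_frame <- function(n_pos, n_neg, sep = 3, seed = 1L) {
  set.seed(seed)
  data.frame(
    score = c(rnorm(n_pos, -sep), rnorm(n_neg, 0)),
    positive = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}
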