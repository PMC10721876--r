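# Threshold classification of ndope scores and the full evaluation
# protocol: ROC calibration, metric suite, stratified split and k-fold CV,
# Mann-Whitney comparison of score distributions.
#
# Orientation throughout: LOWER score = positive (more stable model = more
# likely interaction); the decision boundary is inclusive (score == threshold
# is called positive, label 1).

# Run expr with a private RNG stream; the session stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Threshold classification of a score
#'
#' Label 1 (interacting) iff `score <= threshold`, else 0.
#'
#' @param score ndope score(s); lower means more stable.
#' @param threshold Decision threshold (inclusive).
#' @return Integer vector of 1/0 calls.
#' @examples
#' classify(c(-257.39, -256.52, -200), threshold = -256)
#' @export
classify <- function(score, threshold) {
  if (!all(is.finite(score)) || !is.finite(threshold)) {
    stop_validation("scores and threshold must be finite")
  }
  as.integer(score <= threshold)
}

#' ROC curve for score-threshold classification
#'
#' Candidate thresholds are the sorted unique observed scores plus -Inf/+Inf
#' sentinels; at each threshold `t`, `TPR` is the fraction of positives and
#' `FPR` the fraction of negatives with score `<= t`.  The AUC is computed
#' by rank statistics and equals the tie-corrected pair count
#' `U / (n_pos * n_neg)` where `U` counts (positive, negative) pairs with
#' the positive scoring lower, ties at 0.5.
#'
#' @param pos_scores Scores of the positive (interacting) class.
#' @param neg_scores Scores of the negative class.
#' @return Object of class `roc_curve`: data frame `points` (threshold,
#'   fpr, tpr), `auc`, `n_pos`, `n_neg`, `positive_rule`.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_validation("both score lists must be nonempty")
  }
  thr <- c(-Inf, sort(unique(c(pos_scores, neg_scores))), Inf)
  tpr <- vapply(thr, function(t) mean(pos_scores <= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_scores <= t), 0)
  r <- rank(c(pos_scores, neg_scores))
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  u <- sum(r[seq.int(n_pos + 1L, n_pos + n_neg)]) - n_neg * (n_neg + 1) / 2
  structure(
    list(
      points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
      auc = u / (n_pos * n_neg),
      n_pos = n_pos, n_neg = n_neg,
      positive_rule = "score <= threshold -> positive"
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d pos / %d neg, AUC %.4f (%s)\n",
              x$n_pos, x$n_neg, x$auc, x$positive_rule))
  invisible(x)
}

#' Select the operating threshold from a ROC curve
#'
#' Chooses the threshold whose ROC point is closest (Euclidean) to the
#' perfect-classification corner (0, 1).  Ties are broken by lower FPR,
#' then by lower (more negative) threshold.
#'
#' @param roc A [roc_curve()] object.
#' @return The selected threshold, with attributes `fpr`, `tpr`,
#'   `distance`.
#' @export
select_threshold <- function(roc) {
  p <- roc$points
  dist <- sqrt(p$fpr^2 + (1 - p$tpr)^2)
  best <- order(dist, p$fpr, p$threshold)[1L]
  structure(
    p$threshold[best],
    fpr = p$fpr[best], tpr = p$tpr[best], distance = dist[best]
  )
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; at least one must be
#'   positive.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) < 1) {
    stop_validation("confusion counts must be non-negative, total >= 1")
  }
  structure(as.list(counts), class = "confusion_counts")
}

# Tabulate predictions (1/0) against truth (logical positive).
tabulate_confusion <- function(pred, positive) {
  confusion_counts(
    tp = sum(pred == 1L & positive),
    fp = sum(pred == 1L & !positive),
    tn = sum(pred == 0L & !positive),
    fn = sum(pred == 0L & positive)
  )
}

#' Classification metric suite
#'
#' Accuracy, sensitivity, specificity, F1 and the Matthews correlation
#' coefficient from confusion counts.  Any metric with a zero denominator is
#' reported as `NA`, never silently 0.
#'
#' @param counts A [confusion_counts()] object.
#' @param auc Optional AUC to carry alongside (not derivable from counts).
#' @return Named list (class `metric_set`) with `acc`, `sens`, `spec`,
#'   `f1`, `mcc`, `auc`.
#' @export
metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  # F1 is undefined when precision (no predicted positives) or recall (no
  # actual positives) is undefined.
  f1 <- if (tp + fp == 0 || tp + fn == 0) {
    NA_real_
  } else {
    2 * tp / (2 * tp + fp + fn)
  }
  structure(
    list(
      acc = safe_div(tp + tn, n),
      sens = safe_div(tp, tp + fn),
      spec = safe_div(tn, tn + fp),
      f1 = f1,
      mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
      auc = auc
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  vals <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = digits, format = "f")
  }, "")
  cat("<metric_set> ", paste(names(vals), vals, sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

# Normalize scored records into a data frame with columns score / positive.
# Accepts a data frame (columns ndope-or-score + label-or-positive) as
# produced by the scoring pipeline.
as_scored_frame <- function(records) {
  df <- as.data.frame(records)
  score <- df$score %||% df$ndope
  if (is.null(score)) {
    stop_validation("scored records need a 'score' or 'ndope' column")
  }
  positive <- df$positive
  if (is.null(positive)) {
    if (is.null(df$label)) {
      stop_validation("scored records need a 'label' or 'positive' column")
    }
    unknown <- setdiff(unique(df$label), c(POSITIVE_LABELS, NEGATIVE_LABELS))
    if (length(unknown)) {
      stop_validation("label(s) without a class assignment: ",
                      paste(unknown, collapse = ", "))
    }
    positive <- df$label %in% POSITIVE_LABELS
  }
  data.frame(score = as.numeric(score), positive = as.logical(positive))
}

#' Stratified train/test split
#'
#' Splits scored records into train and test sets, stratified by class, with
#' `round(test_fraction * n)` records per class in the test set.  The
#' shuffle is seeded and reproducible.
#'
#' @param records Scored records (data frame with `score`/`ndope` and
#'   `label`/`positive` columns).
#' @param test_fraction Fraction in (0, 1); the conventional evaluation
#'   holds out 30 percent.
#' @param seed Integer seed.
#' @return List with data frames `train` and `test`.
#' @export
train_test_split <- function(records, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_validation("test_fraction must be in (0, 1)")
  }
  df <- as_scored_frame(records)
  idx_test <- integer()
  for (cls in c(TRUE, FALSE)) {
    idx <- which(df$positive == cls)
    n_test <- round(test_fraction * length(idx))
    if (length(idx) < 2L || n_test < 1L || n_test >= length(idx)) {
      stop_validation(
        "class sizes too small for a ", test_fraction, " split ",
        "(", length(idx), " records in one class)"
      )
    }
    shuffled <- with_seed(mix_seed(seed, 151L, as.integer(cls)),
                          sample(idx))
    idx_test <- c(idx_test, shuffled[seq_len(n_test)])
  }
  list(
    train = df[-idx_test, , drop = FALSE],
    test = df[idx_test, , drop = FALSE]
  )
}

#' Stratified k-fold cross-validation of the threshold classifier
#'
#' For each fold, the threshold is calibrated on the k-1 training folds
#' ([roc_curve()] + [select_threshold()]) and all metrics are computed on
#' the held-out fold (AUC from the held-out scores).  Folds are stratified
#' by class from a seeded shuffle.
#'
#' @param records Scored records (see [train_test_split()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List with `folds` (data frame of per-fold metrics), `mean` and
#'   `sd` (named vectors; sample sd, computed over folds with the metric
#'   defined).
#' @export
kfold_cv <- function(records, k = 5L, seed = 1L) {
  if (k < 2L) stop_validation("k must be >= 2")
  df <- as_scored_frame(records)
  fold <- integer(nrow(df))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(df$positive == cls)
    if (length(idx) < k) {
      stop_validation("each class needs at least k = ", k, " records (",
                      length(idx), " found)")
    }
    shuffled <- with_seed(mix_seed(seed, 271L, as.integer(cls)),
                          sample(idx))
    fold[shuffled] <- rep_len(seq_len(k), length(idx))
  }
  fold_metrics <- lapply(seq_len(k), function(f) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    roc <- roc_curve(train$score[train$positive],
                     train$score[!train$positive])
    thr <- select_threshold(roc)
    pred <- classify(test$score, as.numeric(thr))
    test_auc <- roc_curve(test$score[test$positive],
                          test$score[!test$positive])$auc
    m <- metrics(tabulate_confusion(pred, test$positive), auc = test_auc)
    c(fold = f, threshold = as.numeric(thr), unlist(m))
  })
  folds <- as.data.frame(do.call(rbind, fold_metrics))
  metric_cols <- c("acc", "sens", "spec", "f1", "mcc", "auc")
  list(
    folds = folds,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    sd = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE), 0)
  )
}

#' Mann-Whitney U comparison of two score distributions
#'
#' `U` (for sample `a`) counts pairs where `a` scores lower than `b`, ties
#' at 0.5.  The two-sided p-value is exact (enumeration) when the smaller
#' sample has at most 8 observations and there are no ties; otherwise it
#' uses the normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric score vectors.
#' @return List with `U` and `p`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 4
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_validation("both samples must be nonempty")
  }
  r <- rank(c(a, b))
  n_a <- length(a)
  n_b <- length(b)
  u <- sum(r[seq.int(n_a + 1L, n_a + n_b)]) - n_b * (n_b + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- min(n_a, n_b) <= 8L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  )
  list(U = u, p = p)
}

#' Calibrate the classifier on labeled scores
#'
#' Convenience wrapper: builds the ROC curve, selects the threshold closest
#' to (0, 1), and returns a classed calibration object whose `predict`
#' method applies [classify()].
#'
#' @param pos_scores,neg_scores Scores of the two classes.
#' @return Object of class `ndope_calibration`.
#' @export
calibrate_threshold <- function(pos_scores, neg_scores) {
  roc <- roc_curve(pos_scores, neg_scores)
  thr <- select_threshold(roc)
  structure(
    list(
      threshold = as.numeric(thr),
      fpr = attr(thr, "fpr"), tpr = attr(thr, "tpr"),
      distance = attr(thr, "distance"),
      auc = roc$auc, n_pos = roc$n_pos, n_neg = roc$n_neg,
      roc = roc
    ),
    class = "ndope_calibration"
  )
}

#' @export
print.ndope_calibration <- function(x, ...) {
  cat(sprintf(
    paste0("<ndope_calibration> threshold %.4f ",
           "(FPR %.3f, TPR %.3f, dist %.3f), AUC %.4f on %d pos / %d neg\n"),
    x$threshold, x$fpr, x$tpr, x$distance, x$auc, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
predict.ndope_calibration <- function(object, newdata, ...) {
  classify(newdata, object$threshold)
}
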