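test_that("classification is inclusive at the boundary, lower = positive", {
  expect_equal(classify(-257.39, -256), 1L)
  expect_equal(classify(-256.52, -256), 1L)
  expect_equal(classify(-256, -256), 1L)
  expect_equal(classify(-255.9, -256), 0L)
  # Monotone: lowering a score never flips 1 -> 0.
  set.seed(3)
  s <- rnorm(50)
  expect_true(all(classify(s - abs(rnorm(50)), 0) >= classify(s, 0)))
})

test_that("roc_curve spans (0,0) to (1,1) and separable data reach (0,1)", {
  roc <- roc_curve(c(-300, -280), c(-200, -180))
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_true(any(roc$points$fpr == 0 & roc$points$tpr == 1))
  expect_equal(roc$auc, 1)
  expect_error(roc_curve(numeric(), c(1)), "nonempty")
})

test_that("identical score multisets give AUC 0.5", {
  s <- c(-5, -3, -3, 0, 2)
  expect_equal(roc_curve(s, s)$auc, 0.5)
})

test_that("AUC equals the tie-corrected pair-count oracle", {
  set.seed(42)
  for (i in 1:30) {
    n_pos <- sample(2:50, 1)
    n_neg <- sample(2:50, 1)
    pos <- sample(seq(-20, 0, by = 0.5), n_pos, replace = TRUE)
    neg <- sample(seq(-15, 5, by = 0.5), n_neg, replace = TRUE)
    expect_equal(roc_curve(pos, neg)$auc, auc_pair_count(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("complementary AUCs sum to one on tie-free data", {
  set.seed(7)
  pos <- rnorm(20); neg <- rnorm(25)
  expect_equal(roc_curve(pos, neg)$auc + roc_curve(neg, pos)$auc, 1)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  pos <- rnorm(40, -1); neg <- rnorm(35, 0)
  ours <- roc_curve(pos, neg)$auc
  ref <- suppressMessages(pROC::auc(
    response = rep(c(1, 0), c(40, 35)), predictor = c(pos, neg),
    direction = ">"
  ))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("select_threshold matches the exhaustive-scan oracle", {
  roc <- roc_curve(c(-300, -280), c(-200, -180))
  thr <- select_threshold(roc)
  expect_equal(attr(thr, "distance"), 0)
  expect_equal(attr(thr, "fpr"), 0)
  expect_equal(attr(thr, "tpr"), 1)

  thr1 <- select_threshold(roc_curve(-10, 0))
  expect_equal(as.numeric(thr1), -10)

  set.seed(13)
  for (i in 1:40) {
    pos <- sample(-10:0, sample(2:20, 1), replace = TRUE)  # ties frequent
    neg <- sample(-8:4, sample(2:20, 1), replace = TRUE)
    roc <- roc_curve(pos, neg)
    expect_equal(as.numeric(select_threshold(roc)),
                 select_threshold_oracle(roc))
  }
})

test_that("metrics match direct arithmetic, NA on zero denominators", {
  m <- metrics(confusion_counts(5, 0, 5, 0))
  expect_equal(unlist(m[c("acc", "sens", "spec", "f1", "mcc")]),
               c(acc = 1, sens = 1, spec = 1, f1 = 1, mcc = 1))
  m <- metrics(confusion_counts(2, 1, 2, 1))
  expect_equal(m$mcc, 1 / 3)
  expect_equal(m$f1, 2 / 3)
  m <- metrics(confusion_counts(0, 0, 3, 2))  # no predicted positives
  expect_true(is.na(m$f1))
  expect_true(is.na(m$mcc))
  expect_true(is.na(m$sens) || m$sens == 0)  # tp+fn = 2 -> sens defined 0
  expect_equal(m$sens, 0)

  set.seed(21)
  for (i in 1:200) {
    cc <- sample(0:8, 4, replace = TRUE)
    if (sum(cc) == 0) cc[1] <- 1
    got <- metrics(confusion_counts(cc[1], cc[2], cc[3], cc[4]))
    want <- metrics_oracle(cc[1], cc[2], cc[3], cc[4])
    for (k in names(want)) expect_equal(got[[k]], want[[k]])
  }
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("shifting all scores shifts the threshold, not the metrics", {
  df <- random_scored_frame(30, 30, sep = 2, seed = 5)
  shift <- 123.45
  cal0 <- calibrate_threshold(df$score[df$positive], df$score[!df$positive])
  cal1 <- calibrate_threshold(df$score[df$positive] + shift,
                              df$score[!df$positive] + shift)
  expect_equal(cal1$threshold, cal0$threshold + shift)
  expect_equal(cal1$auc, cal0$auc)
  expect_equal(cal1$fpr, cal0$fpr)
  expect_equal(cal1$tpr, cal0$tpr)
})

test_that("train_test_split is stratified, seeded and validated", {
  df <- random_scored_frame(50, 50, seed = 9)
  sp <- train_test_split(df, test_fraction = 0.3, seed = 4)
  expect_equal(sum(sp$test$positive), 15)
  expect_equal(sum(!sp$test$positive), 15)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  sp2 <- train_test_split(df, test_fraction = 0.3, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- train_test_split(df, test_fraction = 0.3, seed = 5)
  expect_false(identical(sp$test, sp3$test))
  expect_error(train_test_split(df, test_fraction = 1.0), "\\(0, 1\\)")
  expect_error(train_test_split(df[1:51, ], test_fraction = 0.3),
               "too small")
})

test_that("kfold_cv partitions, recalibrates per fold, and is seeded", {
  # Separable classes whose maximum positive score is duplicated across
  # folds, so every fold's calibrated threshold covers its held-out
  # positive.
  df <- data.frame(score = c(-12, -11, -10, -10, -10, 0, 1, 2, 3, 4),
                   positive = rep(c(TRUE, FALSE), each = 5))
  cv <- kfold_cv(df, k = 5, seed = 1)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(unname(cv$mean["acc"]), 1)   # widely separable classes
  expect_equal(unname(cv$sd["acc"]), 0)
  cv2 <- kfold_cv(df, k = 5, seed = 1)
  expect_identical(cv, cv2)
  expect_error(kfold_cv(df, k = 6), "at least k")
  expect_error(kfold_cv(df, k = 1), ">= 2")
})

test_that("mann_whitney U counts pairs favoring the first sample", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 4)
  r <- mann_whitney(5, 5)
  expect_equal(r$U, 0.5)
})

test_that("mann_whitney exact p matches rank-assignment enumeration", {
  set.seed(31)
  for (i in 1:10) {
    n_a <- sample(3:6, 1)
    n_b <- sample(3:7, 1)
    vals <- sample(1:100, n_a + n_b)  # tie-free
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    got <- mann_whitney(a, b)
    expect_equal(got$p, mwu_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("mann_whitney separates the benchmark score distributions", {
  df <- random_scored_frame(40, 40, sep = 3, seed = 17)
  r <- mann_whitney(df$score[df$positive], df$score[!df$positive])
  expect_lt(r$p, 1e-6)
  expect_gt(r$U, 40 * 40 / 2)
})
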