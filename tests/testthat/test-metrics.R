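test_that("confusion tallies match hand counts and partition n", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  yt <- c(1, 1, 0, 0); cm2 <- confusion(yt, 1 - yt)
  expect_equal(cm2$TP + cm2$TN, 0)
  set.seed(50)
  for (i in 1:20) {
    a <- sample(0:1, 30, TRUE); b <- sample(0:1, 30, TRUE)
    cc <- confusion(a, b)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 30)
  }
  expect_error(confusion(c(1, 2), c(0, 1)), "binary")
})

test_that("rate metrics follow their confusion-matrix formulas", {
  perfect <- classification_metrics(confusion(rep(c(1, 0), 50),
                                              rep(c(1, 0), 50)))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  cm <- structure(list(TP = 40, TN = 30, FP = 10, FN = 20),
                  class = "confusion_counts")
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.7, tolerance = 1e-4)
  expect_equal(m$precision, 0.8, tolerance = 1e-4)
  expect_equal(m$recall, 0.6667, tolerance = 1e-4)
  expect_equal(m$f1, 0.7273, tolerance = 1e-4)
  expect_equal(m$fpr, 0.25, tolerance = 1e-12)
  # the halved printed variant is exactly one quarter of the standard F1
  mh <- classification_metrics(cm, f1_variant = "printed_half")
  expect_equal(mh$f1, m$f1 / 4, tolerance = 1e-12)
  degenerate <- structure(list(TP = 0, TN = 5, FP = 0, FN = 5),
                          class = "confusion_counts")
  expect_warning(
    expect_warning(dm <- classification_metrics(degenerate), "F1"),
    "precision")
  expect_equal(dm$precision, 0)
})

test_that("metrics match brute-force tallies on random fixtures", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    yt <- sample(0:1, n, TRUE)
    yp <- sample(0:1, n, TRUE)
    cc <- confusion(yt, yp)
    o <- oracle_counts(yt, yp)
    expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), as.numeric(o),
                 tolerance = 1e-10)
    m <- classification_metrics(suppressWarnings(cc))
    expect_equal(suppressWarnings(m$accuracy),
                 (o["TP"] + o["TN"]) / n, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("AUC equals Mann-Whitney concordance and handles ties", {
  y <- c(rep(0, 10), rep(1, 10))
  s <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  r <- roc_curve(y, s)
  expect_equal(auc(r$fpr, r$tpr), 1.0)
  set.seed(52)
  for (i in 1:50) {
    n <- sample(12:60, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(runif(n), 2)  # coarse scores force ties
    r <- roc_curve(y, s)
    expect_equal(auc(r$fpr, r$tpr), oracle_auc(y, s), tolerance = 1e-10)
  }
  expect_error(roc_curve(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC is near one half for label-independent scores", {
  set.seed(53)
  n <- 4000
  y <- sample(0:1, n, TRUE)
  s <- runif(n)
  r <- roc_curve(y, s)
  # null s.e. of the Mann-Whitney statistic is about sqrt(n+1/(12 np nn))
  np <- sum(y); nn <- n - np
  se <- sqrt((np + nn + 1) / (12 * np * nn))
  expect_lt(abs(auc(r$fpr, r$tpr) - 0.5), 3 * se)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(54)
  y <- sample(0:1, 100, TRUE)
  s <- rnorm(100)
  r1 <- roc_curve(y, s); r2 <- roc_curve(y, exp(s) + 5)
  expect_equal(auc(r1$fpr, r1$tpr), auc(r2$fpr, r2$tpr), tolerance = 1e-12)
})

test_that("dice and IoU agree with closed forms and each other", {
  a <- matrix(0L, 20, 20); a[1:10, 1:10] <- 1L
  expect_equal(dice_score(a, a, 1L), 1.0)
  b <- matrix(0L, 20, 20); b[11:20, 11:20] <- 1L
  expect_equal(dice_score(a, b, 1L), 0.0)
  # 100 px each, overlap 50
  c1 <- matrix(0L, 20, 20); c1[1:10, 1:10] <- 1L
  c2 <- matrix(0L, 20, 20); c2[6:15, 1:10] <- 1L
  expect_equal(dice_score(c1, c2, 1L), 0.5)
  expect_equal(dice_score(matrix(0L, 5, 5), matrix(0L, 5, 5), 1L), 1.0)
  # symmetry, permutation invariance, and the dice/IoU identity
  set.seed(55)
  for (i in 1:30) {
    m1 <- matrix(sample(0:1, 64, TRUE), 8, 8)
    m2 <- matrix(sample(0:1, 64, TRUE), 8, 8)
    d <- dice_score(m1, m2, 1L)
    expect_equal(d, dice_score(m2, m1, 1L), tolerance = 1e-12)
    expect_equal(iou(m1, m2, 1L), d / (2 - d), tolerance = 1e-12)
    perm <- sample(64)
    expect_equal(dice_score(matrix(m1[perm], 8, 8), matrix(m2[perm], 8, 8),
                            1L), d, tolerance = 1e-12)
  }
  expect_error(dice_score(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("metric_report carries every confusion-derived quantity plus AUC", {
  set.seed(56)
  y <- sample(0:1, 200, TRUE)
  s <- plogis(rnorm(200) + 2 * y)
  rep_ <- metric_report(y, s)
  expect_true(all(c("accuracy", "precision", "recall", "f1", "tpr", "fpr",
                    "auc") %in% names(rep_)))
  rates <- unlist(rep_[c("accuracy", "precision", "recall", "f1", "tpr",
                         "fpr", "auc")])
  expect_true(all(rates >= 0 & rates <= 1))
})
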