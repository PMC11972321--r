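test_that("gaussian filter: identity cases and unit-sum kernel", {
  img <- matrix(3.7, 20, 20)
  expect_equal(gaussian_filter(img, 2), img, tolerance = 1e-12)
  noisy <- matrix(rnorm(400), 20, 20)
  expect_identical(gaussian_filter(noisy, 0), noisy)
  expect_error(gaussian_filter(noisy, -1), "non-negative")
})

test_that("gaussian filter impulse response equals the analytic kernel", {
  n <- 33L
  img <- matrix(0, n, n)
  img[17, 17] <- 1
  out <- gaussian_filter(img, 1)
  r <- ceiling(4 * 1)
  k <- exp(-((-r:r))^2 / 2); k <- k / sum(k)
  # separable: response at center = k0^2; one-off = k0*k1
  expect_equal(out[17, 17], k[r + 1]^2, tolerance = 1e-12)
  expect_equal(out[17, 18], k[r + 1] * k[r + 2], tolerance = 1e-12)
})

test_that("gaussian filter preserves the mean under reflect boundary", {
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  # reflect boundary redistributes mass symmetrically; mean drift is tiny
  expect_lt(abs(mean(gaussian_filter(img, 1.5)) - mean(img)), 1e-3)
})

test_that("z-score normalization matches hand computation and is idempotent", {
  m <- matrix(c(1, 2, 3), 3, 1)
  fit <- zscore_normalize(m)
  expect_equal(as.numeric(fit$matrix), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-4)
  again <- zscore_apply(zscore_normalize(fit$matrix), fit$matrix)
  expect_equal(again, fit$matrix, tolerance = 1e-12)
  expect_error(zscore_normalize(cbind(const = rep(2, 5))), "const")
})

test_that("fitted z-score statistics transfer to held-out data", {
  set.seed(2)
  tr <- matrix(rnorm(100, 5, 2), 50, 2)
  te <- matrix(rnorm(20, 5, 2), 10, 2)
  fit <- zscore_normalize(tr)
  out <- zscore_apply(fit, te)
  expect_equal(out[, 1], (te[, 1] - fit$stats$mean[1]) / fit$stats$sd[1])
  # leakage check: test rows do not alter the fitted statistics
  fit2 <- zscore_normalize(rbind(tr, te))
  expect_false(isTRUE(all.equal(fit$stats$mean, fit2$stats$mean)))
})

test_that("outlier flagging follows the z threshold", {
  x <- c(0, 0, 0, 0, 100)
  expect_identical(flag_outliers(x, 1.5), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers(c(-1, 1, -1, 1), 10)))
  z0 <- flag_outliers(c(1, 2, 3, 4), 0)
  expect_true(all(z0[c(1, 4)]))
  expect_error(flag_outliers(rep(1, 5), 2), "zero-variance")
})

test_that("imputation fills means and modes and leaves complete data alone", {
  m <- matrix(c(1, NA, 3), 3, 1)
  expect_equal(as.numeric(impute_missing(m)), c(1, 2, 3))
  full <- matrix(1:6, 3, 2)
  expect_equal(impute_missing(full), full)
  cat_schema <- list(feature_spec("c", "categorical", c(0, 1)))
  mc <- matrix(c(0, 0, 1, NA), 4, 1)
  expect_equal(as.numeric(impute_missing(mc, cat_schema)), c(0, 0, 1, 0))
  expect_error(impute_missing(matrix(NA_real_, 3, 1)), "fully missing")
})

test_that("SMOTE balances counts exactly and interpolates on segments", {
  set.seed(4)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(180, 4), 90, 2))
  y <- c(rep(1, 10), rep(0, 90))
  out <- smote_oversample(X, y, k = 5, target_ratio = 1.0, seed = 9)
  expect_equal(as.numeric(table(out$y)), c(90, 90))
  expect_equal(out$n_synthetic, 80L)
  # majority rows untouched
  expect_identical(out$X[11:100, ], X[11:100, ])
  # every synthetic point within the minority bounding box
  syn <- out$X[101:180, ]
  box_lo <- apply(X[1:10, ], 2, min); box_hi <- apply(X[1:10, ], 2, max)
  expect_true(all(t(syn) >= box_lo - 1e-12 & t(syn) <= box_hi + 1e-12))
})

test_that("SMOTE with coincident minority points reproduces them", {
  X <- rbind(matrix(1, 2, 2) + 0, matrix(5, 20, 2))
  y <- c(1, 1, rep(0, 20))
  out <- smote_oversample(X, y, k = 1, target_ratio = 1.0, seed = 1)
  expect_true(all(out$X[out$y == 1, ] == 1))
  expect_error(smote_oversample(X, y, k = 2), "minority")
})

test_that("augmentation is a mask-consistent geometric transform", {
  p <- gen_phantoms(1, size = 32, seed = 6)[[1]]
  aug <- augment_images(list(p), seed = 8)[[1]]
  expect_setequal(unique(as.integer(aug$mask)), unique(as.integer(p$mask)))
  expect_true(is.integer(aug$mask))
  # class areas are preserved by rotation/flip
  expect_equal(as.numeric(table(aug$mask)), as.numeric(table(p$mask)))
  # flipping twice restores the original
  m <- p$image
  expect_identical(
    cardiopcso:::transform_image(
      cardiopcso:::transform_image(m, flip_h = TRUE), flip_h = TRUE), m)
  expect_identical(cardiopcso:::transform_image(m, 0L, FALSE, FALSE), m)
})

test_that("stratified split keeps class proportions and partitions exactly", {
  y <- c(rep(1, 30), rep(0, 70))
  sp <- stratified_split(y, 0.8, seed = 1)
  expect_equal(sum(y[sp$test] == 1), 6)
  expect_equal(sum(y[sp$test] == 0), 14)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- stratified_split(rep(c(0, 1), 5), 0.5, seed = 2)
  expect_length(sp2$train, 5)
  expect_length(sp2$test, 5)
  expect_error(stratified_split(c(0, 1, 1, 1), 0.5), "at least 2")
})
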