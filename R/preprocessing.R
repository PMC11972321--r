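#' Separable Gaussian filter with reflect boundary
#'
#' Convolves a 2-D image with a normalized Gaussian kernel, applied
#' separately along rows and columns. The kernel is truncated at
#' `ceiling(4 * sigma)` taps on each side and renormalized to unit sum, so a
#' constant image passes through unchanged. Boundaries are handled by
#' reflection (edge pixels mirrored without repetition), which avoids the
#' darkened borders a zero-padded filter produces.
#'
#' @param image 2-D numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma = 0` returns
#'   the input unchanged.
#' @return Filtered matrix of the same shape.
#' @export
gaussian_filter <- function(image, sigma) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(image)
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- apply(image, 2, convolve_reflect, kernel = k)
  t(apply(t(out), 2, convolve_reflect, kernel = k))
}

# 1-D convolution with reflect (mirror, no edge repeat) padding
convolve_reflect <- function(x, kernel) {
  n <- length(x)
  r <- (length(kernel) - 1L) / 2L
  idx <- seq_len(n + 2L * r) - r
  # reflect indices into 1..n (period 2n-2)
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ((idx - 1L) %% (2L * n - 2L))
  idx <- ifelse(idx >= n, 2L * n - 2L - idx, idx) + 1L
  xp <- x[idx]
  as.numeric(stats::filter(xp, kernel, sides = 2))[(r + 1L):(r + n)]
}

#' Fit and apply z-score normalization
#'
#' Standardizes the selected columns to mean zero and unit standard deviation.
#' The population standard deviation (divisor n) is the default so that
#' re-applying the fitted transform to the training data is exactly
#' idempotent; set `sample_sd = TRUE` for the n-1 divisor. The fitted
#' statistics are returned so the identical transform can be applied to
#' held-out data without leakage.
#'
#' @param matrix Numeric matrix.
#' @param columns Column indices or names to standardize (default: all).
#' @param sample_sd Use the sample (n-1) standard deviation instead of the
#'   population one.
#' @return List with `matrix` (transformed) and `stats` (data.frame of
#'   column, mean, sd), of class `zscore_fit`.
#' @export
zscore_normalize <- function(matrix, columns = seq_len(ncol(matrix)),
                             sample_sd = FALSE) {
  if (is.character(columns)) columns <- match(columns, colnames(matrix))
  n <- nrow(matrix)
  mu <- colMeans(matrix[, columns, drop = FALSE])
  sd2 <- colMeans(sweep(matrix[, columns, drop = FALSE], 2, mu)^2)
  if (sample_sd) sd2 <- sd2 * n / (n - 1)
  s <- sqrt(sd2)
  zero <- which(s == 0)
  if (length(zero)) {
    nm <- if (!is.null(colnames(matrix))) colnames(matrix)[columns[zero]]
          else as.character(columns[zero])
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  matrix[, columns] <- sweep(sweep(matrix[, columns, drop = FALSE], 2, mu),
                             2, s, "/")
  structure(list(matrix = matrix,
                 stats = data.frame(column = columns, mean = mu, sd = s)),
            class = "zscore_fit")
}

#' Apply previously fitted z-score statistics to new data
#'
#' @param fit A `zscore_fit` from [zscore_normalize()].
#' @param matrix New data with the same columns.
#' @return Transformed matrix.
#' @export
zscore_apply <- function(fit, matrix) {
  cols <- fit$stats$column
  matrix[, cols] <- sweep(sweep(matrix[, cols, drop = FALSE], 2,
                                fit$stats$mean), 2, fit$stats$sd, "/")
  matrix
}

#' Flag outliers by z-score
#'
#' @param column Numeric vector of length >= 3.
#' @param z_threshold Positive threshold; entries with |z| > threshold are
#'   flagged.
#' @return Logical vector.
#' @export
flag_outliers <- function(column, z_threshold) {
  if (length(column) < 3L) stop("need at least 3 values")
  s <- sqrt(mean((column - mean(column))^2))
  if (s == 0) stop("zero-variance column")
  abs((column - mean(column)) / s) > z_threshold
}

#' Impute missing values by column mean or mode
#'
#' Numeric columns receive the mean of the observed values; categorical
#' columns the mode (smallest code on ties). Missingness is marked by `NA`.
#'
#' @param matrix Numeric matrix, possibly with `NA`s.
#' @param schema Optional schema (list of [feature_spec()]); columns are
#'   treated as numeric when no schema is given.
#' @return Matrix with no missing values.
#' @export
impute_missing <- function(matrix, schema = NULL) {
  kinds <- if (is.null(schema)) rep("numeric", ncol(matrix))
           else vapply(schema, `[[`, character(1), "kind")
  for (j in seq_len(ncol(matrix))) {
    miss <- is.na(matrix[, j])
    if (!any(miss)) next
    obs <- matrix[!miss, j]
    if (!length(obs)) stop("column ", j, " is fully missing")
    fill <- if (kinds[j] == "numeric") mean(obs) else {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])
    }
    matrix[miss, j] <- fill
  }
  matrix
}

#' SMOTE minority oversampling
#'
#' Creates synthetic minority-class rows by interpolating between a minority
#' row and one of its `k` nearest minority neighbours (Euclidean distance):
#' `x_new = x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`. Majority rows
#' are untouched. Enough synthetic rows are appended for the
#' minority/majority count ratio to reach `target_ratio`.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels; the rarer class is treated as minority.
#' @param k Number of nearest neighbours (must be < minority count).
#' @param target_ratio Desired minority/majority ratio in (0, 1].
#' @param seed Integer seed.
#' @return List with augmented `X`, `y`, and `n_synthetic`.
#' @export
smote_oversample <- function(X, y, k = 5L, target_ratio = 1.0, seed = 1L) {
  stopifnot(target_ratio > 0, target_ratio <= 1, k >= 1L)
  cls <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(which.min(cls)))
  idx_min <- which(y == minority)
  n_min <- length(idx_min); n_maj <- length(y) - n_min
  if (n_min <= k)
    stop("minority class has ", n_min, " rows; need more than k = ", k)
  n_new <- max(0L, as.integer(ceiling(target_ratio * n_maj)) - n_min)
  if (n_new == 0L)
    return(list(X = X, y = y, n_synthetic = 0L))

  Xm <- X[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  ord <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)

  set.seed(as.integer(seed))
  parents <- sample.int(n_min, n_new, replace = TRUE)
  picks <- nn[cbind(parents, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  Xnew <- Xm[parents, , drop = FALSE] +
    u * (Xm[picks, , drop = FALSE] - Xm[parents, , drop = FALSE])
  list(X = rbind(X, Xnew),
       y = c(y, rep(minority, n_new)),
       n_synthetic = n_new)
}

#' Randomly augment image/mask pairs
#'
#' Applies a random rotation by a multiple of 90 degrees, random horizontal
#' and vertical flips (the identical geometric transform to image and mask)
#' and a random linear contrast scaling to the image only. Mask labels stay
#' integer.
#'
#' @param pairs List of `phantom_pair`s (or any list with `image`/`mask`).
#' @param seed Integer seed.
#' @param contrast_range Range of the multiplicative contrast factor.
#' @return List of augmented pairs.
#' @export
augment_images <- function(pairs, seed = 1L, contrast_range = c(0.8, 1.2)) {
  set.seed(as.integer(seed))
  lapply(pairs, function(p) {
    rot <- sample(0:3, 1)
    fh <- stats::runif(1) < 0.5
    fv <- stats::runif(1) < 0.5
    cs <- stats::runif(1, contrast_range[1], contrast_range[2])
    img <- transform_image(p$image, rot, fh, fv) * cs
    msk <- transform_image(p$mask, rot, fh, fv)
    storage.mode(msk) <- "integer"
    p$image <- img; p$mask <- msk
    p$meta$augment <- list(rot90 = rot, flip_h = fh, flip_v = fv,
                           contrast = cs)
    p
  })
}

rot90_mat <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

transform_image <- function(m, rot90s = 0L, flip_h = FALSE, flip_v = FALSE) {
  for (i in seq_len(rot90s %% 4L)) m <- rot90_mat(m)
  if (flip_h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (flip_v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Stratified train/test split
#'
#' Partitions row indices so that each class keeps the overall class
#' proportion to within one sample in both parts.
#'
#' @param y Binary 0/1 label vector (both classes present, each with >= 2
#'   members).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` forming an
#'   exact partition of `seq_along(y)`.
#' @export
stratified_split <- function(y, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (any(table(y) < 2L)) stop("each class needs at least 2 members")
  set.seed(as.integer(seed))
  classes <- sort(unique(y))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  # largest-remainder apportionment: per-class test counts sum to the
  # rounded overall test size while staying within one of proportionality
  target <- (1 - fraction) * counts
  n_test_c <- floor(target)
  short <- round((1 - fraction) * length(y)) - sum(n_test_c)
  if (short > 0) {
    give <- order(-(target - n_test_c))[seq_len(short)]
    n_test_c[give] <- n_test_c[give] + 1L
  }
  n_test_c <- pmin(pmax(n_test_c, 1L), counts - 1L)
  test <- integer(0)
  for (i in seq_along(classes))
    test <- c(test, sample(which(y == classes[i]), n_test_c[i]))
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Preprocessing configuration
#'
#' Bundles the tunable constants of the cleaning pipeline.
#'
#' @param gaussian_sigma Image smoothing sigma in pixels (>= 0).
#' @param z_outlier_threshold |z| above which values are flagged (> 0).
#' @param smote_k SMOTE neighbour count (>= 1).
#' @param smote_target_ratio Post-balancing minority/majority ratio (0, 1].
#' @param split_fraction Training fraction (0, 1).
#' @param seed Integer seed.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(gaussian_sigma = 1.0, z_outlier_threshold = 3.0,
                              smote_k = 5L, smote_target_ratio = 1.0,
                              split_fraction = 0.8, seed = 1L) {
  stopifnot(gaussian_sigma >= 0, z_outlier_threshold > 0, smote_k >= 1,
            smote_target_ratio > 0, smote_target_ratio <= 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 z_outlier_threshold = z_outlier_threshold,
                 smote_k = as.integer(smote_k),
                 smote_target_ratio = smote_target_ratio,
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}
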