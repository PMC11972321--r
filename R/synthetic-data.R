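#' Feature specification
#'
#' Describes one column of a tabular clinical dataset: its name, whether it is
#' numeric or categorical, its admissible range or category codes, and whether
#' it participates in the (synthetic) label model.
#'
#' @param name Short feature name.
#' @param kind `"numeric"` or `"categorical"`.
#' @param range For numeric features a length-2 vector `c(lo, hi)` with
#'   `lo < hi`; for categorical features the integer category codes.
#' @param informative Logical; does the feature enter the label model?
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("numeric", "categorical"),
                         range, informative = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "numeric") {
    if (length(range) != 2L || !is.numeric(range) || range[1] >= range[2])
      stop("numeric feature '", name, "' needs range c(lo, hi) with lo < hi")
  } else {
    if (length(range) < 1L) stop("categorical feature '", name,
                                 "' needs a non-empty code set")
  }
  structure(list(name = name, kind = kind, range = range,
                 informative = isTRUE(informative)),
            class = "feature_spec")
}

#' Default cardiovascular tabular schema
#'
#' The 15-predictor clinical schema used throughout the package: demographic
#' and history flags (Sex, Stable_CAD, CVD_history, Smoke, Nitrate, DM,
#' REV_type, LM_lesion, ASA), numeric measurements (Age 20-86 years, LVEF
#' 18-88 %, haemoglobin 55-193.2 g/L, blood urea nitrogen 0.7-119 mmol/L,
#' total cholesterol 73-589 mg/dL, SCV_number 0-3) and the binary outcome
#' MACCE (major adverse cardiac and cerebrovascular events; 0 = none).
#'
#' @return A list of 15 [feature_spec()] objects with attribute
#'   `label = "MACCE"`.
#' @export
default_cvd_schema <- function() {
  specs <- list(
    feature_spec("Sex",         "categorical", c(0, 1)),
    feature_spec("Stable_CAD",  "categorical", c(0, 1)),
    feature_spec("Age",         "numeric",     c(20, 86)),
    feature_spec("CVD_history", "categorical", c(0, 1)),
    feature_spec("Smoke",       "categorical", c(0, 1)),
    feature_spec("Nitrate",     "categorical", c(0, 1)),
    feature_spec("LVEF",        "numeric",     c(18, 88)),
    feature_spec("HBG",         "numeric",     c(55, 193.2)),
    feature_spec("BUN",         "numeric",     c(0.7, 119.0)),
    feature_spec("TC",          "numeric",     c(73, 589)),
    feature_spec("SCV_number",  "categorical", c(0, 1, 2, 3)),
    feature_spec("DM",          "categorical", c(0, 1)),
    feature_spec("REV_type",    "categorical", c(1, 2)),
    feature_spec("LM_lesion",   "categorical", c(0, 1)),
    feature_spec("ASA",         "categorical", c(0, 1))
  )
  attr(specs, "label") <- "MACCE"
  specs
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

#' Generate a synthetic tabular CVD-like dataset
#'
#' Numeric features are drawn uniformly within their declared range and
#' categorical features uniformly over their codes. The binary label is drawn
#' from a logistic model on the standardized informative features, with the
#' intercept solved numerically so the expected class-1 prevalence equals
#' `imbalance_ratio`.
#'
#' @param schema List of [feature_spec()]s (default [default_cvd_schema()]).
#' @param n Number of rows (at least 10).
#' @param seed Integer seed; identical arguments give identical data.
#' @param imbalance_ratio Target class-1 prevalence in (0, 1].
#' @param informative_names Names of features entering the label model.
#' @param effect_sizes Logistic coefficients, one per informative name.
#' @param missing_rate Fraction of entries replaced by `NA` (default 0).
#' @return A `tabular_dataset`: list with `X` (n x p numeric matrix with
#'   column names), `y` (0/1 integer vector), `schema`, and the generation
#'   parameters in `meta`.
#' @export
gen_tabular <- function(schema = default_cvd_schema(), n = 1000L, seed = 1L,
                        imbalance_ratio = 0.3,
                        informative_names = character(0),
                        effect_sizes = numeric(0),
                        missing_rate = 0) {
  stopifnot(n >= 10L, imbalance_ratio > 0, imbalance_ratio <= 1,
            missing_rate >= 0, missing_rate < 1,
            length(informative_names) == length(effect_sizes))
  nms <- schema_names(schema)
  unknown <- setdiff(informative_names, nms)
  if (length(unknown))
    stop("unknown informative feature name(s): ", paste(unknown, collapse = ", "))

  set.seed(as.integer(seed))
  p <- length(schema)
  X <- matrix(0, n, p, dimnames = list(NULL, nms))
  for (j in seq_len(p)) {
    fs <- schema[[j]]
    X[, j] <- if (fs$kind == "numeric")
      stats::runif(n, fs$range[1], fs$range[2])
    else
      sample(fs$range, n, replace = TRUE)
  }

  # Linear predictor on standardized informative columns
  eta <- rep(0, n)
  if (length(informative_names)) {
    for (k in seq_along(informative_names)) {
      col <- X[, informative_names[k]]
      s <- stats::sd(col)
      z <- if (s > 0) (col - mean(col)) / s else col * 0
      eta <- eta + effect_sizes[k] * z
    }
  }
  # Solve the intercept so that mean(plogis(b0 + eta)) = imbalance_ratio
  b0 <- if (imbalance_ratio == 1) Inf else
    stats::uniroot(function(b) mean(stats::plogis(b + eta)) - imbalance_ratio,
                   interval = c(-40, 40), tol = 1e-10)$root
  pr <- stats::plogis(b0 + eta)
  y <- as.integer(stats::runif(n) < pr)

  if (missing_rate > 0) {
    miss <- which(stats::runif(n * p) < missing_rate)
    X[miss] <- NA_real_
  }

  structure(list(X = X, y = y, schema = schema,
                 meta = list(n = n, seed = as.integer(seed),
                             imbalance_ratio = imbalance_ratio,
                             informative_names = informative_names,
                             effect_sizes = effect_sizes,
                             missing_rate = missing_rate)),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat("tabular_dataset:", nrow(x$X), "x", ncol(x$X),
      sprintf("(class-1 prevalence %.3f)\n", mean(x$y)))
  invisible(x)
}

#' Generate annular left-ventricle phantom image/mask pairs
#'
#' Each phantom is a short-axis-like slice: a bright circular blood cavity
#' (label 1) inside a mid-intensity myocardial annulus (label 2) on a dark
#' background (label 0), at a randomized center and radii, with additive
#' Gaussian noise on the image.
#'
#' @param n Number of pairs.
#' @param size Image side length in pixels (>= 32).
#' @param seed Integer seed.
#' @param noise_sigma Standard deviation of the additive Gaussian noise on
#'   the (0, 1)-scaled intensities.
#' @param radius_range Length-2 vector: admissible outer (epicardial) radius
#'   range in pixels; the inner (endocardial) radius is drawn as 40-70 % of
#'   the outer one. Radii must fit inside the image.
#' @param intensities Base intensities for background, cavity, myocardium.
#' @return List of `phantom_pair`s, each with `image` (size x size matrix),
#'   `mask` (integer matrix, labels 0/1/2) and `meta`.
#' @export
gen_phantoms <- function(n = 10L, size = 64L, seed = 1L, noise_sigma = 0.05,
                         radius_range = NULL,
                         intensities = c(background = 0.1, cavity = 0.9,
                                         myocardium = 0.5)) {
  stopifnot(size >= 32L, n >= 1L)
  if (is.null(radius_range)) radius_range <- c(size / 5, size / 3.2)
  if (max(radius_range) > size / 2 - 2)
    stop("radius_range exceeds image bounds: outer radius must be < size/2 - 2")
  set.seed(as.integer(seed))
  gx <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  gy <- matrix(rep(seq_len(size), times = size), size, size) # row index
  lapply(seq_len(n), function(i) {
    r_out <- stats::runif(1, radius_range[1], radius_range[2])
    r_in  <- r_out * stats::runif(1, 0.4, 0.7)
    slack <- size / 2 - r_out - 1
    cx <- size / 2 + stats::runif(1, -slack, slack)
    cy <- size / 2 + stats::runif(1, -slack, slack)
    d2 <- (gx - cx)^2 + (gy - cy)^2
    mask <- matrix(0L, size, size)
    mask[d2 <= r_out^2] <- 2L
    mask[d2 <= r_in^2]  <- 1L
    base <- matrix(intensities[["background"]], size, size)
    base[mask == 2L] <- intensities[["myocardium"]]
    base[mask == 1L] <- intensities[["cavity"]]
    image <- base
    if (noise_sigma > 0)
      image <- image + matrix(stats::rnorm(size * size, 0, noise_sigma),
                              size, size)
    structure(list(image = image, mask = mask,
                   meta = list(center = c(cy, cx), r_inner = r_in,
                               r_outer = r_out, noise_sigma = noise_sigma,
                               seed = as.integer(seed), index = i)),
              class = "phantom_pair")
  })
}

#' Generate linearly separable two-feature data
#'
#' Standard-normal points labelled by the sign of `x1 + x2`, then pushed
#' away from the separating line so every point sits at least `margin / 2`
#' from it; a ground-truthed easy case for classifier calibration.
#'
#' @param n Number of points.
#' @param margin Separation margin (default 1).
#' @param seed Integer seed.
#' @return List with `X` (n x 2 matrix, columns `x1`, `x2`) and `y` (0/1).
#' @export
gen_separable <- function(n = 400L, margin = 1, seed = 1L) {
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(2L * n), n, 2L,
              dimnames = list(NULL, c("x1", "x2")))
  w <- c(1, 1) / sqrt(2)
  f <- as.numeric(X %*% w)
  y <- as.integer(f > 0)
  shift <- (margin / 2 - pmin(abs(f), margin / 2)) * sign(f)
  X <- X + outer(shift, w)
  list(X = X, y = y)
}

#' Write a tabular dataset to CSV with a JSON parameter sidecar
#'
#' @param dataset A `tabular_dataset`.
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @param label Label column name written in the header.
#' @return `path`, invisibly.
#' @export
write_tabular_csv <- function(dataset, path, label = "MACCE") {
  df <- as.data.frame(dataset$X)
  df[[label]] <- dataset$y
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(dataset$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tabular dataset from CSV
#'
#' @param path CSV path with the label in column `label`.
#' @param label Label column name.
#' @param schema Optional schema to attach.
#' @return A `tabular_dataset` (schema `NULL` unless supplied).
#' @export
read_tabular_csv <- function(path, label = "MACCE", schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label %in% names(df)) stop("label column '", label, "' not found")
  y <- as.integer(df[[label]])
  X <- as.matrix(df[setdiff(names(df), label)])
  structure(list(X = X, y = y, schema = schema, meta = list(path = path)),
            class = "tabular_dataset")
}

#' Write a phantom pair as 8-bit PNGs (and optionally NIfTI)
#'
#' The image is linearly clipped to [0, 1] for PNG; the mask is written with
#' its integer labels scaled into the 8-bit range (label k -> k/255).
#'
#' @param pair A `phantom_pair`.
#' @param prefix Output path prefix; writes `<prefix>_image.png`,
#'   `<prefix>_mask.png` and `<prefix>.json`.
#' @param nifti Also write `.nii` files via RNifti when available.
#' @return `prefix`, invisibly.
#' @export
write_phantom <- function(pair, prefix, nifti = FALSE) {
  img <- pmin(pmax(pair$image, 0), 1)
  png::writePNG(img, paste0(prefix, "_image.png"))
  png::writePNG(pair$mask / 255, paste0(prefix, "_mask.png"))
  jsonlite::write_json(pair$meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI output requires the RNifti package")
    RNifti::writeNifti(pair$image, paste0(prefix, "_image.nii"))
    RNifti::writeNifti(pair$mask, paste0(prefix, "_mask.nii"))
  }
  invisible(prefix)
}
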