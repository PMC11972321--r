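test_that("default schema matches the clinical feature table", {
  schema <- default_cvd_schema()
  expect_length(schema, 15L)
  expect_identical(attr(schema, "label"), "MACCE")
  nms <- vapply(schema, `[[`, character(1), "name")
  age <- schema[[which(nms == "Age")]]
  expect_identical(age$kind, "numeric")
  expect_equal(age$range, c(20, 86))
  lvef <- schema[[which(nms == "LVEF")]]
  expect_equal(lvef$range, c(18, 88))
  expect_equal(schema[[which(nms == "REV_type")]]$range, c(1, 2))
  expect_equal(schema[[which(nms == "SCV_number")]]$range, 0:3)
})

test_that("generated values respect schema ranges and label coding", {
  ds <- gen_tabular(n = 10000L, seed = 3)
  for (fs in ds$schema) {
    col <- ds$X[, fs$name]
    if (fs$kind == "numeric") {
      expect_true(all(col >= fs$range[1] & col <= fs$range[2]),
                  label = paste("range of", fs$name))
    } else {
      expect_true(all(col %in% fs$range), label = paste("codes of", fs$name))
    }
  }
  expect_true(all(ds$y %in% c(0, 1)))
  expect_false(anyNA(ds$X))
})

test_that("prevalence matches the requested imbalance with no effects", {
  n <- 4000L
  for (ratio in c(0.3, 0.5)) {
    ds <- gen_tabular(n = n, seed = 7, imbalance_ratio = ratio)
    se <- sqrt(ratio * (1 - ratio) / n)
    expect_lt(abs(mean(ds$y) - ratio), 3 * se)
  }
})

test_that("generation is deterministic in the seed", {
  a <- gen_tabular(n = 200L, seed = 42, informative_names = "Age",
                   effect_sizes = 1.5)
  b <- gen_tabular(n = 200L, seed = 42, informative_names = "Age",
                   effect_sizes = 1.5)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, gen_tabular(n = 200L, seed = 43,
                                          informative_names = "Age",
                                          effect_sizes = 1.5)$y))
})

test_that("a planted coefficient makes its feature the most label-correlated", {
  wins <- 0L
  for (s in 1:10) {
    ds <- gen_tabular(n = 5000L, seed = s, informative_names = "LVEF",
                      effect_sizes = 2)
    r <- abs(suppressWarnings(cor(ds$X, ds$y)))
    wins <- wins + (rownames(r)[which.max(r)] == "LVEF")
  }
  expect_gte(wins, 9L)
})

test_that("unknown informative names and bad sizes are rejected", {
  expect_error(gen_tabular(informative_names = "NotAFeature",
                           effect_sizes = 1), "unknown informative")
  expect_error(gen_tabular(n = 5L))
})

test_that("phantom masks are concentric, exclusive and exhaustive", {
  pairs <- gen_phantoms(5, size = 64, seed = 2, noise_sigma = 0.05)
  for (p in pairs) {
    expect_identical(dim(p$image), dim(p$mask))
    expect_true(all(p$mask %in% 0:2))
    # cavity pixel count close to the analytic disc area
    area <- sum(p$mask == 1L)
    r <- p$meta$r_inner
    expect_lt(abs(area - pi * r^2), 2 * pi * r + 8)
    # cavity strictly inside myocardium ring: dilating cavity meets ring
    expect_gt(sum(p$mask == 2L), 0)
  }
})

test_that("noise-free phantoms are piecewise constant at the base intensities", {
  p <- gen_phantoms(1, size = 64, seed = 9, noise_sigma = 0)[[1]]
  expect_setequal(unique(as.numeric(p$image)), c(0.1, 0.9, 0.5))
  expect_identical(sort(unique(as.numeric(p$image[p$mask == 0L]))), 0.1)
})

test_that("phantom generation is seed-reproducible and bounds-checked", {
  a <- gen_phantoms(3, size = 64, seed = 5)
  b <- gen_phantoms(3, size = 64, seed = 5)
  expect_identical(a, b)
  expect_error(gen_phantoms(1, size = 64, radius_range = c(10, 40)),
               "exceeds image bounds")
})

test_that("CSV round trip preserves the dataset", {
  ds <- gen_tabular(n = 50L, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tabular_csv(ds, path)
  back <- read_tabular_csv(path)
  expect_equal(back$X, ds$X, tolerance = 1e-12)
  expect_identical(back$y, ds$y)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("phantom PNG export writes image, mask and sidecar", {
  p <- gen_phantoms(1, size = 32, seed = 3)[[1]]
  prefix <- file.path(withr::local_tempdir(), "ph")
  write_phantom(p, prefix)
  expect_true(file.exists(paste0(prefix, "_image.png")))
  mask_png <- png::readPNG(paste0(prefix, "_mask.png"))
  expect_equal(sort(unique(round(as.numeric(mask_png) * 255))),
               sort(unique(as.numeric(p$mask))))
})

test_that("separable generator honours its margin", {
  d <- gen_separable(500, margin = 1, seed = 2)
  f <- as.numeric(d$X %*% c(1, 1) / sqrt(2))
  expect_true(all(abs(f) >= 0.5 - 1e-12))
  expect_identical(d$y, as.integer(f > 0))
})
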