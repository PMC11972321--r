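test_that("encoder channels double from base to the cap and mirror back", {
  spec <- unet_spec(depth = 5, base_channels = 8, max_channels = 128)
  expect_identical(spec$channels, c(8L, 16L, 32L, 64L, 128L))
  # the cap binds for deeper/greedier specs
  spec2 <- unet_spec(depth = 6, base_channels = 8, max_channels = 64)
  expect_identical(spec2$channels, c(8L, 16L, 32L, 64L, 64L, 64L))
  m <- build_unet(spec, seed = 1)
  # decoder halves channels back down to the base
  expect_identical(dim(m$params[["dec1.up.W"]]), c(2L, 2L, 16L, 8L))
  expect_identical(dim(m$params[["out.conv.W"]]), c(1L, 1L, 8L, 3L))
})

test_that("construction is deterministic and counts parameters stably", {
  spec <- unet_spec()
  m1 <- build_unet(spec, seed = 4)
  m2 <- build_unet(spec, seed = 4)
  expect_identical(unet_n_params(m1), unet_n_params(m2))
  expect_identical(m1$params, m2$params)
})

test_that("same padding preserves spatial shape; valid arithmetic documented", {
  spec <- unet_spec(depth = 3, base_channels = 2)
  m <- build_unet(spec, seed = 2)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  fwd <- cardiopcso:::unet_forward(m, x, training = FALSE)
  expect_identical(dim(fwd$probs), c(32L, 32L, 3L, 1L))
  expect_identical(conv_output_size(256L, 3L, "valid"), 254L)
  expect_identical(conv_output_size(256L, 3L, "same"), 256L)
})

test_that("class probabilities sum to one per pixel", {
  spec <- unet_spec(depth = 2, base_channels = 2)
  m <- build_unet(spec, seed = 3)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  fwd <- cardiopcso:::unet_forward(m, x, training = FALSE)
  sums <- apply(fwd$probs, c(1, 2, 4), sum)
  expect_equal(as.numeric(sums), rep(1, 16 * 16 * 2), tolerance = 1e-12)
})

test_that("dice loss is zero at perfect probabilities and one at disjoint", {
  mask <- matrix(0L, 8, 8); mask[3:6, 3:6] <- 1L
  oh <- cardiopcso:::masks_to_onehot(array(mask, c(8, 8, 1)), 3)
  expect_equal(dice_loss(oh, mask), 0)
  wrong <- array(0, dim(oh)); wrong[, , 3, ] <- 1  # all myocardium
  # cavity term: both empty in prediction vs nonempty truth -> dice 0;
  # myocardium: empty truth vs full prediction -> dice 0
  expect_equal(dice_loss(wrong, mask), 1)
})

test_that("training reduces Dice loss and segments held-out phantoms", {
  fx <- get_trained_unet()
  hist <- fx$model$loss_history
  expect_length(hist, 20L)
  expect_lt(hist[20], hist[1])
  ev <- evaluate_unet(fx$model, fx$test)
  expect_gte(attr(ev, "mean_dice"), 0.9)
})

test_that("predicted masks stay in the label set and are deterministic", {
  fx <- get_trained_unet()
  img <- fx$test[[1]]$image
  p1 <- predict_mask(fx$model, img)
  p2 <- predict_mask(fx$model, img)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% 0:2))
  expect_identical(dim(p1), dim(img))
})

test_that("a noise-free phantom is segmented nearly perfectly", {
  fx <- get_trained_unet()
  clean <- gen_phantoms(1, size = 64, seed = 77, noise_sigma = 0)[[1]]
  ev <- evaluate_unet(fx$model, list(clean))
  expect_gte(attr(ev, "mean_dice"), 0.95)
})

test_that("training validates input sizes and pair counts", {
  pairs <- gen_phantoms(10, size = 40, seed = 1)
  expect_error(train_unet(unet_spec(), pairs, epochs = 1), "divisible")
  small <- gen_phantoms(4, size = 64, seed = 1)
  expect_error(train_unet(unet_spec(), small, epochs = 1), "at least 8")
})

test_that("ROI crop boxes follow margin, clipping and divisibility rules", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  mask <- matrix(0L, 64, 64); mask[30, 40] <- 1L
  rc <- roi_crop(img, mask, margin = 8)
  expect_identical(dim(rc$image), c(17L, 17L))
  expect_identical(rc$box$rows, c(22L, 38L))
  # whole-image mask crops to the image itself
  full <- roi_crop(img, matrix(1L, 64, 64), margin = 8)
  expect_identical(full$image, img)
  # divisibility growth
  rc16 <- roi_crop(img, mask, margin = 8, divisor = 16)
  expect_identical(dim(rc16$image) %% 16L, c(0L, 0L))
  expect_error(roi_crop(img, matrix(0L, 64, 64)), "empty")
})

test_that("paste-back is lossless inside the box", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  mask <- matrix(0L, 64, 64); mask[20:40, 25:45] <- 1L
  rc <- roi_crop(img, mask, margin = 4)
  expect_identical(roi_paste(rc$image, rc$box, fill = 0)[20:40, 25:45],
                   img[20:40, 25:45])
  # a prediction made in crop space scores identically after paste-back
  # when all foreground lies inside the box
  pred_crop <- matrix(0L, nrow(rc$image), ncol(rc$image))
  pred_crop[mask[rc$box$rows[1]:rc$box$rows[2],
                 rc$box$cols[1]:rc$box$cols[2]] == 1L] <- 1L
  pred_full <- roi_paste(pred_crop, rc$box)
  true_crop <- mask[rc$box$rows[1]:rc$box$rows[2],
                    rc$box$cols[1]:rc$box$cols[2]]
  expect_equal(dice_score(pred_full, mask, 1L),
               dice_score(pred_crop, true_crop, 1L), tolerance = 1e-12)
})
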