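rand_img <- function(H, W, seed = 1) {
  set.seed(seed)
  array(sample(0:255, H * W * 3, TRUE), c(H, W, 3))
}

test_that("resize-and-pad geometry is exact", {
  # 1024 x 768 (W x H) -> content 256 x 192, pad 32 top + 32 bottom
  std <- resize_and_pad(rand_img(768, 1024))
  expect_equal(unname(std$pad), c(32, 32, 0, 0))
  expect_true(all(std$pixels[1:32, , ] == 0))
  expect_true(all(std$pixels[225:256, , ] == 0))
  expect_identical(dim(std$pixels), c(256L, 256L, 3L))
  # 768 x 560 -> content 256 x 187, pad 34 top + 35 bottom
  std <- resize_and_pad(rand_img(560, 768))
  expect_equal(unname(std$pad), c(34, 35, 0, 0))
  # 256 x 256 passes through unchanged
  img <- rand_img(256, 256)
  std <- resize_and_pad(img)
  expect_equal(unname(std$pad), c(0, 0, 0, 0))
  expect_equal(std$pixels, array(as.integer(img), dim(img)))
  # portrait input pads left/right instead
  std <- resize_and_pad(rand_img(400, 200))
  expect_equal(std$pad[["top"]], 0)
  expect_gt(std$pad[["left"]], 0)
  # idempotence on standardised output
  again <- resize_and_pad(std$pixels)
  expect_equal(again$pixels, std$pixels)
})

test_that("masks share the geometry and stay binary", {
  img <- rand_img(560, 768, 2)
  mask <- matrix(0, 560, 768)
  mask[200:400, 300:500] <- 255
  std <- resize_and_pad(img, mask)
  expect_identical(dim(std$mask), c(256L, 256L))
  expect_true(all(std$mask %in% c(0, 1)))
  expect_true(all(std$mask[1:34, ] == 0))
  # lesion survives with approximately scaled area
  scale <- (256 / 768)^2
  expect_equal(sum(std$mask), sum(mask > 0) * scale, tolerance = 0.1)
})

test_that("HSV conversion matches the standard formulas", {
  mk <- function(r, g, b) {
    px <- array(0L, c(1, 1, 3)); px[1, 1, ] <- c(r, g, b)
    structure(list(pixels = px, mask = NULL,
                   pad = c(top = 0, bottom = 0, left = 0, right = 0),
                   original_size = c(1, 1), color_space = "RGB"),
              class = "standardized_image")
  }
  red <- rgb_to_hsv_image(mk(255, 0, 0))
  expect_equal(as.vector(red$pixels), c(0, 255, 255))
  gray <- rgb_to_hsv_image(mk(128, 128, 128))
  expect_equal(as.vector(gray$pixels)[2:3], c(0, 128))
  expect_error(rgb_to_hsv_image(red), "already")
  # round trip RGB -> HSV -> RGB within quantisation error: hue quantised
  # to 8 bits costs up to 3 intensity levels at full saturation
  img <- resize_and_pad(rand_img(8, 8, 3), size = 8)
  back <- csagnet:::hsv_to_rgb_image(rgb_to_hsv_image(img))
  expect_lte(max(abs(back$pixels - img$pixels)), 3)
})

test_that("the flip family enumerates the four arrangements", {
  x <- array(0, c(2, 2, 1)); x[1, 1, 1] <- 1; x[2, 2, 1] <- 2
  fam <- flip_family(x)
  expect_length(fam, 4)
  expect_equal(fam[[1]], x)
  expect_equal(fam[[2]][1, 2, 1], 1); expect_equal(fam[[2]][2, 1, 1], 2)
  expect_equal(fam[[3]][2, 1, 1], 1); expect_equal(fam[[3]][1, 2, 1], 2)
  expect_equal(fam[[4]][2, 2, 1], 1); expect_equal(fam[[4]][1, 1, 1], 2)
  # involution, bit-exact
  expect_identical(csagnet:::flip_one(csagnet:::flip_one(x, 1), 1), x)
  expect_identical(csagnet:::flip_one(csagnet:::flip_one(x, 2), 2), x)
})

test_that("training-set expansion is exactly 8N with stable ordering", {
  mk_pair <- function(seed) {
    img <- rand_img(20, 28, seed)
    mask <- matrix(0, 20, 28); mask[5:15, 8:20] <- 255
    resize_and_pad(img, mask, size = 16)
  }
  pairs <- lapply(1:3, mk_pair)
  ts <- build_training_set(pairs)
  expect_length(ts$samples, 24)
  expect_equal(nrow(ts$manifest), 24)
  expect_equal(ts$manifest$source, rep(1:3, each = 8))
  expect_equal(ts$manifest$color_space, rep(rep(c("RGB", "HSV"), each = 4), 3))
  expect_equal(ts$manifest$flip, rep(0:3, 6))
  # lesion pixel count invariant under flips; HSV copies share the mask
  base <- sum(pairs[[1]]$mask)
  for (k in 1:8) expect_equal(sum(ts$samples[[k]]$mask), base)
  # single pair -> 8; duplicates preserved
  expect_length(build_training_set(pairs[1])$samples, 8)
  expect_length(build_training_set(pairs[c(1, 1)])$samples, 16)
  expect_error(build_training_set(list()), "length|>= 1")
})

test_that("unpad_mask restores the original geometry", {
  img <- rand_img(560, 768, 9)
  mask <- matrix(0, 560, 768); mask[150:350, 250:550] <- 255
  std <- resize_and_pad(img, mask)
  back <- unpad_mask(std$mask, std)
  expect_identical(dim(back), c(560L, 768L))
  # area approximately preserved through the round trip
  expect_equal(sum(back) / sum(mask > 0), 1, tolerance = 0.05)
  expect_error(unpad_mask(std$mask[1:10, 1:10], std), "size")
})
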