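test_that("crop_resize takes the centered square then resamples", {
  set.seed(301)
  img <- array(runif(60 * 45 * 3), c(60, 45, 3))
  out <- crop_resize(img, 32)
  expect_equal(dim(out), c(32, 32, 3))
  # square input already at the target size is returned unchanged
  sq <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_identical(crop_resize(sq, 40), sq)
  # constant image stays constant under bilinear resampling
  const <- array(0.42, c(64, 64, 3))
  out2 <- crop_resize(const, 24)
  expect_equal(max(abs(out2 - 0.42)), 0, tolerance = 1e-12)
  expect_error(crop_resize(array(0.5, c(1, 10, 3)), 8), "2 px")
})

test_that("crop_resize crops before resampling", {
  # left/right borders of a wide image must not influence the output
  set.seed(302)
  inner <- array(runif(50 * 50 * 3), c(50, 50, 3))
  wide1 <- array(0, c(50, 90, 3)); wide1[, 21:70, ] <- inner
  wide2 <- array(1, c(50, 90, 3)); wide2[, 21:70, ] <- inner
  expect_equal(crop_resize(wide1, 25), crop_resize(wide2, 25))
})

test_that("Shades of Gray reduces to Gray World at p = 1", {
  set.seed(303)
  img <- array(runif(32 * 32 * 3, 0.05, 0.95), c(32, 32, 3))
  expect_equal(estimate_illuminant(img, 1), oracle_gray_world(img),
               tolerance = 1e-6)
  # a uniformly gray image is already neutral
  expect_equal(estimate_illuminant(array(0.7, c(16, 16, 3)), 6), rep(1, 3))
  zr <- array(runif(12), c(2, 2, 3))
  zr[, , 1] <- 0
  expect_error(estimate_illuminant(zr, 6), "zero")
  expect_error(estimate_illuminant(img, 0.5), ">= 1")
})

test_that("Shades of Gray approaches max-RGB as p grows large", {
  set.seed(304)
  for (i in 1:5) {
    img <- array(runif(32 * 32 * 3, 0.05, 0.95), c(32, 32, 3))
    g <- estimate_illuminant(img, 256)
    expect_lt(max(abs(g / oracle_max_rgb(img) - 1)), 0.01)
  }
})

test_that("illuminant correction equalizes Minkowski means pre-clipping", {
  set.seed(305)
  img <- array(runif(32 * 32 * 3, 0.05, 0.9), c(32, 32, 3))
  img[, , 1] <- pmin(img[, , 1] * 2, 1)   # strong red cast
  g <- estimate_illuminant(img, 6)
  corr <- apply_illuminant(img, g, clip = FALSE)
  mink <- vapply(1:3, function(ch) mean(corr[, , ch]^6)^(1 / 6), numeric(1))
  expect_lt(max(mink) - min(mink), 1e-6)
  # identity gains change nothing
  expect_identical(apply_illuminant(img, c(1, 1, 1)), img)
  expect_error(apply_illuminant(img, c(1, -1, 1)), "positive")
})

test_that("correction is idempotent up to one intensity level", {
  set.seed(306)
  img <- render_lesion(c(1, 0, 1), 64)$pixels
  i1 <- apply_illuminant(img, estimate_illuminant(img, 6))
  i2 <- apply_illuminant(i1, estimate_illuminant(i1, 6))
  expect_lt(max(abs(i2 - i1)), 1 / 255)
})

test_that("correction moves tinted renders toward the cast-free reference", {
  wins <- 0
  for (i in 1:20) {
    set.seed(400 + i)
    im <- render_lesion(as.integer(runif(3) < 0.5), 64)
    ref <- cast_free_reference(im)$pixels
    co <- apply_illuminant(im$pixels, estimate_illuminant(im$pixels, 6))
    if (sum((co - ref)^2) < sum((im$pixels - ref)^2)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("CLAHE leaves a constant image essentially unchanged", {
  const <- array(0.5, c(32, 32, 3))
  out <- clahe(const, clip_limit = 2, tile_grid = c(4, 4))
  expect_lt(max(abs(out - const)), 2 / 255)
  expect_error(clahe(const, clip_limit = 2, tile_grid = c(64, 4)), "tile")
  expect_error(clahe(const, clip_limit = -1), "positive")
})

test_that("single-tile unclipped CLAHE matches global equalization", {
  set.seed(307)
  # neutral (gray-axis) image keeps the comparison inside the sRGB gamut
  g <- matrix(runif(64 * 64, 0.3, 0.7), 64)
  img <- array(rep(g, 3), c(64, 64, 3))
  out <- clahe(img, clip_limit = 1e6, tile_grid = c(1, 1))
  lab_in <- dermrank:::srgb_to_lab(matrix(img, ncol = 3))
  lab_out <- dermrank:::srgb_to_lab(matrix(out, ncol = 3))
  bins <- pmin(255, pmax(0, floor(lab_in[, 1] / 100 * 256)))
  cdf <- cumsum(tabulate(bins + 1, 256))
  oracle_L <- (255 * cdf / length(bins))[bins + 1] / 255 * 100
  expect_lt(max(abs(lab_out[, 1] - oracle_L)) * 255 / 100, 2)
})

test_that("CLAHE raises the contrast of a low-contrast ramp", {
  ramp <- array(rep(seq(0.45, 0.55, length.out = 64), each = 64),
                c(64, 64, 3))
  out <- clahe(ramp, clip_limit = 4, tile_grid = c(4, 4))
  expect_gte(sd(out), sd(ramp))
})

test_that("per-tile CLAHE mappings are nondecreasing", {
  set.seed(308)
  for (i in 1:10) {
    bins <- sample(0:255, 500, replace = TRUE, prob = runif(256))
    map <- dermrank:::clahe_tile_map(bins, 500, clip_limit = 2)
    expect_true(all(diff(map) >= 0))
  }
})

test_that("the preprocessing chain is deterministic and configurable", {
  set.seed(309)
  img <- render_lesion(c(1, 1, 0), 64)$pixels
  cfg <- preprocess_config(target_size = 48)
  a <- preprocess_image(img, cfg)
  b <- preprocess_image(img, cfg)
  expect_identical(a, b)
  expect_equal(dim(a), c(48, 48, 3))
  expect_length(attr(a, "illuminant_gains"), 3)
  cfg2 <- preprocess_config(target_size = 48,
                            enabled_stages = "crop_resize")
  expect_null(attr(preprocess_image(img, cfg2), "illuminant_gains"))
})
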