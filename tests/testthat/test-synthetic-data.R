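test_that("EM-like generation is seeded, binary and self-consistent", {
  a <- generate_em_like(2, 32, 32, seed = 71)
  b <- generate_em_like(2, 32, 32, seed = 71)
  expect_identical(a, b)                      # bit-identical under the same seed
  expect_false(identical(a, generate_em_like(2, 32, 32, seed = 72)))
  for (s in a) {
    expect_true(all(s$mask %in% c(0L, 1L)))   # exactly binary
    expect_true(all(is.finite(s$image)))
    expect_identical(dim(s$image), c(32L, 32L, 1L))
    # labels and mask agree: membrane where label 0, interiors labeled
    expect_identical(s$labels == 0L, s$mask == 0L)
  }
  expect_error(generate_em_like(1, 32, 32, seed = 1, cell_density = 0), "density")
})

test_that("membrane fraction at default density stays in the calibrated band", {
  samples <- generate_em_like(100, 64, 64, seed = 73)
  frac <- mean(vapply(samples, function(s) mean(s$mask == 0L), numeric(1)))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.35)
})

test_that("EM-like labelings round-trip through the Rand score", {
  for (s in generate_em_like(3, 32, 32, seed = 74))
    expect_identical(foreground_restricted_rand_score(s$labels, s$labels), 1)
})

test_that("BRATs-like labels partition the image with nested tumor cores", {
  samples <- generate_brats_like(4, 64, 64, seed = 75)
  expect_identical(samples, generate_brats_like(4, 64, 64, seed = 75))
  for (s in samples) {
    expect_identical(dim(s$image), c(64L, 64L, 4L))
    # one-hot channels sum to 1 at every pixel
    expect_equal(apply(s$mask, c(1, 2), sum), matrix(1, 64, 64), tolerance = 1e-12)
    expect_true(all(s$labels %in% 0:3))
    # cores lie inside the edema-or-core region by construction
    core <- s$labels >= 2
    tumor <- s$labels >= 1
    expect_true(all(tumor[core]))
    if (isTRUE(s$meta$small_tumor)) expect_lt(mean(tumor), 0.02)
  }
})

test_that("class pixel frequencies match the configured priors", {
  samples <- generate_brats_like(200, 80, 80, seed = 76)
  freq <- rowMeans(vapply(samples, function(s)
    vapply(0:3, function(k) mean(s$labels == k), numeric(1)), numeric(4)))
  names(freq) <- c("background", "edema", "non_enhancing", "enhancing")
  expected <- samples[[1]]$meta$expected_class_fraction
  for (k in names(freq))
    expect_lt(abs(freq[[k]] - expected[[k]]) / expected[[k]], 0.2)
})

test_that("preprocessing crops centrally, standardizes, and is identity-safe", {
  # 240x240 center-cropped to 144x144 -> offsets (48, 48)
  img <- matrix(0, 240, 240)
  img[48 + 72, 48 + 72] <- 1       # center of the crop window
  out <- preprocess_sample(img, img, target_size = c(144, 144), crop = c(144, 144),
                           standardize = FALSE)
  expect_equal(out$image[72, 72], 1)
  expect_equal(sum(out$image), 1)
  # constant image standardizes to all zeros (sigma = 0 guard)
  flat <- matrix(3.7, 32, 32)
  out <- preprocess_sample(flat, flat > 0, target_size = c(32, 32))
  expect_identical(out$image, matrix(0, 32, 32))
  # identity resize leaves the image untouched
  set.seed(77)
  img <- matrix(runif(32 * 32), 32, 32)
  out <- preprocess_sample(img, img > 0.5, target_size = c(32, 32), standardize = FALSE)
  expect_identical(out$image, img)
  # standardized output has zero mean, unit variance
  out <- preprocess_sample(img, img > 0.5, target_size = c(16, 16))
  expect_equal(mean(out$image), 0, tolerance = 1e-12)
  expect_equal(mean(out$image^2), 1, tolerance = 1e-12)
  expect_error(preprocess_sample(img, img > 0.5, c(16, 16), crop = c(64, 64)),
               "exceeds")
})

test_that("resizing a mask keeps labels exact (nearest neighbour)", {
  set.seed(78)
  lab <- matrix(sample(0:3, 48 * 48, replace = TRUE), 48, 48)
  out <- preprocess_sample(matrix(runif(48 * 48), 48), lab, target_size = c(20, 20),
                           standardize = FALSE)
  expect_true(all(out$mask %in% 0:3))
})

test_that("augmentation is jointly geometric, label-safe, and involutive for flips", {
  s <- generate_em_like(1, 32, 32, seed = 79)[[1]]
  # flip twice -> original
  flip_cfg <- augment_config(horizontal_flip = 1, zoom_range = c(1, 1),
                             shift_range = c(0, 0))
  once <- augment_sample(s, flip_cfg, seed = 1)
  twice <- augment_sample(once, flip_cfg, seed = 2)
  expect_equal(twice$image, s$image, tolerance = 1e-12)
  expect_identical(twice$mask, s$mask)
  expect_false(isTRUE(all.equal(once$image, s$image)))
  # identity transform is exact
  id_cfg <- augment_config(horizontal_flip = 0, zoom_range = c(1, 1),
                           shift_range = c(0, 0))
  same <- augment_sample(s, id_cfg, seed = 3)
  expect_equal(same$image, s$image, tolerance = 1e-12)
  expect_identical(same$mask, s$mask)
  # masks stay valid class-index images across random transforms
  cfg <- augment_config()
  labels_seen <- unique(as.vector(s$mask))
  for (seed in 1:100) {
    aug <- augment_sample(s, cfg, seed = seed)
    expect_true(all(aug$mask %in% labels_seen))
    expect_identical(dim(aug$mask), dim(s$mask))
  }
  # the same transform is applied to image and mask: membranes stay dark
  aug <- augment_sample(s, augment_config(horizontal_flip = 1), seed = 5)
  expect_lt(mean(aug$image[, , 1][aug$mask == 0L]),
            mean(aug$image[, , 1][aug$mask == 1L]))
})
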