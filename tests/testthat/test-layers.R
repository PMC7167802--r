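test_that("weight standardization matches hand arithmetic and zeroes constant filters", {
  # constant 3x3 depthwise filter: sigma = 0, numerator 0, eps keeps it finite
  W <- array(0.7, c(3, 3, 1, 1))
  expect_equal(weight_standardize(W), array(0, c(3, 3, 1, 1)))

  # one output channel with weights (1, 2, 3): mu = 2, sigma = sqrt(2/3)
  W <- array(c(1, 2, 3), c(1, 3, 1, 1))
  got <- weight_standardize(W, eps = 1e-12)
  expect_equal(as.vector(got), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # per-group mean ~0 and population std sigma/(sigma+eps) ~ 1 for any W
  set.seed(41)
  W <- array(rnorm(3 * 3 * 5 * 7), c(3, 3, 5, 7))
  Ws <- weight_standardize(W, eps = 1e-8)
  m <- matrix(Ws, ncol = 7)
  expect_lt(max(abs(colMeans(m))), 1e-12)
  expect_equal(sqrt(colMeans(m^2) - colMeans(m)^2), rep(1, 7), tolerance = 1e-6)
})

test_that("weight standardization groups depthwise kernels per channel", {
  # each channel's 9 weights standardized independently
  W <- array(0, c(3, 3, 2, 1))
  W[, , 1, 1] <- 1:9
  W[, , 2, 1] <- 100 + (1:9) * 10
  Ws <- weight_standardize(W, eps = 1e-12)
  expect_equal(Ws[, , 1, 1], Ws[, , 2, 1], tolerance = 1e-9)
  expect_equal(mean(Ws[, , 2, 1]), 0, tolerance = 1e-12)
})

test_that("weight standardization is idempotent in the small-eps limit", {
  set.seed(7)
  eps <- 1e-7
  for (shape in list(c(3, 3, 4, 6), c(3, 3, 8, 1), c(1, 1, 4, 4))) {
    W <- array(rnorm(prod(shape)), shape)
    once <- weight_standardize(W, eps = eps)
    twice <- weight_standardize(once, eps = eps)
    expect_lt(max(abs(twice - once)), 50 * eps)
  }
})

test_that("weight standardization rejects malformed input", {
  expect_error(weight_standardize(matrix(1, 3, 3)), "4-D")
  expect_error(weight_standardize(array(1, c(3, 3, 1, 1)), eps = 0), "positive")
  expect_error(weight_standardize(array(1, c(3, 3, 1, 1)), eps = -1), "positive")
})

test_that("group normalization matches hand arithmetic and the two-pass oracle", {
  # constant group maps to zero (zero-variance guard)
  x <- array(5, c(1, 3, 3, 2))
  expect_equal(group_normalize(x, num_groups = 1), array(0, dim(x)), tolerance = 1e-3)

  # one example, one group, values {1, 3}: mu = 2, sigma = 1 -> {-1, +1}
  x <- array(c(1, 3), c(1, 1, 2, 1))
  got <- group_normalize(x, num_groups = 1, eps = 1e-12)
  expect_equal(as.vector(got), c(-1, 1), tolerance = 1e-5)

  # G = C (instance norm) and G = 1 (layer norm) vs direct oracle
  set.seed(11)
  x <- array(rnorm(2 * 4 * 5 * 6), c(2, 4, 5, 6))
  eps <- 1e-5
  inst <- group_normalize(x, num_groups = 6, eps = eps)
  for (n in 1:2) for (c in 1:6)
    expect_equal(inst[n, , , c], oracle_group_norm(x[n, , , c], eps), tolerance = 1e-12)
  lay <- group_normalize(x, num_groups = 1, eps = eps)
  for (n in 1:2)
    expect_equal(lay[n, , , ], oracle_group_norm(x[n, , , ], eps), tolerance = 1e-12)
})

test_that("group normalization never pools across the batch", {
  set.seed(12)
  x1 <- array(rnorm(4 * 4 * 4), c(1, 4, 4, 4))
  x2 <- x1 * 10
  both <- array(0, c(2, 4, 4, 4))
  both[1, , , ] <- x1; both[2, , , ] <- x2
  joint <- group_normalize(both, num_groups = 2)
  expect_equal(joint[1, , , , drop = FALSE], group_normalize(x1, num_groups = 2))
  expect_equal(array(joint[2, , , ], c(1, 4, 4, 4)), group_normalize(x2, num_groups = 2))
})

test_that("group normalization applies the per-channel affine and validates input", {
  set.seed(13)
  x <- array(rnorm(1 * 2 * 2 * 4), c(1, 2, 2, 4))
  gamma <- c(1, 2, 3, 4); beta <- c(0.5, 0, -0.5, 1)
  plain <- group_normalize(x, num_groups = 2)
  scaled <- group_normalize(x, num_groups = 2, gamma = gamma, beta = beta)
  for (c in 1:4)
    expect_equal(scaled[, , , c], plain[, , , c] * gamma[c] + beta[c], tolerance = 1e-12)
  expect_error(group_normalize(x, num_groups = 3), "divisible")
  expect_error(group_normalize(x, num_groups = 2, eps = 0), "positive")
})

test_that("depthwise separable convolution reproduces the identity factorization", {
  set.seed(21)
  x <- array(rnorm(1 * 6 * 6 * 3), c(1, 6, 6, 3))
  dw <- array(0, c(3, 3, 3, 1)); dw[2, 2, , 1] <- 1    # per-channel delta
  pw <- array(0, c(1, 1, 3, 3)); for (c in 1:3) pw[1, 1, c, c] <- 1
  expect_equal(depthwise_separable_conv(x, dw, pw), x, tolerance = 1e-12)
})

test_that("depthwise separable convolution matches hand arithmetic on a 1x1 input", {
  x <- array(c(2, 3), c(1, 1, 1, 2))
  dw <- array(0, c(3, 3, 2, 1)); dw[2, 2, 1, 1] <- 0.5; dw[2, 2, 2, 1] <- 2
  pw <- array(c(1, 1, 1, -1), c(1, 1, 2, 2))  # columns (1,1) and (1,-1)
  got <- depthwise_separable_conv(x, dw, pw)
  expect_equal(as.vector(got), c(7, -5))      # depthwise (1, 6); pointwise (7, -5)
})

test_that("depthwise separable convolution equals the nested-loop oracle", {
  set.seed(22)
  x <- array(rnorm(1 * 8 * 8 * 4), c(1, 8, 8, 4))
  dw <- array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))
  pw <- array(rnorm(4 * 5), c(1, 1, 4, 5))
  b <- rnorm(5)
  want <- oracle_conv2d(oracle_dwconv2d(x, dw), pw, b)
  expect_equal(depthwise_separable_conv(x, dw, pw, b), want, tolerance = 1e-5)
})

test_that("depthwise separable convolution is linear in its input when bias is zero", {
  set.seed(23)
  dw <- array(rnorm(3 * 3 * 3), c(3, 3, 3, 1))
  pw <- array(rnorm(3 * 4), c(1, 1, 3, 4))
  x1 <- array(rnorm(2 * 5 * 5 * 3), c(2, 5, 5, 3))
  x2 <- array(rnorm(2 * 5 * 5 * 3), c(2, 5, 5, 3))
  f <- function(x) depthwise_separable_conv(x, dw, pw)
  expect_equal(f(2.5 * x1 - 0.7 * x2), 2.5 * f(x1) - 0.7 * f(x2), tolerance = 1e-10)
})

test_that("layer output shapes depend only on input shapes", {
  set.seed(24)
  for (hw in c(4L, 7L)) {
    x <- array(rnorm(2 * hw * hw * 4), c(2, hw, hw, 4))
    dw <- array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))
    pw <- array(rnorm(4 * 6), c(1, 1, 4, 6))
    expect_identical(dim(depthwise_separable_conv(x, dw, pw)), c(2L, hw, hw, 6L))
    expect_identical(dim(group_normalize(x, num_groups = 2)), dim(x))
    expect_identical(dim(weight_standardize(dw)), dim(dw))
  }
  expect_error(depthwise_separable_conv(
    array(0, c(1, 4, 4, 3)), array(0, c(3, 3, 4, 1)), array(0, c(1, 1, 4, 2))),
    "channel mismatch")
})
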