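#' Weight standardization of a convolution kernel
#'
#' Reparameterizes a 4-D convolution kernel so that, within each
#' standardization group, the weights have zero mean and (population)
#' standard deviation close to one: `W_hat = (W - mu) / (sigma + eps)`.
#' For a standard or pointwise kernel of shape
#' `(kernel_h, kernel_w, in_channels, out_channels)` the group is the full
#' fan-in of each output channel (`kernel_h * kernel_w * in_channels`
#' weights). For a depthwise kernel of shape `(kernel_h, kernel_w,
#' channels, 1)` each channel's `kernel_h * kernel_w` filter is its own
#' group, which is how the standardization is applied to the depthwise
#' 3x3 kernels of SD-UNet.
#'
#' `sigma` is the population standard deviation (divide by the group
#' size, not size - 1), and `eps` is added to `sigma` itself, not to the
#' variance. A constant filter therefore maps to an all-zero filter.
#'
#' @param W Real 4-D array, the convolution kernel.
#' @param eps Small positive numerical guard added to the standard
#'   deviation. Default `1e-5`.
#' @param depthwise Logical; treat `W` as a depthwise kernel (group =
#'   each channel's spatial filter). Defaults to `TRUE` when the fourth
#'   dimension has extent 1.
#' @return An array of the same shape as `W` containing the
#'   standardized weights.
#' @examples
#' W <- array(rnorm(3 * 3 * 4 * 8), c(3, 3, 4, 8))
#' Ws <- weight_standardize(W)
#' colMeans(matrix(Ws, ncol = 8))  # ~0 per output channel
#' @export
weight_standardize <- function(W, eps = 1e-5, depthwise = (dim(W)[4L] == 1L)) {
  .assert(.is_arr4(W), "W must be a 4-D array")
  .assert(is.numeric(eps) && length(eps) == 1L && eps > 0, "eps must be a positive scalar")
  d <- dim(W)
  n_groups <- if (depthwise) d[3L] * d[4L] else d[4L]
  m <- matrix(W, ncol = n_groups)        # one column per standardization group
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(m^2) - mu^2)
  sigma[sigma < 0 | is.nan(sigma)] <- 0  # guard tiny negative from cancellation
  m <- sweep(m, 2L, mu, "-")
  m <- sweep(m, 2L, sigma + eps, "/")
  array(m, d)
}

# Gradient of weight standardization: given g = dL/dW_hat, return dL/dW.
# dW_j = (g_j - mean(g)) / (sigma + eps) - What_j * mean(g * What) / sigma
# with the second term defined as 0 for a constant (sigma = 0) group.
.ws_bwd <- function(W, g, eps = 1e-5, depthwise = (dim(W)[4L] == 1L)) {
  d <- dim(W)
  n_groups <- if (depthwise) d[3L] * d[4L] else d[4L]
  m <- matrix(W, ncol = n_groups)
  gm <- matrix(g, ncol = n_groups)
  mu <- colMeans(m)
  sigma <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  denom <- sigma + eps
  what <- sweep(sweep(m, 2L, mu, "-"), 2L, denom, "/")
  gc_ <- sweep(gm, 2L, colMeans(gm), "-")
  coef <- colMeans(gm * what) / ifelse(sigma > 1e-12, sigma, Inf)
  dW <- sweep(gc_, 2L, denom, "/") - sweep(what, 2L, coef, "*")
  array(dW, d)
}

#' Group normalization of a feature map
#'
#' Normalizes a channel-last feature map `(N, H, W, C)` per example and
#' per channel group: statistics are pooled over the spatial dimensions
#' and the channels within each group, never across the batch axis, then
#' a per-channel affine transform `gamma * x_hat + beta` is applied.
#' With `num_groups = C` this is instance normalization; with
#' `num_groups = 1` it is layer normalization over `(H, W, C)`.
#'
#' @param x Real 4-D array `(batch, height, width, channels)`.
#' @param num_groups Number of channel groups `G`; `C` must be divisible
#'   by `G`. Default 32, the setting used throughout SD-UNet.
#' @param gamma,beta Per-channel scale and shift vectors of length `C`.
#'   Default to ones and zeros.
#' @param eps Small positive guard added to the group variance. Default
#'   `1e-5`.
#' @return A 4-D array of the same shape as `x`.
#' @examples
#' x <- array(rnorm(2 * 4 * 4 * 8), c(2, 4, 4, 8))
#' y <- group_normalize(x, num_groups = 4)
#' @export
group_normalize <- function(x, num_groups = 32L, gamma = NULL, beta = NULL, eps = 1e-5) {
  .assert(.is_arr4(x), "x must be a 4-D array (N, H, W, C)")
  C <- dim(x)[4L]
  .assert(num_groups >= 1L && C %% num_groups == 0L,
          "channel count must be divisible by num_groups")
  .assert(eps > 0, "eps must be positive")
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  .assert(length(gamma) == C && length(beta) == C,
          "gamma and beta must have one entry per channel")
  .gn_fwd(x, as.integer(num_groups), gamma, beta, eps)$y
}

# Forward with cache. Layout trick: aperm to (H, W, C, N) and reshape to
# (H*W*Cg, G*N) so each column is one normalization group of one example.
.gn_fwd <- function(x, G, gamma, beta, eps) {
  d <- dim(x)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  Cg <- C %/% G
  xp <- aperm(x, c(2L, 3L, 4L, 1L))
  dim(xp) <- c(H * W * Cg, G * N)
  mu <- colMeans(xp)
  v <- colMeans(xp^2) - mu^2
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- sweep(sweep(xp, 2L, mu, "-"), 2L, invstd, "*")
  dim(xhat) <- c(H, W, C, N)
  xhat <- aperm(xhat, c(4L, 1L, 2L, 3L))
  ym <- .mat4(xhat)
  nr <- nrow(ym)
  y <- .unmat4(ym * rep(gamma, each = nr) + rep(beta, each = nr), d)
  list(y = y, xhat = xhat, invstd = invstd, gamma = gamma)
}

.gn_bwd <- function(cache, G, dy) {
  d <- dim(dy)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  Cg <- C %/% G
  nr <- N * H * W
  dym <- .mat4(dy)
  xhm <- .mat4(cache$xhat)
  dgamma <- colSums(dym * xhm)
  dbeta <- colSums(dym)
  dxhat <- .unmat4(dym * rep(cache$gamma, each = nr), d)
  # per-group: dx = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dp <- aperm(dxhat, c(2L, 3L, 4L, 1L)); dim(dp) <- c(H * W * Cg, G * N)
  xp <- aperm(cache$xhat, c(2L, 3L, 4L, 1L)); dim(xp) <- c(H * W * Cg, G * N)
  t1 <- sweep(dp, 2L, colMeans(dp), "-")
  t2 <- sweep(xp, 2L, colMeans(dp * xp), "*")
  dxp <- sweep(t1 - t2, 2L, cache$invstd, "*")
  dim(dxp) <- c(H, W, C, N)
  list(dx = aperm(dxp, c(4L, 1L, 2L, 3L)), dgamma = dgamma, dbeta = dbeta)
}

# Thin batch normalization (per-channel over batch and space) for the
# ablation variants; batch statistics in training, running averages at
# evaluation (momentum 0.9).
.bn_fwd <- function(x, gamma, beta, running, eps, training) {
  d <- dim(x)
  xm <- .mat4(x)
  nr <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- 0.9 * running$mean + 0.1 * mu
    running$var <- 0.9 * running$var + 0.1 * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, invstd, "*")
  y <- .unmat4(xhat * rep(gamma, each = nr) + rep(beta, each = nr), d)
  list(y = y, xhat = .unmat4(xhat, d), invstd = invstd, gamma = gamma,
       running = running)
}

.bn_bwd <- function(cache, dy) {
  d <- dim(dy)
  nr <- prod(d[1:3])
  dym <- .mat4(dy)
  xhm <- .mat4(cache$xhat)
  dgamma <- colSums(dym * xhm)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(cache$gamma, each = nr)
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(xhm, 2L, colMeans(dxhat * xhm), "*")
  dx <- sweep(t1 - t2, 2L, cache$invstd, "*")
  list(dx = .unmat4(dx, d), dgamma = dgamma, dbeta = dbeta)
}

#' Depthwise separable convolution
#'
#' Factorizes a k x k convolution into a depthwise stage, which convolves
#' each input channel with its own k x k filter (no cross-channel
#' mixing), followed by a pointwise (1 x 1) stage that forms every output
#' channel as a weighted sum over channels at each pixel, plus a bias.
#' Stride 1, "same" padding: the output spatial size equals the input's.
#'
#' @param x Feature map, 4-D array `(N, H, W, C)`.
#' @param dw Depthwise kernel `(k, k, C, 1)` (channel multiplier 1).
#' @param pw Pointwise kernel `(1, 1, C, N_out)`.
#' @param bias Optional length-`N_out` bias added by the pointwise stage.
#' @return 4-D array `(N, H, W, N_out)`.
#' @examples
#' x <- array(rnorm(1 * 8 * 8 * 4), c(1, 8, 8, 4))
#' dw <- array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))
#' pw <- array(rnorm(4 * 6), c(1, 1, 4, 6))
#' y <- depthwise_separable_conv(x, dw, pw)
#' @export
depthwise_separable_conv <- function(x, dw, pw, bias = NULL) {
  .assert(.is_arr4(x) && .is_arr4(dw) && .is_arr4(pw),
          "x, dw and pw must be 4-D arrays")
  .assert(dim(dw)[4L] == 1L, "depthwise kernel must have channel multiplier 1")
  .assert(dim(x)[4L] == dim(dw)[3L] && dim(dw)[3L] == dim(pw)[3L],
          "channel mismatch between x, dw and pw")
  .assert(dim(pw)[1L] == 1L && dim(pw)[2L] == 1L, "pw must be a 1x1 kernel")
  mid <- .dwconv_fwd(x, dw)
  .conv_fwd(mid, pw, bias)
}
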