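# Internal dense-array primitives for the channel-last (N, H, W, C) layout.
# All convolutions are "same"-padded, stride 1; even kernels pad bottom/right.

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.is_arr4 <- function(x) is.array(x) && length(dim(x)) == 4L

# flatten (N,H,W,C) -> (N*H*W, C); column-major order keeps channels as columns
.mat4 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
  x
}

.unmat4 <- function(m, d) {
  dim(m) <- d
  m
}

# zero-padded spatial shift: out[n,h,w,c] = x[n, h+dy, w+dx, c]
.shift4 <- function(x, dy, dx) {
  d <- dim(x)
  H <- d[2L]; W <- d[3L]
  if (dy == 0L && dx == 0L) return(x)
  out <- array(0, d)
  h_lo <- max(1L, 1L + dy); h_hi <- min(H, H + dy)   # source rows h+dy in 1..H
  w_lo <- max(1L, 1L + dx); w_hi <- min(W, W + dx)
  if (h_lo > h_hi || w_lo > w_hi) return(out)        # shift clears the image
  hs <- h_lo:h_hi
  ws <- w_lo:w_hi
  out[, hs - dy, ws - dx, ] <- x[, hs, ws, , drop = FALSE]
  out
}

# kernel tap offsets: odd kernels centred, even kernels anchored top-left
.kernel_offsets <- function(k) {
  if (k %% 2L == 1L) seq.int(-(k - 1L) / 2L, (k - 1L) / 2L) else seq.int(0L, k - 1L)
}

## ---- standard convolution (k x k, stride 1, same padding) ----

.conv_fwd <- function(x, W, b = NULL) {
  d <- dim(x); kh <- dim(W)[1L]; kw <- dim(W)[2L]
  cin <- dim(W)[3L]; cout <- dim(W)[4L]
  .assert(d[4L] == cin, "conv: channel mismatch between input and kernel")
  offy <- .kernel_offsets(kh); offx <- .kernel_offsets(kw)
  y <- matrix(0, d[1L] * d[2L] * d[3L], cout)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    Wk <- array(W[i, j, , ], c(cin, cout))
    y <- y + .mat4(.shift4(x, offy[i], offx[j])) %*% Wk
  }
  if (!is.null(b)) y <- y + rep(b, each = nrow(y))
  .unmat4(y, c(d[1L], d[2L], d[3L], cout))
}

.conv_bwd <- function(x, W, dy) {
  d <- dim(x); kh <- dim(W)[1L]; kw <- dim(W)[2L]
  cin <- dim(W)[3L]; cout <- dim(W)[4L]
  offy <- .kernel_offsets(kh); offx <- .kernel_offsets(kw)
  dym <- .mat4(dy)
  dW <- array(0, dim(W))
  dxm <- matrix(0, nrow(dym), cin)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    xs <- .mat4(.shift4(x, offy[i], offx[j]))
    dW[i, j, , ] <- crossprod(xs, dym)
    Wk <- array(W[i, j, , ], c(cin, cout))
    contrib <- .unmat4(tcrossprod(dym, Wk), c(d[1L], d[2L], d[3L], cin))
    dxm <- dxm + .mat4(.shift4(contrib, -offy[i], -offx[j]))
  }
  list(dx = .unmat4(dxm, d), dW = dW, db = colSums(dym))
}

## ---- depthwise convolution (k x k per-channel, multiplier 1) ----

.dwconv_fwd <- function(x, Wdw) {
  d <- dim(x); kh <- dim(Wdw)[1L]; kw <- dim(Wdw)[2L]; C <- dim(Wdw)[3L]
  .assert(d[4L] == C, "depthwise conv: channel mismatch")
  offy <- .kernel_offsets(kh); offx <- .kernel_offsets(kw)
  nr <- d[1L] * d[2L] * d[3L]
  y <- matrix(0, nr, C)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    w <- Wdw[i, j, , 1L]
    y <- y + .mat4(.shift4(x, offy[i], offx[j])) * rep(w, each = nr)
  }
  .unmat4(y, d)
}

.dwconv_bwd <- function(x, Wdw, dy) {
  d <- dim(x); kh <- dim(Wdw)[1L]; kw <- dim(Wdw)[2L]; C <- dim(Wdw)[3L]
  offy <- .kernel_offsets(kh); offx <- .kernel_offsets(kw)
  nr <- d[1L] * d[2L] * d[3L]
  dym <- .mat4(dy)
  dW <- array(0, dim(Wdw))
  dxm <- matrix(0, nr, C)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    xs <- .mat4(.shift4(x, offy[i], offx[j]))
    dW[i, j, , 1L] <- colSums(xs * dym)
    w <- Wdw[i, j, , 1L]
    contrib <- .unmat4(dym * rep(w, each = nr), d)
    dxm <- dxm + .mat4(.shift4(contrib, -offy[i], -offx[j]))
  }
  list(dx = .unmat4(dxm, d), dW = dW)
}

## ---- 2x2 max pooling, stride 2 ----

.maxpool_fwd <- function(x) {
  d <- dim(x)
  .assert(d[2L] %% 2L == 0L && d[3L] %% 2L == 0L, "maxpool: spatial dims must be even")
  ho <- seq.int(1L, d[2L], 2L); he <- ho + 1L
  wo <- seq.int(1L, d[3L], 2L); we <- wo + 1L
  x1 <- x[, ho, wo, , drop = FALSE]; x2 <- x[, he, wo, , drop = FALSE]
  x3 <- x[, ho, we, , drop = FALSE]; x4 <- x[, he, we, , drop = FALSE]
  y <- pmax(pmax(x1, x2), pmax(x3, x4))
  # route gradient to the first window position attaining the max
  m1 <- x1 == y
  m2 <- (x2 == y) & !m1
  m3 <- (x3 == y) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(y = y, masks = list(m1, m2, m3, m4), in_dim = d)
}

.maxpool_bwd <- function(cache, dy) {
  d <- cache$in_dim
  ho <- seq.int(1L, d[2L], 2L); he <- ho + 1L
  wo <- seq.int(1L, d[3L], 2L); we <- wo + 1L
  dx <- array(0, d)
  dx[, ho, wo, ] <- dy * cache$masks[[1L]]
  dx[, he, wo, ] <- dy * cache$masks[[2L]]
  dx[, ho, we, ] <- dy * cache$masks[[3L]]
  dx[, he, we, ] <- dy * cache$masks[[4L]]
  dx
}

## ---- nearest-neighbour x2 upsampling ----

.upsample_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1L], 2L * d[2L], 2L * d[3L], d[4L]))
  ho <- seq.int(1L, 2L * d[2L], 2L); wo <- seq.int(1L, 2L * d[3L], 2L)
  y[, ho, wo, ] <- x; y[, ho + 1L, wo, ] <- x
  y[, ho, wo + 1L, ] <- x; y[, ho + 1L, wo + 1L, ] <- x
  y
}

.upsample_bwd <- function(dy) {
  d <- dim(dy)
  ho <- seq.int(1L, d[2L], 2L); wo <- seq.int(1L, d[3L], 2L)
  dy[, ho, wo, , drop = FALSE] + dy[, ho + 1L, wo, , drop = FALSE] +
    dy[, ho, wo + 1L, , drop = FALSE] + dy[, ho + 1L, wo + 1L, , drop = FALSE]
}
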