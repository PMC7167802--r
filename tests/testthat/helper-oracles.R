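# Independent brute-force oracles. These deliberately share no code with
# the package internals: convolutions are nested loops, pair scores are
# explicit O(n^2) enumerations, entropies are direct summations.

# direct k x k standard convolution, same padding, stride 1
oracle_conv2d <- function(x, W, b = NULL) {
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  offy <- if (kh %% 2 == 1) -(kh - 1) / 2 else 0
  offx <- if (kw %% 2 == 1) -(kw - 1) / 2 else 0
  y <- array(0, c(d[1], d[2], d[3], cout))
  for (n in 1:d[1]) for (h in 1:d[2]) for (w in 1:d[3]) for (o in 1:cout) {
    acc <- 0
    for (i in 1:kh) for (j in 1:kw) for (c in 1:d[4]) {
      hh <- h + i - 1 + offy; ww <- w + j - 1 + offx
      if (hh >= 1 && hh <= d[2] && ww >= 1 && ww <= d[3])
        acc <- acc + x[n, hh, ww, c] * W[i, j, c, o]
    }
    y[n, h, w, o] <- acc + if (is.null(b)) 0 else b[o]
  }
  y
}

# direct depthwise convolution (channel multiplier 1)
oracle_dwconv2d <- function(x, Wdw) {
  d <- dim(x); kh <- dim(Wdw)[1]; kw <- dim(Wdw)[2]
  offy <- if (kh %% 2 == 1) -(kh - 1) / 2 else 0
  offx <- if (kw %% 2 == 1) -(kw - 1) / 2 else 0
  y <- array(0, d)
  for (n in 1:d[1]) for (h in 1:d[2]) for (w in 1:d[3]) for (c in 1:d[4]) {
    acc <- 0
    for (i in 1:kh) for (j in 1:kw) {
      hh <- h + i - 1 + offy; ww <- w + j - 1 + offx
      if (hh >= 1 && hh <= d[2] && ww >= 1 && ww <= d[3])
        acc <- acc + x[n, hh, ww, c] * Wdw[i, j, c, 1]
    }
    y[n, h, w, c] <- acc
  }
  y
}

# pair-enumeration Rand F-score restricted to T-foreground
oracle_rand_score <- function(S, T) {
  keep <- which(T > 0)
  s <- S[keep]; t <- T[keep]
  same_both <- same_s <- same_t <- 0
  n <- length(s)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ss <- s[i] == s[j]; tt <- t[i] == t[j]
    if (ss && tt) same_both <- same_both + 1
    if (ss) same_s <- same_s + 1
    if (tt) same_t <- same_t + 1
  }
  merge_score <- if (same_t > 0) same_both / same_t else 1
  split_score <- if (same_s > 0) same_both / same_s else 1
  if (merge_score + split_score == 0) return(0)
  2 * merge_score * split_score / (merge_score + split_score)
}

# direct-summation mutual-information F-score
oracle_info_score <- function(S, T) {
  keep <- which(T > 0)
  s <- S[keep]; t <- T[keep]
  n <- length(s)
  su <- unique(s); tu <- unique(t)
  hs <- ht <- I <- 0
  for (a in su) { p <- sum(s == a) / n; hs <- hs - p * log(p) }
  for (b in tu) { p <- sum(t == b) / n; ht <- ht - p * log(p) }
  for (a in su) for (b in tu) {
    pj <- sum(s == a & t == b) / n
    if (pj > 0) I <- I + pj * log(pj / ((sum(s == a) / n) * (sum(t == b) / n)))
  }
  I <- max(I, 0)
  if (hs == 0 && ht == 0) return(1)
  rs <- if (hs > 0) I / hs else 0
  rt <- if (ht > 0) I / ht else 0
  if (rs + rt == 0) return(0)
  2 * rs * rt / (rs + rt)
}

# direct two-pass mean/variance normalization of one channel group
oracle_group_norm <- function(vals, eps) {
  mu <- mean(vals)
  v <- mean((vals - mu)^2)
  (vals - mu) / sqrt(v + eps)
}

# random labeled segmentation pair for score tests
random_seg_pair <- function(H, W, k_s, k_t, bg_frac = 0.2) {
  S <- matrix(sample.int(k_s, H * W, replace = TRUE), H, W)
  T <- matrix(sample.int(k_t, H * W, replace = TRUE), H, W)
  T[matrix(runif(H * W) < bg_frac, H, W)] <- 0
  list(S = S, T = T)
}

tiny_em_data <- function(n = 4, hw = 32, seed = 2) generate_em_like(n, hw, hw, seed = seed)

tiny_graph <- function(hw = 32, base = 4, variant = "sd_unet", out_ch = 1, seed = 3) {
  cfg <- model_config(input_height = hw, input_width = hw, input_channels = 1,
                      base_filters = base, dropout_rate = 0,
                      output_channels = out_ch, seed = seed)
  suppressWarnings(build_variant(variant, cfg))
}
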