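# Seeded generators emulating the statistical structure of the two
# benchmark settings: EM membrane stacks with in-out binary labels, and
# multi-modal MRI slices with nested multi-class tumor labels.

# smooth unit-scale noise field: blurred white noise rescaled to [0, 1]
.smooth_field <- function(H, W, sigma = 6) {
  z <- matrix(stats::rnorm(H * W), H, W)
  k <- stats::dnorm(seq(-ceiling(2 * sigma), ceiling(2 * sigma)), sd = sigma)
  k <- k / sum(k)
  kl <- length(k)
  x <- array(z, c(1L, H, W, 1L))
  ones <- array(1, c(1L, H, W, 1L))
  Kh <- array(k, c(kl, 1L, 1L, 1L))
  Kw <- array(rep(k, each = 1L), c(1L, kl, 1L, 1L))
  blur <- function(a) .conv_fwd(.conv_fwd(a, Kh), Kw)
  sm <- blur(x) / blur(ones)   # renormalize to undo zero-padding at edges
  sm <- matrix(sm, H, W)
  rng <- range(sm)
  if (diff(rng) == 0) return(matrix(0.5, H, W))
  (sm - rng[1L]) / diff(rng)
}

# seed points with minimum-separation rejection to avoid sliver cells
.poisson_disk <- function(n_pts, H, W, min_sep, max_tries = 4000L) {
  pts <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  while (nrow(pts) < n_pts && tries < max_tries) {
    cand <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2)) >= min_sep)
      pts <- rbind(pts, cand)
    tries <- tries + 1L
  }
  pts
}

#' Generate EM-like membrane segmentation samples
#'
#' Emulates serial-section EM slices with in-out labels: a seeded point
#' process partitions the image into cells (a Voronoi tessellation with
#' minimum-separation rejection), cell walls 1-3 px wide become mask
#' value 0 (membrane) and interiors value 1, and the image renders
#' interiors as bright textured regions with correlated noise and
#' membranes as dark ridges. The per-sample `labels` field carries the
#' cell partition (integer segment IDs, 0 on membranes) for
#' Rand/information scoring.
#'
#' `cell_density` controls the expected number of cells,
#' `round(cell_density * H * W / 64)` (so cell diameter, not count, is
#' preserved across image sizes); the default 0.1 gives ~25 px diameter
#' cells and a membrane-pixel fraction around 0.15.
#'
#' @param n Number of samples.
#' @param H,W Image size in pixels.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param cell_density Cells per 64 pixels, in (0, 1].
#' @return List of `n` samples, each a list with `image` (`(H, W, 1)`
#'   array in `[0, 1]`), `mask` (`(H, W)` integer, 1 = interior,
#'   0 = membrane), `labels` (`(H, W)` integer segment IDs) and `meta`.
#' @export
generate_em_like <- function(n, H = 256L, W = 256L, seed = 1L, cell_density = 0.1) {
  .assert(n >= 1L && H >= 8L && W >= 8L, "n, H, W must be positive (H, W >= 8)")
  .assert(cell_density > 0 && cell_density <= 1, "cell_density must be in (0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n_cells <- max(2L, as.integer(round(cell_density * H * W / 64)))
  min_sep <- 0.6 * sqrt(H * W / n_cells)
  hh <- matrix(rep(seq_len(H), W), H, W)
  ww <- matrix(rep(seq_len(W), each = H), H, W)
  lapply(seq_len(n), function(i) {
    pts <- .poisson_disk(n_cells, H, W, min_sep)
    .assert(nrow(pts) >= 2L, "degenerate tessellation: fewer than 2 seed points")
    d2all <- vapply(seq_len(nrow(pts)), function(j)
      (hh - pts[j, 1L])^2 + (ww - pts[j, 2L])^2, matrix(0, H, W))
    dim(d2all) <- c(H * W, nrow(pts))
    nearest <- max.col(-d2all, ties.method = "first")
    d1 <- sqrt(d2all[cbind(seq_len(H * W), nearest)])
    d2all[cbind(seq_len(H * W), nearest)] <- Inf
    d2 <- sqrt(apply(d2all, 1L, min))
    width <- 1 + 2 * .smooth_field(H, W, sigma = max(4, H / 16))  # 1..3 px jitter
    wall <- matrix(d2 - d1, H, W) <= width
    mask <- matrix(1L, H, W); mask[wall] <- 0L
    labels <- matrix(as.integer(nearest), H, W); labels[wall] <- 0L
    cell_shade <- stats::runif(nrow(pts), 0.55, 0.85)
    img <- matrix(cell_shade[nearest], H, W)
    img[wall] <- stats::runif(1, 0.08, 0.18)
    img <- img + 0.10 * (.smooth_field(H, W, sigma = 3) - 0.5) +
      0.03 * matrix(stats::rnorm(H * W), H, W)
    img <- pmin(pmax(img, 0), 1)
    list(image = array(img, c(H, W, 1L)), mask = mask, labels = labels,
         meta = list(kind = "em_like", seed = seed, index = i,
                     cell_density = cell_density, n_cells = nrow(pts)))
  })
}

# filled rotated ellipse indicator on the pixel grid
.ellipse_mask <- function(H, W, ch, cw, a, b, theta) {
  hh <- matrix(rep(seq_len(H), W), H, W) - ch
  ww <- matrix(rep(seq_len(W), each = H), H, W) - cw
  u <- cos(theta) * hh + sin(theta) * ww
  v <- -sin(theta) * hh + cos(theta) * ww
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate BRATs-like multi-modal tumor samples
#'
#' Emulates 2-D slices of multi-parametric MRI: four image channels
#' (modality surrogates with distinct contrast responses) and a 4-class
#' label partition -- background (0), edema (1), non-enhancing core (2)
#' and enhancing core (3) -- built as nested concentric ellipses so the
#' cores always lie inside the edema. A configurable fraction of samples
#' carries small tumors (under 2% of pixels) to exercise the
#' small-lesion regime; the rest draw an edema area fraction uniform in
#' 6-14% of the image. Expected class pixel fractions implied by these
#' settings are reported in each sample's `meta$expected_class_fraction`.
#'
#' @inheritParams generate_em_like
#' @param small_tumor_frac Fraction of samples with small (<2% of
#'   pixels) tumors. Default 0.25.
#' @return List of samples with `image` (`(H, W, 4)`), `mask`
#'   (`(H, W, 4)` one-hot), `labels` (`(H, W)` class indices 0..3) and
#'   `meta`.
#' @export
generate_brats_like <- function(n, H = 144L, W = 144L, seed = 1L,
                                small_tumor_frac = 0.25) {
  .assert(n >= 1L && H >= 16L && W >= 16L, "n, H, W must be positive (H, W >= 16)")
  .assert(small_tumor_frac >= 0 && small_tumor_frac <= 1,
          "small_tumor_frac must lie in [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # area fractions: large tumors U(0.06, 0.14), small U(0.004, 0.018);
  # cores concentric: enhancing 30% of edema area, non-enhancing 15%
  f_enh <- 0.30; f_non <- 0.15
  mean_area <- small_tumor_frac * 0.011 + (1 - small_tumor_frac) * 0.10
  expected <- c(background = 1 - mean_area,
                edema = mean_area * (1 - f_enh),
                non_enhancing = mean_area * f_non,
                enhancing = mean_area * (f_enh - f_non))
  lapply(seq_len(n), function(i) {
    small <- stats::runif(1) < small_tumor_frac
    area <- if (small) stats::runif(1, 0.004, 0.018) else stats::runif(1, 0.06, 0.14)
    aspect <- stats::runif(1, 0.7, 1.3)
    theta <- stats::runif(1, 0, pi)
    ab <- sqrt(area * H * W / pi)
    a <- ab * sqrt(aspect); b <- ab / sqrt(aspect)
    ch <- stats::runif(1, 1 + a, H - a)
    cw <- stats::runif(1, 1 + b, W - b)
    edema <- .ellipse_mask(H, W, ch, cw, a, b, theta)
    enh <- .ellipse_mask(H, W, ch, cw, a * sqrt(f_enh), b * sqrt(f_enh), theta)
    non <- .ellipse_mask(H, W, ch, cw, a * sqrt(f_non), b * sqrt(f_non), theta)
    labels <- matrix(0L, H, W)
    labels[edema] <- 1L
    labels[enh] <- 3L
    labels[non] <- 2L
    onehot <- array(0, c(H, W, 4L))
    for (k in 0:3) onehot[, , k + 1L][labels == k] <- 1
    # modality surrogates: distinct mean responses per tissue class
    resp <- rbind(background = c(0.35, 0.30, 0.30, 0.25),
                  edema = c(0.30, 0.35, 0.75, 0.80),
                  non_enhancing = c(0.20, 0.25, 0.55, 0.60),
                  enhancing = c(0.45, 0.90, 0.60, 0.65))
    img <- array(0, c(H, W, 4L))
    tex <- .smooth_field(H, W, sigma = 5)
    for (m in 1:4) {
      base <- matrix(resp[labels + 1L, m], H, W)
      img[, , m] <- pmin(pmax(base + 0.08 * (tex - 0.5) +
                                0.04 * matrix(stats::rnorm(H * W), H, W), 0), 1)
    }
    list(image = img, mask = onehot, labels = labels,
         meta = list(kind = "brats_like", seed = seed, index = i,
                     small_tumor = small, area_fraction = area,
                     expected_class_fraction = expected))
  })
}

## ---- preprocessing ----

# pixel-centre coordinate mapping; identical sizes map exactly
.resize2d <- function(m, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  if (H == out_h && W == out_w) return(m)
  sy <- H / out_h; sx <- W / out_w
  yc <- (seq_len(out_h) - 0.5) * sy + 0.5
  xc <- (seq_len(out_w) - 0.5) * sx + 0.5
  if (method == "nearest") {
    yi <- pmin(pmax(round(yc), 1L), H)
    xi <- pmin(pmax(round(xc), 1L), W)
    return(m[yi, xi, drop = FALSE])
  }
  y0 <- pmin(pmax(floor(yc), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xc), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(yc - y0, 0), 1); wx <- pmin(pmax(xc - x0, 0), 1)
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y1, x0, drop = FALSE]
  m01 <- m[y0, x1, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wyM <- matrix(wy, out_h, out_w); wxM <- matrix(wx, out_h, out_w, byrow = TRUE)
  m00 * (1 - wyM) * (1 - wxM) + m10 * wyM * (1 - wxM) +
    m01 * (1 - wyM) * wxM + m11 * wyM * wxM
}

.apply_planes <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  d <- dim(x)
  planes <- lapply(seq_len(d[3L]), function(k) f(x[, , k]))
  out <- array(0, c(dim(planes[[1L]]), d[3L]))
  for (k in seq_len(d[3L])) out[, , k] <- planes[[k]]
  out
}

#' Center-crop, resize and standardize an image/mask pair
#'
#' Optionally center-crops both image and mask to `crop` (height,
#' width), then resizes to `target_size` -- bilinear interpolation for
#' the image, nearest neighbour for the mask so labels stay valid class
#' indices -- and standardizes the image to zero mean and unit variance
#' (population SD over all pixels and channels; a constant image maps to
#' all zeros).
#'
#' @param image `(H, W)` matrix or `(H, W, C)` array.
#' @param mask `(H, W)` integer matrix or `(H, W, K)` one-hot array.
#' @param target_size Length-2 integer vector (height, width).
#' @param crop Optional length-2 crop size taken centrally before
#'   resizing; must not exceed the source size. Crop offsets are
#'   `floor((source - crop) / 2)`.
#' @param standardize Standardize the image? Default `TRUE`.
#' @return List with fields `image` and `mask`.
#' @export
preprocess_sample <- function(image, mask, target_size, crop = NULL,
                              standardize = TRUE) {
  .assert(length(target_size) == 2L && all(target_size >= 1),
          "target_size must be (height, width)")
  src <- c(nrow(image), ncol(image))
  if (!is.null(crop)) {
    .assert(all(crop <= src), "crop size exceeds source size")
    off <- floor((src - crop) / 2)
    sel_h <- off[1L] + seq_len(crop[1L]); sel_w <- off[2L] + seq_len(crop[2L])
    image <- if (is.matrix(image)) image[sel_h, sel_w, drop = FALSE]
             else image[sel_h, sel_w, , drop = FALSE]
    mask <- if (is.matrix(mask)) mask[sel_h, sel_w, drop = FALSE]
            else mask[sel_h, sel_w, , drop = FALSE]
  }
  image <- .apply_planes(image, function(p)
    .resize2d(p, target_size[1L], target_size[2L], "bilinear"))
  mask <- .apply_planes(mask, function(p)
    .resize2d(p, target_size[1L], target_size[2L], "nearest"))
  if (standardize) {
    mu <- mean(image)
    sdv <- sqrt(mean((image - mu)^2))
    image <- if (sdv > 0) (image - mu) / sdv else image * 0
  }
  list(image = image, mask = mask)
}

## ---- augmentation ----

#' Augmentation configuration
#'
#' @param horizontal_flip Probability of a left-right flip.
#' @param zoom_range Length-2 positive range the zoom factor is drawn
#'   from (1 = no zoom). Default `c(0.9, 1.1)`.
#' @param shift_range Length-2 fractional (height, width) maximum
#'   shifts; the shift is drawn uniformly in `+/- shift_range`.
#'   Default `c(0.1, 0.1)`.
#' @return List of class `"augment_config"`.
#' @export
augment_config <- function(horizontal_flip = 0.5, zoom_range = c(0.9, 1.1),
                           shift_range = c(0.1, 0.1)) {
  .assert(horizontal_flip >= 0 && horizontal_flip <= 1,
          "flip probability must be in [0, 1]")
  .assert(length(zoom_range) == 2L && all(zoom_range > 0), "zoom bounds must be positive")
  .assert(length(shift_range) == 2L && all(shift_range >= 0), "shift range must be >= 0")
  structure(list(horizontal_flip = horizontal_flip, zoom_range = sort(zoom_range),
                 shift_range = shift_range), class = "augment_config")
}

# mirror-reflect an index vector into 1..n (no edge repetition)
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (round(i) - 1L) %% p
  j <- ifelse(j >= n, p - j, j)
  as.integer(j + 1L)
}

#' Jointly augment an image/mask sample
#'
#' Draws one spatial transform -- horizontal flip with the configured
#' probability, isotropic zoom about the image centre, fractional
#' height/width shift -- and applies it identically to image, mask and
#' (when present) `labels`. The image is resampled bilinearly, mask and
#' labels by nearest neighbour (no fractional labels can appear), and
#' out-of-bounds regions are filled by mirror reflection. A zoom of 1
#' with zero shift and no flip is the exact identity.
#'
#' @param sample List with `image` and `mask` (and optionally `labels`),
#'   as produced by the generators.
#' @param cfg An [augment_config()].
#' @param seed Integer seed for the transform draw.
#' @return A sample list of the same structure.
#' @export
augment_sample <- function(sample, cfg = augment_config(), seed = 1L) {
  .assert(inherits(cfg, "augment_config"), "cfg must be an augment_config")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  H <- nrow(sample$image); W <- ncol(sample$image)
  flip <- stats::runif(1) < cfg$horizontal_flip
  zoom <- stats::runif(1, cfg$zoom_range[1L], cfg$zoom_range[2L])
  sh <- stats::runif(1, -cfg$shift_range[1L], cfg$shift_range[1L]) * H
  sw <- stats::runif(1, -cfg$shift_range[2L], cfg$shift_range[2L]) * W
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- (seq_len(H) - cy) / zoom + cy - sh
  xs <- (seq_len(W) - cx) / zoom + cx - sw
  if (flip) xs <- rev(xs)
  bilinear <- function(m) {
    y0 <- floor(ys); x0 <- floor(xs)
    wy <- ys - y0; wx <- xs - x0
    iy0 <- .reflect_idx(y0, H); iy1 <- .reflect_idx(y0 + 1, H)
    ix0 <- .reflect_idx(x0, W); ix1 <- .reflect_idx(x0 + 1, W)
    wyM <- matrix(wy, H, W); wxM <- matrix(wx, H, W, byrow = TRUE)
    m[iy0, ix0, drop = FALSE] * (1 - wyM) * (1 - wxM) +
      m[iy1, ix0, drop = FALSE] * wyM * (1 - wxM) +
      m[iy0, ix1, drop = FALSE] * (1 - wyM) * wxM +
      m[iy1, ix1, drop = FALSE] * wyM * wxM
  }
  nearest <- function(m) m[.reflect_idx(round(ys), H), .reflect_idx(round(xs), W),
                           drop = FALSE]
  out <- sample
  out$image <- .apply_planes(sample$image, bilinear)
  out$mask <- .apply_planes(sample$mask, nearest)
  if (!is.null(sample$labels)) out$labels <- .apply_planes(sample$labels, nearest)
  out$meta <- c(sample$meta, list(augment = list(flip = flip, zoom = zoom,
                                                 shift = c(sh, sw), seed = seed)))
  out
}
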