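#' Loss configuration
#'
#' @param bce_weight,dice_weight Non-negative weights of the binary
#'   cross-entropy and (negated) soft-Dice terms; at least one must be
#'   positive. Defaults (1, 1).
#' @param smooth Soft-Dice stabilizer added to numerator and
#'   denominator; prevents 0/0 on empty masks. Default 1.
#' @return List of class `"loss_config"`.
#' @export
loss_config <- function(bce_weight = 1, dice_weight = 1, smooth = 1) {
  .assert(bce_weight >= 0 && dice_weight >= 0 && bce_weight + dice_weight > 0,
          "at least one loss weight must be positive")
  .assert(smooth > 0, "smooth must be positive")
  structure(list(bce_weight = bce_weight, dice_weight = dice_weight,
                 smooth = smooth), class = "loss_config")
}

.clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy loss
#'
#' Mean over pixels (and channels) of
#' `-(y log p + (1 - y) log(1 - p))`, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param pred_prob Predicted probabilities (any shape).
#' @param truth Binary targets, same shape.
#' @return Scalar loss.
#' @export
bce_loss <- function(pred_prob, truth) {
  .assert(length(pred_prob) == length(truth), "shape mismatch")
  p <- .clip_prob(pred_prob)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Soft (differentiable) Dice coefficient
#'
#' `(2 sum(p y) + smooth) / (sum(p) + sum(y) + smooth)`. For binary
#' `p = y` and `smooth -> 0` this is 1; for disjoint supports it is 0.
#' The negative of this value is used as a loss term. Multi-channel
#' inputs are scored per channel and averaged.
#'
#' @inheritParams bce_loss
#' @param smooth Stabilizer, default 1.
#' @return Scalar in (0, 1] (for non-degenerate smooth).
#' @export
soft_dice <- function(pred_prob, truth, smooth = 1) {
  .assert(length(pred_prob) == length(truth), "shape mismatch")
  d <- dim(pred_prob)
  if (!is.null(d) && length(d) == 4L && d[4L] > 1L) {
    pm <- .mat4(pred_prob); ym <- .mat4(truth)
    num <- 2 * colSums(pm * ym) + smooth
    den <- colSums(pm) + colSums(ym) + smooth
    return(mean(num / den))
  }
  (2 * sum(pred_prob * truth) + smooth) / (sum(pred_prob) + sum(truth) + smooth)
}

#' Weighted BCE minus soft-Dice training loss
#'
#' `bce_weight * BCE - dice_weight * softDice`: the cross-entropy pulls
#' per-pixel probabilities toward the labels while the negated Dice term
#' directly rewards overlap, which matters under foreground/background
#' imbalance.
#'
#' @inheritParams bce_loss
#' @param cfg A [loss_config()].
#' @return Scalar loss (can be negative: a perfect prediction
#'   approaches `-dice_weight`).
#' @export
combined_loss <- function(pred_prob, truth, cfg = loss_config()) {
  .assert(inherits(cfg, "loss_config"), "cfg must be a loss_config")
  cfg$bce_weight * bce_loss(pred_prob, truth) -
    cfg$dice_weight * soft_dice(pred_prob, truth, cfg$smooth)
}

# Gradient of the combined loss w.r.t. the predicted probabilities.
.combined_loss_grad <- function(pred_prob, truth, cfg) {
  p <- .clip_prob(pred_prob)
  n <- length(p)
  # clipping bounds the factor; composed with a sigmoid this reduces to
  # the numerically stable (p - y) / n logit gradient
  g <- cfg$bce_weight * (p - truth) / (p * (1 - p)) / n
  if (cfg$dice_weight > 0) {
    d <- dim(pred_prob)
    if (!is.null(d) && length(d) == 4L && d[4L] > 1L) {
      pm <- .mat4(pred_prob); ym <- .mat4(truth)
      num <- 2 * colSums(pm * ym) + cfg$smooth
      den <- colSums(pm) + colSums(ym) + cfg$smooth
      K <- d[4L]
      gd <- sweep(sweep(2 * ym, 2L, den, "/"), 2L, num / den^2, "-") / K
      g <- g - cfg$dice_weight * .unmat4(gd, d)
    } else {
      num <- 2 * sum(pred_prob * truth) + cfg$smooth
      den <- sum(pred_prob) + sum(truth) + cfg$smooth
      g <- g - cfg$dice_weight * (2 * truth / den - num / den^2)
    }
  }
  g
}
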