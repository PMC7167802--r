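#' Confusion counts of a thresholded probability map
#'
#' Binarizes the prediction at `threshold` (`pred >= threshold` is
#' positive) and tallies true/false positives/negatives against a binary
#' truth mask.
#'
#' @param pred_prob Numeric array of probabilities; any shape.
#' @param truth Binary mask (0/1 or logical) of the same shape.
#' @param threshold Scalar in (0, 1). Default 0.5.
#' @return A list of class `"confusion_counts"` with integer fields
#'   `TP`, `TN`, `FP`, `FN` summing to the number of pixels.
#' @export
confusion_counts <- function(pred_prob, truth, threshold = 0.5) {
  .assert(length(pred_prob) == length(truth) &&
            identical(dim(pred_prob) %||% length(pred_prob),
                      dim(truth) %||% length(truth)),
          "prediction and truth shapes must match")
  .assert(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  p <- pred_prob >= threshold
  y <- truth > 0
  out <- list(TP = sum(p & y), TN = sum(!p & !y),
              FP = sum(p & !y), FN = sum(!p & y))
  class(out) <- "confusion_counts"
  out
}

#' Pixel accuracy, intersection-over-union and Dice coefficient
#'
#' `accuracy = (TP + TN) / total`; `iou = TP / (TP + FP + FN)`;
#' `dice = 2 TP / (2 TP + FP + FN)`. Empty-union convention: when
#' `TP = FP = FN = 0` (both prediction and truth empty) IOU and Dice are
#' 1; when exactly one side is empty they are 0 (which the formulas give
#' directly). Dice and IOU are algebraically linked:
#' `dice = 2 iou / (1 + iou)`.
#'
#' @param c A [confusion_counts()] object (or list with TP/TN/FP/FN).
#' @return A scalar in `[0, 1]`.
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  .assert(tot > 0, "no pixels to evaluate")
  (c$TP + c$TN) / tot
}

#' @rdname accuracy
#' @export
iou <- function(c) {
  den <- c$TP + c$FP + c$FN
  if (den == 0) return(1)
  c$TP / den
}

#' @rdname accuracy
#' @export
dice <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(1)
  2 * c$TP / den
}

#' Label connected components of a binary mask
#'
#' 4-connectivity component labeling (diagonal contact does not join
#' components -- the right convention for membrane images, where
#' 8-connectivity leaks across thin walls). Background pixels get label
#' 0.
#'
#' @param mask Logical or 0/1 matrix; `TRUE`/1 = foreground.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  .assert(is.matrix(mask), "mask must be a matrix")
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)   # 4-connectivity
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# Contingency table of segment co-occurrence restricted to T-foreground.
.seg_contingency <- function(S, T) {
  .assert(all(dim(S) == dim(T)), "segmentations must have equal shape")
  keep <- T > 0
  .assert(any(keep), "ground truth has no foreground pixels")
  s <- as.integer(factor(S[keep]))
  t <- as.integer(factor(T[keep]))
  n <- length(s)
  counts <- table(s, t)
  list(nij = as.matrix(counts), n = n)
}

#' Foreground-restricted Rand F-score of two segmentations
#'
#' Restricted to pixels that are foreground in the ground truth `T`
#' (label > 0), considers all unordered pixel pairs and computes the
#' merge score -- the probability that a pair in the same `T` segment is
#' also in the same `S` segment -- and the split score -- the
#' probability that a pair in the same `S` segment is also in the same
#' `T` segment. Returns their harmonic mean (equal weights). Computed
#' from the label contingency table via sums of squared counts, never by
#' pair enumeration.
#'
#' @param S Predicted segmentation: integer matrix of segment IDs
#'   (0 = boundary/background).
#' @param T Ground-truth segmentation, same shape.
#' @return Scalar in `[0, 1]`; 1 iff the segmentations agree on the
#'   foreground up to relabeling.
#' @export
foreground_restricted_rand_score <- function(S, T) {
  ct <- .seg_contingency(S, T)
  nij <- ct$nij
  pairs_both <- (sum(nij^2) - ct$n) / 2
  pairs_S <- (sum(rowSums(nij)^2) - ct$n) / 2
  pairs_T <- (sum(colSums(nij)^2) - ct$n) / 2
  merge_score <- if (pairs_T > 0) pairs_both / pairs_T else 1
  split_score <- if (pairs_S > 0) pairs_both / pairs_S else 1
  if (merge_score + split_score == 0) return(0)
  2 * merge_score * split_score / (merge_score + split_score)
}

#' Foreground-restricted information-theoretic F-score
#'
#' From the same foreground-restricted contingency table as
#' [foreground_restricted_rand_score()], computes the mutual information
#' `I(S;T)` and entropies `H(S)`, `H(T)` of the segment-label
#' distributions (`0 log 0 = 0`), and returns the harmonic mean of
#' `I/H(S)` and `I/H(T)`. A degenerate single-segment labeling has
#' `H = 0`; its ratio is defined as 1 when both labelings are
#' single-segment (then they agree trivially) and 0 otherwise.
#'
#' @inheritParams foreground_restricted_rand_score
#' @return Scalar in `[0, 1]`.
#' @export
information_theoretic_score <- function(S, T) {
  ct <- .seg_contingency(S, T)
  p <- ct$nij / ct$n
  ps <- rowSums(p)
  pt <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hs <- ent(ps); ht <- ent(pt)
  keep <- p > 0
  I <- sum(p[keep] * log(p[keep] / outer(ps, pt)[keep]))
  I <- max(I, 0)   # clip float negatives
  if (hs == 0 && ht == 0) return(1)
  rs <- if (hs > 0) I / hs else 0
  rt <- if (ht > 0) I / ht else 0
  if (rs + rt == 0) return(0)
  2 * rs * rt / (rs + rt)
}

#' Maximal Rand and information scores over a threshold sweep
#'
#' For each threshold, binarizes a boundary-probability map (pixels with
#' probability `>=` threshold are boundary), labels the connected
#' components of the non-boundary pixels (4-connectivity) as segments,
#' scores the labeling against the ground-truth segmentation restricted
#' to its foreground, and returns the maxima over the sweep -- the
#' "maximal foreground-restricted" scores used for boundary-map
#' evaluation. Foreground restriction approximates the border-thinning
#' of the EM challenge protocol: ground-truth boundary pixels (label 0)
#' are excluded from scoring.
#'
#' @param boundary_prob Numeric matrix in `[0, 1]`: probability that a
#'   pixel is boundary/membrane.
#' @param T Ground-truth segmentation (integer matrix, 0 = boundary).
#' @param thresholds Numeric vector of thresholds in (0, 1). Default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return Named list with elements `v_rand` and `v_info` (the maxima)
#'   and `by_threshold`, a data.frame of per-threshold scores.
#' @export
maximal_score_over_thresholds <- function(boundary_prob, T,
                                          thresholds = seq(0.05, 0.95, by = 0.05)) {
  .assert(length(thresholds) >= 1L, "threshold list must be non-empty")
  .assert(is.matrix(boundary_prob) && all(dim(boundary_prob) == dim(T)),
          "boundary map and truth must be matrices of equal shape")
  vr <- vi <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    S <- label_components(boundary_prob < thresholds[k])
    vr[k] <- foreground_restricted_rand_score(S, T)
    vi[k] <- information_theoretic_score(S, T)
  }
  list(v_rand = max(vr), v_info = max(vi),
       by_threshold = data.frame(threshold = thresholds, v_rand = vr, v_info = vi))
}
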