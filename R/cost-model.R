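#' Multiplication cost of a standard convolution layer
#'
#' Number of scalar multiplications performed by a k x k standard
#' convolution over a square feature map:
#' `Dk * Dk * M * N * Df * Df`.
#'
#' @param Dk Kernel size (square), positive integer.
#' @param M Input channels.
#' @param N Output channels.
#' @param Df Square feature-map side length.
#' @return The exact count as a double (counts can exceed
#'   `.Machine$integer.max`).
#' @seealso [separable_conv_cost()], [cost_reduction_ratio()]
#' @export
standard_conv_cost <- function(Dk, M, N, Df) {
  .check_cost_spec(Dk, M, N, Df)
  Dk * Dk * M * N * Df * Df
}

#' Multiplication cost of a depthwise separable convolution layer
#'
#' Depthwise term plus pointwise term:
#' `Dk * Dk * M * Df * Df + M * N * Df * Df`.
#'
#' @inheritParams standard_conv_cost
#' @return The exact count as a double.
#' @export
separable_conv_cost <- function(Dk, M, N, Df) {
  .check_cost_spec(Dk, M, N, Df)
  Dk * Dk * M * Df * Df + M * N * Df * Df
}

#' Computation-reduction factor of the depthwise separable factorization
#'
#' Ratio of the standard to the separable cost. The feature-map side and
#' the shared input-channel count cancel, leaving
#' `Dk^2 * N / (Dk^2 + N)`: monotonically increasing in `N` and bounded
#' above by `Dk^2`, which is why 3x3 separable layers approach a 9-fold
#' saving at large widths ("8 or 9 times" at deep-layer widths).
#'
#' @inheritParams standard_conv_cost
#' @param Df Feature-map side; irrelevant to the ratio (cancels), kept
#'   for symmetry with the cost functions.
#' @return The reduction factor (> 0).
#' @examples
#' cost_reduction_ratio(3, 512, 512) # ~8.85
#' @export
cost_reduction_ratio <- function(Dk, M, N, Df = 1) {
  .check_cost_spec(Dk, M, N, Df)
  standard_conv_cost(Dk, M, N, Df) / separable_conv_cost(Dk, M, N, Df)
}

.check_cost_spec <- function(Dk, M, N, Df) {
  for (v in list(Dk, M, N, Df))
    .assert(is.numeric(v) && length(v) == 1L && v >= 1 && v == floor(v),
            "cost spec fields must be positive integers")
  invisible(TRUE)
}

#' Parameter and FLOP accounting for a model graph
#'
#' Walks a [LayerGraph][build_sd_unet] and tallies, per layer and in
#' total: trainable parameters (kernel weights, biases, normalization
#' scale/shift), kernel-only weights, per-pixel multiply-adds (the
#' standard accounting: the convolution cost formulas evaluated at each
#' layer's own spatial size), and `flops_2x_weights`: FLOPs defined as
#' two operations (one multiply, one add) per convolution kernel weight
#' with each kernel counted once -- i.e. `2 x` the kernel-only weight
#' count, excluding biases and normalization affines. The latter
#' convention is what makes a ~31M-parameter U-Net a "62M FLOP" model
#' and its separable counterpart a "7.8M FLOP" one.
#'
#' @param graph A layer graph from [build_sd_unet()], [build_unet()] or
#'   [build_variant()].
#' @return An object of class `"cost_report"`: a list with `layers` (a
#'   data.frame of per-layer rows), `totals` (raw counts), and
#'   `totals_millions` (rounded to one decimal). Totals always equal the
#'   column sums of the rows.
#' @examples
#' g <- build_sd_unet(model_config(input_height = 64, input_width = 64))
#' rep <- model_accounting(g)
#' rep$totals_millions
#' @export
model_accounting <- function(graph) {
  .assert(inherits(graph, "sdunet_graph"), "graph must be an sdunet_graph")
  rows <- list()
  for (ly in graph$layers) {
    p <- .layer_param_counts(ly)
    if (is.null(p)) next
    Df2 <- prod(ly$output_shape[1:2])
    mult_adds <- switch(ly$kind,
      conv = ly$kernel^2 * ly$in_ch * ly$out_ch * Df2,
      ds_conv = ly$kernel^2 * ly$in_ch * Df2 + ly$in_ch * ly$out_ch * Df2,
      0)
    rows[[length(rows) + 1L]] <- data.frame(
      name = ly$name, kind = ly$kind,
      params = p$kernel + p$bias + p$affine,
      kernel_weights = p$kernel,
      mult_adds = mult_adds,
      flops_2x_weights = 2 * p$kernel,
      stringsAsFactors = FALSE)
  }
  layers <- do.call(rbind, rows)
  totals <- c(params = sum(layers$params),
              kernel_weights = sum(layers$kernel_weights),
              mult_adds = sum(layers$mult_adds),
              flops_2x_weights = sum(layers$flops_2x_weights))
  out <- list(layers = layers, totals = totals,
              totals_millions = round(totals / 1e6, 1),
              model_size_bytes = 4 * totals[["params"]])
  class(out) <- "cost_report"
  out
}

# kernel / bias / normalization-affine counts for one layer record
.layer_param_counts <- function(ly) {
  switch(ly$kind,
    conv = list(kernel = ly$kernel^2 * ly$in_ch * ly$out_ch,
                bias = if (isTRUE(ly$bias)) ly$out_ch else 0L, affine = 0L),
    ds_conv = list(kernel = ly$kernel^2 * ly$in_ch + ly$in_ch * ly$out_ch,
                   bias = if (isTRUE(ly$bias)) ly$out_ch else 0L, affine = 0L),
    gn = list(kernel = 0L, bias = 0L, affine = 2L * ly$channels),
    bn = list(kernel = 0L, bias = 0L, affine = 2L * ly$channels),
    NULL)
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Model cost report\n")
  df <- x$layers
  df$mult_adds <- format(df$mult_adds, big.mark = ",")
  print(df, row.names = FALSE)
  cat(sprintf("\nTotals: %s parameters (%.1fM), %s kernel weights\n",
              format(x$totals[["params"]], big.mark = ","),
              x$totals_millions[["params"]],
              format(x$totals[["kernel_weights"]], big.mark = ",")))
  cat(sprintf("FLOPs (2 ops/kernel weight): %.1fM;  per-pixel mult-adds: %s\n",
              x$totals_millions[["flops_2x_weights"]],
              format(x$totals[["mult_adds"]], big.mark = ",")))
  cat(sprintf("Weights-only size: %.1f MB (4 bytes/parameter)\n",
              x$model_size_bytes / 2^20))
  invisible(x)
}
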