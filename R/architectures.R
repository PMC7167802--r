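#' Model configuration
#'
#' Collects the knobs shared by all architecture builders.
#'
#' @param input_height,input_width Input spatial size; must be divisible
#'   by 16 (the encoder applies four 2x max-poolings).
#' @param input_channels Input channels (1 for grayscale EM slices, 4
#'   for multi-modal MRI).
#' @param base_filters Channel width of the first encoder block; widths
#'   double at each encoder level (default 64, giving 64..1024).
#' @param variant One of `"sd_unet"`, `"unet"`, `"unet_gn"`,
#'   `"unet_dw_bn"`, `"unet_dw_gn"`, `"sd_unet_bn_ws"`.
#' @param num_groups Group-normalization group count (default 32). When
#'   a layer has fewer channels than `num_groups`, or a width not
#'   divisible by it, that layer falls back to one group per channel
#'   with a warning.
#' @param dropout_rate Dropout rate for the two regularized encoder
#'   blocks (default 0.5; set 0 to disable).
#' @param output_channels 1 for binary (sigmoid) heads, >1 for
#'   multi-class (softmax) heads.
#' @param seed Seed used by [init_weights()] by default.
#' @return A list of class `"sdunet_config"`.
#' @export
model_config <- function(input_height = 256L, input_width = 256L,
                         input_channels = 1L, base_filters = 64L,
                         variant = "sd_unet", num_groups = 32L,
                         dropout_rate = 0.5, output_channels = 1L,
                         seed = 42L) {
  variant <- match.arg(variant, names(.variant_options))
  .assert(input_height %% 16L == 0L && input_width %% 16L == 0L,
          "input sides must be divisible by 16 (four 2x poolings)")
  .assert(base_filters >= 1L && input_channels >= 1L && output_channels >= 1L,
          "channel counts must be positive")
  .assert(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must be in [0, 1)")
  .assert(num_groups >= 1L, "num_groups must be positive")
  cfg <- list(input_height = as.integer(input_height),
              input_width = as.integer(input_width),
              input_channels = as.integer(input_channels),
              base_filters = as.integer(base_filters),
              variant = variant, num_groups = as.integer(num_groups),
              dropout_rate = dropout_rate,
              output_channels = as.integer(output_channels),
              seed = as.integer(seed))
  class(cfg) <- "sdunet_config"
  cfg
}

# (separable convs?, normalization kind, weight standardization?) per variant
.variant_options <- list(
  sd_unet       = list(separable = TRUE,  norm = "gn",   ws = TRUE),
  unet          = list(separable = FALSE, norm = "none", ws = FALSE),
  unet_gn       = list(separable = FALSE, norm = "gn",   ws = FALSE),
  unet_dw_bn    = list(separable = TRUE,  norm = "bn",   ws = FALSE),
  unet_dw_gn    = list(separable = TRUE,  norm = "gn",   ws = FALSE),
  sd_unet_bn_ws = list(separable = TRUE,  norm = "bn",   ws = TRUE)
)

#' Build the SD-UNet layer graph
#'
#' SD-UNet keeps the U-Net encoder-decoder topology -- five encoder
#' levels with channel doubling from `base_filters`, four 2x2
#' max-poolings, skip concatenations, and a decoder that upsamples by 2
#' (nearest neighbour) followed by a 2x2 convolution -- but factorizes
#' every convolution except the very first into a depthwise plus a
#' pointwise stage. Group normalization (one layer per block, placed
#' after the block's second convolution) replaces batch normalization,
#' and all depthwise 3x3 kernels are weight-standardized at every
#' forward pass. Dropout regularizes the two deepest encoder blocks.
#' The head is a 1x1 convolution with a sigmoid (1 output channel) or
#' softmax (>1) activation.
#'
#' With the default 256x256x1 input and `base_filters = 64` the graph
#' has 3.9M trainable parameters, against 31M for the plain U-Net of
#' [build_unet()] -- the eightfold saving bought by the factorization.
#'
#' @param cfg A [model_config()]; the variant field is forced to the
#'   builder's own variant.
#' @return A list of class `"sdunet_graph"` with ordered layer records
#'   (name, kind, inputs, kernel/channel metadata, resolved output
#'   shapes).
#' @examples
#' g <- build_sd_unet(model_config(input_height = 64, input_width = 64,
#'                                 base_filters = 8))
#' summary(g)
#' @export
build_sd_unet <- function(cfg = model_config()) {
  cfg$variant <- "sd_unet"
  .build_graph(cfg)
}

#' Build the baseline U-Net layer graph
#'
#' Classic four-pool U-Net: two 3x3 convolutions (with bias, ReLU) per
#' block, channel doubling `base_filters .. 16 x base_filters`, decoder
#' upsampling by 2 followed by a 2x2 convolution, skip concatenations,
#' and a final 1x1 convolution. Implemented with "same" padding so the
#' output map matches the input size. No normalization layers.
#'
#' @inheritParams build_sd_unet
#' @return A `"sdunet_graph"`.
#' @export
build_unet <- function(cfg = model_config()) {
  cfg$variant <- "unet"
  .build_graph(cfg)
}

#' Build any ablation variant
#'
#' The six variants share one topology and differ only in whether
#' convolutions are depthwise separable, which normalization layer is
#' used (GN, BN or none), and whether the depthwise 3x3 kernels are
#' weight standardized. All depthwise variants therefore have identical
#' parameter counts up to normalization-affine differences, and
#' disabling weight standardization (a reparameterization, not a
#' parameter) changes neither shapes nor counts.
#'
#' @param name Variant name; one of `names(sdunet_variants())`.
#' @inheritParams build_sd_unet
#' @return A `"sdunet_graph"`.
#' @export
build_variant <- function(name, cfg = model_config()) {
  .assert(name %in% names(.variant_options),
          paste0("unknown variant '", name, "'"))
  cfg$variant <- name
  .build_graph(cfg)
}

#' Names of the buildable architecture variants
#' @return Named list of the per-variant options (separable?, norm, ws?).
#' @export
sdunet_variants <- function() .variant_options

## ---- graph construction ----

.build_graph <- function(cfg) {
  opt <- .variant_options[[cfg$variant]]
  st <- new.env(parent = emptyenv())
  st$layers <- list()
  st$shapes <- list()
  st$warned_groups <- FALSE

  add <- function(rec, out_shape) {
    rec$output_shape <- as.integer(out_shape)
    st$layers[[rec$name]] <- rec
    st$shapes[[rec$name]] <- rec$output_shape
    rec$name
  }
  shp <- function(nm) st$shapes[[nm]]

  conv <- function(nm, input, k, out_ch, separable, ws = FALSE) {
    s <- shp(input)
    kind <- if (separable) "ds_conv" else "conv"
    add(list(name = nm, kind = kind, inputs = input, kernel = as.integer(k),
             in_ch = s[3L], out_ch = as.integer(out_ch), bias = TRUE,
             ws = separable && ws && k == 3L),
        c(s[1:2], out_ch))
  }
  relu <- function(nm, input) add(list(name = nm, kind = "relu", inputs = input), shp(input))
  norm <- function(nm, input) {
    if (opt$norm == "none") return(input)
    s <- shp(input); C <- s[3L]
    G <- cfg$num_groups
    if (opt$norm == "gn" && (C < G || C %% G != 0L)) {
      if (!st$warned_groups) {
        warning(sprintf("channel width %d incompatible with %d groups; falling back to one group per channel for such layers", C, G), call. = FALSE)
        st$warned_groups <- TRUE
      }
      G <- C
    }
    add(list(name = nm, kind = opt$norm, inputs = input, channels = C,
             groups = if (opt$norm == "gn") as.integer(G) else NA_integer_),
        s)
  }
  pool <- function(nm, input) {
    s <- shp(input)
    add(list(name = nm, kind = "maxpool", inputs = input), c(s[1:2] %/% 2L, s[3L]))
  }
  upsample <- function(nm, input) {
    s <- shp(input)
    add(list(name = nm, kind = "upsample", inputs = input), c(s[1:2] * 2L, s[3L]))
  }
  concat <- function(nm, a, b) {
    sa <- shp(a); sb <- shp(b)
    .assert(all(sa[1:2] == sb[1:2]), "concatenation joins unequal spatial dims")
    add(list(name = nm, kind = "concat", inputs = c(a, b)), c(sa[1:2], sa[3L] + sb[3L]))
  }
  dropout <- function(nm, input) add(list(name = nm, kind = "dropout", inputs = input,
                                          rate = cfg$dropout_rate), shp(input))

  add(list(name = "input", kind = "input", inputs = character(0)),
      c(cfg$input_height, cfg$input_width, cfg$input_channels))

  # one encoder/decoder block: conv+ReLU, conv, norm, ReLU
  block <- function(tag, input, out_ch, first_standard = FALSE) {
    a <- conv(paste0(tag, "_conv1"), input, 3L, out_ch,
              separable = opt$separable && !first_standard, ws = opt$ws)
    a <- relu(paste0(tag, "_relu1"), a)
    b <- conv(paste0(tag, "_conv2"), a, 3L, out_ch, separable = opt$separable, ws = opt$ws)
    b <- norm(paste0(tag, "_norm"), b)
    relu(paste0(tag, "_relu2"), b)
  }

  nb <- cfg$base_filters
  widths <- nb * c(1L, 2L, 4L, 8L, 16L)

  # encoder; skips taken at full pre-pool resolution
  e1 <- block("enc1", "input", widths[1L], first_standard = TRUE)
  p1 <- pool("enc1_pool", e1)
  e2 <- block("enc2", p1, widths[2L]); p2 <- pool("enc2_pool", e2)
  e3 <- block("enc3", p2, widths[3L]); p3 <- pool("enc3_pool", e3)
  e4 <- block("enc4", p3, widths[4L])
  d4 <- dropout("enc4_drop", e4)
  p4 <- pool("enc4_pool", d4)
  e5 <- block("enc5", p4, widths[5L])
  bottom <- dropout("enc5_drop", e5)

  skips <- c(e1, e2, e3, d4)
  x <- bottom
  for (lev in 4:1) {
    tag <- paste0("dec", lev)
    u <- upsample(paste0(tag, "_up"), x)
    u <- conv(paste0(tag, "_upconv"), u, 2L, widths[lev], separable = opt$separable,
              ws = opt$ws)
    u <- relu(paste0(tag, "_uprelu"), u)
    m <- concat(paste0(tag, "_concat"), skips[lev], u)
    x <- block(tag, m, widths[lev])
  }

  h <- conv("head_conv", x, 1L, cfg$output_channels, separable = FALSE)
  out_act <- if (cfg$output_channels == 1L) "sigmoid" else "softmax"
  add(list(name = "head_act", kind = out_act, inputs = h), shp(h))

  g <- list(variant = cfg$variant, cfg = cfg, options = opt,
            layers = st$layers,
            input_shape = c(cfg$input_height, cfg$input_width, cfg$input_channels),
            output_shape = st$shapes[["head_act"]],
            n_pools = 4L)
  class(g) <- "sdunet_graph"
  g
}

#' Initialize trainable weights for a graph
#'
#' He-uniform initialization for all convolution kernels (bound
#' `sqrt(6 / fan_in)`), zeros for biases and normalization shifts, ones
#' for normalization scales. Fully determined by the seed: two calls
#' with equal seeds produce identical weights.
#'
#' @param graph A `"sdunet_graph"`.
#' @param seed Integer seed; defaults to the graph's configured seed.
#' @return Named list of per-layer weight lists.
#' @export
init_weights <- function(graph, seed = graph$cfg$seed) {
  .assert(inherits(graph, "sdunet_graph"), "graph must be an sdunet_graph")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  he <- function(n, fan_in) {
    lim <- sqrt(6 / fan_in)
    stats::runif(n, -lim, lim)
  }
  w <- list()
  for (ly in graph$layers) {
    w[[ly$name]] <- switch(ly$kind,
      conv = list(
        W = array(he(ly$kernel^2 * ly$in_ch * ly$out_ch, ly$kernel^2 * ly$in_ch),
                  c(ly$kernel, ly$kernel, ly$in_ch, ly$out_ch)),
        b = rep(0, ly$out_ch)),
      ds_conv = list(
        dw = array(he(ly$kernel^2 * ly$in_ch, ly$kernel^2),
                   c(ly$kernel, ly$kernel, ly$in_ch, 1L)),
        pw = array(he(ly$in_ch * ly$out_ch, ly$in_ch),
                   c(1L, 1L, ly$in_ch, ly$out_ch)),
        b = rep(0, ly$out_ch)),
      gn = list(gamma = rep(1, ly$channels), beta = rep(0, ly$channels)),
      bn = list(gamma = rep(1, ly$channels), beta = rep(0, ly$channels),
                running = list(mean = rep(0, ly$channels), var = rep(1, ly$channels))),
      NULL)
  }
  w[!vapply(w, is.null, logical(1L))]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
summary.sdunet_graph <- function(object, ...) {
  acc <- model_accounting(object)
  params <- stats::setNames(acc$layers$params, acc$layers$name)
  df <- do.call(rbind, lapply(object$layers, function(ly) data.frame(
    name = ly$name, kind = ly$kind,
    output_shape = paste(ly$output_shape, collapse = "x"),
    params = if (ly$name %in% names(params)) params[[ly$name]] else 0,
    stringsAsFactors = FALSE)))
  cat(sprintf("%s graph: input %s -> output %s\n", object$variant,
              paste(object$input_shape, collapse = "x"),
              paste(object$output_shape, collapse = "x")))
  print(df, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %s (%.1fM)\n",
              format(acc$totals[["params"]], big.mark = ","),
              acc$totals_millions[["params"]]))
  invisible(df)
}

#' @export
print.sdunet_graph <- function(x, ...) {
  cat(sprintf("<sdunet_graph> variant=%s, %d layers, input %s, output %s\n",
              x$variant, length(x$layers),
              paste(x$input_shape, collapse = "x"),
              paste(x$output_shape, collapse = "x")))
  invisible(x)
}

#' Serialize a layer graph to JSON
#'
#' @param graph A `"sdunet_graph"`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
graph_to_json <- function(graph, path = NULL) {
  .assert(inherits(graph, "sdunet_graph"), "graph must be an sdunet_graph")
  obj <- list(variant = graph$variant,
              input_shape = graph$input_shape,
              output_shape = graph$output_shape,
              layers = unname(lapply(graph$layers, function(ly) ly)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
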