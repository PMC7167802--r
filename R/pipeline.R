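#' Training configuration
#'
#' @param learning_rate Adam learning rate. The defaults used on the two
#'   data regimes are `1e-4` (EM-like, binary cross-entropy) and `1e-5`
#'   (BRATs-like, Dice + BCE); small overfitting runs converge faster
#'   around `1e-3`.
#' @param epochs Number of epochs.
#' @param steps_per_epoch Optimizer steps per epoch; default covers the
#'   dataset once per epoch.
#' @param batch_size Mini-batch size; default 2 (group normalization is
#'   designed for such micro-batches).
#' @param loss `"bce"` or `"dice_bce"`.
#' @param seed Seed controlling batch shuffling and dropout; the whole
#'   run is a pure function of (data, weights, cfg).
#' @param checkpoint_dir Optional directory; when given, the best
#'   validation-Dice weights and the history JSON are written there.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 1L,
                         steps_per_epoch = NULL, batch_size = 2L,
                         loss = c("bce", "dice_bce"), seed = 1L,
                         checkpoint_dir = NULL) {
  loss <- match.arg(loss)
  .assert(learning_rate >= 0, "learning_rate must be >= 0")
  .assert(batch_size >= 1L && epochs >= 1L, "batch_size and epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 steps_per_epoch = steps_per_epoch,
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

.loss_cfg_for <- function(kind) {
  if (kind == "bce") loss_config(bce_weight = 1, dice_weight = 0)
  else loss_config(bce_weight = 1, dice_weight = 1)
}

# stack sample images/masks into (N, H, W, C) batches
.stack_images <- function(samples, field = "image") {
  first <- samples[[1L]][[field]]
  d <- if (is.matrix(first)) c(dim(first), 1L) else dim(first)
  out <- array(0, c(length(samples), d))
  for (i in seq_along(samples)) out[i, , , ] <- samples[[i]][[field]]
  out
}

.mask_to_targets <- function(samples, out_ch) {
  first <- samples[[1L]]$mask
  d2 <- c(nrow(first), ncol(first))
  out <- array(0, c(length(samples), d2, out_ch))
  for (i in seq_along(samples)) {
    m <- samples[[i]]$mask
    if (is.matrix(m)) {
      .assert(out_ch == 1L, "integer mask with a multi-channel head")
      out[i, , , 1L] <- as.numeric(m > 0)
    } else {
      .assert(dim(m)[3L] == out_ch, "one-hot mask channel count mismatch")
      out[i, , , ] <- m
    }
  }
  out
}

#' Train a model graph
#'
#' Seeded end-to-end optimization with Adam (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8) and full backpropagation through every layer, including
#' the weight-standardization reparameterization of the depthwise
#' kernels. Records per-epoch loss, accuracy, Dice and IOU (at
#' threshold 0.5) for the training data and, when given, a validation
#' split; with a `checkpoint_dir` the best-validation-Dice weights and
#' the history are serialized there.
#'
#' @param graph A `"sdunet_graph"`.
#' @param data List of samples (`image` + `mask`), e.g. from
#'   [generate_em_like()].
#' @param cfg A [train_config()].
#' @param val_data Optional validation samples.
#' @param weights Optional starting weights; default
#'   `init_weights(graph)`.
#' @return An object of class `"sdunet_fit"`: list with `graph`,
#'   `weights` (final), `best_weights`, `history` (data.frame with one
#'   row per epoch and split).
#' @export
train_sdunet <- function(graph, data, cfg = train_config(), val_data = NULL,
                         weights = NULL) {
  .assert(inherits(graph, "sdunet_graph"), "graph must be an sdunet_graph")
  .assert(length(data) >= 1L, "empty training data")
  if (is.null(weights)) weights <- init_weights(graph)
  lcfg <- .loss_cfg_for(cfg$loss)
  out_ch <- graph$output_shape[3L]
  steps <- cfg$steps_per_epoch %||% max(1L, ceiling(length(data) / cfg$batch_size))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  adam <- .adam_init(weights)
  history <- list()
  best <- list(dice = -Inf, weights = weights)

  for (epoch in seq_len(cfg$epochs)) {
    epoch_loss <- 0
    for (step in seq_len(steps)) {
      idx <- sample.int(length(data), min(cfg$batch_size, length(data)))
      x <- .stack_images(data[idx])
      y <- .mask_to_targets(data[idx], out_ch)
      fw <- .forward_graph(graph, weights, x, training = TRUE)
      weights <- fw$weights   # BN running statistics
      loss <- combined_loss(fw$output, y, lcfg)
      .assert(is.finite(loss), sprintf("non-finite loss at epoch %d step %d", epoch, step))
      dout <- .combined_loss_grad(fw$output, y, lcfg)
      grads <- .backward_graph(graph, weights, fw, dout)
      if (cfg$learning_rate > 0) {
        upd <- .adam_step(weights, grads, adam, cfg$learning_rate)
        weights <- upd$weights
        adam <- upd$state
      }
      epoch_loss <- epoch_loss + loss
    }
    tr <- .epoch_metrics(graph, weights, data, lcfg, out_ch)
    tr$loss_running <- epoch_loss / steps
    history[[length(history) + 1L]] <- data.frame(epoch = epoch, split = "train", tr)
    if (!is.null(val_data)) {
      va <- .epoch_metrics(graph, weights, val_data, lcfg, out_ch)
      va$loss_running <- NA_real_
      history[[length(history) + 1L]] <- data.frame(epoch = epoch, split = "val", va)
      if (va$dice > best$dice) best <- list(dice = va$dice, weights = weights)
    } else if (tr$dice > best$dice) best <- list(dice = tr$dice, weights = weights)
  }
  history <- do.call(rbind, history)

  fit <- structure(list(graph = graph, weights = weights,
                        best_weights = best$weights, history = history,
                        config = cfg),
                   class = "sdunet_fit")
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(best$weights, file.path(cfg$checkpoint_dir, "best_weights.rds"))
    jsonlite::write_json(history, file.path(cfg$checkpoint_dir, "history.json"),
                         dataframe = "rows", digits = NA)
  }
  fit
}

.epoch_metrics <- function(graph, weights, samples, lcfg, out_ch) {
  x <- .stack_images(samples)
  y <- .mask_to_targets(samples, out_ch)
  fw <- .forward_graph(graph, weights, x, training = FALSE)
  cc <- confusion_counts(fw$output, y, 0.5)
  data.frame(loss = combined_loss(fw$output, y, lcfg),
             accuracy = accuracy(cc), dice = dice(cc), iou = iou(cc))
}

#' Predict probability maps
#'
#' Runs the forward pass in evaluation mode (dropout off, batch-norm
#' running statistics). Inputs whose sides are not divisible by 16 are
#' reflect-padded with a warning and the output is cropped back.
#'
#' @param object An `"sdunet_fit"` from [train_sdunet()].
#' @param images A `(N, H, W, C)` array, a single `(H, W, C)` array, or
#'   a list of samples with `image` fields.
#' @param use_best Use the checkpointed best weights (default) rather
#'   than the final ones.
#' @param ... Unused.
#' @return `(N, H, W, K)` array of probabilities in (0, 1).
#' @export
predict.sdunet_fit <- function(object, images, use_best = TRUE, ...) {
  w <- if (use_best) object$best_weights else object$weights
  sdunet_forward(object$graph, w, images)
}

#' Forward pass of a graph on an image stack
#'
#' @param graph A `"sdunet_graph"`.
#' @param weights Weights as from [init_weights()].
#' @param images As in [predict.sdunet_fit()].
#' @return `(N, H, W, K)` probability array.
#' @export
sdunet_forward <- function(graph, weights, images) {
  if (is.list(images) && !is.null(images[[1L]]$image)) images <- .stack_images(images)
  if (length(dim(images)) == 3L) images <- array(images, c(1L, dim(images)))
  .assert(.is_arr4(images), "images must be a 4-D (N, H, W, C) array")
  d <- dim(images)
  div <- 2L^graph$n_pools
  pad_h <- (div - d[2L] %% div) %% div
  pad_w <- (div - d[3L] %% div) %% div
  if (pad_h > 0L || pad_w > 0L) {
    warning(sprintf("input %dx%d not divisible by %d; reflect-padding to %dx%d",
                    d[2L], d[3L], div, d[2L] + pad_h, d[3L] + pad_w), call. = FALSE)
    ih <- c(seq_len(d[2L]), .reflect_idx(d[2L] + seq_len(pad_h), d[2L]))
    iw <- c(seq_len(d[3L]), .reflect_idx(d[3L] + seq_len(pad_w), d[3L]))
    padded <- images[, ih, iw, , drop = FALSE]
    out <- .forward_graph(graph, weights, padded, training = FALSE)$output
    return(out[, seq_len(d[2L]), seq_len(d[3L]), , drop = FALSE])
  }
  .forward_graph(graph, weights, images, training = FALSE)$output
}

#' Evaluate a fitted model on labeled samples
#'
#' Computes pixel accuracy, IOU and Dice over the pooled pixel stream at
#' threshold 0.5 and, for binary (in-out boundary style) heads, the
#' maximal foreground-restricted Rand and information-theoretic scores
#' over a threshold sweep, using each sample's `labels` segmentation
#' (or, failing that, the 4-connected components of its mask).
#'
#' @param fit An `"sdunet_fit"` (or a list with `graph` and `weights`).
#' @param data List of samples with `image`, `mask`, optionally
#'   `labels`.
#' @param thresholds Sweep for the Rand/information maxima.
#' @return List of class `"sdunet_eval"`: `accuracy`, `iou`, `dice`,
#'   `loss`, and for binary heads `v_rand`, `v_info` (mean of
#'   per-sample maxima).
#' @export
evaluate_model <- function(fit, data, thresholds = seq(0.05, 0.95, by = 0.05)) {
  .assert(length(data) >= 1L, "empty evaluation data")
  graph <- fit$graph
  w <- fit$best_weights %||% fit$weights
  out_ch <- graph$output_shape[3L]
  probs <- sdunet_forward(graph, w, data)
  y <- .mask_to_targets(data, out_ch)
  cc <- confusion_counts(probs, y, 0.5)
  res <- list(accuracy = accuracy(cc), iou = iou(cc), dice = dice(cc),
              loss = combined_loss(probs, y, .loss_cfg_for(
                if (out_ch == 1L) "bce" else "dice_bce")),
              n_samples = length(data))
  if (out_ch == 1L) {
    vr <- vi <- numeric(length(data))
    for (i in seq_along(data)) {
      truth_seg <- data[[i]]$labels %||%
        label_components(if (is.matrix(data[[i]]$mask)) data[[i]]$mask > 0
                         else data[[i]]$mask[, , 1L] > 0)
      boundary <- 1 - probs[i, , , 1L]   # head predicts P(interior)
      mx <- maximal_score_over_thresholds(boundary, truth_seg, thresholds)
      vr[i] <- mx$v_rand; vi[i] <- mx$v_info
    }
    res$v_rand <- mean(vr)
    res$v_info <- mean(vi)
  }
  class(res) <- "sdunet_eval"
  res
}

#' @export
print.sdunet_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d samples:\n", x$n_samples))
  cat(sprintf("  accuracy %.4f  IOU %.4f  Dice %.4f  loss %.4f\n",
              x$accuracy, x$iou, x$dice, x$loss))
  if (!is.null(x$v_rand))
    cat(sprintf("  maximal V_Rand %.4f  maximal V_Info %.4f\n", x$v_rand, x$v_info))
  invisible(x)
}

#' Plot training curves
#'
#' @param history The `history` data.frame of an `"sdunet_fit"`.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_history <- function(history) {
  .assert(requireNamespace("ggplot2", quietly = TRUE),
          "ggplot2 is required for plotting")
  ggplot2::ggplot(history, ggplot2::aes(x = epoch, y = loss, colour = split)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}
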