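# Forward and reverse passes through a layer graph, plus Adam.
# Activations are (N, H, W, C) arrays keyed by layer name; each layer
# caches what its backward rule needs. Weight standardization is applied
# to the depthwise kernels at every forward pass (a reparameterization:
# the optimizer steps on the raw kernels).

.forward_graph <- function(graph, weights, x, training = FALSE) {
  .assert(.is_arr4(x), "input must be a 4-D (N, H, W, C) array")
  .assert(all(dim(x)[2:4] == graph$input_shape),
          sprintf("input shape %s does not match graph input %s",
                  paste(dim(x)[2:4], collapse = "x"),
                  paste(graph$input_shape, collapse = "x")))
  acts <- list()
  cache <- list()
  for (ly in graph$layers) {
    nm <- ly$name
    w <- weights[[nm]]
    inp <- if (length(ly$inputs)) acts[[ly$inputs[1L]]] else NULL
    switch(ly$kind,
      input = { acts[[nm]] <- x },
      conv = {
        acts[[nm]] <- .conv_fwd(inp, w$W, w$b)
      },
      ds_conv = {
        dw <- if (isTRUE(ly$ws)) weight_standardize(w$dw) else w$dw
        mid <- .dwconv_fwd(inp, dw)
        acts[[nm]] <- .conv_fwd(mid, w$pw, w$b)
        cache[[nm]] <- list(mid = mid, dw_eff = dw)
      },
      gn = {
        fw <- .gn_fwd(inp, ly$groups, w$gamma, w$beta, 1e-5)
        acts[[nm]] <- fw$y
        cache[[nm]] <- fw[c("xhat", "invstd", "gamma")]
      },
      bn = {
        fw <- .bn_fwd(inp, w$gamma, w$beta, w$running, 1e-5, training)
        acts[[nm]] <- fw$y
        cache[[nm]] <- fw[c("xhat", "invstd", "gamma")]
        if (training) weights[[nm]]$running <- fw$running
      },
      relu = {
        acts[[nm]] <- pmax(inp, 0)
      },
      sigmoid = {
        acts[[nm]] <- 1 / (1 + exp(-inp))
      },
      softmax = {
        # per-pixel over channels; recycling over the contiguous (N,H,W)
        # prefix broadcasts the row-wise max and sum across channels
        mx <- do.call(pmax, lapply(seq_len(dim(inp)[4L]),
                                   function(c) inp[, , , c, drop = FALSE]))
        e <- exp(inp - as.vector(mx))
        acts[[nm]] <- e / rowSums(.mat4(e))
      },
      maxpool = {
        fw <- .maxpool_fwd(inp)
        acts[[nm]] <- fw$y
        cache[[nm]] <- fw[c("masks", "in_dim")]
      },
      upsample = {
        acts[[nm]] <- .upsample_fwd(inp)
      },
      concat = {
        b <- acts[[ly$inputs[2L]]]
        acts[[nm]] <- .concat4(inp, b)
        cache[[nm]] <- c(dim(inp)[4L], dim(b)[4L])
      },
      dropout = {
        if (training && ly$rate > 0) {
          keep <- array(stats::runif(length(inp)) >= ly$rate, dim(inp))
          acts[[nm]] <- inp * keep / (1 - ly$rate)
          cache[[nm]] <- keep
        } else acts[[nm]] <- inp
      },
      stop("unknown layer kind: ", ly$kind))
  }
  last <- graph$layers[[length(graph$layers)]]$name
  list(output = acts[[last]], acts = acts, cache = cache, weights = weights)
}

.concat4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4L] + dim(b)[4L]))
  out[, , , seq_len(d[4L])] <- a
  out[, , , d[4L] + seq_len(dim(b)[4L])] <- b
  out
}

# Reverse pass; returns gradients for every trainable tensor (same
# nesting as the weights list) given dL/d(output).
.backward_graph <- function(graph, weights, fw, dout) {
  grads <- list()
  dacts <- list()
  layers <- graph$layers
  last <- layers[[length(layers)]]$name
  dacts[[last]] <- dout
  bump <- function(nm, g) {
    dacts[[nm]] <<- if (is.null(dacts[[nm]])) g else dacts[[nm]] + g
  }
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    nm <- ly$name
    dy <- dacts[[nm]]
    if (is.null(dy)) next
    w <- weights[[nm]]
    inp_nm <- if (length(ly$inputs)) ly$inputs[1L] else NULL
    inp <- if (!is.null(inp_nm)) fw$acts[[inp_nm]] else NULL
    switch(ly$kind,
      input = {},
      conv = {
        bw <- .conv_bwd(inp, w$W, dy)
        grads[[nm]] <- list(W = bw$dW, b = bw$db)
        bump(inp_nm, bw$dx)
      },
      ds_conv = {
        cc <- fw$cache[[nm]]
        bw2 <- .conv_bwd(cc$mid, w$pw, dy)
        bw1 <- .dwconv_bwd(inp, cc$dw_eff, bw2$dx)
        ddw <- if (isTRUE(ly$ws)) .ws_bwd(w$dw, bw1$dW) else bw1$dW
        grads[[nm]] <- list(dw = ddw, pw = bw2$dW, b = bw2$db)
        bump(inp_nm, bw1$dx)
      },
      gn = {
        bw <- .gn_bwd(fw$cache[[nm]], ly$groups, dy)
        grads[[nm]] <- list(gamma = bw$dgamma, beta = bw$dbeta)
        bump(inp_nm, bw$dx)
      },
      bn = {
        bw <- .bn_bwd(fw$cache[[nm]], dy)
        grads[[nm]] <- list(gamma = bw$dgamma, beta = bw$dbeta)
        bump(inp_nm, bw$dx)
      },
      relu = bump(inp_nm, dy * (fw$acts[[nm]] > 0)),
      sigmoid = {
        p <- fw$acts[[nm]]
        bump(inp_nm, dy * p * (1 - p))
      },
      softmax = {
        p <- fw$acts[[nm]]
        s <- rowSums(.mat4(dy * p))   # recycles across channels below
        bump(inp_nm, p * (dy - s))
      },
      maxpool = bump(inp_nm, .maxpool_bwd(fw$cache[[nm]], dy)),
      upsample = bump(inp_nm, .upsample_bwd(dy)),
      concat = {
        ca <- fw$cache[[nm]][1L]
        bump(inp_nm, dy[, , , seq_len(ca), drop = FALSE])
        bump(ly$inputs[2L], dy[, , , ca + seq_len(dim(dy)[4L] - ca), drop = FALSE])
      },
      dropout = {
        cc <- fw$cache[[nm]]
        if (is.null(cc)) bump(inp_nm, dy)
        else bump(inp_nm, dy * cc / (1 - ly$rate))
      })
  }
  grads
}

## ---- Adam ----

# moment buffers are created lazily (first step) from the gradient shapes
.adam_init <- function(weights) list(t = 0L, m = list(), v = list())

`%||%` <- function(a, b) if (is.null(a)) b else a

.trainable_names <- function(weights) {
  out <- list()
  for (nm in names(weights)) {
    f <- setdiff(names(weights[[nm]]), "running")
    if (length(f)) out[[nm]] <- stats::setNames(as.list(f), f)
  }
  out
}

.adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m <- state$m[[nm]][[f]]
      if (is.null(m)) m <- g * 0
      v <- state$v[[nm]][[f]]
      if (is.null(v)) v <- g * 0
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      state$m[[nm]][[f]] <- m
      state$v[[nm]][[f]] <- v
      weights[[nm]][[f]] <- weights[[nm]][[f]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(weights = weights, state = state)
}
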