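# Minimal seeded neural-network engine: 1-D convolutions, dense layers,
# ReLU/softmax/dropout/global-average-pooling, manual backprop and Adam.
# Dense ops go through BLAS (tcrossprod/crossprod); conv-stage activations
# are lists of (channels x length) matrices, one per batch element.

#' Dense (fully connected) layer
#'
#' @param n_in,n_out input and output widths.
#' @param init_scale optional standard deviation for the weight draw;
#'   defaults to He initialization `sqrt(2 / n_in)`.
#' @return A layer object for use in [nn_sequential()].
#' @keywords internal
nn_linear <- function(n_in, n_out, init_scale = NULL) {
  sd <- if (is.null(init_scale)) sqrt(2 / n_in) else init_scale
  structure(list(
    type = "linear",
    par = list(
      W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
      b = numeric(n_out)
    )
  ), class = "nn_layer")
}

#' 1-D convolution layer (kernel 3, stride 1, padding 1)
#'
#' Keeps sequence length unchanged. Weights are stored as one
#' `(out_channels x in_channels)` matrix per kernel tap.
#'
#' @param in_ch,out_ch channel counts.
#' @return A layer object.
#' @keywords internal
nn_conv1d <- function(in_ch, out_ch) {
  sd <- sqrt(2 / (in_ch * 3))
  mk <- function() matrix(stats::rnorm(in_ch * out_ch, sd = sd), out_ch, in_ch)
  structure(list(
    type = "conv1d", in_ch = in_ch, out_ch = out_ch,
    par = list(W1 = mk(), W2 = mk(), W3 = mk(), b = numeric(out_ch))
  ), class = "nn_layer")
}

nn_relu <- function() structure(list(type = "relu", par = list()), class = "nn_layer")
nn_avgpool1d <- function(k) structure(list(type = "avgpool", k = as.integer(k), par = list()), class = "nn_layer")
nn_flatten <- function() structure(list(type = "flatten", par = list()), class = "nn_layer")
nn_gap <- function() structure(list(type = "gap", par = list()), class = "nn_layer")
nn_softmax <- function() structure(list(type = "softmax", par = list()), class = "nn_layer")
nn_dropout <- function(p) structure(list(type = "dropout", p = p, par = list()), class = "nn_layer")

#' Assemble layers into a sequential network
#' @param ... layer objects, applied in order.
#' @keywords internal
nn_sequential <- function(...) structure(list(layers = list(...)), class = "nn_net")

.shiftL <- function(m) cbind(m[, -1L, drop = FALSE], 0)  # column t+1 -> t
.shiftR <- function(m) cbind(0, m[, -ncol(m), drop = FALSE])

.conv_fwd <- function(layer, x) {
  p <- layer$par
  lapply(x, function(m) {
    p$W1 %*% .shiftR(m) + p$W2 %*% m + p$W3 %*% .shiftL(m) + p$b
  })
}

.layer_forward <- function(layer, x, train) {
  switch(layer$type,
    linear = list(out = sweep(x %*% layer$par$W, 2, layer$par$b, "+"),
                  cache = list(x = x)),
    conv1d = list(out = .conv_fwd(layer, x), cache = list(x = x)),
    relu = {
      out <- if (is.list(x)) lapply(x, function(m) m * (m > 0)) else x * (x > 0)
      list(out = out, cache = list(x = x))
    },
    avgpool = {
      k <- layer$k
      pool1 <- function(m) {
        L2 <- k * (ncol(m) %/% k)
        out <- 0
        for (j in seq_len(k)) out <- out + m[, seq(j, L2, by = k), drop = FALSE]
        out / k
      }
      list(out = lapply(x, pool1), cache = list(dims = dim(x[[1L]])))
    },
    flatten = {
      out <- do.call(rbind, lapply(x, as.vector))
      list(out = out, cache = list(dims = dim(x[[1L]])))
    },
    gap = {
      out <- do.call(rbind, lapply(x, rowMeans))
      list(out = out, cache = list(dims = dim(x[[1L]])))
    },
    softmax = {
      z <- x - apply(x, 1L, max)
      e <- exp(z)
      out <- e / rowSums(e)
      list(out = out, cache = list(y = out))
    },
    dropout = {
      if (train && layer$p > 0) {
        keep <- matrix(stats::runif(length(x)) >= layer$p, nrow(x), ncol(x))
        scale <- 1 / (1 - layer$p)
        list(out = x * keep * scale, cache = list(mask = keep, scale = scale))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

.layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    linear = {
      x <- cache$x
      list(dx = tcrossprod(dout, layer$par$W),
           grads = list(W = crossprod(x, dout), b = colSums(dout)))
    },
    conv1d = {
      p <- layer$par
      x <- cache$x
      dW1 <- dW2 <- dW3 <- matrix(0, layer$out_ch, layer$in_ch)
      db <- numeric(layer$out_ch)
      dx <- vector("list", length(x))
      for (i in seq_along(x)) {
        g <- dout[[i]]
        xi <- x[[i]]
        dW1 <- dW1 + tcrossprod(g, .shiftR(xi))
        dW2 <- dW2 + tcrossprod(g, xi)
        dW3 <- dW3 + tcrossprod(g, .shiftL(xi))
        db <- db + rowSums(g)
        dx[[i]] <- .shiftL(crossprod(p$W1, g)) + crossprod(p$W2, g) +
          .shiftR(crossprod(p$W3, g))
      }
      list(dx = dx, grads = list(W1 = dW1, W2 = dW2, W3 = dW3, b = db))
    },
    relu = {
      x <- cache$x
      dx <- if (is.list(x)) {
        Map(function(m, g) g * (m > 0), x, dout)
      } else dout * (x > 0)
      list(dx = dx, grads = list())
    },
    avgpool = {
      k <- layer$k
      d <- cache$dims
      unpool1 <- function(g) {
        m <- matrix(0, d[1L], d[2L])
        L2 <- k * (d[2L] %/% k)
        for (j in seq_len(k)) m[, seq(j, L2, by = k)] <- m[, seq(j, L2, by = k)] + g / k
        m
      }
      list(dx = lapply(dout, unpool1), grads = list())
    },
    flatten = {
      d <- cache$dims
      dx <- lapply(seq_len(nrow(dout)), function(i) matrix(dout[i, ], d[1L], d[2L]))
      list(dx = dx, grads = list())
    },
    gap = {
      d <- cache$dims
      dx <- lapply(seq_len(nrow(dout)), function(i) {
        matrix(rep(dout[i, ] / d[2L], d[2L]), d[1L], d[2L])
      })
      list(dx = dx, grads = list())
    },
    softmax = {
      y <- cache$y
      list(dx = (dout - rowSums(dout * y)) * y, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask * cache$scale, grads = list())
    }
  )
}

#' Forward pass through a sequential network
#' @param net a network from [nn_sequential()].
#' @param x input (batch matrix, or list of channel-by-length matrices).
#' @param train logical; enables dropout masks.
#' @return list with `out` and per-layer `caches`.
#' @keywords internal
nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    step <- .layer_forward(net$layers[[i]], x, train)
    caches[[i]] <- step$cache
    x <- step$out
  }
  list(out = x, caches = caches)
}

#' Backward pass; returns gradient wrt input and per-layer parameter grads
#' @keywords internal
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    step <- .layer_backward(net$layers[[i]], caches[[i]], dout)
    grads[[i]] <- step$grads
    dout <- step$dx
  }
  list(dinput = dout, grads = grads)
}

#' Flatten network parameters into a single named list
#' @keywords internal
nn_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$par)) {
      out[[paste0("L", i, ".", nm)]] <- net$layers[[i]]$par[[nm]]
    }
  }
  out
}

nn_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$par)) {
      net$layers[[i]]$par[[nm]] <- params[[paste0("L", i, ".", nm)]]
    }
  }
  net
}

nn_grads_flat <- function(net, grads) {
  out <- list()
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$par)) {
      out[[paste0("L", i, ".", nm)]] <- grads[[i]][[nm]]
    }
  }
  out
}

#' Count of free parameters in a network
#' @keywords internal
nn_n_params <- function(net) {
  sum(vapply(nn_params(net), length, integer(1)))
}

# ---- Adam -------------------------------------------------------------

#' Initialise Adam state for a flat parameter list
#' @keywords internal
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update; returns updated params and state
#'
#' @param params,grads flat lists with matching names.
#' @param state from [adam_init()].
#' @param lr learning rate for this step.
#' @keywords internal
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Learning rate under the step schedule
#'
#' Initial rate multiplied by `factor` every `step` epochs (epoch 76 is the
#' first reduced epoch for the default step of 75).
#'
#' @param epoch 1-based epoch index.
#' @param lr0 initial learning rate.
#' @param step epochs per decay period.
#' @param factor multiplicative decay.
#' @return learning rate in effect at `epoch`.
#' @export
#' @examples
#' lr_at_epoch(75)  # 0.001
#' lr_at_epoch(76)  # 1e-4
lr_at_epoch <- function(epoch, lr0 = 0.001, step = 75L, factor = 0.1) {
  lr0 * factor^(floor((epoch - 1) / step))
}
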