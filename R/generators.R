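# Conditional decoder-style CNN generators, one per modality. Each maps the
# scalar normalized HTL temperature (as a 1-channel, length-1 sequence) to a
# full modality vector: resampled thermogram (mass fraction scale),
# preprocessed FT-IR vector, or 10-group composition via a softmax head.

#' Architecture specification for one generation model
#'
#' Defaults fix the layer stacks: TGA uses two conv+ReLU blocks (16, 32
#' channels) and a 1024-wide dense head; FT-IR adds a third conv block (64
#' channels) and dropout 0.3 after the hidden dense layer; GC-MS uses three
#' 64-channel conv blocks, global average pooling and a 128-wide head ending
#' in a softmax over the 10 composition groups.
#'
#' @param modality one of `"TGA"`, `"FTIR"`, `"GCMS"`.
#' @param output_dim length of the generated vector; defaults to 721
#'   (TGA grid), 3476 (FT-IR grid) or 10 (composition groups).
#' @param input_length length of the conditioning sequence (1: the scalar
#'   normalized temperature).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(modality = c("TGA", "FTIR", "GCMS"),
                           output_dim = NULL, input_length = 1L) {
  modality <- match.arg(modality)
  defaults <- list(
    TGA = list(conv_channels = c(16L, 32L), hidden = 1024L, dropout = 0,
               gap = FALSE, softmax = FALSE, out = 721L),
    FTIR = list(conv_channels = c(16L, 32L, 64L), hidden = 1024L, dropout = 0.3,
                gap = FALSE, softmax = FALSE, out = 3476L),
    GCMS = list(conv_channels = c(64L, 64L, 64L), hidden = 128L, dropout = 0,
                gap = TRUE, softmax = TRUE, out = 10L)
  )[[modality]]
  structure(list(modality = modality,
                 conv_channels = defaults$conv_channels,
                 kernel_size = 3L, stride = 1L, padding = 1L,
                 hidden = defaults$hidden, dropout = defaults$dropout,
                 gap = defaults$gap, softmax = defaults$softmax,
                 output_dim = if (is.null(output_dim)) defaults$out else as.integer(output_dim),
                 input_length = as.integer(input_length), input_channels = 1L),
            class = "generator_spec")
}

#' Build an untrained generator from a spec
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for the weight initialization.
#' @return A `lc_generator` handle (network, spec, training state).
#' @export
build_generator <- function(spec, seed = 1L) {
  if (!inherits(spec, "generator_spec")) stop("argument error: not a generator_spec")
  with_seed(seed, {
    layers <- list()
    in_ch <- spec$input_channels
    for (ch in spec$conv_channels) {
      layers <- c(layers, list(nn_conv1d(in_ch, ch), nn_relu()))
      in_ch <- ch
    }
    if (spec$gap) {
      layers <- c(layers, list(nn_gap(), nn_linear(in_ch, spec$hidden), nn_relu(),
                               nn_linear(spec$hidden, spec$output_dim), nn_softmax()))
    } else {
      flat <- in_ch * spec$input_length
      layers <- c(layers, list(nn_flatten(), nn_linear(flat, spec$hidden), nn_relu()))
      if (spec$dropout > 0) layers <- c(layers, list(nn_dropout(spec$dropout)))
      layers <- c(layers, list(nn_linear(spec$hidden, spec$output_dim)))
    }
    structure(list(net = do.call(nn_sequential, layers), spec = spec,
                   trained = FALSE, loss_history = numeric()),
              class = "lc_generator")
  })
}

#' Layer/shape trace of a generator
#'
#' One row per layer with its type and output shape, for architecture
#' conformance checks.
#' @param model an `lc_generator`.
#' @return data.frame with columns `layer`, `shape`.
#' @export
generator_trace <- function(model) {
  spec <- model$spec
  L <- spec$input_length
  rows <- list()
  add <- function(layer, shape) rows[[length(rows) + 1L]] <<- data.frame(layer = layer, shape = shape)
  in_ch <- spec$input_channels
  for (ch in spec$conv_channels) {
    add(sprintf("Conv1D(%d, %d, kernel=3, stride=1, padding=1) + ReLU", in_ch, ch),
        sprintf("(%d, %d)", ch, L))
    in_ch <- ch
  }
  if (spec$gap) {
    add("GlobalAveragePooling", sprintf("(%d)", in_ch))
    add(sprintf("Linear(%d, %d) + ReLU", in_ch, spec$hidden), sprintf("(%d)", spec$hidden))
    add(sprintf("Linear(%d, %d) + Softmax", spec$hidden, spec$output_dim),
        sprintf("(%d)", spec$output_dim))
  } else {
    add("Flatten", sprintf("(%d)", in_ch * L))
    add(sprintf("Linear(%d, %d) + ReLU", in_ch * L, spec$hidden), sprintf("(%d)", spec$hidden))
    if (spec$dropout > 0) add(sprintf("Dropout(%.1f)", spec$dropout), sprintf("(%d)", spec$hidden))
    add(sprintf("Linear(%d, %d)", spec$hidden, spec$output_dim), sprintf("(%d)", spec$output_dim))
  }
  do.call(rbind, rows)
}

#' Conditioning vector for a generator
#'
#' The scalar normalized HTL temperature tiled to the input length, as one
#' input channel.
#'
#' @param htl_temperature_c HTL condition in degrees C.
#' @param input_length conditioning sequence length.
#' @return A `1 x input_length` matrix.
#' @export
encode_condition <- function(htl_temperature_c, input_length = 1L) {
  .check_htl_domain(htl_temperature_c)
  matrix(htl_tau(htl_temperature_c), 1L, input_length)
}

#' Training configuration (Adam with a step learning-rate schedule)
#'
#' @param learning_rate initial Adam learning rate.
#' @param lr_step_epoch epochs per decay period of the step schedule.
#' @param lr_factor multiplicative decay applied each period.
#' @param batch_size minibatch size (saturated to the dataset when larger).
#' @param epochs number of training epochs.
#' @param seed integer seed controlling initial shuffling, dropout and any
#'   sampling during training.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, lr_step_epoch = 75L,
                         lr_factor = 0.1, batch_size = 32L, epochs = 100L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, lr_step_epoch > 0, lr_factor > 0, lr_factor <= 1,
            batch_size > 0, epochs > 0)
  structure(list(learning_rate = learning_rate,
                 lr_step_epoch = as.integer(lr_step_epoch),
                 lr_factor = lr_factor, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Train a generator on (condition, target) pairs
#'
#' Minimizes the mean squared error between generated and target vectors
#' with Adam under the step learning-rate schedule. Fully reproducible
#' under a fixed `cfg$seed`.
#'
#' @param model an `lc_generator` from [build_generator()].
#' @param pairs list of `list(condition = , target = )`, with `condition`
#'   in degrees C and `target` a vector of length `spec$output_dim` on the
#'   training scale (mass fraction for TGA, log-absorbance values for
#'   FT-IR, simplex fractions for GC-MS).
#' @param cfg a [train_config()].
#' @return The trained model, with `$loss_history` (one MSE per epoch).
#' @export
train_generator <- function(model, pairs, cfg = train_config()) {
  if (length(pairs) < 2) stop("argument error: need at least 2 training pairs")
  d <- model$spec$output_dim
  targets <- do.call(rbind, lapply(pairs, function(p) {
    if (length(p$target) != d) {
      stop("shape error: target length ", length(p$target), ", expected ", d)
    }
    as.numeric(p$target)
  }))
  inputs <- lapply(pairs, function(p) encode_condition(p$condition, model$spec$input_length))
  n <- length(pairs)
  net <- model$net
  params <- nn_params(net)
  state <- adam_init(params)
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(epoch, cfg$learning_rate, cfg$lr_step_epoch, cfg$lr_factor)
      order_idx <- sample.int(n)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        fwd <- nn_forward(net, inputs[idx], train = TRUE)
        yhat <- fwd$out
        y <- targets[idx, , drop = FALSE]
        resid <- yhat - y
        loss <- mean(resid^2)
        epoch_loss <- epoch_loss + loss * length(idx)
        dout <- 2 * resid / length(resid)
        bwd <- nn_backward(net, fwd$caches, dout)
        step <- adam_step(params, nn_grads_flat(net, bwd$grads), state, lr)
        params <- step$params
        state <- step$state
        net <- nn_set_params(net, params)
      }
      history[epoch] <- epoch_loss / n
    }
  })
  model$net <- net
  model$trained <- TRUE
  model$loss_history <- history
  model
}

#' Generate a modality vector at an HTL temperature
#'
#' Deterministic given the trained weights (dropout inactive at inference).
#'
#' @param model a trained `lc_generator`.
#' @param htl_temperature_c HTL condition in degrees C.
#' @return Numeric vector of length `spec$output_dim`; on the 10-simplex
#'   for the GC-MS modality.
#' @export
generate_at_temperature <- function(model, htl_temperature_c) {
  if (!inherits(model, "lc_generator") || !isTRUE(model$trained)) {
    stop("state error: generator has not been trained", call. = FALSE)
  }
  x <- list(encode_condition(htl_temperature_c, model$spec$input_length))
  as.numeric(nn_forward(model$net, x, train = FALSE)$out)
}

#' Assemble generated sample triplets at requested temperatures
#'
#' @param models list with trained `tga`, `ftir` and `gcms` generators.
#' @param temps HTL temperatures to generate at; defaults to the six
#'   interpolation conditions 260/280/315/345/365/390 degrees C.
#' @return List of [sample_triplet()] objects, one per temperature.
#' @export
augment_dataset <- function(models, temps = c(260, 280, 315, 345, 365, 390)) {
  for (m in c("tga", "ftir", "gcms")) {
    if (is.null(models[[m]]) || !isTRUE(models[[m]]$trained)) {
      stop("state error: trained '", m, "' generator missing", call. = FALSE)
    }
  }
  lapply(temps, function(t_c) {
    tga_v <- generate_at_temperature(models$tga, t_c) * 100  # mass fraction -> %
    ftir_v <- generate_at_temperature(models$ftir, t_c)
    gcms_v <- generate_at_temperature(models$gcms, t_c)
    sample_triplet(
      t_c,
      tga = thermogram_resampled(tga_v, htl_temperature_c = t_c),
      ftir = ir_preprocessed(ftir_v, t_c),
      gcms = composition_vector(gcms_v, t_c)
    )
  })
}
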