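# Multimodal VAE with a mixture-of-experts head. Separate conv encoders map
# the TGA and FT-IR vectors to diagonal-Gaussian posteriors; the posteriors
# are fused by a product of experts (with a standard-normal prior expert);
# a reparameterized latent sample drives two reconstruction decoders and a
# gated mixture of simplex-valued experts that predicts the GC-MS
# composition. Training minimizes the unweighted sum of the two
# reconstruction MSEs, the prediction MSE and the KL divergence to N(0, I).

#' Diagonal-Gaussian latent posterior
#'
#' @param mu,logvar equal-length numeric vectors (or matrices with one row
#'   per batch element): mean and log variance per latent dimension.
#' @return A `gaussian_latent` object.
#' @export
gaussian_latent <- function(mu, logvar) {
  if (length(mu) != length(logvar)) stop("shape error: mu/logvar length mismatch")
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("gaussian_latent: non-finite parameters")
  }
  structure(list(mu = mu, logvar = logvar), class = "gaussian_latent")
}

#' MVAE-MoE configuration
#'
#' @param tga_dim,ftir_dim,gcms_dim modality vector lengths.
#' @param latent_dim shared latent dimensionality.
#' @param encoder_conv_channels channels of the two encoder conv blocks.
#' @param encoder_hidden width of the dense layer feeding the (mu, logvar)
#'   heads.
#' @param n_experts number of mixture experts.
#' @param expert_hidden,gating_hidden hidden widths of expert and gating
#'   networks.
#' @param seed seed for weight initialization.
#' @return An `mvae_moe_config` object.
#' @export
mvae_moe_config <- function(tga_dim = 721L, ftir_dim = 3476L, gcms_dim = 10L,
                            latent_dim = 16L, encoder_conv_channels = c(16L, 32L),
                            encoder_hidden = 256L, n_experts = 4L,
                            expert_hidden = 64L, gating_hidden = 32L, seed = 1L) {
  stopifnot(tga_dim > 0, ftir_dim > 0, gcms_dim > 0, latent_dim > 0,
            n_experts >= 1, expert_hidden > 0, gating_hidden > 0)
  structure(list(tga_dim = as.integer(tga_dim), ftir_dim = as.integer(ftir_dim),
                 gcms_dim = as.integer(gcms_dim), latent_dim = as.integer(latent_dim),
                 encoder_conv_channels = as.integer(encoder_conv_channels),
                 encoder_hidden = as.integer(encoder_hidden),
                 n_experts = as.integer(n_experts),
                 expert_hidden = as.integer(expert_hidden),
                 gating_hidden = as.integer(gating_hidden),
                 seed = as.integer(seed)),
            class = "mvae_moe_config")
}

# Conv blocks with average pooling (factor 4) keep the flattened feature
# width, and with it the dense-layer parameter count, manageable for the
# long FT-IR vectors; the (mu, logvar) heads start with an informative mean
# (He-scaled) and near-unit variance so the fused posterior carries input
# signal from the first epoch.
.build_encoder <- function(input_dim, cfg) {
  layers <- list()
  in_ch <- 1L
  len <- input_dim
  for (ch in cfg$encoder_conv_channels) {
    layers <- c(layers, list(nn_conv1d(in_ch, ch), nn_relu(), nn_avgpool1d(4L)))
    in_ch <- ch
    len <- len %/% 4L
  }
  layers <- c(layers, list(nn_flatten(),
                           nn_linear(in_ch * len, cfg$encoder_hidden),
                           nn_relu()))
  list(trunk = do.call(nn_sequential, layers),
       mu = nn_sequential(nn_linear(cfg$encoder_hidden, cfg$latent_dim)),
       lv = nn_sequential(nn_linear(cfg$encoder_hidden, cfg$latent_dim,
                                    init_scale = 0.01)))
}

#' Build an untrained MVAE-MoE model
#'
#' @param cfg an [mvae_moe_config()].
#' @return An `lc_mvae` handle.
#' @export
build_mvae_moe <- function(cfg = mvae_moe_config()) {
  with_seed(cfg$seed, {
    model <- list(
      cfg = cfg,
      enc_tga = .build_encoder(cfg$tga_dim, cfg),
      enc_ftir = .build_encoder(cfg$ftir_dim, cfg),
      dec_tga = nn_sequential(nn_linear(cfg$latent_dim, 1024L), nn_relu(),
                              nn_linear(1024L, cfg$tga_dim)),
      dec_ftir = nn_sequential(nn_linear(cfg$latent_dim, 1024L), nn_relu(),
                               nn_dropout(0.3),
                               nn_linear(1024L, cfg$ftir_dim)),
      experts = lapply(seq_len(cfg$n_experts), function(i) {
        nn_sequential(nn_linear(cfg$latent_dim, cfg$expert_hidden), nn_relu(),
                      nn_linear(cfg$expert_hidden, cfg$gcms_dim), nn_softmax())
      }),
      gating = nn_sequential(nn_linear(cfg$latent_dim, cfg$gating_hidden), nn_relu(),
                             nn_linear(cfg$gating_hidden, cfg$n_experts), nn_softmax()),
      # per-modality standardization fitted from the training set; identity
      # until train_predictor() fills it in
      center = list(tga = 0, ftir = 0), scale = list(tga = 1, ftir = 1),
      trained = FALSE, loss_history = NULL
    )
    class(model) <- "lc_mvae"
    model
  })
}

.mvae_nets <- function(model) {
  nets <- list(
    enc_tga_trunk = model$enc_tga$trunk, enc_tga_mu = model$enc_tga$mu,
    enc_tga_lv = model$enc_tga$lv,
    enc_ftir_trunk = model$enc_ftir$trunk, enc_ftir_mu = model$enc_ftir$mu,
    enc_ftir_lv = model$enc_ftir$lv,
    dec_tga = model$dec_tga, dec_ftir = model$dec_ftir,
    gating = model$gating
  )
  for (e in seq_along(model$experts)) {
    nets[[paste0("expert", e)]] <- model$experts[[e]]
  }
  nets
}

.mvae_set_nets <- function(model, nets) {
  model$enc_tga$trunk <- nets$enc_tga_trunk
  model$enc_tga$mu <- nets$enc_tga_mu
  model$enc_tga$lv <- nets$enc_tga_lv
  model$enc_ftir$trunk <- nets$enc_ftir_trunk
  model$enc_ftir$mu <- nets$enc_ftir_mu
  model$enc_ftir$lv <- nets$enc_ftir_lv
  model$dec_tga <- nets$dec_tga
  model$dec_ftir <- nets$dec_ftir
  model$gating <- nets$gating
  for (e in seq_along(model$experts)) {
    model$experts[[e]] <- nets[[paste0("expert", e)]]
  }
  model
}

.mvae_params <- function(model) {
  nets <- .mvae_nets(model)
  out <- list()
  for (nm in names(nets)) {
    p <- nn_params(nets[[nm]])
    names(p) <- paste0(nm, "::", names(p))
    out <- c(out, p)
  }
  out
}

.mvae_set_params <- function(model, params) {
  nets <- .mvae_nets(model)
  for (nm in names(nets)) {
    pref <- paste0(nm, "::")
    sub <- params[startsWith(names(params), pref)]
    names(sub) <- substring(names(sub), nchar(pref) + 1L)
    nets[[nm]] <- nn_set_params(nets[[nm]], sub)
  }
  .mvae_set_nets(model, nets)
}

# Batch helpers: modality matrices (n x dim), standardized by the model's
# per-element center/scale so between-condition contrast carries the signal.
.standardize <- function(x, model, which) {
  ctr <- model$center[[which]]
  scl <- model$scale[[which]]
  if (length(ctr) == 1 && length(scl) == 1) return((x - ctr) / scl)
  sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
}

.triplets_to_batch <- function(triplets, model) {
  tga <- do.call(rbind, lapply(triplets, function(t) t$tga$mass_pct / 100))
  ftir <- do.call(rbind, lapply(triplets, function(t) t$ftir$values))
  list(
    tga = .standardize(tga, model, "tga"),
    ftir = .standardize(ftir, model, "ftir"),
    gcms = do.call(rbind, lapply(triplets, function(t) t$gcms$fractions))
  )
}

# Per-element center and floored scale from the training matrices.
.fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  top <- max(sds)
  scl <- if (top == 0) rep(1, ncol(x)) else pmax(sds, 0.05 * top)
  list(center = ctr, scale = scl)
}

.as_conv_batch <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i) matrix(mat[i, ], 1L))
}

#' Encode one modality vector to its Gaussian posterior
#'
#' The input is standardized by the per-element center/scale fitted during
#' training before entering the encoder.
#'
#' @param x modality vector on the training scale (mass fraction for TGA,
#'   log-absorbance values for FT-IR).
#' @param modality `"TGA"` or `"FTIR"`.
#' @param model an `lc_mvae`.
#' @return A [gaussian_latent()].
#' @export
encode_modality <- function(x, modality = c("TGA", "FTIR"), model) {
  modality <- match.arg(modality)
  enc <- if (modality == "TGA") model$enc_tga else model$enc_ftir
  want <- if (modality == "TGA") model$cfg$tga_dim else model$cfg$ftir_dim
  if (length(x) != want) {
    stop("shape error: ", modality, " input length ", length(x),
         ", expected ", want, call. = FALSE)
  }
  xs <- .standardize(matrix(as.numeric(x), 1L), model, tolower(modality))
  h <- nn_forward(enc$trunk, list(xs))$out
  gaussian_latent(as.numeric(nn_forward(enc$mu, h)$out),
                  as.numeric(nn_forward(enc$lv, h)$out))
}

#' Fuse Gaussian posteriors by a product of experts
#'
#' Includes a standard-normal prior expert: the fused precision is
#' `1 + sum(1 / sigma_i^2)` and the fused mean is the precision-weighted
#' average of the expert means.
#'
#' @param posteriors non-empty list of [gaussian_latent()] with equal
#'   latent dimension (vectors or conforming matrices).
#' @return The fused [gaussian_latent()].
#' @export
fuse_experts <- function(posteriors) {
  if (length(posteriors) == 0) stop("argument error: no posteriors to fuse")
  prec <- 1  # the N(0, I) prior expert
  wmu <- 0
  for (g in posteriors) {
    e <- exp(-g$logvar)
    prec <- prec + e
    wmu <- wmu + g$mu * e
  }
  gaussian_latent(wmu / prec, -log(prec))
}

#' Reparameterized latent sample
#'
#' @param g a [gaussian_latent()].
#' @param noise standard-normal draw of matching shape (0 gives the mean).
#' @return `mu + exp(logvar / 2) * noise`.
#' @export
reparameterize <- function(g, noise) {
  if (length(noise) == 1) noise <- noise + 0 * g$mu
  if (length(noise) != length(g$mu)) stop("shape error: noise length mismatch")
  g$mu + exp(g$logvar / 2) * noise
}

#' Decode a latent vector back to a modality vector
#'
#' @param z latent vector (length `latent_dim`).
#' @param modality `"TGA"` or `"FTIR"`.
#' @param model an `lc_mvae`.
#' @return Reconstructed modality vector on the training scale.
#' @export
decode_modality <- function(z, modality = c("TGA", "FTIR"), model) {
  modality <- match.arg(modality)
  if (length(z) != model$cfg$latent_dim) stop("shape error: bad latent length")
  dec <- if (modality == "TGA") model$dec_tga else model$dec_ftir
  out <- as.numeric(nn_forward(dec, matrix(z, 1L), train = FALSE)$out)
  key <- tolower(modality)
  out * model$scale[[key]] + model$center[[key]]  # back to the input scale
}

# Internal batched MoE head: returns prediction matrix, gate matrix and the
# per-expert outputs plus forward caches for backprop.
.moe_forward <- function(model, z_mat, train = FALSE) {
  gate_fwd <- nn_forward(model$gating, z_mat, train = train)
  gate <- gate_fwd$out
  expert_fwd <- lapply(model$experts, function(e) nn_forward(e, z_mat, train = train))
  pred <- 0
  for (e in seq_along(expert_fwd)) {
    pred <- pred + gate[, e] * expert_fwd[[e]]$out
  }
  list(pred = pred, gate = gate, gate_fwd = gate_fwd, expert_fwd = expert_fwd)
}

#' Predict a composition from a latent vector
#'
#' Experts each emit a simplex point; the gating network mixes them
#' convexly, so the output is always on the 10-simplex.
#'
#' @param z latent vector of length `latent_dim`.
#' @param model an `lc_mvae`.
#' @return List with `composition` (named fractions) and `expert_weights`.
#' @export
predict_composition <- function(z, model) {
  if (length(z) != model$cfg$latent_dim) stop("shape error: bad latent length")
  mo <- .moe_forward(model, matrix(z, 1L))
  comp <- as.numeric(mo$pred)
  names(comp) <- gcms_groups()[seq_len(model$cfg$gcms_dim)]
  list(composition = comp, expert_weights = as.numeric(mo$gate))
}

#' Per-term KL divergence to the standard normal
#' @keywords internal
.kl_terms <- function(mu, logvar) -0.5 * (1 + logvar - mu^2 - exp(logvar))

# Full forward pass on a batch; returns everything backprop needs.
.mvae_forward <- function(model, batch, eps, train = FALSE) {
  n <- nrow(batch$tga)
  tga_trunk <- nn_forward(model$enc_tga$trunk, .as_conv_batch(batch$tga), train)
  ftir_trunk <- nn_forward(model$enc_ftir$trunk, .as_conv_batch(batch$ftir), train)
  tga_mu <- nn_forward(model$enc_tga$mu, tga_trunk$out)
  tga_lv <- nn_forward(model$enc_tga$lv, tga_trunk$out)
  ftir_mu <- nn_forward(model$enc_ftir$mu, ftir_trunk$out)
  ftir_lv <- nn_forward(model$enc_ftir$lv, ftir_trunk$out)

  e_tga <- exp(-tga_lv$out)
  e_ftir <- exp(-ftir_lv$out)
  prec <- 1 + e_tga + e_ftir
  mu_f <- (tga_mu$out * e_tga + ftir_mu$out * e_ftir) / prec
  lv_f <- -log(prec)
  z <- mu_f + exp(lv_f / 2) * eps

  rec_tga <- nn_forward(model$dec_tga, z, train)
  rec_ftir <- nn_forward(model$dec_ftir, z, train)
  moe <- .moe_forward(model, z, train)

  # per-sample squared error summed over vector elements, averaged over the
  # batch -- same reduction convention as the KL term
  recon_tga <- sum((rec_tga$out - batch$tga)^2) / n
  recon_ftir <- sum((rec_ftir$out - batch$ftir)^2) / n
  pred <- sum((moe$pred - batch$gcms)^2) / n
  kl <- sum(.kl_terms(mu_f, lv_f)) / n

  list(n = n, eps = eps,
       tga_trunk = tga_trunk, ftir_trunk = ftir_trunk,
       tga_mu = tga_mu, tga_lv = tga_lv, ftir_mu = ftir_mu, ftir_lv = ftir_lv,
       e_tga = e_tga, e_ftir = e_ftir, prec = prec, mu_f = mu_f, lv_f = lv_f,
       z = z, rec_tga = rec_tga, rec_ftir = rec_ftir, moe = moe,
       losses = loss_breakdown(recon_tga, recon_ftir, pred, kl))
}

# Backward pass; returns flat gradients keyed like .mvae_params().
.mvae_backward <- function(model, fw, batch) {
  n <- fw$n
  grads <- list()
  put <- function(nm, g) {
    names(g) <- paste0(nm, "::", names(g))
    grads <<- c(grads, g)
  }

  d_rec_tga <- 2 * (fw$rec_tga$out - batch$tga) / n
  bw_dec_tga <- nn_backward(model$dec_tga, fw$rec_tga$caches, d_rec_tga)
  put("dec_tga", nn_grads_flat(model$dec_tga, bw_dec_tga$grads))

  d_rec_ftir <- 2 * (fw$rec_ftir$out - batch$ftir) / n
  bw_dec_ftir <- nn_backward(model$dec_ftir, fw$rec_ftir$caches, d_rec_ftir)
  put("dec_ftir", nn_grads_flat(model$dec_ftir, bw_dec_ftir$grads))

  d_pred <- 2 * (fw$moe$pred - batch$gcms) / n
  dz <- bw_dec_tga$dinput + bw_dec_ftir$dinput
  d_gate <- matrix(0, n, model$cfg$n_experts)
  for (e in seq_along(model$experts)) {
    pe <- fw$moe$expert_fwd[[e]]$out
    bw_e <- nn_backward(model$experts[[e]], fw$moe$expert_fwd[[e]]$caches,
                        d_pred * fw$moe$gate[, e])
    put(paste0("expert", e), nn_grads_flat(model$experts[[e]], bw_e$grads))
    dz <- dz + bw_e$dinput
    d_gate[, e] <- rowSums(d_pred * pe)
  }
  bw_gate <- nn_backward(model$gating, fw$moe$gate_fwd$caches, d_gate)
  put("gating", nn_grads_flat(model$gating, bw_gate$grads))
  dz <- dz + bw_gate$dinput

  # z = mu_f + exp(lv_f / 2) * eps, plus KL on the fused posterior
  d_mu_f <- dz + fw$mu_f / n
  d_lv_f <- dz * fw$eps * 0.5 * exp(fw$lv_f / 2) - 0.5 * (1 - exp(fw$lv_f)) / n

  # product-of-experts fusion backward
  poe_back <- function(mu_i, e_i) {
    d_mu_i <- d_mu_f * e_i / fw$prec
    d_lv_i <- d_mu_f * (-e_i * (mu_i - fw$mu_f) / fw$prec) + d_lv_f * e_i / fw$prec
    list(mu = d_mu_i, lv = d_lv_i)
  }
  g_tga <- poe_back(fw$tga_mu$out, fw$e_tga)
  g_ftir <- poe_back(fw$ftir_mu$out, fw$e_ftir)

  for (side in c("tga", "ftir")) {
    enc <- if (side == "tga") model$enc_tga else model$enc_ftir
    fw_tr <- fw[[paste0(side, "_trunk")]]
    fw_mu <- fw[[paste0(side, "_mu")]]
    fw_lv <- fw[[paste0(side, "_lv")]]
    g <- if (side == "tga") g_tga else g_ftir
    bw_mu <- nn_backward(enc$mu, fw_mu$caches, g$mu)
    bw_lv <- nn_backward(enc$lv, fw_lv$caches, g$lv)
    put(paste0("enc_", side, "_mu"), nn_grads_flat(enc$mu, bw_mu$grads))
    put(paste0("enc_", side, "_lv"), nn_grads_flat(enc$lv, bw_lv$grads))
    bw_tr <- nn_backward(enc$trunk, fw_tr$caches, bw_mu$dinput + bw_lv$dinput)
    put(paste0("enc_", side, "_trunk"), nn_grads_flat(enc$trunk, bw_tr$grads))
  }
  grads
}

#' Loss breakdown of the composite objective
#'
#' @param recon_tga,recon_ftir reconstruction MSEs.
#' @param pred prediction MSE.
#' @param kl KL divergence to the standard normal.
#' @return A `loss_breakdown` with `total` the exact unweighted sum.
#' @export
loss_breakdown <- function(recon_tga, recon_ftir, pred, kl) {
  structure(list(recon_tga = recon_tga, recon_ftir = recon_ftir,
                 pred = pred, kl = kl,
                 total = recon_tga + recon_ftir + pred + kl),
            class = "loss_breakdown")
}

#' Compute the composite loss on a batch of triplets
#'
#' Reconstruction and prediction terms are per-sample squared errors summed
#' over vector elements and averaged over the batch; the KL term is summed
#' over latent dimensions and averaged over the batch, on the fused
#' posterior.
#'
#' @param batch list of [sample_triplet()].
#' @param model an `lc_mvae`.
#' @param noise `"zero"` for deterministic evaluation at the posterior
#'   mean, `"sample"` for a reparameterized draw, or a numeric matrix
#'   (batch x latent) of noise values.
#' @return A [loss_breakdown()].
#' @export
compute_losses <- function(batch, model, noise = "zero") {
  if (length(batch) == 0) stop("argument error: empty batch")
  for (t in batch) stop_on_violations(validate_triplet(t), "sample_triplet")
  b <- .triplets_to_batch(batch, model)
  n <- length(batch)
  eps <- if (is.matrix(noise)) noise
  else if (identical(noise, "sample")) matrix(stats::rnorm(n * model$cfg$latent_dim),
                                              n, model$cfg$latent_dim)
  else matrix(0, n, model$cfg$latent_dim)
  .mvae_forward(model, b, eps, train = FALSE)$losses
}

#' Train the MVAE-MoE predictor
#'
#' Joint Adam optimization of encoders, decoders, experts and gating under
#' the step learning-rate schedule, with reparameterized sampling during
#' training. Fully reproducible under fixed seeds.
#'
#' @param data list of at least two [sample_triplet()] objects.
#' @param cfg a [train_config()].
#' @param mcfg an [mvae_moe_config()] (its seed controls initialization).
#' @return Trained `lc_mvae` with `$loss_history`, a data.frame of one
#'   [loss_breakdown()] per epoch.
#' @export
train_predictor <- function(data, cfg = train_config(), mcfg = mvae_moe_config()) {
  if (length(data) < 2) stop("argument error: need at least 2 training triplets")
  for (t in data) stop_on_violations(validate_triplet(t), "sample_triplet")
  model <- build_mvae_moe(mcfg)
  # fit the per-modality standardizers on the training set
  tga_raw <- do.call(rbind, lapply(data, function(t) t$tga$mass_pct / 100))
  ftir_raw <- do.call(rbind, lapply(data, function(t) t$ftir$values))
  st_tga <- .fit_standardizer(tga_raw)
  st_ftir <- .fit_standardizer(ftir_raw)
  model$center <- list(tga = st_tga$center, ftir = st_ftir$center)
  model$scale <- list(tga = st_tga$scale, ftir = st_ftir$scale)
  # base-rate initialization: every expert starts at the mean training
  # composition, so the mixture opens at the best constant prediction
  mean_comp <- colMeans(do.call(rbind, lapply(data, function(t) t$gcms$fractions)))
  base_logit <- log(pmax(mean_comp, 1e-4))
  for (e in seq_along(model$experts)) {
    k <- length(model$experts[[e]]$layers) - 1L  # final linear before softmax
    model$experts[[e]]$layers[[k]]$par$b <- base_logit - mean(base_logit)
  }
  full <- .triplets_to_batch(data, model)
  n <- length(data)
  params <- .mvae_params(model)
  state <- adam_init(params)
  history <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(epoch, cfg$learning_rate, cfg$lr_step_epoch, cfg$lr_factor)
      order_idx <- sample.int(n)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
      acc <- c(recon_tga = 0, recon_ftir = 0, pred = 0, kl = 0)
      for (idx in batches) {
        b <- list(tga = full$tga[idx, , drop = FALSE],
                  ftir = full$ftir[idx, , drop = FALSE],
                  gcms = full$gcms[idx, , drop = FALSE])
        eps <- matrix(stats::rnorm(length(idx) * mcfg$latent_dim),
                      length(idx), mcfg$latent_dim)
        fw <- .mvae_forward(model, b, eps, train = TRUE)
        grads <- .mvae_backward(model, fw, b)
        step <- adam_step(params, grads, state, lr)
        params <- step$params
        state <- step$state
        model <- .mvae_set_params(model, params)
        w <- length(idx) / n
        acc <- acc + w * c(fw$losses$recon_tga, fw$losses$recon_ftir,
                           fw$losses$pred, fw$losses$kl)
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, recon_tga = acc[["recon_tga"]],
        recon_ftir = acc[["recon_ftir"]], pred = acc[["pred"]], kl = acc[["kl"]],
        total = acc[["recon_tga"]] + acc[["recon_ftir"]] + acc[["pred"]] + acc[["kl"]])
    }
  })
  model$trained <- TRUE
  model$loss_history <- do.call(rbind, history)
  model
}

#' Predict a GC-MS composition from TGA and FT-IR measurements
#'
#' Encodes both modalities, fuses the posteriors and evaluates the mixture
#' head at the fused posterior mean (no sampling at inference), so repeated
#' calls are identical.
#'
#' @param model a trained `lc_mvae`.
#' @param tga a [thermogram_resampled()].
#' @param ftir an [ir_preprocessed()].
#' @return A [composition_vector()].
#' @export
predict_gcms <- function(model, tga, ftir) {
  if (!inherits(model, "lc_mvae") || !isTRUE(model$trained)) {
    stop("state error: predictor has not been trained", call. = FALSE)
  }
  g_tga <- encode_modality(tga$mass_pct / 100, "TGA", model)
  g_ftir <- encode_modality(ftir$values, "FTIR", model)
  fused <- fuse_experts(list(g_tga, g_ftir))
  out <- predict_composition(fused$mu, model)
  composition_vector(out$composition, tga$htl_temperature_c)
}
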