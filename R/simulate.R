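# Seeded simulator of study-like raw data: TGA thermograms built from
# logistic mass-loss steps, FT-IR transmittance spectra built from Gaussian
# absorption dips on a flat baseline, and 114-row GC-MS derivative tables
# whose detected totals deliberately fall short of 100%. All condition
# dependence runs through the normalized HTL temperature
# tau = (T - 250) / 150, which maps the four anchor conditions onto [0, 1].

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Normalized HTL condition
#'
#' @param htl_temperature_c HTL temperature in degrees C.
#' @return `(T - 250) / 150`; the anchors 250/300/350/400 map to 0, 1/3, 2/3, 1.
#' @export
htl_tau <- function(htl_temperature_c) (htl_temperature_c - 250) / 150

.check_htl_domain <- function(htl_temperature_c) {
  if (!is.finite(htl_temperature_c) ||
      htl_temperature_c < 240 || htl_temperature_c > 410) {
    stop("domain error: htl_temperature_c must lie in [240, 410], got ",
         htl_temperature_c, call. = FALSE)
  }
}

#' Simulator parameters
#'
#' Defaults emulate lignin-like data: a small moisture-loss step near 80
#' degrees C, a main devolatilization step near 330 degrees C, a slow char
#' step near 550 degrees C and roughly 45% residue for TGA; O-H, C-H, C=O,
#' aromatic-skeletal and C-O bands for FT-IR; and nine-group compositions
#' whose syringyl/guaiacyl share declines while low-molecular-weight groups
#' rise with HTL severity. Each TGA step and FT-IR dip carries coefficients
#' linear in the normalized condition tau.
#'
#' @param tga_steps list of steps, each `list(amplitude = c(a0, a1),
#'   center = c(c0, c1), width = w)`: amplitude/center evaluate as
#'   `a0 + a1 * tau` (percent of initial mass, degrees C).
#' @param tga_residue_pct residual mass percent at the end of the scan.
#' @param tga_point_spacing_c scan sampling interval in degrees C.
#' @param tga_start_c,tga_end_c nominal scan window; with nonzero noise a
#'   seeded sub-degree start/end jitter emulates run-to-run variability.
#' @param ftir_peaks data.frame with `center_cm1`, `width_cm1`, `depth_pct`
#'   and `depth_slope` (dip depth evaluates as `depth_pct + depth_slope * tau`).
#' @param ftir_baseline_pct flat transmittance baseline in percent.
#' @param ftir_replicate_offset_sd per-replicate baseline offset SD (percent).
#' @param ftir_outlier_prob,ftir_outlier_sd rate and SD of sparse noise
#'   spikes; together with the baseline offset these occasionally push
#'   recorded transmittance above 100%, as seen in real exports.
#' @param noise_sd_tga,noise_sd_ftir additive Gaussian point-noise SDs.
#' @param gcms_logit_coeffs 9 x 3 matrix of (intercept, linear, quadratic)
#'   coefficients in tau for the group logits (rows ordered as
#'   `gcms_groups()[1:9]`).
#' @param derivatives_per_group integer partition of 114 compounds over the
#'   nine groups.
#' @param undetected_fraction_range range of the undetected mass fraction;
#'   the realized fraction varies smoothly within it across conditions.
#' @param seed default seed used when an operation is not given one.
#' @return A `simulator_params` object.
#' @export
simulator_params <- function(
    tga_steps = list(
      list(amplitude = c(3, 0), center = c(80, 0), width = 12),
      list(amplitude = c(36, 3), center = c(335, -25), width = 28),
      list(amplitude = c(16, -3), center = c(550, 30), width = 60)),
    tga_residue_pct = 45,
    tga_point_spacing_c = 0.034,
    tga_start_c = 39.6,
    tga_end_c = 787.5,
    ftir_peaks = data.frame(
      center_cm1 = c(3400, 2930, 1730, 1600, 1510, 1215, 1030),
      width_cm1 = c(150, 60, 40, 30, 25, 40, 50),
      depth_pct = c(20, 10, 12, 15, 12, 14, 18),
      depth_slope = c(-6, 4, 8, -4, -6, -4, -8)),
    ftir_baseline_pct = 98.5,
    ftir_replicate_offset_sd = 0.5,
    ftir_outlier_prob = 0.003,
    ftir_outlier_sd = 2,
    noise_sd_tga = 0.05,
    noise_sd_ftir = 0.3,
    gcms_logit_coeffs = rbind(
      Syringyl = c(-1.43, -0.8, 0),
      Guaiacyl = c(-1.61, -0.5, 0),
      PolyAromatics_C10_C21 = c(-2.81, 2.0, -1.6),
      OtherAromatics_C6_C20 = c(-1.27, 0.3, 0),
      Alkanes = c(-3.91, 1.2, 0),
      Cyclic = c(-3.10, 0.2, 0),
      FattyAcids = c(-2.90, 1.5, -1.0),
      Alcohol = c(-3.91, 0.5, 0),
      GlycerolDerived = c(-2.53, 0.8, 0)),
    derivatives_per_group = c(20L, 18L, 15L, 16L, 10L, 9L, 10L, 8L, 8L),
    undetected_fraction_range = c(0.08, 0.14),
    seed = 1L) {
  p <- structure(as.list(environment()), class = "simulator_params")
  tau_probe <- htl_tau(c(240, 410))
  amp_tot <- vapply(tau_probe, function(tau) {
    sum(vapply(p$tga_steps, function(s) s$amplitude[1] + s$amplitude[2] * tau,
               numeric(1)))
  }, numeric(1))
  if (any(vapply(p$tga_steps, function(s)
    min(s$amplitude[1] + s$amplitude[2] * htl_tau(c(240, 410))), numeric(1)) < 0)) {
    stop("simulator_params: step amplitudes must stay non-negative over the domain")
  }
  if (any(p$tga_residue_pct + amp_tot > 100 + 1e-9)) {
    stop("simulator_params: residue plus step amplitudes must not exceed 100")
  }
  if (any(p$ftir_peaks$center_cm1 < 650 | p$ftir_peaks$center_cm1 > 4000)) {
    stop("simulator_params: peak centers must lie within [650, 4000] 1/cm")
  }
  if (sum(p$derivatives_per_group) != 114L) {
    stop("simulator_params: derivatives_per_group must sum to 114")
  }
  p
}

# Noiseless TGA mass curve (% of initial mass) at scan temperatures `temp_c`.
.tga_true_mass <- function(temp_c, htl_temperature_c, params) {
  tau <- htl_tau(htl_temperature_c)
  loss <- 0
  for (s in params$tga_steps) {
    amp <- s$amplitude[1] + s$amplitude[2] * tau
    ctr <- s$center[1] + s$center[2] * tau
    loss <- loss + amp * stats::plogis((temp_c - ctr) / s$width)
  }
  100 - loss
}

# Noiseless FT-IR transmittance (%) on the canonical grid.
.ftir_true_transmittance <- function(htl_temperature_c, params) {
  tau <- htl_tau(htl_temperature_c)
  nu <- ftir_grid()
  tr <- rep(params$ftir_baseline_pct, length(nu))
  for (i in seq_len(nrow(params$ftir_peaks))) {
    pk <- params$ftir_peaks[i, ]
    depth <- pk$depth_pct + pk$depth_slope * tau
    tr <- tr - depth * exp(-(nu - pk$center_cm1)^2 / (2 * pk$width_cm1^2))
  }
  tr
}

# Deterministic undetected mass fraction: varies smoothly within the
# configured range across the condition domain.
.undetected_fraction <- function(htl_temperature_c, params) {
  rng <- params$undetected_fraction_range
  mid <- mean(rng)
  amp <- 0.45 * diff(rng)
  mid - amp * cos(2 * pi * htl_tau(htl_temperature_c))
}

# True nine-group fractions (summing to 1 before the undetected shortfall).
.gcms_true_groups <- function(htl_temperature_c, params) {
  tau <- htl_tau(htl_temperature_c)
  logits <- params$gcms_logit_coeffs %*% c(1, tau, tau^2)
  e <- exp(logits - max(logits))
  g <- as.numeric(e / sum(e))
  names(g) <- rownames(params$gcms_logit_coeffs)
  g
}

#' Simulate one raw TGA thermogram
#'
#' Noiseless mass is a sum of logistic decomposition steps over a residue
#' plateau and is non-increasing in scan temperature; seeded Gaussian noise
#' and (with nonzero noise) a sub-degree start/end jitter are added on top.
#'
#' @param htl_temperature_c HTL condition in `[240, 410]` degrees C.
#' @param params a [simulator_params()].
#' @param seed integer seed; defaults to `params$seed`.
#' @return A [thermogram_raw()] with roughly 22,000 points.
#' @export
simulate_tga_raw <- function(htl_temperature_c, params = simulator_params(),
                             seed = params$seed) {
  .check_htl_domain(htl_temperature_c)
  with_seed(seed, {
    noisy <- params$noise_sd_tga > 0
    start <- params$tga_start_c + if (noisy) stats::runif(1, 0, 0.8) else 0
    end <- params$tga_end_c - if (noisy) stats::runif(1, 0, 1.5) else 0
    temps <- seq(start, end, by = params$tga_point_spacing_c)
    mass <- .tga_true_mass(temps, htl_temperature_c, params)
    if (noisy) mass <- mass + stats::rnorm(length(temps), sd = params$noise_sd_tga)
    thermogram_raw(temps, pmin(mass, 110), htl_temperature_c)
  })
}

#' Simulate three FT-IR transmittance replicates
#'
#' Replicates share one noiseless spectrum (baseline minus Gaussian dips);
#' each adds a seeded baseline offset and point noise, so a few recorded
#' points can exceed 100% transmittance as in real exports.
#'
#' @inheritParams simulate_tga_raw
#' @return List of three [ir_spectrum_raw()] on the canonical 3476-point grid.
#' @export
simulate_ftir_replicates <- function(htl_temperature_c, params = simulator_params(),
                                     seed = params$seed) {
  .check_htl_domain(htl_temperature_c)
  true_tr <- .ftir_true_transmittance(htl_temperature_c, params)
  nu <- ftir_grid()
  with_seed(seed, {
    lapply(1:3, function(k) {
      offset <- if (params$ftir_replicate_offset_sd > 0)
        stats::rnorm(1, sd = params$ftir_replicate_offset_sd) else 0
      noise <- if (params$noise_sd_ftir > 0)
        stats::rnorm(length(nu), sd = params$noise_sd_ftir) else 0
      if (params$noise_sd_ftir > 0 && params$ftir_outlier_prob > 0) {
        spike <- stats::runif(length(nu)) < params$ftir_outlier_prob
        noise[spike] <- noise[spike] +
          stats::rnorm(sum(spike), sd = params$ftir_outlier_sd)
      }
      ir_spectrum_raw(nu, true_tr + offset + noise, k, htl_temperature_c)
    })
  })
}

#' Simulate one GC-MS derivative table
#'
#' The nine group proportions follow a softmax of quadratic-in-tau logits,
#' split over 114 compound rows by fixed within-group weights. A seeded
#' subset of rows is flagged undetected and the remaining rows are
#' renormalized so the detected total equals `100 * (1 - u)`, where the
#' undetected fraction `u` varies smoothly within
#' `undetected_fraction_range` across conditions.
#'
#' @inheritParams simulate_tga_raw
#' @return A [derivative_table()] with 114 rows.
#' @export
simulate_gcms_table <- function(htl_temperature_c, params = simulator_params(),
                                seed = params$seed) {
  .check_htl_domain(htl_temperature_c)
  g <- .gcms_true_groups(htl_temperature_c, params)
  u <- .undetected_fraction(htl_temperature_c, params)
  n_per <- params$derivatives_per_group
  groups9 <- gcms_groups()[1:9]
  with_seed(seed, {
    rows <- lapply(seq_along(groups9), function(k) {
      n_k <- n_per[k]
      w <- exp(-0.25 * (seq_len(n_k) - 1))
      w <- w / sum(w)
      nominal <- g[k] * 100 * w
      detected <- rep(TRUE, n_k)
      if (u > 0) {
        target <- u * g[k] * 100
        cum <- 0
        for (j in sample.int(n_k)) {
          if (cum + nominal[j] <= target) {
            detected[j] <- FALSE
            cum <- cum + nominal[j]
          }
        }
      }
      pct <- numeric(n_k)
      det_sum <- sum(nominal[detected])
      if (det_sum > 0) {
        pct[detected] <- nominal[detected] * (g[k] * 100 * (1 - u)) / det_sum
      }
      data.frame(compound = sprintf("%s_%d", groups9[k], seq_len(n_k)),
                 group = groups9[k], proportion_pct = pct, detected = detected)
    })
    df <- do.call(rbind, rows)
    derivative_table(df$compound, df$group, df$proportion_pct, df$detected,
                     htl_temperature_c)
  })
}

#' Simulate a full study bundle plus a ground-truth oracle
#'
#' Per anchor condition: one raw thermogram, three FT-IR replicates and one
#' derivative table. The returned oracle maps any condition in the domain to
#' its noiseless processed triplet (resampled TGA, log-transformed FT-IR,
#' composition on the 10-simplex); it is meant for evaluation only, never
#' for training.
#'
#' @param anchor_temps at least two HTL conditions in degrees C.
#' @inheritParams simulate_tga_raw
#' @param preprocess_cfg a [preprocess_config()] used by the oracle.
#' @return List with `tga`, `ftir` (flat list of replicates), `gcms`,
#'   `anchor_temps`, `params` and `oracle(htl_temperature_c)`.
#' @export
simulate_study <- function(anchor_temps = c(250, 300, 350, 400),
                           params = simulator_params(), seed = params$seed,
                           preprocess_cfg = preprocess_config()) {
  if (length(anchor_temps) < 2) {
    stop("simulate_study requires at least two anchor temperatures")
  }
  for (t in anchor_temps) .check_htl_domain(t)
  sub_seed <- function(i, k) (abs(seed) + 97L * i + 13L * k) %% 2147483647L
  tga <- list(); ftir <- list(); gcms <- list()
  for (i in seq_along(anchor_temps)) {
    t_i <- anchor_temps[i]
    tga[[i]] <- simulate_tga_raw(t_i, params, sub_seed(i, 1L))
    ftir <- c(ftir, simulate_ftir_replicates(t_i, params, sub_seed(i, 2L)))
    gcms[[i]] <- simulate_gcms_table(t_i, params, sub_seed(i, 3L))
  }
  noiseless <- params
  noiseless$noise_sd_tga <- 0
  noiseless$noise_sd_ftir <- 0
  noiseless$ftir_replicate_offset_sd <- 0
  oracle <- function(htl_temperature_c) {
    .check_htl_domain(htl_temperature_c)
    raw <- simulate_tga_raw(htl_temperature_c, noiseless, seed = 0L)
    reps <- simulate_ftir_replicates(htl_temperature_c, noiseless, seed = 0L)
    g <- .gcms_true_groups(htl_temperature_c, params)
    u <- .undetected_fraction(htl_temperature_c, params)
    comp <- composition_vector(c(g * (1 - u), Other = u), htl_temperature_c)
    sample_triplet(htl_temperature_c,
                   tga = clip_resample_tga(raw, preprocess_cfg),
                   ftir = preprocess_ftir(reps, preprocess_cfg),
                   gcms = comp)
  }
  list(tga = tga, ftir = ftir, gcms = gcms, anchor_temps = anchor_temps,
       params = params, oracle = oracle)
}
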