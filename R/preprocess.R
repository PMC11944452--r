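# Preprocessing pipelines: TGA clipping + 1-degree-bin resampling, FT-IR
# replicate averaging + clip/offset/log transform, GC-MS group aggregation
# with "Other" closure, and a Wasserstein-1 audit of the information lost
# by TGA resampling.

#' Preprocessing configuration
#'
#' @param tga_clip_low_c,tga_clip_high_c integer clip window in degrees C.
#' @param ftir_clip_pct transmittance ceiling before the offset subtraction.
#' @param ftir_offset offset the clipped mean is subtracted from.
#' @param ftir_floor stabilization constant applied before the logarithm.
#' @param log_base base of the final logarithm (decimal by transmittance /
#'   absorbance convention).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(tga_clip_low_c = 40L, tga_clip_high_c = 760L,
                              ftir_clip_pct = 100, ftir_offset = 101,
                              ftir_floor = 1e-6, log_base = 10) {
  stopifnot(tga_clip_low_c < tga_clip_high_c, ftir_floor > 0, log_base > 1)
  structure(list(tga_clip_low_c = as.integer(tga_clip_low_c),
                 tga_clip_high_c = as.integer(tga_clip_high_c),
                 ftir_clip_pct = ftir_clip_pct, ftir_offset = ftir_offset,
                 ftir_floor = ftir_floor, log_base = log_base),
            class = "preprocess_config")
}

#' Clip and resample a raw thermogram to a 1 degree C grid
#'
#' Points outside the clip window are discarded; the value at integer
#' temperature `t` is the arithmetic mean of raw mass over the centered bin
#' `[t - 0.5, t + 0.5)`. Empty bins are filled by linear interpolation
#' between the nearest non-empty bins. Idempotent on already-binned data.
#'
#' @param raw a [thermogram_raw()] whose scan covers the clip window.
#' @param cfg a [preprocess_config()].
#' @return A [thermogram_resampled()] of length
#'   `tga_clip_high_c - tga_clip_low_c + 1` (721 by default).
#' @export
clip_resample_tga <- function(raw, cfg = preprocess_config()) {
  lo <- cfg$tga_clip_low_c
  hi <- cfg$tga_clip_high_c
  # real scans can start just above the window (e.g. 40.42 on a 40 clip);
  # half-a-bin slack keeps every output bin reachable
  if (min(raw$temperature_c) >= lo + 0.5 || max(raw$temperature_c) < hi - 0.5) {
    stop("coverage error: thermogram spans [",
         round(min(raw$temperature_c), 2), ", ", round(max(raw$temperature_c), 2),
         "] but the clip window is [", lo, ", ", hi, "]", call. = FALSE)
  }
  keep <- raw$temperature_c >= lo - 0.5 & raw$temperature_c < hi + 0.5
  temp <- raw$temperature_c[keep]
  mass <- raw$mass_pct[keep]
  bin <- as.integer(floor(temp + 0.5))
  grid <- seq.int(lo, hi)
  sums <- tapply(mass, factor(bin, levels = grid), sum)
  counts <- tapply(rep(1, length(bin)), factor(bin, levels = grid), sum)
  vals <- as.numeric(sums / counts)
  if (anyNA(vals)) {
    filled <- which(!is.na(vals))
    vals <- stats::approx(grid[filled], vals[filled], xout = grid, rule = 2)$y
  }
  thermogram_resampled(vals, lo, hi, raw$htl_temperature_c)
}

#' Preprocess FT-IR replicates into a log-absorbance-like vector
#'
#' Per wavenumber: mean over replicates, clip at `ftir_clip_pct`, subtract
#' from `ftir_offset`, floor at `ftir_floor`, then take the logarithm in
#' `log_base`. Replicates recorded off the canonical 3476-point grid are
#' first linearly interpolated onto it. The clip guarantees the log
#' argument is at least `ftir_offset - ftir_clip_pct` (1 by default), so
#' outputs lie in `[0, log10(101)]` for non-negative transmittance.
#'
#' @param replicates list of [ir_spectrum_raw()] for one condition.
#' @param cfg a [preprocess_config()].
#' @return An [ir_preprocessed()] of length 3476.
#' @export
preprocess_ftir <- function(replicates, cfg = preprocess_config()) {
  if (inherits(replicates, "ir_spectrum_raw")) replicates <- list(replicates)
  if (length(replicates) == 0) {
    stop("argument error: preprocess_ftir needs at least one replicate")
  }
  grid <- ftir_grid()
  on_grid <- vapply(replicates, function(r) {
    length(r$wavenumber_cm1) == length(grid) &&
      max(abs(r$wavenumber_cm1 - grid)) < 1e-9
  }, logical(1))
  mats <- lapply(seq_along(replicates), function(i) {
    r <- replicates[[i]]
    if (on_grid[i]) return(r$transmittance_pct)
    if (min(r$wavenumber_cm1) > max(grid) || max(r$wavenumber_cm1) < min(grid)) {
      stop("grid error: replicate wavenumbers do not overlap the canonical grid",
           call. = FALSE)
    }
    stats::approx(r$wavenumber_cm1, r$transmittance_pct, xout = grid, rule = 2)$y
  })
  mean_tr <- Reduce(`+`, mats) / length(mats)
  clipped <- pmin(mean_tr, cfg$ftir_clip_pct)
  arg <- pmax(cfg$ftir_offset - clipped, cfg$ftir_floor)
  ir_preprocessed(log(arg, base = cfg$log_base),
                  replicates[[1L]]$htl_temperature_c)
}

#' Aggregate a derivative table into a 10-group composition
#'
#' Each of the nine group fractions is the sum of its detected derivative
#' percentages divided by 100; the closing "Other" fraction is one minus
#' the group total, absorbing the undetected shortfall.
#'
#' @param table a [derivative_table()].
#' @return A [composition_vector()] on the 10-simplex.
#' @export
aggregate_gcms <- function(table) {
  det_sum <- sum(table$proportion_pct[table$detected])
  if (det_sum > 100 + 1e-6) {
    stop("validation error: detected proportions sum to ", round(det_sum, 4),
         " > 100", call. = FALSE)
  }
  groups9 <- gcms_groups()[1:9]
  by_group <- vapply(groups9, function(g) {
    sum(table$proportion_pct[table$detected & table$group == g])
  }, numeric(1)) / 100
  frac <- c(by_group, Other = max(0, 1 - sum(by_group)))
  composition_vector(frac, attr(table, "htl_temperature_c") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wasserstein-1 audit of the TGA resampling step
#'
#' Distance between the empirical distributions of raw and resampled mass
#' values (restricted to the clip window), on the mass-fraction scale
#' (values divided by 100). Small values mean the 1-degree binning
#' preserved the distribution of the thermogram.
#'
#' @param raw a [thermogram_raw()].
#' @param resampled the matching [thermogram_resampled()].
#' @param cfg a [preprocess_config()] defining the clip window.
#' @return Non-negative scalar distance on the mass-fraction scale.
#' @export
preprocessing_information_loss <- function(raw, resampled,
                                           cfg = preprocess_config()) {
  keep <- raw$temperature_c >= cfg$tga_clip_low_c &
    raw$temperature_c <= cfg$tga_clip_high_c
  if (!any(keep) || length(resampled$mass_pct) == 0) {
    stop("argument error: empty inputs to the information-loss audit")
  }
  wasserstein1(raw$mass_pct[keep] / 100, resampled$mass_pct / 100)
}
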