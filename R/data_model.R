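# Domain types for the three analytical modalities. Constructors validate
# eagerly; validate_triplet() reports violations without raising so that
# pipelines can audit questionable data.

#' Group vocabulary for GC-MS compositions
#'
#' The nine compound groups observed among lignin depolymerization products,
#' plus the closing "Other" class that absorbs undetected mass.
#'
#' @return Character vector of the ten composition labels.
#' @export
gcms_groups <- function() {
  c("Syringyl", "Guaiacyl", "PolyAromatics_C10_C21", "OtherAromatics_C6_C20",
    "Alkanes", "Cyclic", "FattyAcids", "Alcohol", "GlycerolDerived", "Other")
}

#' Raw TGA thermogram
#'
#' @param temperature_c strictly increasing scan temperatures in degrees C.
#' @param mass_pct percent of initial mass at each temperature.
#' @param htl_temperature_c hydrothermal liquefaction condition in degrees C.
#' @return A `thermogram_raw` object.
#' @export
thermogram_raw <- function(temperature_c, mass_pct, htl_temperature_c) {
  x <- structure(list(temperature_c = as.numeric(temperature_c),
                      mass_pct = as.numeric(mass_pct),
                      htl_temperature_c = as.numeric(htl_temperature_c)),
                 class = "thermogram_raw")
  stop_on_violations(validate_record(x), "thermogram_raw")
  x
}

#' Resampled thermogram on a 1 degree C grid
#'
#' @param mass_pct one value per integer degree over the grid.
#' @param grid_start_c,grid_end_c inclusive integer grid bounds.
#' @param htl_temperature_c HTL condition in degrees C (optional).
#' @return A `thermogram_resampled` object.
#' @export
thermogram_resampled <- function(mass_pct, grid_start_c = 40L, grid_end_c = 760L,
                                 htl_temperature_c = NA_real_) {
  x <- structure(list(grid_start_c = as.integer(grid_start_c),
                      grid_end_c = as.integer(grid_end_c),
                      mass_pct = as.numeric(mass_pct),
                      htl_temperature_c = as.numeric(htl_temperature_c)),
                 class = "thermogram_resampled")
  stop_on_violations(validate_record(x), "thermogram_resampled")
  x
}

#' Raw FT-IR transmittance spectrum (one replicate)
#'
#' Transmittance may slightly exceed 100 percent through instrument noise;
#' the preprocessing step clips it.
#'
#' @param wavenumber_cm1 strictly increasing wavenumbers (1/cm).
#' @param transmittance_pct percent transmittance.
#' @param replicate_id replicate index, 1 to 3.
#' @param htl_temperature_c HTL condition in degrees C.
#' @return An `ir_spectrum_raw` object.
#' @export
ir_spectrum_raw <- function(wavenumber_cm1, transmittance_pct, replicate_id,
                            htl_temperature_c) {
  x <- structure(list(wavenumber_cm1 = as.numeric(wavenumber_cm1),
                      transmittance_pct = as.numeric(transmittance_pct),
                      replicate_id = as.integer(replicate_id),
                      htl_temperature_c = as.numeric(htl_temperature_c)),
                 class = "ir_spectrum_raw")
  stop_on_violations(validate_record(x), "ir_spectrum_raw")
  x
}

#' The canonical 3476-point FT-IR wavenumber grid
#'
#' Evenly spaced from 649.8934 to 4000.6047 1/cm.
#' @return Numeric vector of length 3476.
#' @export
ftir_grid <- function() {
  seq(649.8934, 4000.6047, length.out = 3476L)
}

#' Preprocessed FT-IR vector (log-absorbance-like scale)
#'
#' @param values numeric vector of length 3476.
#' @param htl_temperature_c HTL condition in degrees C (optional).
#' @return An `ir_preprocessed` object.
#' @export
ir_preprocessed <- function(values, htl_temperature_c = NA_real_) {
  x <- structure(list(values = as.numeric(values),
                      htl_temperature_c = as.numeric(htl_temperature_c)),
                 class = "ir_preprocessed")
  stop_on_violations(validate_record(x), "ir_preprocessed")
  x
}

#' Per-compound GC-MS derivative table
#'
#' @param compound compound names.
#' @param group group label for each compound (one of the nine groups).
#' @param proportion_pct percent of total for each compound.
#' @param detected logical; undetected compounds contribute no measured mass.
#' @param htl_temperature_c HTL condition in degrees C.
#' @return A data.frame of class `derivative_table`.
#' @export
derivative_table <- function(compound, group, proportion_pct, detected,
                             htl_temperature_c = NA_real_) {
  x <- data.frame(compound = as.character(compound),
                  group = as.character(group),
                  proportion_pct = as.numeric(proportion_pct),
                  detected = as.logical(detected),
                  stringsAsFactors = FALSE)
  attr(x, "htl_temperature_c") <- as.numeric(htl_temperature_c)
  class(x) <- c("derivative_table", "data.frame")
  stop_on_violations(validate_record(x), "derivative_table")
  x
}

#' Composition vector on the 10-simplex
#'
#' @param fractions named numeric vector over [gcms_groups()], non-negative,
#'   summing to one.
#' @param htl_temperature_c HTL condition in degrees C (optional).
#' @return A `composition_vector` object.
#' @export
composition_vector <- function(fractions, htl_temperature_c = NA_real_) {
  if (is.null(names(fractions))) names(fractions) <- gcms_groups()
  fractions <- fractions[gcms_groups()]
  x <- structure(list(fractions = as.numeric(fractions),
                      htl_temperature_c = as.numeric(htl_temperature_c)),
                 class = "composition_vector")
  names(x$fractions) <- gcms_groups()
  stop_on_violations(validate_record(x), "composition_vector")
  x
}

#' One HTL condition's aligned processed data
#'
#' @param htl_temperature_c HTL condition in degrees C.
#' @param tga a `thermogram_resampled`.
#' @param ftir an `ir_preprocessed`.
#' @param gcms a `composition_vector`.
#' @return A `sample_triplet` object. Use [validate_triplet()] to audit.
#' @export
sample_triplet <- function(htl_temperature_c, tga, ftir, gcms) {
  structure(list(htl_temperature_c = as.numeric(htl_temperature_c),
                 tga = tga, ftir = ftir, gcms = gcms),
            class = "sample_triplet")
}

# ---- validation -------------------------------------------------------

#' @keywords internal
stop_on_violations <- function(violations, what) {
  if (length(violations)) {
    stop(what, " validation: ", paste(violations, collapse = "; "), call. = FALSE)
  }
  invisible(NULL)
}

#' Validate a typed record, returning violation messages
#'
#' Total: never raises; every failure maps to a message naming the field and
#' the rule it breaks.
#'
#' @param x a record created by one of the type constructors (or a bare list
#'   shaped like one).
#' @return Character vector of violations (empty when valid).
#' @export
validate_record <- function(x) {
  v <- character()
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v
  cls <- class(x)[1L]
  if (cls == "thermogram_raw") {
    v <- add(length(x$temperature_c) != length(x$mass_pct),
             "temperature_c/mass_pct: unequal lengths")
    v <- add(any(!is.finite(x$temperature_c)), "temperature_c: non-finite values")
    v <- add(any(diff(x$temperature_c) <= 0), "temperature_c: not strictly increasing")
    v <- add(any(x$temperature_c < 30 | x$temperature_c > 800),
             "temperature_c: out of range [30, 800]")
    v <- add(any(!is.finite(x$mass_pct)), "mass_pct: non-finite values")
    v <- add(any(x$mass_pct <= 0 | x$mass_pct > 110), "mass_pct: out of range (0, 110]")
  } else if (cls == "thermogram_resampled") {
    expected <- x$grid_end_c - x$grid_start_c + 1L
    v <- add(x$grid_start_c >= x$grid_end_c, "grid: start must precede end")
    v <- add(length(x$mass_pct) != expected,
             sprintf("mass_pct: length %d does not match grid length %d",
                     length(x$mass_pct), expected))
    v <- add(any(!is.finite(x$mass_pct)), "mass_pct: non-finite values")
  } else if (cls == "ir_spectrum_raw") {
    v <- add(length(x$wavenumber_cm1) != length(x$transmittance_pct),
             "wavenumber_cm1/transmittance_pct: unequal lengths")
    v <- add(any(diff(x$wavenumber_cm1) <= 0),
             "wavenumber_cm1: not strictly increasing")
    v <- add(!(x$replicate_id %in% 1:3), "replicate_id: must be 1, 2 or 3")
    v <- add(any(!is.finite(x$transmittance_pct)), "transmittance_pct: non-finite values")
  } else if (cls == "ir_preprocessed") {
    v <- add(length(x$values) != 3476L,
             sprintf("values: length %d, expected 3476", length(x$values)))
    v <- add(any(!is.finite(x$values)), "values: non-finite values")
  } else if (cls == "derivative_table") {
    ok_groups <- x$group %in% gcms_groups()[1:9]
    v <- add(any(!ok_groups),
             paste0("group: labels outside the nine-group vocabulary: ",
                    paste(unique(x$group[!ok_groups]), collapse = ", ")))
    v <- add(any(x$proportion_pct < 0), "proportion_pct: negative values")
    v <- add(sum(x$proportion_pct[x$detected]) > 100 + 1e-6,
             "proportion_pct: detected total exceeds 100")
  } else if (cls == "composition_vector") {
    v <- add(length(x$fractions) != 10L, "fractions: must have 10 entries")
    v <- add(any(!is.finite(x$fractions)), "fractions: non-finite values")
    v <- add(any(x$fractions < 0), "fractions: negative values")
    v <- add(is.finite(sum(x$fractions)) && abs(sum(x$fractions) - 1) > 1e-6,
             "fractions: sum-to-one violated")
  } else {
    v <- c(v, paste0("unknown record class: ", cls))
  }
  v
}

#' Audit a sample triplet against all type invariants
#'
#' @param t a `sample_triplet`.
#' @return Character vector of violation messages; empty when every
#'   component invariant holds.
#' @export
validate_triplet <- function(t) {
  v <- character()
  for (field in c("tga", "ftir", "gcms")) {
    sub <- validate_record(t[[field]])
    if (length(sub)) v <- c(v, paste0(field, ": ", sub))
  }
  if (!is.finite(t$htl_temperature_c)) {
    v <- c(v, "htl_temperature_c: non-finite")
  }
  v
}
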