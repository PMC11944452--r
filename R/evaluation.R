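# Metric suite: linear-interpolation references for unseen conditions, MAE,
# R-squared, Pearson correlation (population moments), and the
# Wasserstein-1 distance between 1-D empirical distributions.

#' Linear interpolation between two condition-indexed vectors
#'
#' @param x1,x2 the two condition values (e.g. HTL temperatures), distinct.
#' @param y1,y2 equal-length vectors observed at `x1` and `x2`.
#' @param x query condition, inside the closed interval spanned by `x1`, `x2`.
#' @return Elementwise `y1 + (x - x1) / (x2 - x1) * (y2 - y1)`.
#' @export
linear_interpolate <- function(x1, y1, x2, y2, x) {
  if (x1 == x2) stop("degenerate-interval error: x1 equals x2", call. = FALSE)
  if (length(y1) != length(y2)) stop("shape error: y1 and y2 differ in length")
  if (x < min(x1, x2) || x > max(x1, x2)) {
    stop("domain error: x = ", x, " outside [", min(x1, x2), ", ",
         max(x1, x2), "]", call. = FALSE)
  }
  if (x == x1) return(y1)  # endpoint identities hold exactly
  if (x == x2) return(y2)
  y1 + (x - x1) / (x2 - x1) * (y2 - y1)
}

#' Mean absolute error
#' @param y,yhat equal-length numeric vectors (reference, estimate).
#' @return `(1/n) * sum(|y - yhat|)`.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0) {
    stop("shape error: mae needs equal non-zero lengths")
  }
  mean(abs(y - yhat))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` about the mean of `y`; may be negative when the
#' estimate does worse than the constant mean.
#' @param y,yhat equal-length numeric vectors; `y` must not be constant.
#' @return Scalar, at most 1.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("shape error: r_squared needs equal lengths of at least 2")
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("undefined-denominator error: y is constant")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Pearson correlation coefficient (population moments)
#' @param y,yhat equal-length numeric vectors, neither constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("shape error: pearson needs equal lengths of at least 2")
  }
  cy <- y - mean(y)
  cz <- yhat - mean(yhat)
  denom <- sqrt(sum(cy^2) * sum(cz^2))
  if (denom == 0) stop("undefined-correlation error: zero variance input")
  sum(cy * cz) / denom
}

#' Wasserstein-1 distance between 1-D empirical distributions
#'
#' For equal sample sizes this is the mean absolute difference of the
#' sorted samples; in general it is the integral of the absolute ECDF
#' difference.
#'
#' @param p_samples,q_samples non-empty numeric samples.
#' @return Non-negative scalar.
#' @export
wasserstein1 <- function(p_samples, q_samples) {
  n <- length(p_samples)
  m <- length(q_samples)
  if (n == 0 || m == 0) stop("argument error: empty sample in wasserstein1")
  if (n == m) return(mean(abs(sort(p_samples) - sort(q_samples))))
  grid <- sort(c(p_samples, q_samples))
  fp <- stats::ecdf(p_samples)(grid)
  fq <- stats::ecdf(q_samples)(grid)
  k <- length(grid)
  sum(abs(fp[-k] - fq[-k]) * diff(grid))
}

#' Bracketing anchor pair for a query condition
#' @keywords internal
.bracket <- function(x, anchors) {
  if (!any(anchors <= x) || !any(anchors >= x)) {
    stop("domain error: ", x, " is not bracketed by the anchors", call. = FALSE)
  }
  c(max(anchors[anchors <= x]), min(anchors[anchors >= x]))
}

#' Evaluate generated vectors against interpolated anchor references
#'
#' For each query condition the reference is the linear interpolation of
#' the two nearest bracketing anchors; MAE, R-squared and Pearson are
#' computed elementwise over the vector's components.
#'
#' @param generated named list (names = temperatures) of generated vectors.
#' @param anchors named list (names = temperatures) of anchor vectors.
#' @param temps conditions to evaluate; default all names of `generated`.
#' @return data.frame with columns temperature_c, mae, r2, pearson.
#' @export
evaluate_generation <- function(generated, anchors,
                                temps = as.numeric(names(generated))) {
  anchor_t <- as.numeric(names(anchors))
  rows <- lapply(temps, function(x) {
    br <- .bracket(x, anchor_t)
    ref <- if (br[1] == br[2]) anchors[[as.character(br[1])]] else
      linear_interpolate(br[1], anchors[[as.character(br[1])]],
                         br[2], anchors[[as.character(br[2])]], x)
    gen <- generated[[as.character(x)]]
    data.frame(temperature_c = x, mae = mae(ref, gen),
               r2 = r_squared(ref, gen), pearson = pearson(ref, gen))
  })
  do.call(rbind, rows)
}

#' Evaluate predicted compositions against references
#'
#' Metrics are computed per condition over the 10 group fractions.
#'
#' @param predictions,references named lists (names = temperatures) of
#'   [composition_vector()] objects (or bare 10-vectors); the two sets of
#'   names must match.
#' @return data.frame with columns temperature_c, mae, r2, pearson.
#' @export
evaluate_prediction <- function(predictions, references) {
  if (!setequal(names(predictions), names(references))) {
    stop("argument error: prediction and reference temperature keys differ")
  }
  as_vec <- function(x) if (inherits(x, "composition_vector")) x$fractions else x
  rows <- lapply(names(predictions), function(k) {
    p <- as_vec(predictions[[k]])
    r <- as_vec(references[[k]])
    # a constant prediction has no defined correlation; report NA, not an error
    pr <- tryCatch(pearson(r, p), error = function(e) NA_real_)
    data.frame(temperature_c = as.numeric(k), mae = mae(r, p),
               r2 = r_squared(r, p), pearson = pr)
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature_c), , drop = FALSE]
}

#' Write evaluation tables to disk
#'
#' Emits one CSV per metric table plus a JSON summary; regenerating from
#' identical inputs gives byte-identical files.
#'
#' @param tables named list of data.frames (e.g. per-modality generation
#'   metrics, prediction metrics, the Wasserstein audit).
#' @param path output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(tables, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    fp <- file.path(path, paste0(nm, ".csv"))
    .write_table(as.data.frame(tables[[nm]]), fp)
    paths <- c(paths, fp)
  }
  sp <- file.path(path, "summary.json")
  jsonlite::write_json(tables, sp, dataframe = "rows", digits = NA, na = "null")
  invisible(c(paths, sp))
}
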