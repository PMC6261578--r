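#' Bundle reference samples for curve validation
#'
#' A reference set holds the two control yields scored under the customer's
#' own conditions: a negative control at 0 Gy and a positive control
#' irradiated at a known dose `xr` (typically 1.5 Gy). It is used to decide
#' whether an established calibration curve transfers to those conditions
#' ([validate_curve()]) and, when it does not, to build a replacement
#' two-point curve ([build_reference_curve()]).
#'
#' @param y0 Yield (foci/cell) of the negative control at 0 Gy.
#' @param n0 Cells scored for the negative control.
#' @param yr Yield of the positive control at dose `xr`.
#' @param nr Cells scored for the positive control.
#' @param xr Known dose of the positive control in Gy (default 1.5).
#' @return An object of class `h2ax_refset`.
#' @examples
#' reference_set(y0 = 0.4625, n0 = 400, yr = 5.02, nr = 200, xr = 1.5)
#' @export
reference_set <- function(y0, n0, yr, nr, xr = 1.5) {
  if (xr <= 0) abort("`xr` must be positive.", class = "h2ax_input_error")
  if (n0 < 1 || nr < 1) {
    abort("Cell counts must be at least 1.", class = "h2ax_input_error")
  }
  if (y0 < 0 || yr < 0) {
    abort("Yields must be non-negative.", class = "h2ax_input_error")
  }
  structure(list(y0 = y0, n0 = n0, yr = yr, nr = nr, xr = xr),
            class = "h2ax_refset")
}

#' @export
print.h2ax_refset <- function(x, ...) {
  cat("<h2ax_refset>\n")
  cat(sprintf("  negative control: y0 = %.4f foci/cell over %d cells (0 Gy)\n",
              x$y0, as.integer(x$n0)))
  cat(sprintf("  positive control: yr = %.4f foci/cell over %d cells (%.2f Gy)\n",
              x$yr, as.integer(x$nr), x$xr))
  invisible(x)
}

#' Pool replicate reference samples at a common dose
#'
#' Several reference samples taken at the same dose are equivalent to one
#' larger sample: total foci over total cells. At 0 Gy this pooling may span
#' time-after-exposure labels, since without exposure the time label is
#' meaningless.
#'
#' @param samples Data frame with columns `yield` and `n_cells` (and
#'   optionally `dose_gy`, which must then be constant).
#' @return A one-row tibble with the pooled `yield` and `n_cells`.
#' @examples
#' pool_reference_samples(
#'   tibble::tibble(yield = c(68, 117) / 200, n_cells = c(200, 200))
#' )
#' @export
pool_reference_samples <- function(samples) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    abort("`samples` must be a non-empty data frame.",
          class = "h2ax_input_error")
  }
  if (!all(c("yield", "n_cells") %in% names(samples))) {
    abort("`samples` needs columns `yield` and `n_cells`.",
          class = "h2ax_input_error")
  }
  if ("dose_gy" %in% names(samples) &&
      length(unique(samples$dose_gy)) > 1) {
    abort("Reference samples can only be pooled at a common dose.",
          class = "h2ax_input_error")
  }
  tibble(
    yield = sum(samples$yield * samples$n_cells) / sum(samples$n_cells),
    n_cells = sum(samples$n_cells)
  )
}

#' Quasi-Poisson prediction interval for a yield
#'
#' Approximate prediction interval for the yield of a fresh sample of
#' `n_prime` cells at dose `x`, assuming the calibration curve holds:
#' `A + B*x +/- q_crit * sqrt(phi * (A + B*x) / n_prime)`. The width scales
#' with the square roots of the dispersion and of 1/`n_prime`.
#'
#' @param curve Linear [calibration_curve()].
#' @param dose Dose(s) in Gy at which to predict.
#' @param n_prime Number of cells the new sample is scored over.
#' @param phi Dispersion index (default resolves as in [estimate_dose()]).
#' @param q_crit Critical multiplier (2 for an approximate 95% interval).
#' @return A tibble with one row per dose: `dose`, `fit`, `lo`, `hi`.
#' @examples
#' curve_1h <- calibration_curve(0.150, 12.518, phi = 60)
#' prediction_interval(curve_1h, dose = 1.5, n_prime = 200, q_crit = 2)
#' @export
prediction_interval <- function(curve, dose, n_prime, phi = NULL, q_crit = 2) {
  stopifnot(is_h2ax_curve(curve))
  if (curve$model_form != "linear") {
    abort("Prediction intervals are defined for linear curves.",
          class = "h2ax_input_error")
  }
  if (n_prime < 1) abort("`n_prime` must be at least 1.",
                         class = "h2ax_input_error")
  res <- resolve_phi(phi, curve)
  fit <- curve_yield(curve, dose)
  if (any(fit <= 0)) {
    abort("Fitted mean is non-positive at a requested dose.",
          class = "h2ax_degenerate_interval")
  }
  half <- q_crit * sqrt(res$phi * fit / n_prime)
  tibble(dose = dose, fit = fit, lo = fit - half, hi = fit + half)
}

#' Validate a calibration curve against reference samples
#'
#' Checks both reference yields against quasi-Poisson prediction intervals
#' around the calibration curve: the negative control against the interval
#' at 0 Gy (multiplier `q_neg`, default 3 — more leeway for the small
#' background yield) and the positive control against the interval at `xr`
#' (multiplier `q_pos`, default 2, an approximate 95% interval — the slope
#' matters most). There are two yields to check but a single decision: the
#' curve is discarded as a whole if either yield falls outside its interval.
#' A yield exactly on an endpoint counts as inside.
#'
#' @param curve Linear [calibration_curve()].
#' @param ref A [reference_set()].
#' @param phi Dispersion index. Never estimated from the reference samples
#'   themselves (two yields cannot support a dispersion estimate); resolves
#'   from the argument, the curve, or the consensus 60.
#' @param q_neg,q_pos Critical multipliers for the negative and positive
#'   control intervals.
#' @return An object of class `h2ax_validation` with the two intervals,
#'   inside/outside flags, and `decision` (`"accept"` or `"discard"`).
#'   `tidy()` returns a two-row tibble.
#' @examples
#' curve_1h <- calibration_curve(0.150, 12.518, 0.013, 0.158, phi = 60)
#' ref <- reference_set(0.4625, 400, 5.02, 200, 1.5)
#' validate_curve(curve_1h, ref)$decision
#' @export
validate_curve <- function(curve, ref, phi = NULL, q_neg = 3, q_pos = 2) {
  stopifnot(is_h2ax_curve(curve), inherits(ref, "h2ax_refset"))
  res <- resolve_phi(phi, curve)
  pi_neg <- prediction_interval(curve, 0, ref$n0, res$phi, q_neg)
  pi_pos <- prediction_interval(curve, ref$xr, ref$nr, res$phi, q_pos)
  inside_neg <- ref$y0 >= pi_neg$lo && ref$y0 <= pi_neg$hi
  inside_pos <- ref$yr >= pi_pos$lo && ref$yr <= pi_pos$hi
  structure(
    list(
      pi_negative = c(lo = pi_neg$lo, hi = pi_neg$hi),
      pi_positive = c(lo = pi_pos$lo, hi = pi_pos$hi),
      inside_negative = inside_neg,
      inside_positive = inside_pos,
      decision = if (inside_neg && inside_pos) "accept" else "discard",
      q_crit_used = c(negative = q_neg, positive = q_pos),
      phi = res$phi, warnings = res$warnings,
      curve = curve, ref = ref
    ),
    class = "h2ax_validation"
  )
}

#' @export
tidy.h2ax_validation <- function(x, ...) {
  tibble(
    control = c("negative", "positive"),
    dose = c(0, x$ref$xr),
    yield = c(x$ref$y0, x$ref$yr),
    n_cells = c(x$ref$n0, x$ref$nr),
    lo = c(x$pi_negative[["lo"]], x$pi_positive[["lo"]]),
    hi = c(x$pi_negative[["hi"]], x$pi_positive[["hi"]]),
    q_crit = unname(x$q_crit_used),
    inside = c(x$inside_negative, x$inside_positive)
  )
}

#' @export
print.h2ax_validation <- function(x, ...) {
  cat("<h2ax_validation> decision:", x$decision, "\n")
  print(tidy(x))
  invisible(x)
}

#' Build a two-point reference curve
#'
#' When a calibration curve fails validation, the two reference yields
#' determine a replacement line in their own right: intercept `y0` and
#' slope `(yr - y0) / xr`. Its parameters are unbiased for the customer's
#' conditions but carry larger standard errors, obtained from the
#' quasi-Poisson variance of the yields:
#' `SE(A) = sqrt(phi * y0 / n0)` and
#' `SE(B) = sqrt(phi * (y0/n0 + yr/nr)) / xr`.
#'
#' @param ref A [reference_set()].
#' @param phi Dispersion index (from the discarded curve or consensus; never
#'   estimated from the reference samples themselves).
#' @return A linear [calibration_curve()] with `source =
#'   "reference_derived"`, passing exactly through `(0, y0)` and
#'   `(xr, yr)`. A zero-slope curve (when `yr == y0`) is returned with a
#'   `ZERO_SLOPE` warning code attached.
#' @examples
#' ref <- reference_set(0.4625, 400, 5.02, 200, 1.5)
#' build_reference_curve(ref, phi = 60)
#' @export
build_reference_curve <- function(ref, phi = 60) {
  stopifnot(inherits(ref, "h2ax_refset"))
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi <= 0) {
    abort("`phi` must be a single positive number.", class = "h2ax_input_error")
  }
  slope <- (ref$yr - ref$y0) / ref$xr
  curve <- calibration_curve(
    intercept = ref$y0,
    slope = slope,
    se_intercept = sqrt(phi * ref$y0 / ref$n0),
    se_slope = sqrt(phi * (ref$y0 / ref$n0 + ref$yr / ref$nr)) / ref$xr,
    phi = phi,
    source = "reference_derived"
  )
  if (slope == 0) curve <- add_curve_warning(curve, "ZERO_SLOPE")
  curve
}

#' Reference sample ratio (diagnostic)
#'
#' The ratio of the calibration-curve yield at the positive-control dose to
#' the observed positive-control yield, `(A + B*xr) / yr`. Reference yields
#' tend to exceed curve yields (reference samples escape shipment-related
#' focus loss), and multiplying dose estimates by this ratio has been
#' proposed as an adjustment. It is reported purely as a diagnostic here;
#' the estimation workflow never applies it.
#'
#' @inheritParams validate_curve
#' @return A single positive number.
#' @examples
#' curve_24h <- calibration_curve(0.150, 1.956, phi = 60)
#' reference_sample_ratio(curve_24h, reference_set(0.4625, 400, 2.92, 200))
#' @export
reference_sample_ratio <- function(curve, ref) {
  stopifnot(is_h2ax_curve(curve), inherits(ref, "h2ax_refset"))
  if (ref$yr <= 0) {
    abort("The reference sample ratio is undefined for `yr` = 0.",
          class = "h2ax_undefined_ratio")
  }
  curve_yield(curve, ref$xr) / ref$yr
}
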