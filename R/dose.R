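#' Estimate dose from observed yields by inverse regression
#'
#' Inverts a linear calibration curve at each observed yield,
#' `x* = (y* - A) / B`, and quantifies the uncertainty with the
#' covariance-free delta method used in the MULTIBIODOSE framework:
#'
#' `SE^2(x*) = SE^2(A)/B^2 + (y* - A)^2 SE^2(B)/B^4 + phi * y* / (n* B^2)`
#'
#' The three summands — intercept, slope, and sampling contributions — are
#' returned alongside the total so the dominant uncertainty source is
#' visible per sample. Negative dose estimates are returned as-is (they are
#' consistent with an unexposed sample and are flagged, never clipped).
#'
#' @param samples Data frame of customer samples with columns `yield`
#'   (foci/cell) and `n_cells` (cells scored); extra columns are carried
#'   through.
#' @param curve A linear [calibration_curve()].
#' @param phi Dispersion index. Default `NULL` resolves to the curve's
#'   fitted value, falling back to the consensus 60 with a `DEFAULT_PHI`
#'   warning code.
#' @param conf_mult Multiplier for the reported interval
#'   `x* +/- conf_mult * SE` (default 1.96, an approximate 95% interval).
#' @return A tibble with one row per sample: the inputs plus `x_star`,
#'   `se_x_star`, `ci_lo`, `ci_hi`, the additive variance components
#'   `var_intercept`, `var_slope`, `var_sampling`, and a `warnings`
#'   list-column of machine-readable codes.
#' @examples
#' curve_24h <- calibration_curve(0.150, 1.956, 0.013, 0.037, phi = 60)
#' estimate_dose(tibble::tibble(yield = 0.77, n_cells = 200), curve_24h)
#' @export
estimate_dose <- function(samples, curve, phi = NULL, conf_mult = 1.96) {
  samples <- validate_customer_samples(samples)
  stopifnot(is_h2ax_curve(curve))
  if (curve$model_form != "linear") {
    abort("Dose estimation supports linear curves only (quadratic curves are for decomposition demonstrations).",
          class = "h2ax_unsupported_inversion")
  }
  if (curve$slope == 0) {
    abort("Curve slope is zero: the curve cannot be inverted.",
          class = "h2ax_non_invertible")
  }
  res <- resolve_phi(phi, curve)
  comp <- purrr::map2(samples$yield, samples$n_cells, function(y, n) {
    dose_components(curve, y, n, res$phi)
  })
  out <- dplyr::mutate(
    samples,
    x_star = (samples$yield - curve$intercept) / curve$slope,
    var_intercept = purrr::map_dbl(comp, "var_intercept"),
    var_slope = purrr::map_dbl(comp, "var_slope"),
    var_sampling = purrr::map_dbl(comp, "var_sampling")
  )
  out$se_x_star <- sqrt(out$var_intercept + out$var_slope + out$var_sampling)
  out$ci_lo <- out$x_star - conf_mult * out$se_x_star
  out$ci_hi <- out$x_star + conf_mult * out$se_x_star
  base_warn <- union(res$warnings, comp[[1]]$warnings)
  out$warnings <- purrr::map(out$x_star, function(x) {
    if (x < 0) union(base_warn, "BELOW_ZERO") else base_warn
  })
  out
}

# Variance components of one inverse-regression estimate. Missing (NA)
# parameter SEs contribute 0 with a MISSING_SE code, mirroring the applet.
dose_components <- function(curve, yield, n_star, phi) {
  warnings <- character()
  se_a <- curve$se_intercept
  se_b <- curve$se_slope
  if (is.na(se_a) || is.na(se_b)) {
    warnings <- "MISSING_SE"
    se_a <- if (is.na(se_a)) 0 else se_a
    se_b <- if (is.na(se_b)) 0 else se_b
  }
  B <- curve$slope
  if (is.null(curve$quad)) {
    list(
      var_intercept = se_a^2 / B^2,
      var_slope = (yield - curve$intercept)^2 * se_b^2 / B^4,
      var_sampling = phi * yield / (n_star * B^2),
      warnings = warnings
    )
  } else {
    se_c <- curve$se_quad
    if (is.na(se_c)) {
      warnings <- "MISSING_SE"
      se_c <- 0
    }
    x <- invert_quadratic(curve, yield)
    # implicit differentiation of A + Bx + Cx^2 = y*
    denom <- B + 2 * curve$quad * x
    list(
      var_intercept = se_a^2 / denom^2,
      var_slope = x^2 * se_b^2 / denom^2,
      var_quad = x^4 * se_c^2 / denom^2,
      var_sampling = phi * yield / (n_star * denom^2),
      warnings = warnings
    )
  }
}

# Root of C x^2 + B x + (A - y*) = 0; for a saturating curve (C < 0) the
# smaller positive root is the physical branch below saturation.
invert_quadratic <- function(curve, yield) {
  A <- curve$intercept; B <- curve$slope; C <- curve$quad
  disc <- B^2 - 4 * C * (A - yield)
  if (disc < 0) {
    abort("Yield exceeds the saturation level of the quadratic curve.",
          class = "h2ax_non_invertible")
  }
  roots <- c((-B + sqrt(disc)) / (2 * C), (-B - sqrt(disc)) / (2 * C))
  pos <- roots[roots >= 0]
  if (length(pos) == 0) return(max(roots))
  min(pos)
}

#' Decompose dose-estimate variance over a grid of yields
#'
#' Evaluates the additive delta-method variance components (intercept,
#' slope, optional quadratic term, sampling) of the dose estimate over a
#' grid of yields, for a fixed number of scored cells and dispersion. For
#' quadratic curves the inversion root and partial derivatives come from
#' implicit differentiation; the quadratic term's variance typically swamps
#' all other uncertainty sources, which is the argument for preferring
#' linear calibration curves.
#'
#' @param curve Linear or quadratic [calibration_curve()].
#' @param yields Non-empty numeric vector of yields (foci/cell).
#' @param n_star Number of cells scored for the hypothetical sample.
#' @param phi Dispersion index (default resolves as in [estimate_dose()]).
#' @return A tibble with one row per yield: `yield`, `x_star`, the
#'   `var_*` components, and `var_total`.
#' @examples
#' curve_24h <- calibration_curve(0.150, 1.956, 0.013, 0.037, phi = 60)
#' variance_decomposition(curve_24h, yields = 0:5, n_star = 500)
#' @export
variance_decomposition <- function(curve, yields, n_star, phi = NULL) {
  stopifnot(is_h2ax_curve(curve))
  if (length(yields) == 0) {
    abort("`yields` must be non-empty.", class = "h2ax_input_error")
  }
  res <- resolve_phi(phi, curve)
  rows <- purrr::map(yields, function(y) {
    comp <- dose_components(curve, y, n_star, res$phi)
    x <- if (is.null(curve$quad)) {
      (y - curve$intercept) / curve$slope
    } else {
      invert_quadratic(curve, y)
    }
    vars <- comp[startsWith(names(comp), "var_")]
    tibble(yield = y, x_star = x, !!!vars,
           var_total = sum(unlist(vars)))
  })
  dplyr::bind_rows(rows)
}

# phi resolution order: explicit argument > curve's fitted phi > consensus 60
# (with a DEFAULT_PHI warning code).
resolve_phi <- function(phi, curve, default = 60) {
  if (!is.null(phi)) {
    if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi <= 0) {
      abort("`phi` must be a single positive number.",
            class = "h2ax_input_error")
    }
    return(list(phi = phi, warnings = character()))
  }
  if (!is.na(curve$phi)) return(list(phi = curve$phi, warnings = character()))
  list(phi = default, warnings = "DEFAULT_PHI")
}

validate_customer_samples <- function(samples) {
  if (!is.data.frame(samples)) {
    abort("`samples` must be a data frame.", class = "h2ax_input_error")
  }
  samples <- as_tibble(samples)
  if (!all(c("yield", "n_cells") %in% names(samples))) {
    abort("`samples` needs columns `yield` and `n_cells`.",
          class = "h2ax_input_error")
  }
  if (nrow(samples) == 0) {
    abort("`samples` must have at least one row.", class = "h2ax_input_error")
  }
  if (any(!is.finite(samples$yield)) || any(samples$yield < 0)) {
    abort("Yields must be finite and non-negative.", class = "h2ax_input_error")
  }
  if (any(samples$n_cells < 1)) {
    abort("`n_cells` must be at least 1.", class = "h2ax_input_error")
  }
  samples
}
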