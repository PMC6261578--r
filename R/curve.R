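#' Construct a calibration curve object
#'
#' A calibration curve is the information needed to translate an observed
#' focus yield (foci per cell) into an absorbed dose: the dose-response
#' parameters of the linear model `E(y) = A + B * dose` (optionally with a
#' quadratic term `C * dose^2`), their dispersion-corrected standard errors,
#' and the dispersion index `phi` of the focus counts. Curves are produced by
#' [fit_calibration()] and [fit_joint_model()], read from disk by
#' [read_curve()], derived from reference samples by
#' [build_reference_curve()], or entered directly from published parameter
#' tables with this constructor.
#'
#' @param intercept Background yield `A` at 0 Gy, in foci per cell.
#' @param slope Dose-response slope `B`, in foci per cell per Gy.
#' @param se_intercept,se_slope Standard errors of `A` and `B` (already
#'   dispersion-corrected). Use `NA` when unknown; downstream estimation then
#'   substitutes 0 and flags the result with a `MISSING_SE` warning code.
#' @param quad,se_quad Optional quadratic coefficient `C` (foci/cell/Gy^2)
#'   and its standard error; supplying `quad` makes the curve quadratic.
#' @param phi Dispersion index of the focus counts (variance/mean ratio).
#'   `NA` means unknown; the workflow then falls back to the consensus
#'   default 60 with a `DEFAULT_PHI` warning code.
#' @param time_label Optional tag for the time after exposure the curve
#'   refers to (e.g. `"1h"`, `"24h"`).
#' @param fit_df Residual degrees of freedom `N - p` of the fit, if known.
#' @param source Provenance of the parameters: `"fitted"`,
#'   `"user_supplied"`, or `"reference_derived"`.
#'
#' @return An object of class `h2ax_curve`.
#' @examples
#' # The published PHE 24h curve (joint model)
#' curve_24h <- calibration_curve(0.150, 1.956,
#'   se_intercept = 0.013, se_slope = 0.037, phi = 60, time_label = "24h"
#' )
#' curve_24h
#' @export
calibration_curve <- function(intercept, slope,
                              se_intercept = NA_real_, se_slope = NA_real_,
                              quad = NULL, se_quad = NA_real_,
                              phi = NA_real_, time_label = NA_character_,
                              fit_df = NA_integer_,
                              source = c("user_supplied", "fitted",
                                         "reference_derived")) {
  source <- match.arg(source)
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(slope), length(slope) == 1)
  for (se in list(se_intercept, se_slope, se_quad)) {
    if (!is.na(se) && se < 0) {
      abort("Standard errors must be non-negative.", class = "h2ax_input_error")
    }
  }
  if (!is.na(phi) && phi < 0) {
    # phi = 0 can arise from a perfect (zero-residual) fit
    abort("`phi` must be non-negative.", class = "h2ax_input_error")
  }
  structure(
    list(
      intercept = as.numeric(intercept),
      slope = as.numeric(slope),
      quad = if (is.null(quad)) NULL else as.numeric(quad),
      se_intercept = as.numeric(se_intercept),
      se_slope = as.numeric(se_slope),
      se_quad = if (is.null(quad)) NULL else as.numeric(se_quad),
      phi = as.numeric(phi),
      model_form = if (is.null(quad)) "linear" else "quadratic",
      time_label = as.character(time_label),
      fit_df = as.integer(fit_df),
      source = source
    ),
    class = "h2ax_curve"
  )
}

is_h2ax_curve <- function(x) inherits(x, "h2ax_curve")

#' Evaluate a calibration curve at given doses
#'
#' @param curve An [calibration_curve()] object.
#' @param dose Numeric vector of doses in Gy.
#' @return Numeric vector of expected yields (foci/cell).
#' @export
curve_yield <- function(curve, dose) {
  stopifnot(is_h2ax_curve(curve))
  y <- curve$intercept + curve$slope * dose
  if (!is.null(curve$quad)) y <- y + curve$quad * dose^2
  y
}

#' @export
print.h2ax_curve <- function(x, ...) {
  fmt <- function(est, se) {
    if (is.null(est)) return(NULL)
    if (is.na(se)) sprintf("%.3f (se n/a)", est) else sprintf("%.3f (%.3f)", est, se)
  }
  cat("<h2ax_curve> ", x$model_form,
      if (!is.na(x$time_label)) paste0(", ", x$time_label), ", ", x$source, "\n",
      sep = "")
  cat("  A (foci/cell):     ", fmt(x$intercept, x$se_intercept), "\n", sep = "")
  cat("  B (foci/cell/Gy):  ", fmt(x$slope, x$se_slope), "\n", sep = "")
  if (!is.null(x$quad)) {
    cat("  C (foci/cell/Gy2): ", fmt(x$quad, x$se_quad), "\n", sep = "")
  }
  cat("  dispersion phi:    ",
      if (is.na(x$phi)) "unknown (consensus 60 used downstream)"
      else sprintf("%.1f", x$phi), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.h2ax_curve <- function(x, ...) {
  tibble(
    model_form = x$model_form,
    time_label = x$time_label,
    intercept = x$intercept,
    slope = x$slope,
    quad = if (is.null(x$quad)) NA_real_ else x$quad,
    se_intercept = x$se_intercept,
    se_slope = x$se_slope,
    se_quad = if (is.null(x$quad)) NA_real_ else x$se_quad,
    phi = x$phi,
    fit_df = x$fit_df,
    source = x$source
  )
}

# Internal: curve warnings accumulated by IO/workflow (character codes).
curve_warnings <- function(curve) attr(curve, "h2ax_warnings") %||% character()

add_curve_warning <- function(curve, code) {
  attr(curve, "h2ax_warnings") <- union(curve_warnings(curve), code)
  curve
}
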