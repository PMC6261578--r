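#' Workflow configuration
#'
#' Collects the tunable constants of the estimation workflow: the consensus
#' dispersion used when none is supplied (60, a conservative value for
#' manually scored focus counts), the critical multipliers of the two
#' validation intervals, and the multiplier of the reported dose interval.
#'
#' @param phi_default Dispersion index substituted when neither the call nor
#'   the curve provides one.
#' @param q_neg,q_pos Critical multipliers for the negative/positive control
#'   prediction intervals (see [validate_curve()]).
#' @param ci_multiplier Multiplier of the reported interval
#'   `x* +/- ci_multiplier * SE(x*)`.
#' @return A list of class `h2ax_config`.
#' @export
workflow_config <- function(phi_default = 60, q_neg = 3, q_pos = 2,
                            ci_multiplier = 1.96) {
  stopifnot(phi_default > 0, q_neg > 0, q_pos > 0, ci_multiplier > 0)
  structure(list(phi_default = phi_default, q_neg = q_neg, q_pos = q_pos,
                 ci_multiplier = ci_multiplier),
            class = "h2ax_config")
}

#' Resolve which curve to use for dose estimation
#'
#' Implements the decision logic of the estimation applet for a single
#' stratum: fit the calibration data if supplied (data win over an
#' explicitly supplied curve, since a fitted curve carries its own standard
#' errors and dispersion); validate against reference samples if available;
#' on rejection replace the curve by the two-point reference curve; without
#' reference samples use the curve uncontested but warn. Every default
#' substitution (missing standard errors set to 0, missing dispersion set to
#' the consensus default) emits a machine-readable warning code.
#'
#' @param curve Optional [calibration_curve()] (e.g. published parameters).
#' @param calibration_data Optional calibration data frame (single time
#'   stratum) to fit a curve from.
#' @param ref Optional [reference_set()] scored under the customer's
#'   conditions.
#' @param config A [workflow_config()].
#' @return An object of class `h2ax_resolved`: list with `curve`, `phi`
#'   (the dispersion that will be used downstream), `provenance` (one of
#'   `"validated_calibration"`, `"reference_curve"`,
#'   `"unvalidated_calibration"`), `warnings` (character codes), and
#'   `validation` (the [validate_curve()] result, or `NULL`).
#' @examples
#' curve_1h <- calibration_curve(0.150, 12.518, 0.013, 0.158, phi = 60)
#' ref <- reference_set(0.4625, 400, 5.02, 200, 1.5)
#' resolve_curve(curve_1h, ref = ref)$provenance
#' @export
resolve_curve <- function(curve = NULL, calibration_data = NULL, ref = NULL,
                          config = workflow_config()) {
  if (is.null(curve) && is.null(calibration_data)) {
    abort("Supply a curve or calibration data.", class = "h2ax_input_error")
  }
  warnings <- character()
  if (!is.null(calibration_data)) {
    if (!is.null(curve)) warnings <- c(warnings, "DATA_OVERRIDES_CURVE")
    fit <- fit_calibration(calibration_data)
    curve <- fit$curve
  }
  warnings <- union(warnings, curve_warnings(curve))
  # dispersion: curve's own value, else the configured consensus (warn)
  if (is.na(curve$phi)) {
    phi <- config$phi_default
    warnings <- union(warnings, "DEFAULT_PHI")
  } else {
    phi <- curve$phi
  }
  if (is.na(curve$se_intercept) || is.na(curve$se_slope)) {
    curve$se_intercept <- if (is.na(curve$se_intercept)) 0 else curve$se_intercept
    curve$se_slope <- if (is.na(curve$se_slope)) 0 else curve$se_slope
    warnings <- union(warnings, "MISSING_SE")
  }
  validation <- NULL
  if (is.null(ref)) {
    provenance <- "unvalidated_calibration"
    warnings <- union(warnings, "NO_REFERENCE")
  } else {
    validation <- validate_curve(curve, ref, phi = phi,
                                 q_neg = config$q_neg, q_pos = config$q_pos)
    if (validation$decision == "accept") {
      provenance <- "validated_calibration"
    } else {
      curve <- build_reference_curve(ref, phi = phi)
      provenance <- "reference_curve"
      warnings <- union(warnings, curve_warnings(curve))
    }
  }
  structure(
    list(curve = curve, phi = phi, provenance = provenance,
         warnings = warnings, validation = validation, config = config),
    class = "h2ax_resolved"
  )
}

#' @export
print.h2ax_resolved <- function(x, ...) {
  cat("<h2ax_resolved> provenance:", x$provenance, "\n")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = ", "), "\n")
  print(x$curve)
  invisible(x)
}

#' Run the full dose-estimation workflow
#'
#' Resolves the curve to use (per time stratum when several curves are
#' supplied), then produces a dose estimate with delta-method standard
#' error and interval for every customer sample. The result records, per
#' sample, which curve was used (`provenance`) and any warning codes raised
#' while resolving it.
#'
#' @param samples Data frame of customer samples: columns `yield` and
#'   `n_cells`, plus `time` when per-time curves are supplied.
#' @param curve A single [calibration_curve()], or a named list of curves
#'   keyed by time label. A sample whose time label has no matching curve is
#'   an error, never a silent fallback.
#' @param calibration_data Optional calibration data to fit curves from
#'   (single stratum, or with a `time` column for per-label fits).
#' @param ref Optional [reference_set()] or named list of reference sets
#'   keyed by time label.
#' @param config A [workflow_config()].
#' @return A tibble of class `h2ax_report`: one row per sample with
#'   `x_star`, `se_x_star`, `ci_lo`, `ci_hi`, the variance components,
#'   `provenance`, and `warnings` (list-column). The per-stratum
#'   [resolve_curve()] results are attached as attribute `"resolved"`.
#' @examples
#' curve_24h <- calibration_curve(0.150, 1.956, 0.013, 0.037, phi = 60)
#' ref <- reference_set(0.4625, 400, 2.92, 200, 1.5)
#' run_dose_estimation(
#'   tibble::tibble(yield = c(0.32, 0.77), n_cells = 200),
#'   curve = curve_24h, ref = ref
#' )
#' @export
run_dose_estimation <- function(samples, curve = NULL, calibration_data = NULL,
                                ref = NULL, config = workflow_config()) {
  samples <- validate_customer_samples(samples)
  multi <- is.list(curve) && !is_h2ax_curve(curve)
  if (!multi && !"time" %in% names(samples)) {
    resolved <- resolve_curve(curve, calibration_data, ref, config)
    out <- estimate_with_resolved(samples, resolved, config)
    return(structure(out, resolved = list(resolved), config = config,
                     class = c("h2ax_report", class(out))))
  }
  # per-time strata
  if (!"time" %in% names(samples)) {
    abort("Per-time curves supplied but `samples` has no `time` column.",
          class = "h2ax_input_error")
  }
  labels <- unique(samples$time)
  samples$.row <- seq_len(nrow(samples))
  resolved_list <- list()
  parts <- list()
  for (lab in labels) {
    cv <- if (multi) {
      if (!lab %in% names(curve)) {
        abort(paste0("No curve supplied for time label '", lab, "'."),
              class = "h2ax_input_error")
      }
      curve[[lab]]
    } else curve
    cd <- if (!is.null(calibration_data) && "time" %in% names(calibration_data)) {
      calibration_data[calibration_data$time == lab, , drop = FALSE]
    } else calibration_data
    rf <- if (is.list(ref) && !inherits(ref, "h2ax_refset")) ref[[lab]] else ref
    resolved <- resolve_curve(cv, cd, rf, config)
    resolved_list[[lab]] <- resolved
    parts[[lab]] <- estimate_with_resolved(
      samples[samples$time == lab, , drop = FALSE], resolved, config
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(parts), .data$.row)
  out$.row <- NULL
  structure(out, resolved = resolved_list, config = config,
            class = c("h2ax_report", class(out)))
}

estimate_with_resolved <- function(samples, resolved, config) {
  out <- estimate_dose(samples, resolved$curve, phi = resolved$phi,
                       conf_mult = config$ci_multiplier)
  out$provenance <- resolved$provenance
  out$warnings <- purrr::map(out$warnings, union, resolved$warnings)
  out
}

#' @export
print.h2ax_report <- function(x, ...) {
  cat("<h2ax_report>", nrow(x), "dose estimate(s)\n")
  NextMethod()
  invisible(x)
}
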