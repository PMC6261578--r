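#' Analysis of deviance for a donor effect
#'
#' Tests whether inter-donor variation adds explanatory power beyond dose
#' and time after exposure. Identity-link Poisson models are fitted
#' sequentially — intercept only, `+ dose`, `+ dose:time`, `+ donor` — and
#' the deviance explained by the donor factor, scaled by the Pearson
#' dispersion estimate of the full model, is referred to a chi-squared
#' distribution with (number of donors − 1) degrees of freedom. A large
#' p-value indicates that intra-individual variation (captured by the
#' dispersion index) swamps the inter-individual variation, so donors need
#' not be modelled explicitly.
#'
#' @param data Calibration data frame with columns `dose_gy`, `n_cells`,
#'   `focus_count`, `donor`, and optionally `time` (two labels at most; when
#'   present, the dose-by-time interaction of the joint model is included
#'   before the donor term).
#' @return An object of class `h2ax_devtest`: a list with the sequential
#'   deviance `table` (source, df, deviance explained, residual deviance),
#'   the scaled `statistic`, its `df`, the `p_value`, and the dispersion
#'   `phi` used for scaling. `tidy()` returns the table.
#' @examples
#' d <- simulate_calibration(seed = 4, donors = 6, donor_sd = 0)
#' donor_effect_test(d)$p_value
#' @export
donor_effect_test <- function(data) {
  data <- validate_calibration_data(data)
  if (!"donor" %in% names(data)) {
    abort("donor_effect_test() needs a `donor` column.",
          class = "h2ax_input_error")
  }
  donor <- factor(data$donor)
  if (nlevels(donor) < 2) {
    abort("The donor factor needs at least 2 levels.",
          class = "h2ax_input_error")
  }
  has_time <- "time" %in% names(data) && length(unique(data$time)) > 1
  one <- rep(1, nrow(data))
  mats <- list(`1` = cbind(`(Intercept)` = one))
  mats$dose <- cbind(mats$`1`, dose = data$dose_gy)
  if (has_time) {
    labels <- sort(unique(data$time))
    if (length(labels) != 2) {
      abort("At most two time labels are supported.", class = "h2ax_input_error")
    }
    mats$time <- cbind(mats$dose,
                       `dose:time2` = data$dose_gy * (data$time == labels[2]))
  }
  donor_dummies <- stats::model.matrix(~donor)[, -1, drop = FALSE]
  mats$donor <- cbind(mats[[length(mats)]], donor_dummies)

  fits <- lapply(mats, function(X) qp_irls(X, data$focus_count, data$n_cells))
  resid_dev <- vapply(fits, `[[`, numeric(1), "deviance")
  dfs <- vapply(mats, ncol, integer(1))
  full <- fits[[length(fits)]]
  phi <- estimate_dispersion(data, full$mu, n_params = unname(dfs[length(dfs)]))

  tbl <- tibble(
    source = names(mats),
    df = c(1L, diff(dfs)),
    deviance_explained = c(NA_real_, unname(-diff(resid_dev))),
    residual_deviance = unname(resid_dev)
  )
  donor_dev <- unname(tbl$deviance_explained[tbl$source == "donor"])
  donor_df <- nlevels(donor) - 1L
  statistic <- max(donor_dev, 0) / phi
  structure(
    list(table = tbl, statistic = statistic, df = donor_df,
         p_value = pchisq(statistic, donor_df, lower.tail = FALSE),
         phi = phi),
    class = "h2ax_devtest"
  )
}

#' @export
tidy.h2ax_devtest <- function(x, ...) x$table

#' @export
glance.h2ax_devtest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         dispersion = x$phi)
}

#' @export
print.h2ax_devtest <- function(x, ...) {
  cat("<h2ax_devtest> analysis of deviance (identity-link Poisson)\n")
  print(x$table)
  cat(sprintf("donor: Delta(Dev)/phi = %.2f on %d df, p = %.3f (phi = %.2f)\n",
              x$statistic, x$df, x$p_value, x$phi))
  invisible(x)
}
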