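#' Fit an identity-link quasi-Poisson calibration curve
#'
#' Fits the dose-response model `E(y) = A + B * dose` (or
#' `A + B * dose + C * dose^2`) to focus yields by Fisher scoring on the
#' absolute counts, with the number of scored cells entering as a weight.
#' The quasi-Poisson score equations do not involve the dispersion, so the
#' point estimates coincide with a plain Poisson fit; the dispersion index
#' is estimated afterwards from the Pearson statistic
#' (`sum((Y - n*mu)^2 / (n*mu)) / (N - p)`) and inflates the Poisson-based
#' standard errors by its square root.
#'
#' @param data A data frame of scored samples with columns `dose_gy`,
#'   `n_cells`, and `focus_count` (total foci over the `n_cells` cells);
#'   optional columns `time`, `donor`, `scorer`. One row per sample.
#' @param model_form `"linear"` or `"quadratic"`. Quadratic fits require at
#'   least three distinct doses and are supported for dispersion diagnostics
#'   and variance decomposition, not for routine dose estimation.
#' @param time_label Optional label recorded on the returned curve. When
#'   `data` has a `time` column, the fit is restricted to that label.
#' @param max_iter,tol Fisher-scoring iteration cap and relative-change
#'   convergence tolerance.
#'
#' @return An object of class `h2ax_fit` with components `curve` (an
#'   [calibration_curve()]), `coefficients`, `se_poisson` (uncorrected,
#'   Poisson-based), `se` (dispersion-corrected), `phi`, `vcov_poisson`,
#'   `fitted` (per-row mean yields), `deviance` (Poisson deviance on
#'   counts), `df_residual`, and the input `data`. Use [tidy()] and
#'   [glance()] for tabular summaries.
#' @examples
#' d <- simulate_calibration(seed = 1)
#' fit <- fit_calibration(dplyr::filter(d, time == "24h"), time_label = "24h")
#' tidy(fit)
#' glance(fit)
#' @export
fit_calibration <- function(data, model_form = c("linear", "quadratic"),
                            time_label = NULL, max_iter = 100, tol = 1e-8) {
  model_form <- match.arg(model_form)
  data <- validate_calibration_data(data)
  if (!is.null(time_label) && "time" %in% names(data)) {
    data <- data[data$time == time_label, , drop = FALSE]
    if (nrow(data) == 0) {
      abort(paste0("No rows with time label '", time_label, "'."),
            class = "h2ax_input_error")
    }
  }
  if (is.null(time_label) && "time" %in% names(data) &&
      length(unique(data$time)) > 1) {
    abort("Multiple time labels present; supply `time_label` or use fit_joint_model().",
          class = "h2ax_input_error")
  }
  n_doses <- length(unique(data$dose_gy))
  min_doses <- if (model_form == "linear") 2L else 3L
  if (n_doses < min_doses) {
    abort(sprintf("%s fit needs at least %d distinct doses (got %d).",
                  model_form, min_doses, n_doses),
          class = "h2ax_input_error")
  }
  X <- if (model_form == "linear") {
    cbind(`(Intercept)` = 1, dose = data$dose_gy)
  } else {
    cbind(`(Intercept)` = 1, dose = data$dose_gy, dose2 = data$dose_gy^2)
  }
  fit <- qp_irls(X, data$focus_count, data$n_cells,
                 max_iter = max_iter, tol = tol)
  p <- ncol(X)
  phi <- estimate_dispersion(data, fit$mu, n_params = p)
  # a perfect fit gives phi = 0 and hence zero corrected SEs
  se <- if (phi > 0) correct_standard_errors(fit$se_poisson, phi)
        else fit$se_poisson * 0
  label <- if (!is.null(time_label)) time_label
           else if ("time" %in% names(data)) unique(data$time)[1]
           else NA_character_
  curve <- calibration_curve(
    intercept = fit$beta[1], slope = fit$beta[2],
    se_intercept = se[1], se_slope = se[2],
    quad = if (model_form == "quadratic") fit$beta[3] else NULL,
    se_quad = if (model_form == "quadratic") se[3] else NA_real_,
    phi = phi, time_label = label,
    fit_df = nrow(data) - p, source = "fitted"
  )
  structure(
    list(curve = curve, coefficients = fit$beta,
         se_poisson = fit$se_poisson, se = se, phi = phi,
         vcov_poisson = fit$vcov, fitted = fit$mu,
         deviance = fit$deviance, df_residual = nrow(data) - p,
         iterations = fit$iterations, converged = fit$converged,
         model_form = model_form, data = data),
    class = "h2ax_fit"
  )
}

#' Fit the joint two-time calibration model
#'
#' Fits `E(y) = a + b1 * dose + b2 * dose * 1{time == second label}` across
#' two time-after-exposure strata, sharing the background yield `a`: in the
#' absence of exposure the time after irradiation is meaningless, so the
#' intercept must be common. The first (alphabetically ordered) time label is
#' the baseline; its curve has slope `b1`, the second label's slope is
#' `b1 + b2`, with the slope standard error of the second curve obtained
#' from the full covariance of `(b1, b2)`.
#'
#' @inheritParams fit_calibration
#' @return An object of class `c("h2ax_joint_fit", "h2ax_fit")`; the
#'   `curves` component is a named list of per-time [calibration_curve()]
#'   objects sharing the fitted intercept.
#' @examples
#' d <- simulate_calibration(seed = 1)
#' jf <- fit_joint_model(d)
#' tidy(jf)
#' @export
fit_joint_model <- function(data, max_iter = 100, tol = 1e-8) {
  data <- validate_calibration_data(data)
  if (!"time" %in% names(data)) {
    abort("fit_joint_model() needs a `time` column.", class = "h2ax_input_error")
  }
  labels <- sort(unique(data$time))
  if (length(labels) != 2) {
    abort(sprintf("fit_joint_model() needs exactly 2 time labels (got %d).",
                  length(labels)),
          class = "h2ax_input_error")
  }
  ind2 <- as.numeric(data$time == labels[2])
  X <- cbind(`(Intercept)` = 1, dose = data$dose_gy,
             `dose:time2` = data$dose_gy * ind2)
  if (qr(X)$rank < 3) {
    abort("Dose and dose-by-time columns are collinear.",
          class = "h2ax_input_error")
  }
  fit <- qp_irls(X, data$focus_count, data$n_cells,
                 max_iter = max_iter, tol = tol)
  phi <- estimate_dispersion(data, fit$mu, n_params = 3L)
  se <- if (phi > 0) correct_standard_errors(fit$se_poisson, phi)
        else fit$se_poisson * 0
  # slope of the second stratum is b1 + b2; its variance needs cov(b1, b2)
  v2 <- phi * (fit$vcov[2, 2] + fit$vcov[3, 3] + 2 * fit$vcov[2, 3])
  curves <- list(
    calibration_curve(fit$beta[1], fit$beta[2], se[1], se[2],
                      phi = phi, time_label = labels[1],
                      fit_df = nrow(data) - 3L, source = "fitted"),
    calibration_curve(fit$beta[1], fit$beta[2] + fit$beta[3], se[1], sqrt(v2),
                      phi = phi, time_label = labels[2],
                      fit_df = nrow(data) - 3L, source = "fitted")
  )
  names(curves) <- labels
  structure(
    list(curves = curves, curve = curves[[1]], coefficients = fit$beta,
         se_poisson = fit$se_poisson, se = se, phi = phi,
         vcov_poisson = fit$vcov, fitted = fit$mu,
         deviance = fit$deviance, df_residual = nrow(data) - 3L,
         iterations = fit$iterations, converged = fit$converged,
         model_form = "joint", time_labels = labels, data = data),
    class = c("h2ax_joint_fit", "h2ax_fit")
  )
}

#' Estimate the dispersion index from a fitted model
#'
#' Pearson-statistic estimate of the dispersion (variance/mean ratio) of the
#' focus counts: `sum((Y - n*mu)^2 / (n*mu)) / (N - p)`, with `Y` the
#' absolute counts, `n` the cells scored per sample, `mu` the fitted mean
#' yields, `N` the number of samples and `p` the number of mean parameters.
#'
#' @param data Calibration data frame (columns `n_cells`, `focus_count`).
#' @param fitted_means Fitted mean yields (foci/cell), one per row of `data`.
#' @param n_params Number of mean parameters `p` (2 linear, 3 quadratic or
#'   joint; add 1 per extra model term).
#' @return The dispersion estimate (a single positive number; 0 for a
#'   perfect fit).
#' @examples
#' d <- tibble::tibble(dose_gy = c(0, 1), n_cells = 10, focus_count = c(12, 30))
#' estimate_dispersion(d, fitted_means = c(1.0, 3.2), n_params = 0)
#' @export
estimate_dispersion <- function(data, fitted_means, n_params) {
  data <- validate_calibration_data(data)
  if (length(fitted_means) != nrow(data)) {
    abort("`fitted_means` must have one value per row of `data`.",
          class = "h2ax_input_error")
  }
  if (any(fitted_means <= 0)) {
    abort("All fitted means must be positive.", class = "h2ax_input_error")
  }
  N <- nrow(data)
  if (N - n_params <= 0) {
    abort("Dispersion is undefined: N - p must be positive.",
          class = "h2ax_undefined_dispersion")
  }
  y <- data$focus_count / data$n_cells
  sum(data$n_cells * (y - fitted_means)^2 / fitted_means) / (N - n_params)
}

#' Dispersion-correct Poisson standard errors
#'
#' Under the quasi-Poisson model the point estimates equal the Poisson ones
#' but their standard errors must be inflated by the square root of the
#' dispersion index: `SE = sqrt(phi) * SE_P`.
#'
#' @param poisson_se Non-negative numeric vector of Poisson-based standard
#'   errors (square roots of the diagonal of the inverse Fisher information).
#' @param phi Positive dispersion index.
#' @return Corrected standard errors, same length as `poisson_se`.
#' @examples
#' correct_standard_errors(0.1, phi = 60)
#' @export
correct_standard_errors <- function(poisson_se, phi) {
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi <= 0) {
    abort("`phi` must be a single positive number.", class = "h2ax_input_error")
  }
  if (any(poisson_se < 0, na.rm = TRUE)) {
    abort("Standard errors must be non-negative.", class = "h2ax_input_error")
  }
  sqrt(phi) * poisson_se
}

# ---------------------------------------------------------------------------
# Core solver: identity-link Poisson/quasi-Poisson Fisher scoring on counts.
#
# Score equations (yield scale, weight n per sample):
#   sum_i n_i * x_i * (y_i - mu_i) / mu_i = 0,   mu_i = X beta
# Fisher scoring with identity link reduces to iteratively reweighted least
# squares with working weights W = n / mu and working response y itself.
# Steps are halved until all fitted means stay positive (the score divides
# by mu); a fit that converges onto a non-positive mean fails loudly.
qp_irls <- function(X, counts, cells, max_iter = 100, tol = 1e-8) {
  y <- counts / cells
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
  if (is.null(beta) || anyNA(beta)) {
    abort("Design matrix is rank-deficient.", class = "h2ax_input_error")
  }
  mu <- drop(X %*% beta)
  if (any(mu <= 0)) {
    # shift the OLS start upward just enough to make all means positive
    shift <- -min(mu) + max(mean(y), 1e-3)
    beta[1] <- beta[1] + shift
    mu <- drop(X %*% beta)
  }
  pois_dev <- function(b) {
    m <- cells * drop(X %*% b)
    if (any(m <= 0)) return(Inf)
    2 * sum(ifelse(counts > 0, counts * log(counts / m), 0) - (counts - m))
  }
  converged <- FALSE
  iter <- 0L
  dev_old <- pois_dev(beta)
  for (iter in seq_len(max_iter)) {
    W <- cells / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% y),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      abort("Fisher scoring failed: singular weighted information matrix.",
            class = "h2ax_fit_failure")
    }
    beta_new <- drop(beta_new)
    # damp the step until fitted means stay positive and the Poisson
    # deviance does not increase (guards against oscillation when a fitted
    # mean approaches zero and the working weights blow up)
    halvings <- 0L
    while (pois_dev(beta_new) > dev_old + 1e-10 && halvings < 50L) {
      beta_new <- (beta + beta_new) / 2
      halvings <- halvings + 1L
    }
    if (halvings == 50L && !is.finite(pois_dev(beta_new))) {
      abort("Degenerate fit: fitted mean non-positive at a design dose.",
            class = "h2ax_degenerate_fit")
    }
    dev_new <- pois_dev(beta_new)
    delta <- max(abs(beta_new - beta) / pmax(abs(beta), 1e-8))
    dev_delta <- abs(dev_new - dev_old) / (abs(dev_old) + 1e-8)
    beta <- beta_new
    mu <- drop(X %*% beta)
    dev_old <- dev_new
    if (delta < tol || dev_delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf("Fisher scoring did not converge in %d iterations.", max_iter),
          class = "h2ax_fit_failure")
  }
  if (any(mu <= 0)) {
    abort("Degenerate fit: fitted mean non-positive at a design dose.",
          class = "h2ax_degenerate_fit")
  }
  info <- t(X * (cells / mu)) %*% X
  vcov <- solve(info)
  m <- cells * mu
  dev_terms <- ifelse(counts > 0, counts * log(counts / m), 0) - (counts - m)
  list(beta = setNames(drop(beta), colnames(X)),
       mu = mu, vcov = vcov,
       se_poisson = sqrt(diag(vcov)),
       deviance = 2 * sum(dev_terms),
       iterations = iter, converged = converged)
}

# ---------------------------------------------------------------------------
# broom-style methods

#' @export
tidy.h2ax_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    std.error.poisson = unname(x$se_poisson)
  )
}

#' @export
glance.h2ax_fit <- function(x, ...) {
  tibble(
    model_form = x$model_form,
    nobs = nrow(x$data),
    df.residual = x$df_residual,
    dispersion = x$phi,
    deviance = x$deviance,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
print.h2ax_fit <- function(x, ...) {
  cat("<h2ax_fit> identity-link quasi-Poisson, ", x$model_form,
      " model, N = ", nrow(x$data), "\n", sep = "")
  print(tidy(x))
  cat("dispersion phi =", format(x$phi, digits = 4), "\n")
  invisible(x)
}
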