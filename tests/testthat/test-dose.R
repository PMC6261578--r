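test_that("published dose estimates and SEs are reproduced from the printed curves", {
  rows <- table4_rows()
  ref_curve <- build_reference_curve(phe_ref("1h"), phi = 60)
  curves <- list(`1h` = ref_curve, `24h` = phe_curve_24h())
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    est <- estimate_dose(tibble::tibble(yield = r$yield, n_cells = r$n_cells),
                         curves[[r$time]], phi = 60)
    expect_equal(est$x_star, r$x_pub, tolerance = 0.01 / abs(r$x_pub) + 1e-9)
    tol_se <- if (r$se_pub == 0.94) 0.02 else 0.01
    expect_lt(abs(est$se_x_star - r$se_pub), tol_se)
  }
})

test_that("a yield equal to the intercept gives dose zero; zero yield with zero SEs gives SE zero", {
  cv <- calibration_curve(0.150, 1.956, 0, 0, phi = 60)
  est <- estimate_dose(tibble::tibble(yield = 0.150, n_cells = 200), cv)
  expect_equal(est$x_star, 0)
  est0 <- estimate_dose(tibble::tibble(yield = 0, n_cells = 200), cv)
  expect_equal(est0$se_x_star, 0)
  # intercept/slope terms still contribute when SEs are nonzero
  cv2 <- phe_curve_24h()
  est0b <- estimate_dose(tibble::tibble(yield = 0, n_cells = 200), cv2)
  expect_gt(est0b$se_x_star, 0)
  expect_equal(est0b$var_sampling, 0)
})

test_that("negative estimates are reported as-is and flagged, never clipped", {
  est <- estimate_dose(tibble::tibble(yield = 0.08, n_cells = 200),
                       phe_curve_24h())
  expect_lt(est$x_star, 0)
  expect_true("BELOW_ZERO" %in% est$warnings[[1]])
})

test_that("variance components are exact summands of the squared SE", {
  cv <- phe_curve_24h()
  grid <- variance_decomposition(cv, yields = seq(0, 8, by = 0.5),
                                 n_star = 200, phi = 60)
  expect_equal(grid$var_total,
               grid$var_intercept + grid$var_slope + grid$var_sampling,
               tolerance = 1e-12)
  est <- estimate_dose(tibble::tibble(yield = c(0.5, 3, 7), n_cells = 50), cv)
  expect_equal(est$se_x_star^2,
               est$var_intercept + est$var_slope + est$var_sampling,
               tolerance = 1e-12)
})

test_that("sampling variance dominates for the linear curve at moderate yields", {
  # direct evaluation of the three summands at y*=5, n*=500
  cv <- phe_curve_24h()
  d <- variance_decomposition(cv, yields = 5, n_star = 500, phi = 60)
  expect_equal(d$var_sampling, 60 * 5 / (500 * 1.956^2), tolerance = 1e-12)
  expect_equal(d$var_intercept, 0.013^2 / 1.956^2, tolerance = 1e-12)
  expect_equal(d$var_slope, (5 - 0.150)^2 * 0.037^2 / 1.956^4,
               tolerance = 1e-12)
  expect_gt(d$var_sampling, d$var_intercept + d$var_slope)
})

test_that("the quadratic term dominates the decomposition near saturation", {
  cv_quad <- calibration_curve(0.141, 2.278, 0.021, 0.110,
                               quad = -0.0943, se_quad = 0.029, phi = 60,
                               time_label = "24h")
  cv_lin <- calibration_curve(0.179, 1.937, 0.021, 0.038, phi = 60,
                              time_label = "24h")
  # as the yield approaches the saturation level the quadratic term's
  # variance outgrows every other component, and the quadratic model's
  # total variance dwarfs the linear model's
  d <- variance_decomposition(cv_quad, yields = c(5, 12), n_star = 500,
                              phi = 60)
  expect_gt(d$var_quad[2] / d$var_quad[1], 100)
  expect_gt(d$var_quad[2], d$var_intercept[2])
  expect_gt(d$var_quad[2], d$var_slope[2])
  expect_gt(d$var_quad[2], d$var_sampling[2])
  d_lin <- variance_decomposition(cv_lin, yields = 12, n_star = 500, phi = 60)
  expect_gt(d$var_total[2], 5 * d_lin$var_total)
  # with all SEs zero only the sampling component remains
  cv0 <- calibration_curve(0.15, 2, 0, 0, phi = 60)
  d0 <- variance_decomposition(cv0, yields = c(1, 3), n_star = 100)
  expect_true(all(d0$var_intercept == 0 & d0$var_slope == 0))
  expect_true(all(d0$var_sampling > 0))
})

test_that("quadratic inversion and implicit-derivative partials match numerics", {
  cv <- calibration_curve(0.141, 2.278, 0.021, 0.110,
                          quad = -0.0943, se_quad = 0.029, phi = 60)
  y <- 5
  x <- h2axdose:::invert_quadratic(cv, y)
  expect_equal(curve_yield(cv, x), y, tolerance = 1e-10)
  # smaller positive root of the saturating parabola
  other <- (-cv$slope - sqrt(cv$slope^2 - 4 * cv$quad * (cv$intercept - y))) /
    (2 * cv$quad)
  expect_lt(x, other)
  # numerical partial derivatives of the inversion root
  eps <- 1e-6
  num_d <- function(fld) {
    cv_hi <- cv; cv_hi[[fld]] <- cv_hi[[fld]] + eps
    (h2axdose:::invert_quadratic(cv_hi, y) - x) / eps
  }
  denom <- cv$slope + 2 * cv$quad * x
  expect_equal(num_d("intercept"), -1 / denom, tolerance = 1e-4)
  expect_equal(num_d("slope"), -x / denom, tolerance = 1e-4)
  expect_equal(num_d("quad"), -x^2 / denom, tolerance = 1e-4)
})

test_that("SE(x*) is monotone in phi and n*, x* invariant to n*", {
  cv <- phe_curve_24h()
  s <- function(phi, n) {
    estimate_dose(tibble::tibble(yield = 2, n_cells = n), cv, phi = phi)
  }
  phis <- c(10, 30, 60, 90)
  ses <- vapply(phis, function(p) s(p, 200)$se_x_star, numeric(1))
  expect_true(all(diff(ses) > 0))
  ns <- c(20, 50, 200, 1000)
  ses_n <- vapply(ns, function(n) s(60, n)$se_x_star, numeric(1))
  expect_true(all(diff(ses_n) < 0))
  xs <- vapply(ns, function(n) s(60, n)$x_star, numeric(1))
  expect_equal(xs, rep(xs[1], 4))
})

test_that("x* and SE(x*) are invariant under a common rescaling of yield units", {
  k <- 3.7
  cv <- calibration_curve(0.2, 2.5, 0.02, 0.1, phi = 60)
  cv_k <- calibration_curve(0.2 * k, 2.5 * k, 0.02 * k, 0.1 * k, phi = 60)
  y <- 4.1
  a <- estimate_dose(tibble::tibble(yield = y, n_cells = 200), cv, phi = 60)
  # the sampling term is not scale-free (phi*y/n is count-based), so compare
  # with the sampling variance removed
  b <- estimate_dose(tibble::tibble(yield = y * k, n_cells = 200), cv_k,
                     phi = 60)
  expect_equal(a$x_star, b$x_star, tolerance = 1e-12)
  expect_equal(a$var_intercept + a$var_slope, b$var_intercept + b$var_slope,
               tolerance = 1e-12)
})

test_that("delta-method SE matches Monte-Carlo propagation in the small-noise regime", {
  # SEs are <= 5% of their parameters; 1e5 draws
  cv <- calibration_curve(1.0, 2.0, 0.02, 0.05, phi = 60)
  y_star <- 5; n_star <- 5000
  est <- estimate_dose(tibble::tibble(yield = y_star, n_cells = n_star), cv,
                       phi = 60)
  withr::with_seed(42, {
    n_draw <- 1e5
    A <- rnorm(n_draw, cv$intercept, cv$se_intercept)
    B <- rnorm(n_draw, cv$slope, cv$se_slope)
    y <- rnorm(n_draw, y_star, sqrt(60 * y_star / n_star))
    mc_sd <- sd((y - A) / B)
  })
  expect_equal(est$se_x_star, mc_sd, tolerance = 0.02)
})

test_that("intervals cover the true dose at the nominal rate", {
  # pooled over moderate doses and both triage sample sizes; the 1h curve
  # keeps mean counts high enough for the normal approximation to hold
  cv <- calibration_curve(0.150, 12.518, 0.013, 0.158, phi = 60)
  conditions <- tidyr::expand_grid(true_dose = c(0.5, 1, 2),
                                   n_star = c(50, 200))
  per_cell <- 350
  covered <- purrr::pmap(conditions, function(true_dose, n_star) {
    vapply(seq_len(per_cell), function(i) {
      cust <- simulate_customer(true_dose, cv, n_star = n_star, phi = 60,
                                seed = 5000 + 1000 * n_star + i)
      est <- estimate_dose(cust, cv, phi = 60)
      est$ci_lo <= true_dose && true_dose <= est$ci_hi
    }, logical(1))
  })
  pooled <- mean(unlist(covered))
  expect_gt(pooled, 0.93)
  expect_lt(pooled, 0.97)
})

test_that("missing curve SEs are treated as zero with a warning code", {
  cv <- calibration_curve(0.150, 1.956, phi = 60) # no SEs
  est <- estimate_dose(tibble::tibble(yield = 2, n_cells = 200), cv)
  expect_true("MISSING_SE" %in% est$warnings[[1]])
  expect_equal(est$var_intercept, 0)
  expect_equal(est$var_slope, 0)
  expect_gt(est$var_sampling, 0)
})

test_that("phi resolves argument > curve > consensus default with warning", {
  cv_phi <- calibration_curve(0.15, 2, 0.01, 0.02, phi = 30)
  cv_nophi <- calibration_curve(0.15, 2, 0.01, 0.02)
  y <- tibble::tibble(yield = 2, n_cells = 200)
  e_arg <- estimate_dose(y, cv_phi, phi = 10)
  e_curve <- estimate_dose(y, cv_phi)
  e_default <- estimate_dose(y, cv_nophi)
  expect_equal(e_arg$var_sampling, 10 * 2 / (200 * 4))
  expect_equal(e_curve$var_sampling, 30 * 2 / (200 * 4))
  expect_equal(e_default$var_sampling, 60 * 2 / (200 * 4))
  expect_true("DEFAULT_PHI" %in% e_default$warnings[[1]])
  expect_false("DEFAULT_PHI" %in% e_curve$warnings[[1]])
})

test_that("inversion errors are signalled for flat and quadratic curves", {
  flat <- calibration_curve(0.5, 0, phi = 60)
  y <- tibble::tibble(yield = 2, n_cells = 200)
  expect_error(estimate_dose(y, flat), class = "h2ax_non_invertible")
  quad <- calibration_curve(0.1, 2, quad = -0.1, phi = 60)
  expect_error(estimate_dose(y, quad), class = "h2ax_unsupported_inversion")
  expect_error(estimate_dose(y, phe_curve_24h(), phi = -2),
               class = "h2ax_input_error")
  expect_error(variance_decomposition(phe_curve_24h(), numeric(0), 200),
               class = "h2ax_input_error")
})
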