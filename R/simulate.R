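#' Calibration design of the PHE focus-count experiment
#'
#' The measurement layout of the X-irradiated whole-blood experiment used
#' throughout the package's examples: design doses 0, 0.05, 0.1, 0.25, 0.5,
#' 1 and 4 Gy, scored 1h and 24h after exposure, 500 cells per sample, with
#' the published replicate counts per dose/time cell (339 samples in
#' total).
#'
#' @param time Which strata to include (default both).
#' @param n_cells Cells scored per sample (default 500).
#' @return A design tibble with columns `dose_gy`, `time`, `n_cells`,
#'   `n_replicates`, suitable for [simulate_calibration()].
#' @examples
#' phe_design()
#' @export
phe_design <- function(time = c("1h", "24h"), n_cells = 500) {
  doses <- c(0, 0.05, 0.1, 0.25, 0.5, 1, 4)
  reps <- list(
    "1h"  = c(56, 16, 16, 16, 55, 28, 0),
    "24h" = c(22, 16, 16, 16, 19, 27, 36)
  )
  time <- match.arg(time, several.ok = TRUE)
  out <- purrr::map(time, function(tl) {
    tibble(dose_gy = doses, time = tl, n_cells = n_cells,
           n_replicates = reps[[tl]])
  })
  dplyr::filter(dplyr::bind_rows(out), .data$n_replicates > 0)
}

#' Simulate an overdispersed focus-count calibration dataset
#'
#' Draws total focus counts around the linear dose response
#' `E(y) = A + B * dose` (per time stratum, sharing the background yield
#' `A`), with count variance `phi` times the Poisson mean — the
#' mean-variance law the quasi-Poisson framework assumes. For `phi > 1` the
#' generating family is negative binomial with `size = mean / (phi - 1)`,
#' which matches that law exactly; `phi = 1` draws plain Poisson counts.
#' Sampling is reproducible: each design row gets its own substream seed
#' derived from `seed`, so appending design rows never perturbs the counts
#' of earlier rows.
#'
#' @param design Design tibble with columns `dose_gy`, `time`, `n_cells`,
#'   `n_replicates` (default [phe_design()]).
#' @param intercept True background yield `A` (foci/cell); default the
#'   published joint-model estimate 0.150.
#' @param slope True slope(s) `B` (foci/cell/Gy): a single number, or a
#'   vector named by time label; defaults to the published joint-model
#'   slopes 12.518 (1h) and 1.956 (24h).
#' @param phi Dispersion index of the counts (default 60, the consensus
#'   value for manually scored foci).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param donors Optional number of donors to cycle samples through; adds a
#'   `donor` column.
#' @param donor_sd Standard deviation (log scale) of a donor-specific
#'   lognormal multiplier on the mean count. The default 0 reflects the
#'   finding that inter-donor variation is absorbed by the overdispersion;
#'   positive values inject a genuine donor effect (for power studies).
#' @return A calibration tibble with one row per sample: `dose_gy`, `time`,
#'   `n_cells`, `focus_count` (and `donor` when requested).
#' @examples
#' d <- simulate_calibration(seed = 1)
#' dplyr::count(d, time, dose_gy)
#' @export
simulate_calibration <- function(design = phe_design(),
                                 intercept = 0.150,
                                 slope = c("1h" = 12.518, "24h" = 1.956),
                                 phi = 60, seed = NULL,
                                 donors = NULL, donor_sd = 0) {
  if (phi < 1) abort("`phi` must be at least 1.", class = "h2ax_input_error")
  stopifnot(all(c("dose_gy", "time", "n_cells", "n_replicates") %in%
                  names(design)))
  slope_for <- function(tl) {
    if (is.null(names(slope))) slope[1]
    else if (tl %in% names(slope)) slope[[tl]]
    else abort(paste0("No slope supplied for time label '", tl, "'."),
               class = "h2ax_input_error")
  }
  donor_mult <- NULL
  if (!is.null(donors)) {
    donor_mult <- if (donor_sd > 0) {
      with_substream(seed, 0L, exp(rnorm(donors, -donor_sd^2 / 2, donor_sd)))
    } else {
      rep(1, donors)
    }
  }
  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    mu_y <- intercept + slope_for(row$time) * row$dose_gy
    if (mu_y <= 0) {
      abort("True mean yield is non-positive at a design dose.",
            class = "h2ax_input_error")
    }
    k <- row$n_replicates
    donor_id <- if (is.null(donors)) NULL else ((seq_len(k) - 1L) %% donors) + 1L
    mean_count <- row$n_cells * mu_y
    if (!is.null(donor_mult)) mean_count <- mean_count * donor_mult[donor_id]
    counts <- with_substream(seed, i, draw_overdispersed(k, mean_count, phi))
    out <- tibble(dose_gy = row$dose_gy, time = row$time,
                  n_cells = row$n_cells, focus_count = counts)
    if (!is.null(donor_id)) out$donor <- paste0("D", donor_id)
    out
  })
  dplyr::bind_rows(rows)
}

#' Simulate a customer sample at a known true dose
#'
#' Draws one overdispersed total focus count with mean
#' `n_star * (A + B * true_dose)` and variance `phi` times that mean, and
#' returns it as a customer sample row.
#'
#' @param true_dose True absorbed dose in Gy.
#' @param curve The true [calibration_curve()] generating the counts.
#' @param n_star Number of cells scored.
#' @param phi Dispersion index (default 60).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A one-row tibble with `yield`, `n_cells`, `total_count`.
#' @examples
#' curve_24h <- calibration_curve(0.150, 1.956, phi = 60)
#' simulate_customer(1, curve_24h, n_star = 200, seed = 7)
#' @export
simulate_customer <- function(true_dose, curve, n_star, phi = 60,
                              seed = NULL) {
  stopifnot(is_h2ax_curve(curve))
  mean_count <- n_star * curve_yield(curve, true_dose)
  if (any(mean_count <= 0)) {
    abort("Curve mean is non-positive at the true dose.",
          class = "h2ax_input_error")
  }
  count <- with_substream(seed, 1L,
                          draw_overdispersed(length(mean_count), mean_count, phi))
  tibble(yield = count / n_star, n_cells = n_star, total_count = count)
}

# Counts with mean m and variance phi * m: negative binomial with
# size = m / (phi - 1) for phi > 1, Poisson at phi = 1.
draw_overdispersed <- function(k, mean_count, phi) {
  if (phi == 1) {
    rpois(k, mean_count)
  } else {
    rnbinom(k, mu = mean_count, size = mean_count / (phi - 1))
  }
}

# Run `expr` under a deterministic substream seed derived from (seed, k),
# restoring the caller's RNG state. seed = NULL draws from the ambient RNG.
with_substream <- function(seed, k, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.double(seed) * 48271 + k * 16807) %% 2147483647)
  expr
}
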