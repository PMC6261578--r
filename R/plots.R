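#' @export
autoplot.h2ax_fit <- function(object, ...) {
  data <- dplyr::mutate(object$data, yield = .data$focus_count / .data$n_cells)
  has_time <- "time" %in% names(data) && length(unique(data$time)) > 1
  grid <- tidyr::expand_grid(
    dose_gy = seq(0, max(data$dose_gy), length.out = 100),
    time = if (has_time) unique(data$time) else NA_character_
  )
  curves <- if (inherits(object, "h2ax_joint_fit")) object$curves
            else list(object$curve)
  grid$fit <- purrr::map2_dbl(grid$dose_gy, grid$time, function(d, tl) {
    cv <- if (has_time) curves[[tl]] else curves[[1]]
    curve_yield(cv, d)
  })
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$dose_gy, y = .data$yield)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::labs(x = "dose (Gy)", y = "yield (foci/cell)")
  if (has_time) p <- p + ggplot2::facet_wrap(~time, scales = "free_y")
  p
}

#' @export
autoplot.h2ax_validation <- function(object, ...) {
  tbl <- tidy(object)
  doses <- seq(0, max(tbl$dose) * 1.1, length.out = 100)
  line <- tibble(dose = doses, fit = curve_yield(object$curve, doses))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.05, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$yield, colour = .data$inside),
                        size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "dose (Gy)", y = "yield (foci/cell)",
                  colour = "inside PI",
                  title = paste("validation decision:", object$decision))
}

#' Plot a dose-estimate variance decomposition
#'
#' Stacked view of the additive delta-method variance components over a
#' grid of yields, the diagnostic that shows which uncertainty source
#' (sampling, intercept, slope, or a quadratic term) dominates.
#'
#' @param decomp Output of [variance_decomposition()].
#' @return A ggplot object.
#' @export
plot_variance_decomposition <- function(decomp) {
  long <- tidyr::pivot_longer(
    dplyr::select(decomp, "yield", dplyr::starts_with("var_"), -"var_total"),
    -"yield", names_to = "component", values_to = "variance",
    names_prefix = "var_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$yield, y = .data$variance,
                                     fill = .data$component)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "yield (foci/cell)", y = expression(var(x^"*")))
}
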