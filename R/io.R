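#' Read a calibration table
#'
#' Reads delimiter-separated calibration data (comma, tab, or whitespace —
#' guessed from the first line unless `delim` is given) with one scored
#' sample per row. The canonical header is `dose_gy, time, n_cells,
#' focus_count` plus optional `donor` and `scorer`; common alternative
#' column names (`dose`, `cells`, `n`, `count`, `foci`, `Y`, `id`) are
#' mapped automatically, and `col_map` can supply any further renames (e.g.
#' for the whitespace-separated `.dat` layout of a deposited dataset:
#' `read_calibration_table(path, col_map = c(dose_gy = "dose", focus_count
#' = "Y"))`). Yields are always recomputed as `focus_count / n_cells`; a
#' yield column in the file is ignored.
#'
#' @param path Path to the text file.
#' @param delim Field delimiter; `NULL` guesses among comma, tab, and
#'   whitespace.
#' @param col_map Named character vector mapping canonical names (names) to
#'   file column names (values).
#' @return A validated calibration tibble (`dose_gy`, `time`, `n_cells`,
#'   `focus_count`, optional `donor`, `scorer`).
#' @export
read_calibration_table <- function(path, delim = NULL, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "h2ax_input_error")
  }
  first <- readLines(path, n = 1)
  if (is.null(delim)) {
    delim <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else "ws"
  }
  df <- if (identical(delim, "ws")) {
    as_tibble(utils::read.table(path, header = TRUE,
                                stringsAsFactors = FALSE))
  } else {
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }
  synonyms <- list(
    dose_gy = c("dose_gy", "dose", "x", "dose.gy"),
    time = c("time", "time_label", "t"),
    n_cells = c("n_cells", "cells", "n", "ncells"),
    focus_count = c("focus_count", "count", "foci", "y_total", "total_count", "Y"),
    donor = c("donor", "donor_id", "id", "individual"),
    scorer = c("scorer", "scorer_id")
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      synonyms[[canon]] <- c(col_map[[canon]], synonyms[[canon]])
    }
  }
  out <- list()
  for (canon in names(synonyms)) {
    hit <- intersect(synonyms[[canon]], names(df))
    if (length(hit)) out[[canon]] <- df[[hit[1]]]
  }
  missing <- setdiff(c("dose_gy", "n_cells", "focus_count"), names(out))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "h2ax_input_error")
  }
  validate_calibration_data(as_tibble(out))
}

# Row-addressed validation of a calibration table.
validate_calibration_data <- function(data) {
  if (!is.data.frame(data)) {
    abort("Calibration data must be a data frame.", class = "h2ax_input_error")
  }
  data <- as_tibble(data)
  missing <- setdiff(c("dose_gy", "n_cells", "focus_count"), names(data))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "h2ax_input_error")
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      abort(sprintf("Row %d: %s.", idx[1], what), class = "h2ax_input_error")
    }
  }
  bad_row(!is.finite(data$dose_gy) | data$dose_gy < 0, "negative or non-finite dose")
  bad_row(!is.finite(data$n_cells) | data$n_cells < 1, "n_cells must be >= 1")
  bad_row(!is.finite(data$focus_count) | data$focus_count < 0,
          "negative or non-finite focus count")
  bad_row(data$focus_count != round(data$focus_count),
          "focus count must be an integer")
  bad_row(data$n_cells != round(data$n_cells), "n_cells must be an integer")
  data
}

curve_schema_version <- "1"

#' Write / read a calibration curve as JSON
#'
#' Curves round-trip losslessly through a flat JSON document with fields
#' `schema`, `model_form`, `time_label`, `A`, `B`, `C`, `se_A`, `se_B`,
#' `se_C`, `phi`, `df`, `source`. Numeric fields are serialized at full
#' precision. A document missing the standard-error fields loads with zeros
#' and a `MISSING_SE` warning code attached to the curve (the applet
#' convention for user-entered curves); a missing `phi` loads as unknown,
#' to be defaulted downstream with a `DEFAULT_PHI` warning.
#'
#' @param curve An [calibration_curve()].
#' @param path File path.
#' @return `write_curve()` returns `path` invisibly; `read_curve()` returns
#'   the curve.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is_h2ax_curve(curve))
  doc <- list(
    schema = curve_schema_version,
    model_form = curve$model_form,
    time_label = curve$time_label,
    A = curve$intercept, B = curve$slope,
    C = if (is.null(curve$quad)) NULL else curve$quad,
    se_A = curve$se_intercept, se_B = curve$se_slope,
    se_C = if (is.null(curve$quad)) NULL else curve$se_quad,
    phi = curve$phi, df = curve$fit_df, source = curve$source
  )
  jsonlite::write_json(doc[!vapply(doc, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "h2ax_input_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("A", "B")) {
    if (is.null(doc[[fld]]) || is.na(doc[[fld]])) {
      abort(paste0("Curve document lacks required field `", fld, "`."),
            class = "h2ax_input_error")
    }
  }
  num_or <- function(x, default) {
    if (is.null(x) || length(x) == 0 || is.na(x)) default else as.numeric(x)
  }
  missing_se <- is.null(doc$se_A) || is.null(doc$se_B) ||
    isTRUE(is.na(doc$se_A)) || isTRUE(is.na(doc$se_B))
  curve <- calibration_curve(
    intercept = doc$A, slope = doc$B,
    se_intercept = num_or(doc$se_A, 0), se_slope = num_or(doc$se_B, 0),
    quad = if (is.null(doc$C) || isTRUE(is.na(doc$C))) NULL else doc$C,
    se_quad = num_or(doc$se_C, 0),
    phi = num_or(doc$phi, NA_real_),
    time_label = num_or_chr(doc$time_label),
    fit_df = as.integer(num_or(doc$df, NA_real_)),
    source = if (is.null(doc$source)) "user_supplied" else doc$source
  )
  if (missing_se) curve <- add_curve_warning(curve, "MISSING_SE")
  curve
}

num_or_chr <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) NA_character_ else as.character(x)
}

#' Write / read an estimation report as JSON
#'
#' Serializes the per-sample records of an [run_dose_estimation()] result
#' (inputs, dose estimate, standard error, interval, variance components,
#' provenance, warning codes) together with run metadata (configuration
#' echo and timestamp). Numeric fields round-trip at full precision.
#'
#' @param report An `h2ax_report` from [run_dose_estimation()].
#' @param path File path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a list with `metadata` and the `estimates` tibble.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "h2ax_report"))
  config <- attr(report, "config")
  resolved <- attr(report, "resolved")
  records <- as_tibble(report)
  records$warnings <- purrr::map(records$warnings, as.character)
  doc <- list(
    schema = curve_schema_version,
    metadata = list(
      config = unclass(config),
      phi_used = purrr::map_dbl(resolved, "phi"),
      provenance = purrr::map_chr(resolved, "provenance"),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    estimates = records
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "h2ax_input_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- as_tibble(doc$estimates)
  if ("warnings" %in% names(est)) {
    est$warnings <- purrr::map(est$warnings, as.character)
  }
  list(metadata = doc$metadata, estimates = est)
}

#' Render an estimation report as text
#'
#' @param report An `h2ax_report`.
#' @return A character vector of display lines (2-3 decimals; full
#'   precision is preserved in the report object and its JSON form).
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "h2ax_report"))
  purrr::pmap_chr(
    list(report$yield, report$n_cells, report$x_star, report$se_x_star,
         report$ci_lo, report$ci_hi, report$provenance,
         purrr::map_chr(report$warnings, paste, collapse = ",")),
    function(y, n, x, se, lo, hi, prov, w) {
      sprintf("y*=%.3f (n*=%d): x*=%.2f Gy, SE=%.2f, CI [%.2f, %.2f] [%s]%s",
              y, as.integer(n), x, se, lo, hi, prov,
              if (nzchar(w)) paste0(" warnings: ", w) else "")
    }
  )
}
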