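#' Low-signal test for one well
#'
#' A well is rejected when its fluorescence range (max - min) inside the
#' fitting window falls strictly below the signal threshold: such wells lack
#' the amplitude needed for a reliable sigmoid fit (empty wells, failed
#' dispenses).
#'
#' @param fluorescence Fluorescence readings of one well.
#' @param threshold Minimum acceptable range, in fluorescence units (>= 0).
#' @return `TRUE` if the well is flagged.
#' @export
flag_low_signal <- function(fluorescence, threshold) {
  stopifnot(threshold >= 0)
  (max(fluorescence) - min(fluorescence)) < threshold
}

#' Inverted-shape test for one well
#'
#' Flags downward-sloping / high-initial-fluorescence curves: wells whose
#' global fluorescence maximum occurs at a lower temperature than the global
#' minimum. Ties on the value are broken by the first occurrence in
#' ascending temperature.
#'
#' @param temperature Ascending temperatures of one well.
#' @param fluorescence Matching fluorescence readings.
#' @return `TRUE` if the well is flagged.
#' @export
flag_inverted <- function(temperature, fluorescence) {
  temperature[which.max(fluorescence)] < temperature[which.min(fluorescence)]
}

#' Discontinuity (gap/jump/spike) test for one well
#'
#' Computes the successive fluorescence changes of the well and flags it when
#' the largest absolute change exceeds `multiplier` times the mean absolute
#' change. Absolute values are used so downward spikes are caught as well as
#' upward ones. A constant curve (mean step zero) is never flagged here --
#' that is the low-signal test's job.
#'
#' @param fluorescence Fluorescence readings of one well (length >= 3).
#' @param multiplier Dimensionless ratio threshold; default 25. Noisy data
#'   may require a higher value.
#' @return `TRUE` if the well is flagged.
#' @export
flag_discontinuity <- function(fluorescence, multiplier = 25) {
  stopifnot(length(fluorescence) >= 3, multiplier > 0)
  steps <- abs(diff(fluorescence))
  m <- mean(steps)
  if (m == 0) return(FALSE)
  max(steps) > multiplier * m
}

qc_metrics_one <- function(temperature, fluorescence) {
  steps <- abs(diff(fluorescence))
  m <- mean(steps)
  list(signal_range = max(fluorescence) - min(fluorescence),
       max_step_ratio = if (length(steps) > 0 && m > 0) max(steps) / m else NA_real_,
       t_at_min = temperature[which.min(fluorescence)],
       t_at_max = temperature[which.max(fluorescence)])
}

#' Quality-control an entire plate of melting curves
#'
#' Applies the three well-rejection rules in order: low signal, inverted
#' shape, discontinuity. Low-signal wells are separated for review and skip
#' the shape checks (there is no meaningful shape to test); wells that meet
#' the signal threshold collect every shape flag that fires. Every well ends
#' up in exactly one of the accepted set or the flagged set.
#'
#' @param curves A `melt_curves` tibble (already cropped to the fitting
#'   window if one is used).
#' @param signal_threshold Minimum fluorescence range, same units as the
#'   export.
#' @param spike_multiplier Discontinuity ratio threshold (default 25).
#' @return A list with `accepted` (curves of unflagged wells) and `report`,
#'   a tibble with one row per well: `well`, `row`, `column`, `flags`
#'   (`";"`-separated, `""` when accepted), `accepted`, `signal_range`,
#'   `max_step_ratio`, `t_at_min`, `t_at_max`.
#' @export
qc_plate <- function(curves, signal_threshold, spike_multiplier = 25) {
  by_well <- split(curves, curves$well)
  report <- purrr::map_dfr(by_well, function(cw) {
    cw <- cw[order(cw$temperature), ]
    met <- qc_metrics_one(cw$temperature, cw$fluorescence)
    flags <- character(0)
    if (flag_low_signal(cw$fluorescence, signal_threshold)) {
      flags <- "LOW_SIGNAL"
    } else {
      if (flag_inverted(cw$temperature, cw$fluorescence)) {
        flags <- c(flags, "INVERTED")
      }
      if (length(cw$fluorescence) >= 3 &&
          flag_discontinuity(cw$fluorescence, spike_multiplier)) {
        flags <- c(flags, "DISCONTINUITY")
      }
    }
    ok <- length(flags) == 0L
    tibble::tibble(well = cw$well[1], row = cw$row[1], column = cw$column[1],
                   flags = paste(flags, collapse = ";"),
                   accepted = ok,
                   signal_range = met$signal_range,
                   max_step_ratio = met$max_step_ratio,
                   t_at_min = met$t_at_min, t_at_max = met$t_at_max)
  })
  report <- dplyr::arrange(report, .data$row, .data$column)
  accepted_wells <- report$well[report$accepted]
  accepted <- curves[curves$well %in% accepted_wells, ]
  list(accepted = accepted, report = report)
}

#' Write a QC report to CSV
#'
#' @param report The `report` tibble from [qc_plate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  readr::write_csv(report, path, progress = FALSE)
  invisible(path)
}
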