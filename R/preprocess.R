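#' Crop melting curves to the fitting window
#'
#' Restricting the fit to the transition region both speeds up and
#' stabilizes the nonlinear regression, so data outside the user-chosen
#' window are removed before any further processing. The filter is inclusive
#' (`t_low <= t <= t_high`) and preserves order.
#'
#' @param curves A `melt_curves` tibble (or any tibble with `well` and
#'   `temperature` columns).
#' @param t_low,t_high Window bounds in degrees C, `t_low < t_high`.
#' @param min_points Minimum surviving points per well (default 8; a
#'   5-parameter fit needs headroom beyond its parameter count).
#' @return The cropped tibble.
#' @export
crop_window <- function(curves, t_low, t_high, min_points = 8) {
  stopifnot(t_low < t_high)
  out <- curves[curves$temperature >= t_low & curves$temperature <= t_high, ]
  n_by_well <- table(out$well)
  starved <- names(n_by_well)[n_by_well < min_points]
  lost <- setdiff(unique(curves$well), unique(out$well))
  if (length(c(starved, lost)) > 0L) {
    stop("fewer than ", min_points, " points survive the fitting window for ",
         "well(s): ", paste(sort(unique(c(starved, lost))), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Centred simple moving average
#'
#' Unweighted mean over a centred window of `window_points` points. Near the
#' edges the window shrinks symmetrically (at index `i` the half-width is
#' `min(k, i-1, n-i)`), so the output has the same length as the input, the
#' endpoints are preserved exactly, and no data are invented by padding.
#'
#' @param x Numeric sequence.
#' @param window_points Odd window size, default 21.
#' @return Smoothed sequence, same length as `x`.
#' @export
moving_average <- function(x, window_points = 21) {
  stopifnot(window_points >= 1, window_points %% 2 == 1)
  n <- length(x)
  k <- (window_points - 1L) / 2L
  vapply(seq_len(n), function(i) {
    h <- min(k, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Rescale a sequence to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. The midpoint
#' melting temperature is invariant under this map, so fitting on normalized
#' values changes only the asymptote parameters.
#'
#' @param x Numeric sequence with `max(x) > min(x)`.
#' @return Sequence in `[0, 1]` with 0 and 1 attained.
#' @export
normalize01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    stop("degenerate range: constant input cannot be normalized ",
         "(should have been flagged as low signal)", call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Trim a smoothed curve to its monotone transition region
#'
#' Discards the pretransition region below the global fluorescence minimum
#' and the aggregation decline above the global maximum: first every point
#' at a temperature below the global minimum's is dropped, then, on the
#' remainder, every point above the global maximum's. Ties are broken by the
#' first occurrence in ascending temperature, so flat plateaus keep their
#' earliest point.
#'
#' @param temperature Ascending temperatures.
#' @param values Matching (smoothed, normalized) fluorescence values.
#' @param min_points Minimum surviving points (default 8).
#' @return A list with trimmed `temperature` and `values`.
#' @export
trim_to_transition <- function(temperature, values, min_points = 8) {
  t_min <- temperature[which.min(values)]
  keep <- temperature >= t_min
  temperature <- temperature[keep]
  values <- values[keep]
  t_max <- temperature[which.max(values)]
  keep <- temperature <= t_max
  temperature <- temperature[keep]
  values <- values[keep]
  if (length(values) < min_points) {
    stop("fewer than ", min_points,
         " points survive transition trimming", call. = FALSE)
  }
  list(temperature = temperature, values = values)
}

#' Preprocess one well for fitting
#'
#' The per-well pipeline applied between QC and the 5PL fit, in order:
#' optional window crop, 21-point centred moving average, 0-1
#' normalization, trim to the transition region bracketed by the global
#' extrema.
#'
#' @param temperature Ascending temperatures of one well.
#' @param fluorescence Matching raw fluorescence values.
#' @param window Optional numeric length-2 `c(t_low, t_high)` fitting window;
#'   `NULL` if the curve is already cropped.
#' @param smoothing_points Moving-average window, odd, default 21.
#' @param min_points Minimum surviving points (default 8).
#' @return A tibble with `temperature` and `norm_fluorescence` in `[0, 1]`.
#' @export
preprocess_well <- function(temperature, fluorescence, window = NULL,
                            smoothing_points = 21, min_points = 8) {
  ord <- order(temperature)
  temperature <- temperature[ord]
  fluorescence <- fluorescence[ord]
  if (!is.null(window)) {
    keep <- temperature >= window[1] & temperature <= window[2]
    temperature <- temperature[keep]
    fluorescence <- fluorescence[keep]
    if (length(fluorescence) < min_points) {
      stop("fewer than ", min_points,
           " points survive the fitting window", call. = FALSE)
    }
  }
  smoothed <- moving_average(fluorescence, smoothing_points)
  norm <- normalize01(smoothed)
  trimmed <- trim_to_transition(temperature, norm, min_points)
  tibble::tibble(temperature = trimmed$temperature,
                 norm_fluorescence = trimmed$values)
}

#' Preprocess all accepted wells of a plate
#'
#' @param curves A `melt_curves` tibble of QC-accepted wells.
#' @inheritParams preprocess_well
#' @return A long tibble with `well`, `row`, `column`, `temperature`,
#'   `norm_fluorescence`.
#' @export
preprocess_plate <- function(curves, window = NULL, smoothing_points = 21,
                             min_points = 8) {
  purrr::map_dfr(split(curves, curves$well), function(cw) {
    cw <- cw[order(cw$temperature), ]
    pc <- preprocess_well(cw$temperature, cw$fluorescence, window = window,
                          smoothing_points = smoothing_points,
                          min_points = min_points)
    tibble::tibble(well = cw$well[1], row = cw$row[1], column = cw$column[1],
                   temperature = pc$temperature,
                   norm_fluorescence = pc$norm_fluorescence)
  })
}
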