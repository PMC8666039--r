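#' Control-well melting-temperature statistics and hit threshold
#'
#' Computes the mean and sample standard deviation (n-1 denominator) of the
#' fitted midpoint Tm of converged control wells, the two-sided hit
#' threshold (`multiplier x sd`) and the one-sided absolute variant
#' (`mean + multiplier x sd`). By default the threshold is 3 standard
#' deviations of the DMSO-treated wells.
#'
#' @param fits Fit table (as from [fit_plate()]) joined to the plate map,
#'   i.e. carrying `compound_id`, `tm`, `converged`.
#' @param control_id Control compound identifier (case-insensitive),
#'   default `"DMSO"`.
#' @param multiplier Threshold multiplier, default 3.
#' @return An object of class `control_stats`: list with `control_id`,
#'   `mean_tm`, `sd_tm`, `n`, `threshold`, `threshold_abs`.
#' @export
control_stats <- function(fits, control_id = "DMSO", multiplier = 3) {
  ctl <- fits[!is.na(fits$compound_id) &
                toupper(fits$compound_id) == toupper(control_id) &
                fits$converged, ]
  if (nrow(ctl) == 0L) {
    stop("no converged control wells found for control token ",
         sQuote(control_id), call. = FALSE)
  }
  if (nrow(ctl) < 2L) {
    stop("at least 2 converged control wells are needed to define a hit ",
         "threshold (found ", nrow(ctl), ")", call. = FALSE)
  }
  sd_tm <- stats::sd(ctl$tm)
  if (sd_tm == 0) {
    warning("control Tm standard deviation is 0; every nonzero shift will ",
            "be called a hit", call. = FALSE)
  }
  structure(list(control_id = control_id,
                 mean_tm = mean(ctl$tm),
                 sd_tm = sd_tm,
                 n = nrow(ctl),
                 multiplier = multiplier,
                 threshold = multiplier * sd_tm,
                 threshold_abs = mean(ctl$tm) + multiplier * sd_tm),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat("Control (", x$control_id, ", n = ", x$n, "): mean Tm ",
      round(x$mean_tm, 3), " degC, SD ", round(x$sd_tm, 4), " degC\n",
      "hit threshold (", x$multiplier, " x SD): ", round(x$threshold, 4),
      " degC;  absolute variant: ", round(x$threshold_abs, 3), " degC\n",
      sep = "")
  invisible(x)
}

#' Aggregate replicate wells per compound
#'
#' Groups converged fits by compound identifier and reports the mean and
#' sample standard deviation of the midpoint Tm, summarizing replicates
#' where present. Non-converged wells are excluded (QC-flagged wells never
#' reach the fit table); a single-replicate compound gets `sd_tm = NA`.
#'
#' @inheritParams control_stats
#' @return A tibble with `compound_id`, `mean_tm`, `sd_tm`, `n`.
#' @export
aggregate_replicates <- function(fits) {
  conv <- fits[fits$converged & !is.na(fits$tm), ]
  dplyr::summarise(dplyr::group_by(conv, .data$compound_id),
                   mean_tm = mean(.data$tm),
                   sd_tm = ifelse(dplyr::n() > 1, stats::sd(.data$tm), NA_real_),
                   n = dplyr::n(), .groups = "drop")
}

#' Call hits against the control-derived threshold
#'
#' Computes each compound's melting-temperature shift
#' `delta_tm = mean_tm - control mean Tm` and tags hits. The default rule is
#' two-sided, `|delta Tm| >= multiplier x SD(control Tm)` (inclusive), so
#' stabilizers and destabilizers are both flagged; `two_sided = FALSE`
#' switches to the one-sided rule `mean_tm >= control mean + multiplier x SD`.
#'
#' @param compounds Per-compound tibble from [aggregate_replicates()].
#' @param controls A `control_stats` object.
#' @param two_sided Use the two-sided `|delta Tm|` rule (default `TRUE`).
#' @return A tibble with `compound_id`, `mean_tm`, `sd_tm`, `n`, `delta_tm`,
#'   `abs_delta_tm`, `hit`.
#' @export
call_hits <- function(compounds, controls, two_sided = TRUE) {
  delta <- compounds$mean_tm - controls$mean_tm
  hit <- if (two_sided) {
    abs(delta) >= controls$threshold
  } else {
    compounds$mean_tm >= controls$threshold_abs
  }
  tibble::tibble(compound_id = compounds$compound_id,
                 mean_tm = compounds$mean_tm,
                 sd_tm = compounds$sd_tm,
                 n = compounds$n,
                 delta_tm = delta,
                 abs_delta_tm = abs(delta),
                 hit = hit)
}
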