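#' Evaluate the 5-parameter log-logistic melting model
#'
#' The asymmetric sigmoid used for melting curves,
#' \deqn{f(x) = c + \frac{d - c}{\left[1 + \exp\big(b(\ln x - \ln e)\big)\right]^{f}}}
#' with `b` the slope, `c` and `d` the lower and upper asymptotes, `e` the
#' inflection point (degrees C) and `f > 0` the asymmetry factor -- the
#' difference in the rates of approach from the inflection point to the two
#' asymptotes. At `f = 1` the curve is symmetric and the model reduces to
#' the 4-parameter log-logistic. Under this parameterization a rising
#' melting curve has `b < 0`.
#'
#' @param x Temperatures, degrees C, strictly positive.
#' @param p Named numeric vector or list with elements `b`, `c`, `d`, `e`,
#'   `f`.
#' @return Model values, between `min(c, d)` and `max(c, d)`.
#' @export
eval_5pl <- function(x, p) {
  p <- as.list(p)
  if (any(x <= 0)) stop("temperatures must be positive (model is in ln x)",
                        call. = FALSE)
  p$c + (p$d - p$c) / (1 + exp(p$b * (log(x) - log(p$e))))^p$f
}

#' Midpoint melting temperature of a 5PL fit
#'
#' For an asymmetric sigmoid the inflection point `e` does not coincide with
#' the half-height midpoint. The midpoint Tm is
#' \deqn{T_m = \frac{e}{\exp\left[-\frac{1}{b}\ln\left(2^{1/f} - 1\right)\right]}}
#' which satisfies `eval_5pl(Tm, p) == (c + d)/2` and equals `e` exactly when
#' `f = 1`.
#'
#' @param p Named numeric vector or list with `b`, `e`, `f` (and optionally
#'   `c`, `d`).
#' @return Midpoint melting temperature in degrees C.
#' @export
midpoint_tm <- function(p) {
  p <- as.list(p)
  if (p$b == 0) stop("degenerate fit: slope b = 0", call. = FALSE)
  if (p$f <= 0) stop("asymmetry factor must be positive", call. = FALSE)
  p$e / exp(-(1 / p$b) * log(2^(1 / p$f) - 1))
}

# Closed-form initialization derived from the symmetric (f = 1) logistic:
# asymptotes from the data range, e0 from the half-height crossing, b0 from
# the 20%/80% crossing temperatures (log16 spans that interval at f = 1).
init_5pl <- function(x, y) {
  c0 <- min(y)
  d0 <- max(y)
  cross <- function(level) {
    thr <- c0 + level * (d0 - c0)
    idx <- which(y >= thr)
    if (length(idx) == 0L) return(NA_real_)
    x[idx[1]]
  }
  e0 <- cross(0.5)
  t20 <- cross(0.2)
  t80 <- cross(0.8)
  b0 <- if (!is.na(t20) && !is.na(t80) && t20 != t80) {
    log(16) / (log(t20) - log(t80))
  } else {
    NA_real_
  }
  if (is.na(e0)) e0 <- stats::median(x)
  if (is.na(b0) || !is.finite(b0)) b0 <- -10
  c(b = b0, c = c0, d = d0, e = e0, f = 1)
}

#' Fit the 5-parameter log-logistic model to one processed melting curve
#'
#' Least-squares fit of [eval_5pl()] via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Starting values come from a closed-form
#' symmetric-logistic heuristic; on failure up to `max_restarts` restarts
#' with deterministically perturbed slope and asymmetry starts are tried.
#' The inflection point is bounded to the fitted temperature span extended
#' by 10% on each side and the asymmetry factor to `[0.05, 20]`; slope and
#' asymptotes are unbounded. An optimizer failure yields a non-converged
#' result carrying the best-found parameters, never an exception.
#'
#' @param temperature Ascending temperatures (> 0), degrees C.
#' @param values Fluorescence values (typically smoothed, normalized,
#'   trimmed).
#' @param fix_f Optionally freeze the asymmetry factor (e.g. `fix_f = 1`
#'   fits the symmetric 4-parameter log-logistic).
#' @param max_restarts Restarts with perturbed starts after a failure.
#' @return An object of class `fivepl_fit`: list with `params` (named b, c,
#'   d, e, f), `std_errors` (asymptotic, from the linearized covariance at
#'   the optimum; NA when not converged), `rse` (residual standard error,
#'   `sqrt(RSS/(n - n_par))`), `midpoint_tm`, `converged`, `n_points`.
#' @export
fit_5pl <- function(temperature, values, fix_f = NULL, max_restarts = 3) {
  n <- length(values)
  if (n <= 5) stop("too few points to fit 5 parameters (n = ", n, ")",
                   call. = FALSE)
  if (any(temperature <= 0)) stop("temperatures must be positive", call. = FALSE)
  ord <- order(temperature)
  x <- temperature[ord]
  y <- values[ord]

  start0 <- init_5pl(x, y)
  span <- range(x)
  pad <- 0.1 * diff(span)
  e_lo <- span[1] - pad
  e_hi <- span[2] + pad
  start0["e"] <- min(max(start0["e"], e_lo), e_hi)

  # deterministic perturbation schedule for restarts
  b_mult <- c(1, 0.5, 2, 1)
  f_start <- c(1, 0.7, 1.5, 2)

  dat <- data.frame(x = x, y = y)
  attempt <- function(start, fixed_f) {
    if (is.null(fixed_f)) {
      frm <- y ~ c + (d - c) / (1 + exp(b * (log(x) - log(e))))^f
      lower <- c(b = -Inf, c = -Inf, d = -Inf, e = e_lo, f = 0.05)
      upper <- c(b = Inf, c = Inf, d = Inf, e = e_hi, f = 20)
    } else {
      frm <- stats::as.formula(paste0(
        "y ~ c + (d - c) / (1 + exp(b * (log(x) - log(e))))^", fixed_f))
      start <- start[c("b", "c", "d", "e")]
      lower <- c(b = -Inf, c = -Inf, d = -Inf, e = e_lo)
      upper <- c(b = Inf, c = Inf, d = Inf, e = e_hi)
    }
    minpack.lm::nlsLM(frm, data = dat, start = as.list(start),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10, ptol = 1e-8))
  }

  fit <- NULL
  for (k in seq_len(max_restarts + 1)) {
    start <- start0
    start["b"] <- start0["b"] * b_mult[k]
    start["f"] <- f_start[k]
    fit <- tryCatch(suppressWarnings(attempt(start, fix_f)),
                    error = function(e) NULL)
    if (!is.null(fit)) break
  }

  n_par <- if (is.null(fix_f)) 5L else 4L
  if (is.null(fit)) {
    params <- start0
    if (!is.null(fix_f)) params["f"] <- fix_f
    res <- structure(list(params = params,
                          std_errors = stats::setNames(rep(NA_real_, 5),
                                                       names(params)),
                          rse = NA_real_,
                          midpoint_tm = NA_real_,
                          converged = FALSE, n_points = n,
                          temperature = x, values = y),
                     class = "fivepl_fit")
    return(res)
  }

  est <- stats::coef(fit)
  params <- c(b = unname(est["b"]), c = unname(est["c"]),
              d = unname(est["d"]), e = unname(est["e"]),
              f = if (is.null(fix_f)) unname(est["f"]) else fix_f)
  se_tab <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  std_errors <- stats::setNames(rep(NA_real_, 5), names(params))
  if (!is.null(se_tab)) std_errors[names(se_tab)] <- se_tab
  rss <- sum(stats::resid(fit)^2)
  rse <- sqrt(rss / (n - n_par))
  tm <- tryCatch(midpoint_tm(params), error = function(e) NA_real_)
  structure(list(params = params, std_errors = std_errors, rse = rse,
                 midpoint_tm = tm, converged = TRUE, n_points = n,
                 temperature = x, values = y,
                 fitted = stats::fitted(fit)),
            class = "fivepl_fit")
}

#' @export
print.fivepl_fit <- function(x, ...) {
  cat("5PL melting-curve fit (", x$n_points, " points, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- rbind(estimate = x$params, std_error = x$std_errors)
  print(round(tab, 4))
  cat("midpoint Tm: ", round(x$midpoint_tm, 3), " degC;  RSE: ",
      signif(x$rse, 4), "\n", sep = "")
  invisible(x)
}

#' Fit every well of a preprocessed plate
#'
#' @param processed Long tibble from [preprocess_plate()].
#' @inheritParams fit_5pl
#' @return A tibble with one row per well: the five parameters, their
#'   standard errors (`se_*`), `rse`, `tm`, `converged`, `n_points`.
#' @export
fit_plate <- function(processed, max_restarts = 3) {
  if (nrow(processed) == 0L) {
    stop("no processed wells to fit (all wells QC-flagged?)", call. = FALSE)
  }
  purrr::map_dfr(split(processed, processed$well), function(pw) {
    ft <- fit_5pl(pw$temperature, pw$norm_fluorescence,
                  max_restarts = max_restarts)
    tibble::tibble(well = pw$well[1], row = pw$row[1], column = pw$column[1],
                   b = ft$params[["b"]], c = ft$params[["c"]],
                   d = ft$params[["d"]], e = ft$params[["e"]],
                   f = ft$params[["f"]],
                   se_b = ft$std_errors[["b"]], se_c = ft$std_errors[["c"]],
                   se_d = ft$std_errors[["d"]], se_e = ft$std_errors[["e"]],
                   se_f = ft$std_errors[["f"]],
                   rse = ft$rse, tm = ft$midpoint_tm,
                   converged = ft$converged, n_points = ft$n_points)
  }) |>
    dplyr::arrange(.data$row, .data$column)
}
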