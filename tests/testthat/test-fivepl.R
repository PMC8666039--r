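test_that("eval_5pl matches closed-form special cases", {
  p <- c(b = -10, c = 0, d = 1, e = 55, f = 1)
  # at x = e with f = 1 the denominator is 2: exact midpoint
  expect_equal(eval_5pl(55, p), 0.5)
  p2 <- c(b = -7, c = 0.2, d = 0.9, e = 60, f = 1)
  expect_equal(eval_5pl(60, p2), (0.2 + 0.9) / 2)
  # upper asymptote for a rising melt (b < 0)
  expect_equal(eval_5pl(1e9, p), 1, tolerance = 1e-6)
  # denominator 2^f at x = e
  p3 <- c(b = -10, c = 0, d = 1, e = 55, f = 2)
  expect_equal(eval_5pl(55, p3), 0.25)
  expect_error(eval_5pl(-3, p), "positive")
})

test_that("midpoint_tm equals e at f = 1 and matches the printed formula", {
  expect_identical(midpoint_tm(c(b = -5, e = 60, f = 1)), 60)
  expect_identical(midpoint_tm(c(b = 12, e = 47.3, f = 1)), 47.3)
  # direct numeric evaluation for b = -10, e = 60, f = 2
  expect_equal(midpoint_tm(c(b = -10, e = 60, f = 2)),
               60 / exp(-(1 / -10) * log(2^(1 / 2) - 1)))
  expect_equal(midpoint_tm(c(b = -10, e = 60, f = 2)), 65.53, tolerance = 1e-3)
  expect_error(midpoint_tm(c(b = 0, e = 60, f = 1)), "degenerate")
})

test_that("midpoint_tm satisfies the half-height identity", {
  set.seed(11)
  for (i in 1:50) {
    p <- c(b = sample(c(-1, 1), 1) * runif(1, 0.5, 20),
           c = runif(1, -1, 1), d = runif(1, 1.5, 3),
           e = runif(1, 35, 85), f = exp(runif(1, log(0.1), log(10))))
    tm <- midpoint_tm(p)
    expect_equal(eval_5pl(tm, p), (p[["c"]] + p[["d"]]) / 2,
                 tolerance = 1e-9)
  }
})

test_that("noise-free 5PL curves are recovered to high accuracy", {
  t <- seq(40, 80, 0.5)
  truth <- c(b = -12, c = 0, d = 1, e = 58, f = 1.4)
  y <- ref_5pl(t, -12, 0, 1, 58, 1.4)
  ft <- fit_5pl(t, y)
  expect_true(ft$converged)
  expect_equal(ft$params[["b"]], -12, tolerance = 1e-3)
  expect_equal(ft$params[["c"]], 0, tolerance = 1e-3)
  expect_equal(ft$params[["d"]], 1, tolerance = 1e-3)
  expect_equal(ft$params[["e"]], 58, tolerance = 1e-3)
  expect_equal(ft$params[["f"]], 1.4, tolerance = 1e-3)
  expect_lt(abs(ft$midpoint_tm - midpoint_tm(truth)), 0.01)
  expect_lt(ft$rse, 1e-6)
})

test_that("Tm is recovered within 0.2 degC under 1% Gaussian noise", {
  t <- seq(40, 80, 0.5)
  truth <- c(b = -12, c = 0, d = 1, e = 58, f = 1.4)
  tm_true <- midpoint_tm(truth)
  set.seed(23)
  y <- ref_5pl(t, -12, 0, 1, 58, 1.4) + rnorm(length(t), 0, 0.01)
  ft <- fit_5pl(t, y)
  expect_true(ft$converged)
  expect_lt(abs(ft$midpoint_tm - tm_true), 0.2)
})

test_that("a symmetric melting curve recovers an asymmetry factor of 1", {
  t <- seq(40, 80, 0.5)
  y <- ref_5pl(t, -12, 0, 1, 58, 1)
  ft <- fit_5pl(t, y)
  expect_true(ft$converged)
  expect_equal(ft$params[["f"]], 1, tolerance = 0.02)
  # and the midpoint then coincides with the inflection point
  expect_equal(ft$midpoint_tm, ft$params[["e"]], tolerance = 1e-3)
})

test_that("fitting is equivariant under affine rescaling of the signal", {
  t <- seq(40, 80, 0.5)
  set.seed(31)
  y <- ref_5pl(t, -12, 0, 1, 58, 1.4) + rnorm(length(t), 0, 0.005)
  f1 <- fit_5pl(t, y)
  f2 <- fit_5pl(t, 1000 * y + 50)
  expect_equal(f1$params[["b"]], f2$params[["b"]], tolerance = 1e-4)
  expect_equal(f1$params[["e"]], f2$params[["e"]], tolerance = 1e-6)
  expect_equal(f1$params[["f"]], f2$params[["f"]], tolerance = 1e-4)
  expect_equal(f1$midpoint_tm, f2$midpoint_tm, tolerance = 1e-6)
  expect_equal(f2$params[["c"]], 1000 * f1$params[["c"]] + 50,
               tolerance = 1e-3)
  expect_equal(f2$params[["d"]], 1000 * f1$params[["d"]] + 50,
               tolerance = 1e-3)
})

test_that("freezing f at 1 reduces to the 4PL and barely moves a symmetric Tm", {
  t <- seq(40, 80, 0.5)
  set.seed(37)
  y <- ref_5pl(t, -12, 0, 1, 58, 1) + rnorm(length(t), 0, 0.005)
  free <- fit_5pl(t, y)
  frozen <- fit_5pl(t, y, fix_f = 1)
  expect_true(frozen$converged)
  expect_equal(frozen$params[["f"]], 1)
  expect_lt(abs(free$midpoint_tm - frozen$midpoint_tm), 0.05)
})

test_that("standard errors and residual standard error are reported", {
  t <- seq(40, 80, 0.5)
  set.seed(41)
  y <- ref_5pl(t, -12, 0, 1, 58, 1.4) + rnorm(length(t), 0, 0.01)
  ft <- fit_5pl(t, y)
  expect_true(all(is.finite(ft$std_errors)))
  expect_true(all(ft$std_errors > 0))
  # rse approximates the injected noise level
  expect_equal(ft$rse, 0.01, tolerance = 0.35)
  expect_equal(ft$n_points, length(t))
  # midpoint lies inside the fitted span
  expect_gt(ft$midpoint_tm, min(t))
  expect_lt(ft$midpoint_tm, max(t))
})

test_that("too few points and degenerate input are rejected or survivable", {
  expect_error(fit_5pl(seq(40, 42, 0.5), rep(0.5, 5)), "too few")
  # unfittable junk: non-converged result, never an exception
  set.seed(43)
  junk <- fit_5pl(seq(40, 49, 1), runif(10))
  expect_s3_class(junk, "fivepl_fit")
  expect_true(is.logical(junk$converged))
})

test_that("fit_plate fits every well of a preprocessed plate", {
  sim <- small_sim()
  qc <- qc_plate(sim$curves, signal_threshold = 50)
  processed <- preprocess_plate(qc$accepted)
  fits <- fit_plate(processed)
  expect_equal(nrow(fits), 96)
  expect_true(all(fits$converged))
  truth <- sim$truth[match(fits$well, sim$truth$well), ]
  expect_lt(max(abs(fits$tm - truth$true_tm)), 0.2)
})
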