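test_that("low-signal rule is a strict less-than on the fluorescence range", {
  expect_true(flag_low_signal(rep(5, 10), threshold = 1))
  # range exactly equal to the threshold is accepted
  expect_false(flag_low_signal(c(0, 10), threshold = 10))
  expect_true(flag_low_signal(c(0, 9.99), threshold = 10))
})

test_that("simulated empty wells fall under a realistic signal threshold", {
  spec <- sim_spec(geometry = "96", n_controls = 8, noise_sd = 2, seed = 3,
                   anomalies = list(list(well = "A1", kind = "flat")))
  sim <- simulate_plate(spec)
  flat <- sim$curves[sim$curves$well == "A1", ]
  expect_true(flag_low_signal(flat$fluorescence, threshold = 50))
  clean <- sim$curves[sim$curves$well == "A2", ]
  expect_false(flag_low_signal(clean$fluorescence, threshold = 50))
})

test_that("inverted test compares temperatures of global extrema", {
  t <- 1:10
  expect_true(flag_inverted(t, rev(1:10)))   # strictly decreasing
  expect_false(flag_inverted(t, 1:10))       # strictly increasing
  # ties broken by first occurrence in ascending temperature
  expect_false(flag_inverted(t, c(1, rep(5, 8), 1)))
  expect_true(flag_inverted(t, c(5, rep(1, 8), 5)))
})

test_that("high-initial-fluorescence simulated curves are flagged inverted", {
  spec <- sim_spec(geometry = "96", n_controls = 8, noise_sd = 2, seed = 4,
                   anomalies = list(list(well = "B2", kind = "inverted")))
  sim <- simulate_plate(spec)
  inv <- sim$curves[sim$curves$well == "B2", ]
  expect_true(flag_inverted(inv$temperature, inv$fluorescence))
})

test_that("spike rule matches hand arithmetic on a 101-point ramp", {
  # 99 unit steps plus one step of +100: mean = (99 + 100)/100 = 1.99,
  # ratio = 100/1.99 = 50.25
  f <- cumsum(c(0, rep(1, 50), 100, rep(1, 49)))
  expect_length(f, 101)
  expect_true(flag_discontinuity(f, multiplier = 25))
  expect_false(flag_discontinuity(f, multiplier = 60))
  # pure linear ramp: ratio 1
  expect_false(flag_discontinuity(seq(0, 100), multiplier = 25))
  # constant curve: vacuously unflagged
  expect_false(flag_discontinuity(rep(3, 10)))
})

test_that("downward spikes are caught through the absolute-value rule", {
  f <- cumsum(c(0, rep(1, 50), -100, rep(1, 49)))
  expect_true(flag_discontinuity(f, multiplier = 25))
})

test_that("qc_plate partitions wells and applies checks in order", {
  spec <- sim_spec(geometry = "96", n_controls = 8, noise_sd = 2, seed = 7,
                   anomalies = list(
                     list(well = "A1", kind = "flat"),
                     list(well = "B2", kind = "inverted"),
                     list(well = "C3", kind = "spike", spike_factor = 100),
                     list(well = "D4", kind = "flat")))
  sim <- simulate_plate(spec)
  qc <- qc_plate(sim$curves, signal_threshold = 50)
  flagged <- qc$report[!qc$report$accepted, ]
  expect_setequal(flagged$well, c("A1", "B2", "C3", "D4"))
  expect_equal(flagged$flags[flagged$well == "A1"], "LOW_SIGNAL")
  expect_equal(flagged$flags[flagged$well == "B2"], "INVERTED")
  expect_equal(flagged$flags[flagged$well == "C3"], "DISCONTINUITY")
  # every well in exactly one of accepted / flagged
  expect_equal(sum(qc$report$accepted) + nrow(flagged), 96)
  expect_setequal(unique(qc$accepted$well), qc$report$well[qc$report$accepted])
  # flags empty <=> accepted
  expect_identical(qc$report$flags == "", qc$report$accepted)
})

test_that("a clean simulated plate produces zero flags", {
  sim <- small_sim()
  qc <- qc_plate(sim$curves, signal_threshold = 50)
  expect_true(all(qc$report$accepted))
})

test_that("an all-flat plate is entirely LOW_SIGNAL and skips shape checks", {
  curves <- tibble::tibble(
    well = rep(c("A1", "A2"), each = 10),
    row = 1L, column = rep(1:2, each = 10),
    temperature = rep(seq(25, 29.5, 0.5), 2),
    fluorescence = rep(7, 20))
  qc <- qc_plate(curves, signal_threshold = 5)
  expect_true(all(qc$report$flags == "LOW_SIGNAL"))
  expect_equal(nrow(qc$accepted), 0)
})

test_that("QC is deterministic and monotone in its thresholds", {
  sim <- small_sim(seed = 19)
  r1 <- qc_plate(sim$curves, signal_threshold = 50)$report
  r2 <- qc_plate(sim$curves, signal_threshold = 50)$report
  expect_identical(r1, r2)

  # raising the signal threshold never unflags a LOW_SIGNAL well
  lo <- qc_plate(sim$curves, signal_threshold = 20)$report
  hi <- qc_plate(sim$curves, signal_threshold = 500)$report
  low_before <- lo$well[grepl("LOW_SIGNAL", lo$flags)]
  low_after <- hi$well[grepl("LOW_SIGNAL", hi$flags)]
  expect_true(all(low_before %in% low_after))

  # raising the multiplier never flags a previously clean well
  m25 <- qc_plate(sim$curves, signal_threshold = 50,
                  spike_multiplier = 25)$report
  m60 <- qc_plate(sim$curves, signal_threshold = 50,
                  spike_multiplier = 60)$report
  disc25 <- m25$well[grepl("DISCONTINUITY", m25$flags)]
  disc60 <- m60$well[grepl("DISCONTINUITY", m60$flags)]
  expect_true(all(disc60 %in% disc25))
})
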