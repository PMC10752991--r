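# Injury criteria: avulsion force threshold, tendon strain grades, muscle
# strain plug-in and the protocol report table.

test_that("mass-to-force conversion uses standard gravity", {
  expect_equal(round(load_to_force(10.8), 2), 105.91)
  expect_equal(load_to_force(0), 0)
  expect_equal(load_to_force(1), 9.80665)
  expect_error(load_to_force(-1), "non-negative")
})

test_that("tendon strain grading is inclusive and peak-based", {
  t <- seq(0, 0.2, by = 1e-3)
  mk <- function(peak) peak * sin(pi * t / 0.2)
  expect_equal(assess_tsic(t, mk(0.03))$severity, "none")
  expect_equal(assess_tsic(t, mk(0.05))$severity, "minor")
  expect_equal(assess_tsic(t, mk(0.09))$severity, "major")
  expect_equal(assess_tsic(t, mk(0.12))$severity, "rupture")
  # boundary: a peak exactly at 4% counts as minor
  f <- assess_tsic(t, c(rep(0.01, 100), 0.04, rep(0.01, 100)), mtu_name = "FDP 3")
  expect_equal(f$severity, "minor")
  expect_equal(f$first_crossing_time, t[101])
  expect_equal(f$peak_value, 0.04)
  expect_error(assess_tsic(numeric(0), numeric(0)), "empty")
})

test_that("first crossing time marks the highest attained grade", {
  t <- 0:10 / 10
  s <- c(0, 0.05, 0.05, 0.09, 0.05, 0.12, 0, 0, 0, 0, 0)
  f <- assess_tsic(t, s)
  expect_equal(f$severity, "rupture")
  expect_equal(f$first_crossing_time, 0.5)
})

test_that("avulsion triggers at the force threshold per strand", {
  t <- seq(0, 0.2, by = 1e-3)
  mk <- function(peak) peak * sin(pi * t / 0.2)
  expect_equal(assess_avulsion(t, mk(106))$severity, "avulsion")
  expect_equal(assess_avulsion(t, mk(105.90))$severity, "none")
  expect_equal(assess_avulsion(t, 0 * t)$severity, "none")
  expect_error(assess_avulsion(t, -mk(10)), "non-negative")
})

test_that("muscle strain criterion is threshold-agnostic", {
  t <- seq(0, 0.1, by = 1e-3)
  mk <- function(peak) peak * sin(pi * t / 0.1)
  expect_equal(assess_msic(t, mk(0.05), c(0.1, 0.2, 0.3))$severity, "none")
  expect_equal(assess_msic(t, mk(0.25), c(0.1, 0.2, 0.3))$severity, "major")
  f <- assess_msic(t, mk(0.25), NULL)
  expect_equal(f$severity, "not-evaluated")
  expect_false(f$evaluated)
  expect_error(assess_msic(t, mk(0.2), c(0.3, 0.2, 0.1)), "increasing")
})

test_that("grading is monotone in the peak value", {
  t <- seq(0, 0.1, by = 1e-3)
  sev_rank <- c(none = 0, minor = 1, major = 2, rupture = 3)
  peaks <- seq(0.01, 0.15, by = 0.005)
  ranks <- vapply(peaks, function(p) {
    sev_rank[[assess_tsic(t, p * sin(pi * t / 0.1))$severity]]
  }, numeric(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("avulsion and strain criteria are independent", {
  # a stiff tendon can transmit an avulsion-level force at low strain
  t <- seq(0, 0.1, by = 1e-3)
  force <- 120 * sin(pi * t / 0.1)
  strain <- 0.03 * sin(pi * t / 0.1)
  th <- injury_thresholds()
  expect_equal(assess_avulsion(t, force, th)$severity, "avulsion")
  expect_equal(assess_tsic(t, strain, th)$severity, "none")
})

test_that("the report table aggregates findings per simulation", {
  t <- seq(0, 0.2, by = 1e-3)
  quiet <- assess_tsic(t, 0.01 * sin(pi * t / 0.2), mtu_name = "FDP 2")
  avul <- assess_avulsion(t, 120 * sin(pi * t / 0.2), mtu_name = "FDS 3")
  avul2 <- assess_avulsion(t, 110 * sin(pi * t / 0.2), mtu_name = "FDP 3")
  avul3 <- assess_avulsion(t, 108 * sin(pi * t / 0.2), mtu_name = "FDP 5")
  rep <- build_report(list(list(quiet), list(quiet, avul),
                           list(avul2, avul, avul3)),
                      data.frame(simulation = 1:3, a_pct = c(0, 80, 100)))
  expect_equal(rep$n_injuries, c(0, 1, 3))
  expect_equal(rep$injury_types[1], "")
  expect_equal(rep$injury_types[2], "Tendon Avulsion")
  expect_equal(rep$injured_mtus[2], "FDS 3")
  expect_equal(rep$injured_mtus[3], "FDP 3, FDS 3, FDP 5")
})

test_that("threshold containers validate their orderings", {
  expect_error(injury_thresholds(tsic_minor = 0.1, tsic_major = 0.08))
  expect_error(injury_thresholds(msic = c(0.3, 0.2, 0.1)), "increasing")
  th <- injury_thresholds()
  expect_equal(th$avulsion_force, 10.8 * 9.80665)
  expect_equal(c(th$tsic_minor, th$tsic_major, th$tsic_rupture),
               c(0.04, 0.08, 0.10))
})
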