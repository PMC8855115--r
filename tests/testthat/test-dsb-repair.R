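test_that("repair-rate interpolation is piecewise linear with clamped ends", {
  rk <- repair_kinetics(c(4, 8), c(0.10, 0.20))
  expect_equal(repair_rate_at_dose(rk, 4), 0.10)   # exact node
  expect_equal(repair_rate_at_dose(rk, 8), 0.20)
  expect_equal(repair_rate_at_dose(rk, 6), 0.15)   # midpoint

  rk4 <- repair_kinetics(c(2, 4, 8, 16), c(0.08, 0.10, 0.20, 0.30))
  # hand-evaluated bracketing segment at 5.3 Gy
  expect_equal(repair_rate_at_dose(rk4, 5.3),
               0.10 + (5.3 - 4) / (8 - 4) * (0.20 - 0.10))
  # outside the tabulated range: nearest endpoint
  expect_equal(repair_rate_at_dose(rk4, 1), 0.08)
  expect_equal(repair_rate_at_dose(rk4, 30), 0.30)
  # any dose between two nodes interpolates between the node rates
  for (d in seq(2.1, 15.9, length.out = 23)) {
    lo <- max(which(rk4$doses <= d)); hi <- lo + 1L
    rate <- repair_rate_at_dose(rk4, d)
    expect_gte(rate, min(rk4$rates[c(lo, hi)]))
    expect_lte(rate, max(rk4$rates[c(lo, hi)]))
  }
})

test_that("repair-kinetics validation rejects bad tables and doses", {
  expect_error(repair_kinetics(4, 0.1), class = "fracdyn_config_error")
  expect_error(repair_kinetics(c(4, 4), c(0.1, 0.2)),
               class = "fracdyn_config_error")
  expect_error(repair_kinetics(c(8, 4), c(0.1, 0.2)),
               class = "fracdyn_config_error")
  expect_error(repair_kinetics(c(4, 8), c(-0.1, 0.2)),
               class = "fracdyn_config_error")
  rk <- repair_kinetics(c(4, 8), c(0.1, 0.2))
  expect_error(repair_rate_at_dose(rk, 0), class = "fracdyn_domain_error")
  expect_error(repair_rate_at_dose(rk, -2), class = "fracdyn_domain_error")
})

test_that("unrepaired DSB fraction follows exponential decay", {
  expect_equal(fraction_unrepaired(0.3, 0), 1)
  expect_equal(fraction_unrepaired(0, 100), 1)
  expect_equal(fraction_unrepaired(log(2) / 12, 24), 0.25)
  expect_error(fraction_unrepaired(-0.1, 1), class = "fracdyn_domain_error")
  expect_error(fraction_unrepaired(0.1, -1), class = "fracdyn_domain_error")

  # monotone nonincreasing in t and in k on grids
  ts <- seq(0, 72, by = 1.5)
  ks <- seq(0, 0.4, by = 0.02)
  for (k in ks) expect_true(all(diff(fraction_unrepaired(k, ts)) <= 0))
  for (t in ts) expect_true(all(diff(fraction_unrepaired(ks, t)) <= 0))
})

test_that("time since fraction reproduces the gated 24 h schedule", {
  fts <- c(0, 24, 48, 72)
  expect_equal(time_since_fraction(30, fts, 1), 30)
  expect_equal(time_since_fraction(30, fts, 2), 6)
  expect_equal(time_since_fraction(10, fts, 2), 0)
  expect_equal(time_since_fraction(24, fts, 2), 0)  # gate is strict
  expect_error(time_since_fraction(10, fts, 0), class = "fracdyn_index_error")
  expect_error(time_since_fraction(10, fts, 5), class = "fracdyn_index_error")
  # generalized fraction times agree with the 24*(i-1) closed form
  for (i in 1:4) for (t in seq(0, 120, by = 7))
    expect_equal(time_since_fraction(t, fts, i), max(t - 24 * (i - 1), 0))
})

test_that("synthetic repair tables repair >80% of DSBs within 24 hours", {
  used_doses <- c(4, 5, 5.3, 6.7, 8, 10)  # doses per fraction in the presets
  for (line in c("9L", "C6")) {
    rk <- synthetic_repair_kinetics(line)
    k24 <- fraction_unrepaired(repair_rate_at_dose(rk, used_doses), 24)
    expect_true(all(k24 < 0.2))
  }
})

test_that("repair-kinetics CSV round-trips", {
  rk <- synthetic_repair_kinetics("C6")
  path <- withr::local_tempfile(fileext = ".csv")
  write_repair_kinetics(rk, path)
  rk2 <- read_repair_kinetics(path)
  expect_equal(rk2$doses, rk$doses)
  expect_equal(rk2$rates, rk$rates)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("dose,k", bad)
  expect_error(read_repair_kinetics(bad), class = "fracdyn_format_error")
})
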