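test_that("schedule presets match the six-arm experimental design", {
  ps <- schedule_presets()
  expect_named(ps, c("16x2", "16x3", "16x4", "20x2", "20x3", "20x4"))
  expect_equal(vapply(ps, function(s) s$total_dose, 0),
               c(`16x2` = 16, `16x3` = 16, `16x4` = 16,
                 `20x2` = 20, `20x3` = 20, `20x4` = 20))
  expect_equal(ps[["16x3"]]$dose_per_fraction, 5.3)
  expect_equal(ps[["20x3"]]$dose_per_fraction, 6.7)
  for (s in ps) expect_true(all(diff(s$fraction_times) == 24))
  # total dose must agree with dose_per_fraction * n within 2%
  expect_error(dose_schedule(c(0, 24), 8, total_dose = 20),
               class = "fracdyn_config_error")
  expect_error(dose_schedule(c(24, 48), 8), class = "fracdyn_config_error")
  expect_error(schedule_preset("12x9"), class = "fracdyn_usage_error")
})

test_that("untreated growth rate has the logistic-Allee form", {
  g <- growth_params(k_p = 0.04, theta = 0.8, A = 0.5)
  expect_equal(untreated_rhs(0.8, g), 0)            # fixed point at theta
  expect_equal(untreated_rhs(0.3, growth_params(0, 0.8, 0.5)), 0)
  gA0 <- growth_params(0.04, 0.8, 0)
  expect_equal(untreated_rhs(0.4, gA0), 0.04 * 0.8 / 8)  # k_p*theta/8
})

test_that("early death rate sums gated, repair-weighted fraction terms", {
  kin <- fx_kin()
  spec3 <- model_family()[["model_3"]]
  sched <- schedule_preset("16x2")
  rad0 <- radiation_params(k_acute_N = 0, alpha_accum_N = 3,
                           k_accum_D = 2e-4, r = 0.02,
                           k_ps = c("16" = 0.05, "20" = 0.08))
  expect_equal(early_death_rate(c(1, 10, 50), spec3, rad0, sched, 0.1, kin),
               c(0, 0, 0))
  spec_none <- model_spec(early = "none", late = "full", senescence = FALSE)
  expect_equal(early_death_rate(25, spec_none, rad0, sched, 0.1, kin), 0)

  # single fraction, k_repair chosen so f_DSB(24) = 0.2: hand-built term
  kin2 <- repair_kinetics(c(1, 16), rep(-log(0.2) / 24, 2))
  s1 <- dose_schedule(0, 8)
  rad <- radiation_params(k_acute_N = 0.4)
  expect_equal(early_death_rate(24, spec3, rad, s1, 0.1, kin2),
               0.4 * 0.1 * 0.2 * tanh(0.2))
  # undelivered fractions contribute nothing
  expect_equal(early_death_rate(0, spec3, rad, s1, 0.1, kin2), 0)
})

test_that("late death rate rises to a peak at 1/r and decays", {
  spec3 <- model_family()[["model_3"]]
  s1 <- dose_schedule(0, 8)
  rad <- radiation_params(alpha_accum_N = 2, k_accum_D = 3e-4, r = 0.025,
                          k_ps = c("8" = 0))
  expect_equal(late_death_rate(0, spec3, rad, s1, 0.1), 0)
  tt <- seq(0, 300, by = 0.05)
  kld <- late_death_rate(tt, spec3, rad, s1, 0.1)
  expect_equal(tt[which.max(kld)], 1 / rad$r, tolerance = 1e-3)
  # alpha = 0 reduces to k_accum_D * D * sum(t_i exp(-r t_i))
  rad0 <- radiation_params(alpha_accum_N = 0, k_accum_D = 3e-4, r = 0.025,
                           k_ps = c("16" = 0))
  s2 <- schedule_preset("16x2")
  t <- 60
  manual <- 3e-4 * 8 * sum(sapply(1:2, function(i) {
    ti <- time_since_fraction(t, s2$fraction_times, i)
    ti * exp(-0.025 * ti)
  }))
  expect_equal(late_death_rate(t, spec3, rad0, s2, 0.2), manual)
})

test_that("treated RHS reduces to untreated growth and conserves totals", {
  g <- fx_growth()
  kin <- fx_kin()
  spec3 <- model_family()[["model_3"]]
  sched <- schedule_preset("16x4")
  zero_rad <- radiation_params(k_ps = c("16" = 0, "20" = 0))
  d <- treated_rhs(c(0.2, 0), 37, spec3, g, zero_rad, sched, 0.2, kin)
  expect_equal(d[1L], untreated_rhs(0.2, g))
  expect_equal(d[2L], 0)

  # pure conversion conserves N_p + N_s
  g0 <- growth_params(0, g$theta, g$A)
  conv <- radiation_params(k_ps = c("16" = 0.3, "20" = 0.3))
  d2 <- treated_rhs(c(0.2, 0.05), 10, spec3, g0, conv, sched, 0.2, kin)
  expect_equal(sum(d2), 0)
  expect_equal(d2[2L], 0.3 * 0.2 * 0.2)

  # at capacity, growth and late-death products vanish
  rad <- synthetic_radiation_params("9L")
  np <- 0.6; ns <- g$theta - np
  d3 <- treated_rhs(c(np, ns), 30, spec3, g, rad, sched, 0.1, kin)
  ked <- early_death_rate(30, spec3, rad, sched, 0.1, kin)
  expect_equal(d3[1L], -(ked + rad$k_ps[["16"]] * 0.1) * np)
})

test_that("the candidate family has the eight stated members", {
  fam <- model_family(k_ps_doses = c(16, 20))
  expect_length(fam, 8L)
  expect_equal(vapply(fam, function(s) s$id, 0L), setNames(1:8, names(fam)))
  m3 <- fam[["model_3"]]
  expect_equal(m3$free_parameter_names,
               c("k_acute_N", "alpha_accum_N", "k_accum_D", "r",
                 "k_ps_16", "k_ps_20"))
  expect_length(m3$free_parameter_names, 6L)
  expect_equal(fam[["model_1"]]$free_parameter_names,
               c("alpha_acute_N", "k_acute_D", "alpha_accum_N", "k_accum_D",
                 "r", "k_ps_16", "k_ps_20"))
  expect_false(any(grepl("^k_ps", fam[["model_8"]]$free_parameter_names)))
  expect_false("r" %in% fam[["model_7"]]$free_parameter_names)
  expect_true(fam[["model_1"]]$senescence)
  expect_false(fam[["model_8"]]$senescence)
})

test_that("Euler simulation honors degenerate limits and output gridding", {
  g0 <- growth_params(0, 0.9, 1)
  kin <- fx_kin()
  spec3 <- model_family()[["model_3"]]
  zero_rad <- radiation_params(k_ps = c("16" = 0, "20" = 0))
  tr <- simulate_confluence(spec3, g0, zero_rad, "16x2", 0.12, kin,
                            output_times = seq(0, 100, by = 10), dt = 0.05)
  expect_equal(tr$N_total, rep(0.12, 11))

  spec8 <- model_family()[["model_8"]]
  rad <- synthetic_radiation_params("9L")
  tr8 <- simulate_confluence(spec8, fx_growth(), rad, "20x2", 0.1, kin,
                             output_times = seq(0, 150, by = 7.3), dt = 0.05)
  expect_true(all(tr8$N_s == 0))

  # output uses the grid point at or before the requested time
  tr2 <- simulate_confluence(spec3, fx_growth(), rad, "16x4", 0.1, kin,
                             output_times = c(0, 10.003, 10.009), dt = 0.01)
  expect_equal(tr2$N_total[2L], tr2$N_total[3L])  # same grid point (10.00)
  expect_error(simulate_confluence(spec3, fx_growth(), rad, "16x4", -0.1,
                                   kin, output_times = c(0, 10)),
               class = "fracdyn_domain_error")
})

test_that("compiled Euler kernel matches a pure-R Euler built on the RHS", {
  g <- fx_growth(); kin <- fx_kin()
  rad <- synthetic_radiation_params("9L")
  for (spec in model_family()[c("model_1", "model_3", "model_8")]) {
    for (sid in c("16x4", "20x2")) {
      ot <- seq(0, 60, by = 4.7)
      a <- simulate_confluence(spec, g, rad, sid, 0.15, kin, ot, dt = 0.02)
      b <- r_euler(spec, g, rad, schedule_preset(sid), 0.15, kin, ot,
                   dt = 0.02)
      expect_equal(a$N_p, b$N_p, tolerance = 1e-10)
      expect_equal(a$N_s, b$N_s, tolerance = 1e-10)
    }
  }
})

test_that("simulated trajectories satisfy the structural invariants", {
  # non-negativity, boundedness by theta (+ Euler overshoot), monotone
  # senescent compartment, across seeded random admissible parameters
  set.seed(401)
  g <- fx_growth(); kin <- fx_kin()
  fam <- model_family()
  dt <- 0.05
  for (i in 1:12) {
    spec <- fam[[sample(8, 1)]]
    rad <- radiation_params(
      alpha_acute_N = runif(1, 0, 8), k_acute_D = runif(1, 0, 0.01),
      k_acute_N = runif(1, 0, 0.3), alpha_accum_N = runif(1, 0, 8),
      k_accum_D = runif(1, 0, 4e-4), k_accum_N = runif(1, 0, 0.01),
      r = runif(1, 0.005, 0.05),
      k_ps = c("16" = runif(1, 0, 0.1), "20" = runif(1, 0, 0.1)))
    sid <- sample(names(schedule_presets()), 1)
    n0 <- exp(runif(1, log(0.03), log(0.3)))
    tr <- simulate_confluence(spec, g, rad, sid, n0, kin,
                              output_times = seq(0, 330, by = 3), dt = dt)
    expect_true(all(tr$N_p >= 0) && all(tr$N_s >= 0))
    expect_true(all(tr$N_total <= g$theta * (1 + 10 * dt * g$k_p)))
    expect_true(all(diff(tr$N_s) >= -1e-12))
  }
})

test_that("early-exponential growth recovers k_p and death terms order correctly", {
  g <- growth_params(k_p = 0.035, theta = 0.95, A = 1)
  kin <- fx_kin()
  spec3 <- model_family()[["model_3"]]
  zero_rad <- radiation_params(k_ps = c("16" = 0, "20" = 0))
  tr <- simulate_confluence(spec3, g, zero_rad, "16x2", 1e-3, kin,
                            output_times = seq(0, 150, by = 2), dt = 0.01)
  win <- tr$N_p < 0.05 * g$theta & tr$time > 0
  slope <- stats::coef(stats::lm(log(tr$N_p[win]) ~ tr$time[win]))[[2L]]
  expect_equal(slope, g$k_p, tolerance = 0.02)

  # single-fraction death ordering: early death maximal just after the
  # fraction then decaying; late death 0 at t=0, peaking at 1/r
  rad <- synthetic_radiation_params("9L")
  s1 <- dose_schedule(0, 8)
  tt <- seq(0.01, 250, by = 0.01)
  ked <- early_death_rate(tt, spec3, rad, s1, 0.1, kin)
  kld <- late_death_rate(tt, spec3, rad, s1, 0.1)
  expect_equal(which.max(ked), 1L)
  expect_true(all(diff(ked) <= 1e-12))
  expect_gt(tt[which.max(kld)], 1)
  expect_equal(tt[which.max(kld)], 1 / rad$r, tolerance = 1e-3)
})
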