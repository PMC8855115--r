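# Calibration tests run on small consistent worlds (generator and fit share
# the Euler step) so optimizer behavior, not discretization, is what is
# being tested; full-resolution dt = 0.01 recovery lives in the acceptance
# suite.

test_that("global residuals vanish at truth and honor canonical ordering", {
  truth <- fx_truth(noise_cv = 0, reps = 2, dt = 0.1)
  ds <- generate_dataset(truth, seed = 42)
  g <- list(`9L` = fx_growth()); kin <- fx_kin()
  spec <- model_family()[["model_3"]]
  par <- fx_model3_par()

  r <- residuals_global(par, spec, ds$curves, g, kin, dt = 0.1)
  expect_lt(max(abs(r)), 1e-12)
  expect_length(r, sum(vapply(ds$curves, function(cv) length(cv$times), 0L)))

  # invariant to input ordering: residuals are concatenated after a
  # canonical sort by replicate id
  shuffled <- ds$curves[sample(length(ds$curves))]
  expect_identical(
    residuals_global(par, spec, ds$curves, g, kin, dt = 0.1),
    residuals_global(par, spec, shuffled, g, kin, dt = 0.1))

  # a single curve with a single (t = 0) observation gives one residual
  cv1 <- confluence_curve("solo", "9L", "16x2", 0, 0.1)
  expect_length(residuals_global(par, spec, list(cv1), g, kin, dt = 0.1), 1L)
  expect_error(residuals_global(par[-1], spec, ds$curves, g, kin),
               class = "fracdyn_config_error")
})

test_that("noise-free curves are recovered near-exactly by the global fit", {
  truth <- fx_truth(noise_cv = 0, reps = 2, dt = 0.1)
  ds <- generate_dataset(truth, seed = 42)
  g <- list(`9L` = fx_growth()); kin <- fx_kin()
  spec <- model_family()[["model_3"]]
  true_par <- fx_model3_par()

  cb <- calibrate_global(spec, ds$curves, g, kin, n_starts = 8, seed = 1,
                         dt = 0.1, control = list(maxfev = 800))
  expect_lt(cb$rss, 1e-16)
  expect_lt(max(abs(cb$estimates / true_par - 1)), 1e-6)
  expect_true(all(cb$estimates >= 0))
  expect_true(all(cb$ci[, "lower"] <= cb$estimates &
                    cb$estimates <= cb$ci[, "upper"]))
  expect_equal(cb$rss, sum(cb$residuals^2))
  expect_equal(cb$m, length(cb$residuals))

  # starting at the truth: immediate convergence, essentially zero RSS
  cb0 <- calibrate_global(spec, ds$curves, g, kin, init = true_par,
                          n_starts = 1, seed = 1, dt = 0.1)
  expect_true(cb0$converged)
  expect_lt(cb0$rss, 1e-10)
})

test_that("calibration is bit-reproducible under a fixed seed", {
  truth <- fx_truth(noise_cv = 0.21, reps = 2, dt = 0.2)
  ds <- generate_dataset(truth, seed = 9)
  g <- list(`9L` = fx_growth()); kin <- fx_kin()
  spec <- model_family()[["model_3"]]
  run <- function() calibrate_global(spec, ds$curves, g, kin, n_starts = 4,
                                     seed = 7, dt = 0.2,
                                     control = list(maxfev = 150))
  a <- run(); b <- run()
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$rss, b$rss)
  expect_identical(a$starts, b$starts)
  expect_true(all(a$estimates >= 0))
  # best-of-restarts: returned RSS is no worse than any restart endpoint
  expect_true(all(a$rss <= a$starts$rss + 1e-15))
})

test_that("single-density designs expose the acute-death collinearity", {
  # with every curve at the same N0, (alpha_acute_N*N0+1)*k_acute_D only
  # enters through its product, so the pair must be flagged
  truth <- fx_truth(noise_cv = 0, reps = 2, dt = 0.2, model_id = 1L)
  truth$n0_range <- c(0.1, 0.100001)
  rad <- synthetic_radiation_params("9L")
  truth$cell_lines[["9L"]]$rad <- rad
  ds <- generate_dataset(truth, seed = 3)
  g <- list(`9L` = fx_growth()); kin <- fx_kin()
  spec <- model_family()[["model_1"]]
  cb <- suppressWarnings(calibrate_global(
    spec, ds$curves, g, kin,
    init = par_from_rad(spec, rad), n_starts = 1, seed = 1, dt = 0.2,
    control = list(maxfev = 200)))
  pair <- cb$collinear_pairs
  expect_true(any(pair$par_a == "alpha_acute_N" & pair$par_b == "k_acute_D"))
})

test_that("untreated-control fitting recovers the growth parameters", {
  g <- growth_params(k_p = 0.035, theta = 0.92, A = 1)
  times <- seq(0, 300, by = 5)
  ctrl <- simulate_untreated(g, 0.04, times, dt = 0.05)
  fit <- fit_growth_params(times, ctrl$N_total, dt = 0.05)
  expect_true(fit$converged)
  expect_equal(fit$growth$k_p, g$k_p, tolerance = 0.02)
  expect_equal(fit$growth$theta, g$theta, tolerance = 0.02)
  expect_lt(fit$rss, 1e-4)
})

test_that("cell-line parameter comparison implements the two-sample z-test", {
  fake <- function(est, se) {
    structure(list(estimates = c(k_accum_D = est),
                   se = c(k_accum_D = se)),
              class = "calibration_result")
  }
  eq <- compare_cell_lines(fake(2e-4, 1e-5), fake(2e-4, 1e-5), "k_accum_D")
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_false(eq$significant)

  # difference of exactly 1.96 pooled SEs sits at the 5% boundary
  se <- c(3e-5, 4e-5)
  delta <- 1.96 * sqrt(sum(se^2))
  bd <- compare_cell_lines(fake(2e-4 + delta, se[1L]), fake(2e-4, se[2L]),
                           "k_accum_D")
  expect_equal(bd$p_value, 0.05, tolerance = 1e-3)
  expect_error(compare_cell_lines(fake(1, 1), fake(1, 1), "nope"),
               class = "fracdyn_domain_error")
})

test_that("a 3x death-rate difference between lines is detected at 5%", {
  # two synthetic lines differing only in k_accum_D (3x), low noise
  g9 <- fx_growth("9L"); kin <- fx_kin()
  mk_truth <- function(kacc) {
    truth <- fx_truth(noise_cv = 0.05, reps = 2, dt = 0.2)
    truth$cell_lines[["9L"]]$rad$k_accum_D <- kacc
    truth
  }
  spec <- model_family()[["model_3"]]
  fit <- function(truth, seed) {
    ds <- generate_dataset(truth, seed = seed)
    calibrate_global(spec, ds$curves, list(`9L` = g9), kin,
                     init = par_from_rad(spec, truth$cell_lines[["9L"]]$rad),
                     n_starts = 2, seed = 1, dt = 0.2,
                     control = list(maxfev = 250))
  }
  cb_a <- fit(mk_truth(2.2e-4), 11)
  cb_b <- fit(mk_truth(6.6e-4), 12)
  cmp <- compare_cell_lines(cb_a, cb_b, "k_accum_D")
  expect_true(cmp$significant)
  expect_lt(cmp$p_value, 0.05)
})
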