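test_that("noiseless replicates equal the generating model exactly", {
  truth <- fx_truth(noise_cv = 0, reps = 1, dt = 0.1)
  cv <- generate_replicate(truth, "9L", "16x4", 0.1, seed = 5)
  sim <- simulate_confluence(truth$generating_model,
                             truth$cell_lines[["9L"]]$growth,
                             truth$cell_lines[["9L"]]$rad,
                             "16x4", 0.1, truth$cell_lines[["9L"]]$kinetics,
                             output_times = cv$times, dt = 0.1)
  expect_equal(cv$confluence, sim$N_total)
  expect_equal(attr(cv, "true_confluence"), sim$N_total)
  expect_equal(cv$N0, cv$confluence[1L])
  expect_error(generate_replicate(truth, "9L", "16x4", 0.9, seed = 5),
               class = "fracdyn_domain_error")
})

test_that("generation is deterministic in the seed", {
  truth <- fx_truth(noise_cv = 0.21, reps = 1, dt = 0.2)
  a <- generate_replicate(truth, "9L", "20x3", 0.07, seed = 123)
  b <- generate_replicate(truth, "9L", "20x3", 0.07, seed = 123)
  expect_identical(a$confluence, b$confluence)
  expect_identical(a$times, b$times)
  c_ <- generate_replicate(truth, "9L", "20x3", 0.07, seed = 124)
  expect_false(identical(a$confluence, c_$confluence))

  ds1 <- generate_dataset(truth, seed = 8)
  ds2 <- generate_dataset(truth, seed = 8)
  expect_identical(curves_to_df(ds1$curves), curves_to_df(ds2$curves))
})

test_that("datasets are full factorials with the configured counts", {
  truth <- default_truth(noise_cv = 0.21, replicates_per_condition = 3,
                         dt = 0.5)
  ds <- generate_dataset(truth, seed = 2)
  expect_length(ds$curves, 2 * 6 * 3)
  df <- curves_to_df(ds$curves)
  counts <- table(df[!duplicated(df$replicate_id),
                     c("cell_line", "schedule_id")])
  expect_true(all(counts == 3))
  for (cv in ds$curves) {
    expect_equal(cv$N0, cv$confluence[1L])
    expect_gte(min(diff(cv$times)), truth$interval_range[1L] - 1e-9)
    expect_lte(max(diff(cv$times)), truth$interval_range[2L] + 1e-9)
    expect_lte(max(cv$times), truth$horizon)
  }
  # sampling cadence covers the horizon
  expect_gt(max(vapply(ds$curves, function(cv) max(cv$times), 0)), 320)
})

test_that("measurement noise has the configured multiplicative CV", {
  truth <- fx_truth(noise_cv = 0.21, reps = 1, dt = 0.5)
  ratios <- unlist(lapply(1:300, function(i) {
    cv <- generate_replicate(truth, "9L", "16x2", 0.1, seed = 1000 + i)
    tv <- attr(cv, "true_confluence")
    keep <- tv > 1e-6
    cv$confluence[keep] / tv[keep]
  }))
  expect_equal(stats::sd(ratios), 0.21, tolerance = 0.02 / 0.21)
  expect_equal(mean(ratios), 1, tolerance = 0.01)
  expect_true(all(ratios >= 0))
})

test_that("stratified split is exhaustive, disjoint and condition-balanced", {
  truth <- fx_truth(noise_cv = 0.1, reps = 12, dt = 1)
  truth$horizon <- 100
  ds <- generate_dataset(truth, seed = 4)
  sp <- train_validation_split(ds, fraction = 0.75, seed = 6)
  expect_length(sp$training, 54)   # 9 of 12 per condition
  expect_length(sp$validation, 18)
  df <- curves_to_df(ds$curves)
  ids_all <- sort(unique(df$replicate_id))
  expect_setequal(c(names(sp$training), names(sp$validation)), ids_all)
  expect_length(intersect(names(sp$training), names(sp$validation)), 0L)
  tr_tab <- table(vapply(sp$training, function(cv) cv$schedule_id, ""))
  expect_true(all(tr_tab == 9))
  sp2 <- train_validation_split(ds, fraction = 0.75, seed = 6)
  expect_identical(names(sp2$training), names(sp$training))
  # singleton stratum goes to training with a warning
  solo <- list(confluence_curve("a", "9L", "16x2", c(0, 5), c(0.1, 0.11)),
               confluence_curve("b", "9L", "16x3", c(0, 5), c(0.1, 0.12)),
               confluence_curve("c", "9L", "16x3", c(0, 5), c(0.2, 0.22)))
  expect_warning(sp3 <- train_validation_split(solo, 0.75, seed = 1,
                                               n_density_strata = 1L),
                 "single replicate")
  expect_true("a" %in% names(sp3$training))
})

test_that("default truth reproduces the treated-curve morphology", {
  # noise-free weak schedule at low seeding: rise, post-treatment decline,
  # late regrowth; a stronger schedule reaches a deeper minimum
  truth <- fx_truth(noise_cv = 0, reps = 1, dt = 0.05)
  weak <- generate_replicate(truth, "9L", "16x4", 0.05, seed = 1)
  y <- attr(weak, "true_confluence"); tt <- weak$times
  i_peak <- which.max(y[tt < 100])
  expect_gt(y[i_peak], y[1L])                         # initial rise
  i_min <- which.min(y[tt > tt[i_peak]]) + i_peak
  expect_lt(y[i_min], y[i_peak])                      # decline
  expect_gt(y[length(y)], y[i_min] * 1.05)            # late regrowth
  strong <- generate_replicate(truth, "9L", "20x2", 0.05, seed = 1)
  expect_lt(min(attr(strong, "true_confluence")), y[i_min])
})

test_that("media-change artifacts create persistent downward jumps", {
  base <- fx_truth(noise_cv = 0, reps = 1, dt = 0.1)
  mc <- fx_truth(noise_cv = 0, reps = 1, dt = 0.1)
  mc$media_change <- list(period = 120, loss_range = c(0.2, 0.3))
  a <- generate_replicate(base, "9L", "16x4", 0.1, seed = 77)
  b <- generate_replicate(mc, "9L", "16x4", 0.1, seed = 77)
  ya <- attr(a, "true_confluence"); yb <- attr(b, "true_confluence")
  expect_identical(a$times, b$times)
  pre <- max(which(a$times <= 120))
  expect_equal(yb[seq_len(pre)], ya[seq_len(pre)])    # identical before jump
  expect_lt(yb[pre + 1L] / ya[pre + 1L], 0.85)        # loss applied after
})
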