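# Shared fixtures for the test suite. All datasets are generated in code;
# sizes and Euler steps are scaled to keep the default run inside its CPU
# budget (noted per test), while dt = 0.01 itself is exercised by the
# oracle-equivalence and recovery acceptance tests.

fx_growth <- function(line = "9L") synthetic_growth_params(line)
fx_kin <- function(line = "9L") synthetic_repair_kinetics(line)

# free-parameter vector of a spec, pulled from a radiation_params truth
par_from_rad <- function(spec, rad) {
  vapply(spec$free_parameter_names, function(nm) {
    if (grepl("^k_ps_", nm)) rad$k_ps[[sub("^k_ps_", "", nm)]]
    else rad[[nm]]
  }, 0)
}

# small single-line truth; consistent generator/fit Euler step
fx_truth <- function(noise_cv = 0, reps = 2, dt = 0.1, model_id = 3L,
                     line = "9L", ...) {
  truth <- default_truth(model_id, noise_cv = noise_cv,
                         replicates_per_condition = reps, dt = dt, ...)
  truth$cell_lines <- truth$cell_lines[line]
  truth
}

fx_model3_par <- function(line = "9L")
  par_from_rad(model_family()[["model_3"]],
               synthetic_radiation_params(line))

# pure-R explicit Euler built on treated_rhs(): the dual route used to
# cross-check the compiled kernel
r_euler <- function(spec, growth, rad, schedule, N0, kinetics, output_times,
                    dt, gate_sharpness = 1) {
  if (is.character(schedule)) schedule <- schedule_preset(schedule)
  n_steps <- ceiling(max(output_times) / dt - 1e-9)
  out_idx <- pmin(floor(output_times / dt + 1e-9), n_steps)
  st <- c(N0, 0)
  out <- matrix(NA_real_, length(output_times), 2)
  for (i in 0:n_steps) {
    hit <- which(out_idx == i)
    if (length(hit)) out[hit, ] <- rep(st, each = length(hit))
    if (i == n_steps) break
    d <- treated_rhs(st, i * dt, spec, growth, rad, schedule, N0, kinetics,
                     gate_sharpness)
    st <- pmax(st + dt * d, 0)
  }
  data.frame(time = output_times, N_p = out[, 1], N_s = out[, 2],
             N_total = out[, 1] + out[, 2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
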