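# Independent high-accuracy oracle for the fixed-step Euler simulator:
# adaptive Runge-Kutta-Fehlberg 4(5) with its own, independently coded
# right-hand side, integrating piecewise between fraction times (the RHS is
# discontinuous where a fraction's death terms switch on).

oracle_coefs <- function(spec, rad, schedule, N0) {
  D <- schedule$dose_per_fraction
  ka <- switch(spec$early,
               full = (rad$alpha_acute_N * N0 + 1) * rad$k_acute_D * D,
               dose_only = rad$k_acute_D * D,
               density_only = rad$k_acute_N * N0,
               none = 0)
  kacc <- switch(spec$late,
                 full = (rad$alpha_accum_N * N0 + 1) * rad$k_accum_D * D,
                 dose_only = rad$k_accum_D * D,
                 density_only = rad$k_accum_N * N0,
                 none = 0)
  kps <- if (spec$senescence)
    rad$k_ps[[sprintf("%g", schedule$total_dose)]] else 0
  list(ka = ka, kacc = kacc, r = rad$r, kps = kps)
}

# RHS over one smooth segment: active_fts are the fractions delivered at or
# before the segment start (their terms are continuous limits at t_i = 0)
oracle_rhs <- function(t, y, P, active_fts) {
  ked <- 0; kld <- 0
  for (ft in active_fts) {
    ti <- t - ft
    f <- exp(-P$krep * ti)
    ked <- ked + P$ka * f * tanh(P$s * f)
    kld <- kld + P$kacc * ti * exp(-P$r * ti)
  }
  ntot <- y[1L] + y[2L]
  grow <- (P$kp - kld) * (ntot / P$theta + P$A) * y[1L] *
    (1 - ntot / P$theta)
  conv <- P$kps * P$N0 * y[1L]
  c(grow - ked * y[1L] - conv, conv)
}

# Fehlberg 4(5) tableau
.rkf <- list(
  a = c(0, 1/4, 3/8, 12/13, 1, 1/2),
  b = list(c(),
           c(1/4),
           c(3/32, 9/32),
           c(1932/2197, -7200/2197, 7296/2197),
           c(439/216, -8, 3680/513, -845/4104),
           c(-8/27, 2, -3544/2565, 1859/4104, -11/40)),
  c4 = c(25/216, 0, 1408/2565, 2197/4104, -1/5, 0),
  c5 = c(16/135, 0, 6656/12825, 28561/56430, -9/50, 2/55))

rk45_segment <- function(f, t0, t1, y, rtol, atol) {
  h <- (t1 - t0) / 10
  t <- t0
  while (t < t1 - 1e-12) {
    h <- min(h, t1 - t)
    k <- matrix(0, 2, 6)
    for (s in 1:6) {
      ys <- y
      if (s > 1) ys <- y + h * drop(k[, 1:(s - 1), drop = FALSE] %*%
                                      .rkf$b[[s]])
      k[, s] <- f(t + .rkf$a[s] * h, ys)
    }
    y4 <- y + h * drop(k %*% .rkf$c4)
    y5 <- y + h * drop(k %*% .rkf$c5)
    err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y5), abs(y))))
    if (is.na(err) || err <= 1) {
      t <- t + h
      y <- y5
    }
    fac <- if (is.na(err) || err == 0) 5 else 0.9 * err^(-0.2)
    h <- h * min(5, max(0.2, fac))
  }
  y
}

rk45_oracle <- function(spec, growth, rad, schedule, N0, kinetics,
                        output_times, gate_sharpness = 1,
                        rtol = 1e-9, atol = 1e-12) {
  cf <- oracle_coefs(spec, rad, schedule, N0)
  P <- list(kp = growth$k_p, theta = growth$theta, A = growth$A,
            N0 = N0, ka = cf$ka, kacc = cf$kacc, r = cf$r, kps = cf$kps,
            krep = repair_rate_at_dose(kinetics, schedule$dose_per_fraction),
            s = gate_sharpness)
  output_times <- sort(output_times)
  brk <- sort(unique(c(0, schedule$fraction_times, output_times)))
  brk <- brk[brk <= max(output_times)]
  y <- c(N0, 0)
  out <- matrix(NA_real_, length(output_times), 2)
  record <- function(tt, y) {
    hit <- which(abs(output_times - tt) < 1e-9)
    if (length(hit)) out[hit, ] <<- rep(y, each = length(hit))
  }
  record(0, y)
  for (k in seq_len(length(brk) - 1L)) {
    t0 <- brk[k]; t1 <- brk[k + 1L]
    active <- schedule$fraction_times[schedule$fraction_times <= t0 + 1e-9]
    y <- rk45_segment(function(t, yy) oracle_rhs(t, yy, P, active),
                      t0, t1, y, rtol, atol)
    record(t1, y)
  }
  data.frame(time = output_times, N_p = out[, 1], N_s = out[, 2],
             N_total = out[, 1] + out[, 2])
}
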