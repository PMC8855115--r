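#' Bounded Levenberg-Marquardt least squares
#'
#' Minimizes `sum(fn(par)^2)` subject to box constraints by a damped
#' Gauss-Newton (Levenberg-Marquardt) iteration with forward-difference
#' Jacobians and projection of trial steps onto the bounds. Written for the
#' radiation-response calibrations in this package: it never throws on slow
#' progress (it returns the best point found with `converged = FALSE`),
#' which matters inside large Monte-Carlo loops.
#'
#' @param fn function mapping a parameter vector to a residual vector.
#' @param par numeric start values (within bounds).
#' @param lower,upper bounds (recycled to `length(par)`).
#' @param ftol,ptol relative decrease / step tolerances (default 1e-10).
#' @param maxfev maximum residual-function evaluations (default 2000).
#' @param max_iter maximum outer iterations.
#' @param typical typical parameter magnitudes (recycled); with
#'   `step_max_factor` they cap each component's per-iteration step at
#'   `step_max_factor * max(|par_j|, typical_j)`, which keeps early
#'   iterations from leaping into degenerate regions (e.g. death rates so
#'   large the population clips to zero and the surface goes flat).
#' @param step_max_factor per-iteration componentwise step cap (default 4).
#' @return list with `par`, `rss`, `residuals`, `converged`, `iterations`,
#'   `nfev`, `message`.
#' @export
lsq_bounded <- function(fn, par, lower = 0, upper = Inf,
                        ftol = 1e-10, ptol = 1e-10,
                        maxfev = 2000, max_iter = 200,
                        typical = 1e-2, step_max_factor = 4) {
  p <- length(par)
  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)
  typical <- rep_len(typical, p)
  par <- pmin(pmax(as.numeric(par), lower), upper)
  r <- fn(par)
  rss <- sum(r * r)
  nfev <- 1L
  lambda <- 1e-3
  converged <- FALSE
  msg <- "maximum iterations reached"
  iter <- 0L

  fd_jac <- function(x, rx) {
    J <- matrix(0, length(rx), p)
    h <- sqrt(.Machine$double.eps) * (abs(x) + sqrt(.Machine$double.eps))
    for (j in seq_len(p)) {
      xj <- x
      # step inward if a forward step would leave the box
      hj <- if (x[j] + h[j] <= upper[j]) h[j] else -h[j]
      xj[j] <- x[j] + hj
      J[, j] <- (fn(xj) - rx) / hj
    }
    nfev <<- nfev + p
    J
  }

  if (rss == 0) {
    converged <- TRUE
    msg <- "zero residual at start"
  }

  while (!converged && iter < max_iter && nfev < maxfev) {
    iter <- iter + 1L
    J <- fd_jac(par, r)
    g <- drop(crossprod(J, r))
    H <- crossprod(J)
    # projected-gradient convergence check (ignore components pushing out
    # of the box at an active bound)
    gp <- g
    gp[par <= lower & g > 0] <- 0
    gp[par >= upper & g < 0] <- 0
    if (max(abs(gp)) < 1e-14 * (1 + rss)) {
      converged <- TRUE
      msg <- "projected gradient ~ 0"
      break
    }
    dscale <- pmax(diag(H), 1e-12)
    step_cap <- step_max_factor * pmax(abs(par), typical)
    improved <- FALSE
    while (!improved && lambda <= 1e12 && nfev < maxfev) {
      step <- tryCatch(
        solve(H + lambda * diag(dscale, p), -g),
        error = function(e) NULL)
      if (is.null(step)) {
        lambda <- lambda * 10
        next
      }
      step <- pmin(pmax(step, -step_cap), step_cap)
      new_par <- pmin(pmax(par + step, lower), upper)
      r_new <- fn(new_par)
      nfev <- nfev + 1L
      rss_new <- sum(r_new * r_new)
      if (is.finite(rss_new) && rss_new < rss) {
        delta_f <- rss - rss_new
        delta_x <- max(abs(new_par - par))
        par <- new_par
        r <- r_new
        rss <- rss_new
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        # declare f/x convergence only in the near-Gauss-Newton regime:
        # with strong damping the accepted steps are short and a small
        # decrease does not mean the optimum is near
        if (lambda <= 1e-2 && delta_f <= ftol * (rss + 1e-300)) {
          converged <- TRUE
          msg <- "relative RSS decrease below ftol"
        } else if (lambda <= 1e-2 &&
                   delta_x <= ptol * (max(abs(par)) + ptol)) {
          converged <- TRUE
          msg <- "step size below ptol"
        }
        if (rss == 0) {
          converged <- TRUE
          msg <- "zero residual"
        }
      } else {
        lambda <- lambda * 5
      }
    }
    if (!improved && !converged) {
      # LM damping suppresses high-curvature directions; before giving up,
      # try plain projected gradient descent with backtracking
      tmax <- 0.5 * max(pmax(abs(par), typical)) / max(abs(gp), 1e-300)
      for (t_try in tmax * 0.3^(0:14)) {
        new_par <- pmin(pmax(par - t_try * gp, lower), upper)
        r_new <- fn(new_par)
        nfev <- nfev + 1L
        rss_new <- sum(r_new * r_new)
        if (is.finite(rss_new) && rss_new < rss) {
          par <- new_par; r <- r_new; rss <- rss_new
          lambda <- 1e-3
          improved <- TRUE
          break
        }
        if (nfev >= maxfev) break
      }
    }
    if (!improved && !converged) {
      # no downhill step found at any damping or along the gradient:
      # local minimum to working precision
      converged <- TRUE
      msg <- "optimum to working precision (no further descent)"
      break
    }
  }
  if (nfev >= maxfev && !converged) msg <- "maxfev reached"

  list(par = par, rss = rss, residuals = r, converged = converged,
       iterations = iter, nfev = nfev, message = msg)
}
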