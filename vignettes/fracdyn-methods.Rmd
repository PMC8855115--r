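---
title: "Modeling time-resolved glioma response to fractionated radiotherapy with fracdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling time-resolved glioma response to fractionated radiotherapy with fracdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical radiobiology summarizes radiation response as an endpoint survival
fraction (the linear-quadratic tradition) and says nothing about *when* cells
die. Time-lapse microscopy of irradiated monolayers produces confluence
curves sampled every few hours for weeks, and those curves show structure an
endpoint model cannot represent: a short-lived apoptotic dip after each
fraction, a slow decline from mitotic catastrophe that peaks days later, and
late regrowth once the radiation effect has decayed. `fracdyn` implements a
two-compartment ordinary-differential-equation model of these dynamics for
fractionated schedules, together with everything needed to use it as an
analysis pipeline: forward simulation, global calibration, information-
criterion model selection, delta-method prediction bands, and agreement
metrics on held-out wells.

## The model

State variables are dimensionless confluences: proliferative cells $N_p(t)$
and senescent cells $N_s(t)$, sharing a carrying capacity $\theta \le 1$.
Untreated growth is logistic with an Allee factor,

$$\frac{dN}{dt} = k_p\, N\left(\frac{N}{\theta}+A\right)\left(1-\frac{N}{\theta}\right),$$

with $(k_p, \theta, A)$ measured on control wells and held fixed during all
radiation fits. Treatment adds three mechanisms:

* **Early (acute) death** at rate
  $k_{ed}(t) = \sum_i k_{acute}\, f_{DSB}(t_i)\,\tanh\!\big(s\,f_{DSB}(t_i)\big)$,
  where $t_i$ is the time since fraction $i$ (zero before delivery),
  $f_{DSB}(t_i) = e^{-k_{repair}(D)\,t_i}$ is the unrepaired fraction of DNA
  double-strand breaks (repair rates measured per dose and linearly
  interpolated; clamped outside the measured range), and the $\tanh$ factor
  is a smooth gate that keeps the right-hand side continuous at fraction
  times.
* **Late (accumulation) death** at rate
  $k_{ld}(t) = \sum_i k_{accum}\, t_i e^{-r t_i}$: misrepair accumulates,
  then radiation efficacy decays at rate $r$; for a single fraction the rate
  peaks at $t = 1/r$.
* **Senescence conversion** $k_{ps}(D_{total})\, N_0\, N_p$ into a
  compartment that occupies space but neither divides nor dies; $k_{ps}$ is
  one free constant per total dose.

The treated system is

$$\frac{dN_p}{dt} = (k_p - k_{ld})\left(\frac{N_p+N_s}{\theta}+A\right) N_p
\left(1-\frac{N_p+N_s}{\theta}\right) - k_{ed} N_p - k_{ps} N_0 N_p,
\qquad \frac{dN_s}{dt} = k_{ps} N_0 N_p.$$

The per-fraction coefficients are averages across fractions and carry the
density and dose dependence. In the full model,
$k_{acute} = (\alpha_{acute,N} N_0 + 1)\,k_{acute,D}\, D$ and
$k_{accum} = (\alpha_{accum,N} N_0 + 1)\,k_{accum,D}\, D$, with $D$ the dose
per fraction and $N_0$ the measured confluence at $t=0$. Systematically
reducing each coefficient (dose-only, density-only, absent) and optionally
removing the senescent compartment yields the eight-member candidate family
of `model_family()`. Member 3 — density-only early death
($k_{acute,N} N_0$), full late death, senescence on; six free parameters
with two total doses — is the member selected as most parsimonious for both
glioma lines.

### Notational choices a maintainer should know

* The growth product multiplies $N_p$ (only proliferative cells divide);
  crowding acts through $N_p + N_s$. The source equations print an
  unsubscripted $N$ there; this is the biologically coherent reading.
* Model 3's late-death coefficient keeps the "$\cdot D$" of the full
  model's definition, making it the full model minus the early dose factor
  only.
* `k_accum_D` is stored in $hr^{-2} Gy^{-1}$: it multiplies both an elapsed
  time and a dose. (Rate tables elsewhere list it as $hr^{-1}$, which is not
  dimensionally consistent with its governing equation.)
* The gate sharpness $s$ defaults to 1 (a literal $\tanh$ of a quantity in
  $[0,1]$). The gate is a continuity device, not a switch: it rescales the
  early-death magnitude, and the calibrated coefficient absorbs that scale.
* Akaike weights use the standard $\exp(-\Delta_i/2)$ normalization, under
  which the best model takes the largest weight. The variant printed in the
  source (weights $\propto \exp(+\delta_i)$ with
  $\delta_i = (AIC_i - AIC_{min})/AIC_{min}$) would rank positive scores in
  reverse; it is available behind `akaike_weights(..., variant = "printed")`
  for comparison only.

## Numerics

Simulation is fully explicit forward Euler with a default step of
$dt = 0.01$ h, initial condition $N_p(0)$ equal to the measured $t=0$
confluence and $N_s(0) = 0$. The state is clipped at zero from below (clip
events are counted), and outputs are read from the Euler grid point at or
before each requested time — no interpolation, since $dt$ is three orders of
magnitude below the 4–6 h sampling interval. The test suite holds this
integrator to < 0.5% relative error (with a 0.001-confluence denominator
floor where trajectories decay to zero) against an independently coded
adaptive Runge–Kutta–Fehlberg 4(5) oracle at tolerance $10^{-9}$, across
random parameterizations of all eight models and all six schedules. The
compiled kernel advances the per-fraction exponentials recursively
($e^{-k(t+dt)} = e^{-kt}e^{-k\,dt}$), so a 330 h simulation costs well under
a millisecond at coarse steps.

Statistical experiments in the tests sometimes run generator *and* fits at a
coarser shared step (0.1–0.2 h) to stay inside CPU budgets; because both
sides share the grid, discretization cancels exactly and only the statistics
under test remain. `calibrate_global(coarse_dt =)` implements the matching
two-grid strategy for production fits: multi-start search on the cheap grid,
then a polish of the winner at the target step.

## Calibration

All training curves of a cell line are fit together — each simulated from
its own $N_0$ and schedule, sharing one parameter vector (the curve's total
dose picks its $k_{ps}$) — by minimizing the unweighted sum of squared
confluence residuals. Parameters are biologically nonnegative, so the
optimizer is a hand-written bounded Levenberg–Marquardt
(`lsq_bounded()`; no bounded least-squares package exists in the target
environment): damped normal-equation steps with forward-difference
Jacobians, componentwise step caps (to keep early iterations from leaping
into the degenerate all-cells-dead plateau where the surface is flat), a
projected-gradient fallback, and convergence declared only in the
near-Gauss-Newton regime. Three practical findings shaped the optimizer
layer and are worth preserving:

* **Search in log space, polish in raw space.** Raw coordinates condition
  terribly (curvatures spanning $10^9$); log coordinates equalize them and
  make the multi-start (default 8 seeded draws, log-uniform over
  $[10^{-5}, 10^{-1}]$ for rates and $[10^{-2}, 10^{2}]$ for dimensionless
  scales) actually find the global basin. But log coordinates lose gradient
  for parameters near zero ($\partial/\partial\log x = x\,\partial/\partial x$),
  so a final bounded fit in raw coordinates finishes the job and lets
  estimates reach the zero boundary exactly.
* **Warm-start the reduced models.** During model selection the full model
  is fit first and every daughter receives an extra start from its mapped
  estimates (reduced coefficients matched at mean density and dose).
  Without this, a daughter model stuck in a local optimum can lose the AICc
  comparison to the full model for reasons that have nothing to do with fit
  quality.
* **Initialize at truth only to test convergence, never coverage-free
  claims.** Recovery tests that assert statistical properties use the full
  multi-start; only the delta-method coverage study (where the estimator is
  assumed to be the least-squares solution) starts at the generating values.

Uncertainty uses the standard nonlinear-regression machinery: central
finite-difference Jacobian $J$ at the optimum (relative step $10^{-6}$),
$\widehat{Cov} = (J^\top J)^{-1}\, RSS/(m-p)$ with a pseudo-inverse fallback
and warning when $J^\top J$ is singular, and $t$-quantile intervals with
$m - p$ degrees of freedom. Two diagnostics accompany every fit: the
parameter correlation matrix computed from the scale-free $(J^\top J)^{-1}$
(meaningful even when $RSS \approx 0$; pairs beyond $|\rho| > 0.99$ are
flagged — single-density designs flag $\alpha_{acute,N}/k_{acute,D}$ as
expected), and a scaled sensitivity per parameter (RMS trajectory change for
a 100% parameter change). A parameter whose sensitivity sits below the
residual noise floor $\sqrt{RSS/(m-p)}$ is practically unidentifiable at
that noise level; at the default truth and 21% noise this screens out
$k_{acute,N}$, whose whole effect is a few-percent dip against a 21% noise
band. Cross-line parameter comparison is a two-sample z-test on
(estimate, SE) pairs, equivalent to comparing the implied normal
distributions.

### A bias worth knowing about

The method uses the measured $t=0$ confluence as both the initial condition
and the density covariate $N_0$, as the experimental protocol dictates. At
21% measurement noise this is a textbook error-in-variables situation: in
synthetic experiments where the generator's true $N_0$ is substituted back,
parameter recovery is excellent, while with measured $N_0$ the late-death
decomposition acquires a systematic $\sim -15\%$ bias (concentrated in
$k_{accum,D}$, partially compensated by $\alpha_{accum,N}$) and the weakly
identified $k_{acute,N}$ can absorb several-fold errors. The recovery test
therefore asserts median relative error over five replicated draws — the
estimator's systematic accuracy — rather than one draw's luck.

## Model selection

Each candidate is scored with the small-sample-corrected AIC,
$AICc = n \ln(RSS/n) + 2p + (2p^2+2p)/(n-p-1)$, using $n$ = number of
training curves (the convention of the source analysis; `n_def =
"observations"` switches to the total point count) and RSS summed over all
points. At the experiment's scale ($n \approx 260$ curves per line) the
correction is mild; at the reduced test scale ($n = 12$–$24$) it is severe
and parsimony dominates, which the selection-recovery tests respect by
scaling the measurement noise as $0.21\sqrt{n/260}$ — preserving each
dataset's information content — and by making every distinguishing term of
the generating model prominent (death terms of order one e-fold; density
factors spanning more than threefold across the tenfold seeding range). The
resulting 8×20 confusion experiment recovers the generating model in the
majority of repetitions for every family member; the residual confusion is
between the full model and its single-parameter reductions, exactly where
small-sample AICc should be conservative.

## Prediction and validation

`predict_confluence()` propagates parameter covariance through the model by
the delta method: pointwise variance $g^\top \widehat{Cov}\, g$ with $g$ the
central-difference gradient of predicted total confluence in the free
parameters, and $t$-based bands. Two band types exist because they answer
different questions: `"confidence"` (the default) brackets the predicted
*mean* and collapses to zero for noise-free fits; `"prediction"` adds the
residual variance $s^2$ and is the band a new noisy *measurement* should
fall inside — the coverage test uses the latter, and a 200-curve synthetic
ensemble puts its empirical 95% coverage inside the accepted [88%, 99%]
window despite the constant-variance approximation to multiplicative noise.

Held-out wells are predicted from their $N_0$ and schedule alone, with the
same parameter set regardless of condition. Agreement is quantified per
replicate over its time points by the Pearson correlation (PCC; linear
association) and Lin's concordance correlation
$CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with population
moments (agreement; penalizes scale and location shifts, so
$|CCC| \le |PCC|$ replicate by replicate), then summarized as mean ± SE
(SD/$\sqrt{n}$) per cell line × schedule, per total-dose group, and overall.
Per-replicate-then-average is the aggregation consistent with reporting an
SE over replicates.

## The synthetic world

No microscopy data are released with the source analysis, so the package
ships a seeded generator (`default_truth()`, `generate_dataset()`) that
emulates the experiment's design: two cell lines, six schedules, seeding
densities drawn log-uniformly over a tenfold range ($N_0 \in [0.03, 0.3]$;
the mapping from plated cells/cm² to confluence is not published, so this
range is a stand-in), sampling times accumulated from uniform 4–6 h gaps to
330 h, and multiplicative Gaussian noise truncated at zero with CV 0.21 (the
reported segmentation error; the true noise law is not published). The
generating parameter values are *synthetic*: the calibrated values exist
only as figures, so defaults were chosen once to satisfy the reported
qualitative constraints — more than 80% of DSBs repaired within 24 h at
every dose used; late death dominating early death; a C6-like preset with
~1.8× larger death and conversion rates than the 9L-like preset but the same
efficacy decay $r$; and trajectories that rise, decline after treatment, and
regrow late under the weaker schedules. Replicate heterogeneity (lognormal
multipliers on the death rates) exists as a knob but defaults to zero: the
calibration model assumes shared parameters, and the default world should
satisfy the model it is used to test. A media-change artifact (periodic
fractional cell loss, simulated as state discontinuities) is off by default
and exists to probe calibration robustness.

What a green test therefore establishes: the estimation machinery recovers
the generating process under the experiment's design, noise level, and
sampling. What it cannot establish: anything about features of real
microscopy the generator omits — segmentation artifacts correlated in time,
replicate-level parameter heterogeneity (observed in the real radiosensitive
line), focus drift, or the dead-cell channel, which is not modeled at all.

## Known limitations

* $k_{ps}$ is a constant per total dose, though mechanistically it should
  depend on time, dose per fraction, and fraction number.
* Ordinary (unweighted) least squares with multiplicative noise
  underweights low-confluence data and carries the error-in-variables bias
  described above; no weighting is applied because none is described for
  the source analysis.
* Linear dose interpolation of repair rates is clamped outside the measured
  2–16 Gy table — a choice, not a measurement.
* The family's daughter models 2, 5 and 6 are reconstructed by analogy with
  the stated early-death reductions; their exact source formulations are in
  supplementary material that is not reproduced here.
* Confusion between the full model and its one-parameter reductions at
  small $n$ is inherent to AICc, not an implementation artifact.
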