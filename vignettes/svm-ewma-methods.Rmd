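---
title: "Risk-adjusted one-sided EWMA charts on AFT and SVR residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adjusted one-sided EWMA charts on AFT and SVR residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmewma)
```

## The monitoring problem

Survival time after cardiac surgery is a continuous quality signal for a
surgical unit, but it is confounded by patient mix: a run of high-risk
patients shortens observed survival with no change in the quality of care.
Risk adjustment removes the predictable patient-mix component before
monitoring. Here the patient-mix covariate is the Parsonnet score, an
integer preoperative risk score on 0–100 (higher = higher predicted
mortality), and patients are followed for 30 days, so survival beyond day 30
is right-censored.

`svmewma` implements two risk-adjustment routes feeding the same one-sided
EWMA chart:

* **RAEWMA** — an accelerated failure time (AFT) regression
  `log T = b0 + b1 * P + sigma * eps` fitted on Phase-I (in-control) data by
  censored maximum likelihood; the monitored quantity is the standardized
  residual `e_t = (log T_t - b0 - b1 P_t) / sigma` (SR-AFT).
* **SVM-EWMA** — an epsilon-insensitive support vector regression of
  `log T` on `P`; the monitored quantity is the SVR residual standardized by
  the Phase-I pool mean and SD (SR-SVM). The SVR makes no linearity or
  error-law assumption, which is the point of the method.

## The chart

Both residual streams are monitored with the lower-one-sided clipped EWMA

```
F_t = min(lam * v_t + (1 - lam) * F_{t-1}, xi),      F_0 = z0 = xi,
```

where `xi` is the Phase-I residual mean (0 after standardization). The clip
absorbs upward excursions so the statistic accumulates evidence of
*decreased* survival only. The chart signals at the first `t` with
`F_t < LCL(t)`,

```
LCL(t) = mu_e - L * sigma_e * sqrt(lam / (2 - lam) * (1 - (1 - lam)^(2t))),
```

with `mu_e`, `sigma_e` the Phase-I residual mean and SD. The time-varying
term is the exact EWMA standard deviation at `t`; an asymptotic mode
(constant limit) is provided for comparison. Comparing `|F_t|` with `L`
directly is sometimes seen as a shorthand for this rule, but it is not
workable: it would flag processes whose statistic sits near zero — i.e.
in-control ones — so this package signals on `F_t < LCL(t)`, the one-sided
design intent.

Tunable parameters:

| parameter | meaning | default | why |
|---|---|---|---|
| `lam` | smoothing constant in (0, 1] | 0.10 / 0.25 in the run-length studies | small `lam` accumulates history, detecting small sustained shifts sooner |
| `L` | limit width in asymptotic-SD units | calibrated | set by `calibrate_L()` to hit a target in-control ARL (370 or 500) |
| `xi`, `z0` | clip level and start | Phase-I residual mean | standard EWMA practice starts the statistic at the in-control mean |
| `horizon` | monitoring truncation | 10^6 observations | ARL estimation cannot loop forever; runs reaching it are reported as censored, never dropped |

## Monte-Carlo run-length engine

Run lengths are estimated by bootstrap: residuals are drawn i.i.d. with
replacement from the Phase-I pool, a shift of magnitude `delta` is applied
in the signaling direction (`v - delta`: the chart watches for *shorter*
survival, so a deterioration of magnitude `delta` moves residuals
downward), and the chart runs to its first signal. Shifts are
applied from `t = 1` (zero-state run lengths). A parametric standard-normal
stream is available as an alternative; it is what makes the closed-form
Shewhart checks possible (`lam = 1`, clip disabled: the run length is
geometric with success probability `pnorm(delta - L)`).

`calibrate_L()` uses common random numbers — the same seed for every
candidate `L` — so each replicate's statistic path is identical across
candidates and the estimated ARL is an exactly non-decreasing step function
of `L`; a coarse bracket is then refined by bisection to tolerance
`max(1, 0.5% of target)`. During calibration, evaluations truncate runs at
50 times the target ARL: for a chart near target the probability of
truncation is about `exp(-50)`, while bracket evaluations at wide limits
would otherwise run every replicate to the full horizon. Percentiles use
linear interpolation between order statistics (R's type-7 quantile), which
is what produces fractional reported percentiles.

The replication standard is 50,000 runs per cell (used by
`scripts/acceptance.R`); the test suite uses 2,000–20,000 replicates per
cell and tolerances computed from the realized Monte-Carlo standard errors.

## The synthetic cohort generator

The cardiac-surgery registry behind the published Phase-I estimates is not
public, so the generator emulates the structure the models assume:
`log T = 5.07026 - 0.03348 * P + 0.57 * eps` (the published Phase-I AFT
estimates), right-censoring at 30 days, and a configurable Parsonnet
distribution. Two quantities those estimates do not pin down are
configuration, not fidelity claims:

* **Parsonnet distribution** — default is a geometric-shaped pmf truncated
  to 0–100 with untruncated mean 10, because real Parsonnet histograms are
  right-skewed with most mass near zero. Any pmf can be supplied.
* **Error law** — default standard normal (log-normal survival), matching
  the "standardized residual" reading of the AFT model; logistic
  (log-logistic) and minimum-Gumbel (Weibull) are offered.

The generator retains the latent uncensored time (`true_time_days`) for
oracle checks only; fitting code never reads it. With the default
parameters about 99% of patients survive past day 30, so realistic Phase-I
cohorts are overwhelmingly censored — which is why the run-length study
conditions use uncensored cohorts (`censor_horizon_days = Inf`,
n = 5000) to form residual pools, mirroring a Phase-I pool built from an
in-control era.

What passing tests on synthetic cohorts do **not** show: the published
out-of-control ARLs (shifted rows of the run-length tables) depend on the
empirical residual distribution of the original registry — its skewness,
discreteness and censoring pattern — which no generator calibrated only to
the printed coefficients can reproduce. In-control behavior (calibration
round-trips, run-length shape, table layout, qualitative shift response)
is reproducible and is what the acceptance checks assert.

## Numerical and design choices

* **AFT estimation** is censored maximum likelihood via
  `survival::survreg` from a deterministic start; exactly collinear
  (noise-free) data would make the likelihood unbounded in `sigma`, so that
  case returns the OLS interpolant with `sigma` at numerical zero.
* **Censored records and residuals**: a censored record has no observed
  `log T`, so it is excluded from residual pools by default (it still
  enters the MLE). Conservative inclusion at the censoring value and
  conditional-mean imputation (normal errors) are options.
* **SVR formulation**: the exact regression formulation is open; this
  package uses standard epsilon-SVR with defaults
  `C = 1`, `epsilon = 0.1`, RBF kernel with width from the median pairwise
  distance heuristic — all configurable and recorded in run manifests, since
  downstream ARLs depend on them. Fitting is libsvm's SMO; tests verify the
  dual solution against a generic interior-point QP on the same problem.
* **Maximal-margin classifier**: the dual QP is assembled in-package,
  solved by a generic interior-point routine and polished by solving the
  support-set KKT system exactly; the offset uses the largest-multiplier
  support vector of each class, a deterministic tie-break.
* **Problem sizes**: Phase-I pools use n = 5000 uncensored patients;
  parameter-recovery checks use n = 10,000; QP oracle comparisons use up to
  12 points in up to 3 dimensions, where brute-force active-set enumeration
  is exact.

## Known limitations

* Out-of-control ARL magnitudes are study-conditional (see above); the
  package reproduces the methodology, not the registry-specific numbers.
* Steady-state (delayed-shift) run lengths and Markov-chain or
  integral-equation ARL approximations are out of scope; the engine is
  Monte-Carlo only.
* The SVR is fitted to uncensored observations; heavy censoring of a
  Phase-I pool therefore shrinks the usable training set.

## A worked example

```{r example, eval = FALSE}
co   <- generate_cohort(cohort_config(n = 5000, censor_horizon_days = Inf,
                                      seed = 11))
svr  <- fit_svr(co$parsonnet, log(co$time_days))
pool <- sr_svm(co, svr)
cal  <- calibrate_L(pool, lam = 0.10, target_arl0 = 370, reps = 10000,
                    seed = 3)
cal
estimate_rl_profile(pool, cal$cfg, delta = 0, reps = 10000, seed = 99)
```

The same pipeline is available from the shell via the `exec/svmewma`
script: `generate`, `fit-aft`, `fit-svr`, `calibrate`, `profile` and
`compare` subcommands, each writing a JSON manifest of its configuration,
seeds and achieved values.
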