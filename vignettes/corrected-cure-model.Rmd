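---
title: "Mixture cure models with a corrected non-cancer mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture cure models with a corrected non-cancer mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curealpha)
```

## The problem

Population-based cancer survival is usually summarized by *net survival* —
the survival patients would experience if their cancer were the only
possible cause of death. In the relative-survival setting it is estimated
without cause-of-death information by comparing the cohort's observed
mortality with the *expected* mortality of a matched general population
(same age, sex, period). Mixture cure models additionally split the cohort
into a cured fraction, which never dies of the cancer, and an uncured
fraction with its own net survival distribution.

Both constructions lean on one comparability assumption: that patients'
non-cancer mortality equals general-population mortality. For several
cancers that assumption fails — treatment late effects, shared risk factors
such as smoking, and socio-economic differences raise (or occasionally
lower) patients' other-cause mortality. When that happens, the excess
("cancer") mortality absorbs part of the other-cause excess, and cure
fractions and net survival are underestimated.

`curealpha` implements a corrected mixture cure model in which patients'
other-cause hazard is a multiplicative factor `alpha` times the population
hazard, `h_e(t) = alpha * h*(age + t)`, with `alpha` estimated jointly with
the cure parameters. `alpha > 1` means excess non-cancer mortality;
`alpha = 1` recovers the conventional mixture cure model exactly.

## Model

For a patient with age `a` at diagnosis and standardized age
`x = (a - 60) / 15`:

* cure fraction: `pi(x) = plogis(beta0 + beta * x)` (logistic link; an
  identity link `pi = beta0 + beta * x` is available and validated rather
  than clamped);
* uncured net survival: Weibull,
  `S_u(t, x) = exp(-lambda * t^gamma)^exp(-delta * x)`;
* net survival: `RS(t, x) = pi(x) + (1 - pi(x)) * S_u(t, x)`;
* observed survival: `S_O(t) = RS(t, x) * S*(t | a)^alpha`, where
  `S*(t | a)` is the conditional population survival.

The observed hazard decomposes as `h_O = h_c + alpha * h*` with excess
hazard `h_c = (1 - pi) f_u / RS`, which gives the individual-record
log-likelihood

```
l = sum_i [ d_i * log(h_c(t_i, x_i) + alpha * h*(a_i + t_i))
            + log RS(t_i, x_i) + alpha * log S*(t_i | a_i) ]
```

In the conventional model (`alpha` fixed at 1) the last term is a constant
and may be dropped; here it carries information about `alpha` and must stay.

### Age-effect sign convention

The package uses the *survival-exponent* convention
`S_u = exp(-lambda t^gamma)^exp(-delta x)` everywhere — in the simulator and
in both likelihoods — so a **negative** `delta` means *older uncured
patients die faster* (the lung-like preset's `delta = -0.3` gives the
uncured hazard the multiplier `exp(0.3 x)`). A single convention on both
the generating and fitting side means the fitted `delta` estimates the
preset value directly; mixing conventions (a hazard multiplier on one side
and a survival exponent on the other) silently flips the sign of the age
effect, which is the classic failure mode this choice guards against.

### Grouped-data (life table) likelihood

Individual records are often unavailable; the grouped path fits the model
to a relative-survival life table, stratified by age class with annual
intervals. Per cell (stratum `k`, interval `j`) the table carries deaths
`d`, the effective number at risk `l = n - 0.5 w` (actuarial half-interval
credit for those censored inside the interval), the observed conditional
interval survival `s_obs = 1 - d / l`, and the Ederer II expected
conditional interval survival `s_exp` — the mean, over patients still at
risk at the interval's start, of their individual conditional population
survival.

The likelihood treats each cell as a binomial: `d ~ Bin(l, 1 - p)` with

```
p = [RS(t_j; x_k) / RS(t_{j-1}; x_k)] * s_exp^alpha      (dialect "exact")
p = [RS(t_j; x_k) / RS(t_{j-1}; x_k)] + alpha * log(s_exp)   ("printed_first_order")
```

The additive dialect is the first-order expansion of the exact one and is
adequate only when cell survivals are near 1; it is retained as an option
but the exact form is the default and is what the simulation study in this
vignette's test suite validates (fitting additively to data whose cells obey
the exact form biases `alpha` noticeably downward once annual conditional
survivals fall below ~0.95, as in the oldest stratum's late intervals).

Two life-table conventions matter numerically:

* **Boundary times.** Follow-up times are assigned to half-open intervals
  `[t_{j-1}, t_j)`. A patient censored *exactly at the analysis horizon* —
  about half the cohort under 50% administrative censoring — survived the
  entire last interval and keeps full risk credit there; treating such
  patients as within-interval withdrawals (half credit) deflates
  last-interval survival enough to bias `alpha` upward by ~0.2 at
  `alpha = 1.2`.
* **Stratum covariate.** Each stratum is evaluated at the realized mean
  standardized age of its members, not the class midpoint, minimizing
  within-stratum aggregation bias.

## Estimation

`fit_cure()` maximizes the appropriate likelihood with BFGS on a working
scale — `log alpha`, `log lambda`, `log gamma` unconstrained, `beta0`,
`beta`, `delta` unchanged — so the positivity constraints can never be
violated. Standard errors come from the inverse numerical Hessian at the
optimum; 95% Wald intervals are formed on the working scale and
back-transformed, keeping intervals for positive parameters positive and
the interval for `pi60` (inverse-logit of the `beta0` interval) inside
(0, 1). The logit-transform interval for `pi60` was chosen over the delta
method for the same boundary-respecting reason.

Starting values are deterministic: `alpha = 1`, trends at 0, the cure
fraction at the empirical relative-survival plateau (last-interval pooled
cumulative relative survival, clamped to `[0.05, 0.95]`), and the Weibull
parameters from a least-squares line on `log(-log)` of the early cumulative
relative survival. Non-convergence triggers up to three restarts jittered
on the working scale, seeded deterministically from the data so that a
batch re-run is bit-identical. A fit that still fails is returned with
`converged = FALSE`, never silently. Events recorded at exactly `t = 0` are
shifted to half a day (0.5/365.25 years) before the hazard is evaluated.

Cells whose predicted conditional survival leaves `(0, 1)` — possible under
the additive dialect or an invalid identity-link cure fraction — contribute
a large smooth penalty rather than `NaN`, so quasi-Newton steps always see
a finite objective; at a valid optimum the penalty is inactive.

## The simulator

`generate_cohort()` reproduces the study conditions the estimators are
validated under:

* ages drawn from four equal-probability classes (40-57, 58-64, 65-69,
  70-74), continuous uniform within `[lo, hi + 1)` of each class;
* population mortality Weibull from birth with scale 88 y and shape 11
  (a both-sexes French 2002 life-table fit); non-cancer death times by
  inverse transform from `S*(t | age)^alpha`;
* cancer death times from the mixture by inverse transform: a uniform draw
  below `pi(x)` marks the patient cured (infinite time);
* administrative censoring with probability 0.5 and loss to follow-up with
  probability 0.03, each uniform on the 15-year registry window when
  active; shorter analysis horizons *truncate* this fixed design rather
  than compressing the censoring distribution (truncation reproduces the
  study's short-follow-up behaviour; compression visibly inflates the
  spread of `alpha` estimates);
* the event indicator ties (`T_C = T_D`) resolve to "dead".

Three single-switch robustness violations are built in: an
exponentiated-Weibull uncured survival (second shape `theta`), an
age-linear `alpha` (slope `b_alpha` per year of age), and a patient-level
random `alpha` (log-uniform, mean-preserving bounds with a given max/min
ratio). Each reduces exactly to the base generator at its null setting, and
at most one may be active.

The age-linear violation is centered, by default, at the *design's own
expected age* (62.625 under the default classes) rather than a hard-coded
constant: the violation's defining property is that the sample mean of
`alpha_x` equals the target `alpha`, which only holds when the centering
matches the actual age distribution. A fixed mis-centering of 0.375 years
shifts every patient's `alpha` by `0.375 * b_alpha` and contaminates the
bias being measured.

What the simulator does *not* emulate: calendar-period drift of population
mortality, sex- or region-stratified life tables, non-linear age effects,
informative censoring, and reporting artefacts of real registries. Passing
tests therefore demonstrate correctness of the estimators under the model's
own assumptions (plus the three controlled violations), not robustness to
everything real data can do.

## Monte-Carlo machinery and problem sizes

`run_replicates()` expands one seed into recorded per-replicate sub-seeds
(any single replicate is reproducible in isolation), fits each simulated
cohort, and `performance()` reports per parameter the absolute bias
`AB = mean(estimate) - truth`, the spread `SD` (denominator `R - 1`) and
the coverage `CVR` of the nominal 95% intervals, over converged replicates
only, with the non-convergence count kept. `scenario_grid()` enumerates the
study's factor grids (scenario x alpha x data mode; model variant; sample
size x follow-up; `theta`; `b_alpha`; `alpha` ratio) with overridable `R`
and `N`.

The package's test suite exercises each replicate cell at `R = 300`
cohorts of `N = 10,000` — enough that the Monte-Carlo tolerance
`3 * SD / sqrt(R)` resolves every tabulated bias it checks — and the
bundled acceptance script uses `R = 1000` for the coverage computation.
One grouped-data replicate (generate, tabulate, fit) costs ~40 ms, an
individual-data fit of `N = 10,000` about a second; grouped fitting is the
default everywhere for that reason.

## Known limitations and honest failure modes

* **The conventional model under strong misspecification.** Fitted to data
  generated with `alpha = 2` (breast-like scenario), the conventional
  (`alpha = 1`) model's likelihood is *bimodal*: a cure-like mode with
  `pi60` around 0.40, and a no-cure mode (`pi -> 0`, strongly negative
  `delta`) in which the Weibull-with-age-effect mimics the population
  mortality's age gradient. Asymptotically the no-cure mode is the global
  maximum; at `N = 10,000` it wins in roughly half the replicates, so the
  average downward bias of the fitted cure fraction is even larger than a
  local search around the truth would suggest. The package reports the
  global optimum it finds rather than privileging the cure-like basin;
  users fitting conventional cure models to data with suspected excess
  non-cancer mortality should treat a collapsed cure fraction as a symptom
  of exactly that misspecification. At milder misspecification
  (`alpha` 1.2-1.5) the cure-like mode is the global one and the bias is
  reproducible and smooth.
* Identifiability of `alpha` rests on the uncured excess hazard flattening
  while population mortality keeps rising with age; short follow-up
  (5 years) leaves `alpha` weakly identified (upward-biased, very wide).
* The uncured distribution is Weibull only; lognormal, loglogistic or
  spline alternatives are out of scope.
* Grouped fits assume the life table's expected survival is computed from
  the same population mortality that generated (or, for real data,
  matches) the cohort; life-table mismatch is not modelled.
* The exponentiated-Weibull is used for *generation* only; fitting it is
  out of scope. Note that at second shape `theta = 0.5`
  (rate-scale 0.4, shape 0.8) the five-year survival evaluates to ~12.5%,
  not single digits as one might eyeball from the hazard plots — the
  implemented formula is the authority for what the generator does.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_preset("breast", alpha = 1.2, n = 10000)
cohort <- generate_cohort(cfg, seed = 1)
lt <- build_life_table(cohort, cfg$pop)
fit <- fit_cure(lt)
fit$coef
predict_summary(fit$params)
```
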