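#' Cure fraction as a function of standardized age
#'
#' `pi(x)`: the proportion of patients who will never die of the diagnosed
#' cancer, at standardized age `x = (age - 60)/15`. Logistic link:
#' `pi(x) = 1/(1 + exp(-beta0 - beta x))`; identity link:
#' `pi(x) = beta0 + beta x`, which is validated (an error names the offending
#' `x` if the value leaves `[0, 1]`). The `corrected_no_cure` variant returns
#' 0 everywhere.
#'
#' @param params A [cure_params()] object.
#' @param x Standardized age(s).
#' @return Cure probabilities in `[0, 1]`.
#' @export
cure_fraction <- function(params, x = 0) {
  stopifnot(inherits(params, "cure_params"))
  if (params$variant == "corrected_no_cure") return(rep(0, length(x)))
  eta <- params$beta0 + params$beta * x
  if (params$link == "logistic") {
    stats::plogis(eta)
  } else {
    bad <- which(eta < 0 | eta > 1)
    if (length(bad))
      stop(sprintf("identity link: pi outside [0, 1] at x = %s",
                   paste(signif(x[bad], 4), collapse = ", ")))
    eta
  }
}

# Weibull exponent shared by survival/density/hazard of the uncured:
# cumulative excess hazard of the uncured = lambda * t^gamma * exp(-delta x)
uncured_cumhaz <- function(params, t, x) {
  params$lambda * t^params$gamma * exp(-params$delta * x)
}

#' Net survival of the uncured
#'
#' Weibull net survival of patients destined to die of their cancer:
#' `S_u(t, x) = exp(-lambda t^gamma * exp(-delta x))`. Equals 1 at `t = 0`
#' and is strictly decreasing in `t`.
#'
#' @param params A [cure_params()] object.
#' @param t Years since diagnosis (>= 0).
#' @param x Standardized age(s).
#' @return Survival probabilities.
#' @export
uncured_survival <- function(params, t, x = 0) {
  stopifnot(inherits(params, "cure_params"))
  if (any(t < 0)) stop("t must be >= 0")
  exp(-uncured_cumhaz(params, t, x))
}

#' Density of time to cancer death among the uncured
#'
#' `f_u(t, x) = gamma lambda t^(gamma - 1) exp(-delta x) S_u(t, x)`;
#' integrates to 1 over `[0, Inf)`.
#'
#' @inheritParams uncured_survival
#' @return Densities per year.
#' @export
uncured_density <- function(params, t, x = 0) {
  stopifnot(inherits(params, "cure_params"))
  if (any(t < 0)) stop("t must be >= 0")
  params$gamma * params$lambda * t^(params$gamma - 1) *
    exp(-params$delta * x) * exp(-uncured_cumhaz(params, t, x))
}

#' Net (relative) survival of the whole patient group
#'
#' The mixture `RS(t, x) = pi(x) + (1 - pi(x)) S_u(t, x)`: survival that
#' would be observed if the diagnosed cancer were the only cause of death.
#' Tends to the cure plateau `pi(x)` as `t` grows.
#'
#' @inheritParams uncured_survival
#' @return Net survival probabilities.
#' @export
net_survival <- function(params, t, x = 0) {
  p <- cure_fraction(params, x)
  p + (1 - p) * uncured_survival(params, t, x)
}

#' Excess (cancer-attributable) hazard
#'
#' `h_c(t, x) = (1 - pi) f_u / [pi + (1 - pi) S_u]`, the force of mortality
#' attributable to the cancer; equals `-d/dt log RS(t, x)` and tends to 0 as
#' `t` grows whenever `pi > 0`.
#'
#' @inheritParams uncured_survival
#' @param t Years since diagnosis (> 0; `t^(gamma-1)` may diverge at 0).
#' @return Hazards per year.
#' @export
excess_hazard <- function(params, t, x = 0) {
  if (any(t <= 0)) stop("t must be > 0")
  p <- cure_fraction(params, x)
  su <- uncured_survival(params, t, x)
  (1 - p) * uncured_density(params, t, x) / (p + (1 - p) * su)
}

#' Observed (all-cause) survival under the corrected model
#'
#' `S_O(t) = RS(t, x) * S*(t | age)^alpha`: net survival times the
#' general-population survival raised to the excess-mortality power. With
#' `alpha = 1` this is the conventional relative-survival decomposition.
#'
#' @inheritParams uncured_survival
#' @param pop A [pop_weibull()] or [pop_lifetable()] object.
#' @param age Age at diagnosis in years.
#' @param x Standardized age; defaults to `std_age(age)`.
#' @return Observed survival probabilities.
#' @export
observed_survival <- function(params, pop, t, age, x = std_age(age)) {
  net_survival(params, t, x) * expected_survival(pop, age, t)^params$alpha
}

#' Exponentiated-Weibull net survival of the uncured
#'
#' Three-parameter generalization used to break the Weibull assumption:
#' `S_u(t, x) = {1 - [1 - exp(-lambda t^gamma)]^theta}^exp(-delta x)`.
#' The second shape `theta` modulates the distance from the Weibull
#' (`theta = 1` recovers [uncured_survival()] exactly); `theta < 1` gives a
#' U-shaped hazard, `theta > 1` a bell-shaped one.
#'
#' @param t Years since diagnosis (>= 0).
#' @param lambda,gamma Weibull rate-scale and shape (> 0).
#' @param theta Second shape parameter (> 0).
#' @param delta Age effect per 15 years.
#' @param x Standardized age(s).
#' @return Survival probabilities.
#' @export
exp_weibull_survival <- function(t, lambda, gamma, theta = 1, delta = 0, x = 0) {
  stopifnot(lambda > 0, gamma > 0)
  if (theta <= 0) stop("theta must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  (1 - (1 - exp(-lambda * t^gamma))^theta)^exp(-delta * x)
}

#' Net survival and cure fraction by age
#'
#' Tabulates, for each age at diagnosis, the cure fraction and net survival
#' at a set of horizons (default 1, 5, 10 and 15 years) — the summary
#' typically reported alongside a fitted cure model.
#'
#' @param params A [cure_params()] object (typically `fit$params` from
#'   [fit_cure()]).
#' @param ages Ages at diagnosis in years.
#' @param horizons Years since diagnosis.
#' @return A data frame with one row per age: `age`, `x`, `pi`, and one
#'   `ns_<h>y` column per horizon; net survival is non-increasing across
#'   horizons.
#' @export
predict_summary <- function(params, ages = c(40, 50, 60, 70),
                            horizons = c(1, 5, 10, 15)) {
  stopifnot(inherits(params, "cure_params"))
  x <- std_age(ages)
  out <- data.frame(age = ages, x = x, pi = cure_fraction(params, x))
  for (h in horizons)
    out[[sprintf("ns_%gy", h)]] <- net_survival(params, h, x)
  out
}
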