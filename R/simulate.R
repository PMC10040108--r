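#' Simulation scenario configuration
#'
#' Bundles everything needed to generate a virtual cohort: cohort size,
#' follow-up horizon, censoring probabilities, the age-class sampling design,
#' the cure-model truths, the population mortality, and at most one of three
#' robustness violations:
#' * `theta != 1`: uncured survival generated from the exponentiated-Weibull
#'   instead of the Weibull;
#' * `b_alpha != 0`: alpha depends linearly on age,
#'   `alpha_x = alpha + b_alpha (age - age_center)`;
#' * `alpha_ratio > 1`: alpha varies randomly between patients, `log(alpha)`
#'   uniform on bounds with the given max/min ratio and mean alpha (see
#'   [random_alpha_bounds()]).
#'
#' @param n Cohort size.
#' @param max_followup Analysis follow-up horizon in years (default 15);
#'   follow-up beyond it is truncated (censored at the horizon), which is how
#'   shorter "lengths of potential follow-up" are obtained from the fixed
#'   registry design.
#' @param p_ac,p_lf Probabilities of administrative censoring (default 0.5)
#'   and loss to follow-up (default 0.03); each draws a censoring time
#'   uniform on `[0, censoring_horizon]`, otherwise the horizon itself.
#' @param censoring_horizon Registry window for the censoring draws
#'   (default 15 years, independent of `max_followup`).
#' @param age_breaks Bounds of the four equal-probability age classes
#'   (default 40-57, 58-64, 65-69, 70-74; continuous ages in `[40, 75)`).
#' @param pi60,beta,lambda,gamma,delta Cure-model truths (see
#'   [cure_params()]).
#' @param alpha Excess non-cancer mortality truth (> 0).
#' @param pop Population mortality (default [pop_weibull()] with scale 88,
#'   shape 11).
#' @param theta Exponentiated-Weibull second shape (1 = Weibull).
#' @param b_alpha Age slope of alpha per year of age (0 = constant alpha).
#' @param age_center Centering constant for the age-dependent alpha. The
#'   default (`NULL`) uses the expected age under the class design (62.625
#'   for the default classes), which keeps the mean of `alpha_x` over a
#'   sample equal to the target `alpha` -- the defining property of this
#'   violation.
#' @param alpha_ratio Max/min ratio for the random alpha (1 = constant).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n = 10000, max_followup = 15,
                            p_ac = 0.5, p_lf = 0.03,
                            censoring_horizon = 15,
                            age_breaks = c(40, 58, 65, 70, 75),
                            pi60, beta, lambda, gamma, delta,
                            alpha = 1, pop = pop_weibull(),
                            theta = 1, b_alpha = 0, age_center = NULL,
                            alpha_ratio = 1) {
  stopifnot(n >= 1, max_followup > 0, censoring_horizon > 0,
            p_ac >= 0, p_ac <= 1, p_lf >= 0, p_lf <= 1,
            length(age_breaks) >= 2, all(diff(age_breaks) > 0),
            alpha > 0, theta > 0, alpha_ratio >= 1,
            inherits(pop, "pop_mortality"))
  if (is.null(age_center)) {
    K <- length(age_breaks) - 1
    age_center <- mean((age_breaks[-1] + age_breaks[-(K + 1)]) / 2)
  }
  violations <- c(weibull = theta != 1, age_alpha = b_alpha != 0,
                  random_alpha = alpha_ratio > 1)
  if (sum(violations) > 1)
    stop("at most one robustness violation may be active; got: ",
         paste(names(violations)[violations], collapse = ", "))
  cfg <- structure(list(n = n, max_followup = max_followup,
                        censoring_horizon = censoring_horizon, p_ac = p_ac,
                        p_lf = p_lf, age_breaks = age_breaks, pi60 = pi60,
                        beta = beta, lambda = lambda, gamma = gamma,
                        delta = delta, alpha = alpha, pop = pop,
                        theta = theta, b_alpha = b_alpha,
                        age_center = age_center, alpha_ratio = alpha_ratio),
                   class = "scenario_config")
  if (b_alpha != 0) {
    a_rng <- alpha_for_age(cfg, range(age_breaks))
    if (any(a_rng <= 0))
      stop("age-dependent alpha is non-positive within the age range")
  }
  # validate the cure truths early
  cure_params(alpha = alpha, pi60 = pi60, beta = beta, lambda = lambda,
              gamma = gamma, delta = delta)
  cfg
}

#' Scenario presets
#'
#' The two study scenarios, mirroring the survival patterns of breast-like
#' (high cure, slow uncured mortality) and lung-like (low cure, fast uncured
#' mortality) cancers:
#' * `"breast"`: `pi60 = 0.7, lambda = 0.1, gamma = 1.1, beta = -0.15,
#'   delta = 0`;
#' * `"lung"`: `pi60 = 0.1, lambda = 0.9, gamma = 0.8, beta = -0.75,
#'   delta = -0.3`.
#'
#' @param scenario `"breast"` or `"lung"`.
#' @param ... Overrides passed to [scenario_config()] (e.g. `alpha`, `n`,
#'   `max_followup`, robustness settings).
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(scenario = c("breast", "lung"), ...) {
  scenario <- match.arg(scenario)
  truths <- switch(scenario,
    breast = list(pi60 = 0.7, lambda = 0.1, gamma = 1.1, beta = -0.15, delta = 0),
    lung   = list(pi60 = 0.1, lambda = 0.9, gamma = 0.8, beta = -0.75, delta = -0.3))
  do.call(scenario_config, utils::modifyList(truths, list(...)))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: n = %d, follow-up %g y, P_AC = %g, P_LF = %g\n",
              x$n, x$max_followup, x$p_ac, x$p_lf))
  cat(sprintf("  truths: alpha = %g, pi60 = %g, beta = %g, lambda = %g, gamma = %g, delta = %g\n",
              x$alpha, x$pi60, x$beta, x$lambda, x$gamma, x$delta))
  if (x$theta != 1) cat(sprintf("  violation: exponentiated-Weibull theta = %g\n", x$theta))
  if (x$b_alpha != 0) cat(sprintf("  violation: age-dependent alpha, b = %g (center %g)\n",
                                  x$b_alpha, x$age_center))
  if (x$alpha_ratio > 1) cat(sprintf("  violation: random alpha, max/min ratio %g\n",
                                     x$alpha_ratio))
  invisible(x)
}

#' Sample ages at diagnosis
#'
#' Picks one of the four age classes with equal probability 1/4, then a
#' continuous uniform age within `[lo, hi)` of the class, so the class
#' labelled 40-57 covers real ages up to just under 58.
#'
#' @param config A [scenario_config()].
#' @param n Number of ages (default `config$n`).
#' @return Ages in years.
#' @export
sample_ages <- function(config, n = config$n) {
  br <- config$age_breaks
  K <- length(br) - 1
  k <- sample.int(K, n, replace = TRUE)
  stats::runif(n, br[k], br[k + 1])
}

#' Sample censoring times
#'
#' Two competing censoring mechanisms: administrative censoring (probability
#' `p_ac`) and loss to follow-up (probability `p_lf`), each drawing a time
#' uniform on `[0, censoring_horizon]` when active and the full registry
#' window when not; the censoring time is the minimum of the two. Truncation
#' to the analysis horizon `max_followup` happens in [generate_cohort()],
#' not here.
#'
#' @inheritParams sample_ages
#' @return Censoring times in `[0, censoring_horizon]`.
#' @export
sample_censoring_time <- function(config, n = config$n) {
  F <- config$censoring_horizon
  t1 <- ifelse(stats::runif(n) < config$p_ac, stats::runif(n, 0, F), F)
  t2 <- ifelse(stats::runif(n) < config$p_lf, stats::runif(n, 0, F), F)
  pmin(t1, t2)
}

#' Sample times to cancer death from the mixture
#'
#' Inverse-transform sampling from the mixture cure model: a uniform draw
#' `u* <= pi(x)` marks a cured patient (time `Inf`); otherwise the time
#' solves `S_u(t, x) = (u* - pi(x)) / (1 - pi(x))` with `S_u` the Weibull
#' (or, when `config$theta != 1`, exponentiated-Weibull) uncured survival
#' under the survival-exponent age convention `exp(-delta x)`.
#'
#' @inheritParams sample_ages
#' @param x Standardized ages (recycled against `u`).
#' @param u Optional uniform(0, 1) draws; drawn internally by default.
#' @return Times in years, `Inf` for the cured.
#' @export
sample_cancer_death_time <- function(config, x, u = NULL) {
  n <- length(x)
  if (is.null(u)) u <- stats::runif(n)
  pi <- stats::plogis(stats::qlogis(config$pi60) + config$beta * x)
  t <- rep(Inf, n)
  unc <- u > pi
  if (any(unc)) {
    v <- (u[unc] - pi[unc]) / (1 - pi[unc])    # target uncured survival
    w <- v^exp(config$delta * x[unc])          # strip the age exponent
    core <- if (config$theta == 1) w else 1 - (1 - w)^(1 / config$theta)
    t[unc] <- (-log(core) / config$lambda)^(1 / config$gamma)
  }
  t
}

#' Alpha as a function of age (age-dependent violation)
#'
#' `alpha_x = alpha + b_alpha (age - age_center)`; errors if the result is
#' non-positive at any requested age.
#'
#' @inheritParams sample_ages
#' @param age Ages in years.
#' @return Per-age alpha values (> 0).
#' @export
alpha_for_age <- function(config, age) {
  a <- config$alpha + config$b_alpha * (age - config$age_center)
  if (any(a <= 0))
    stop("age-dependent alpha non-positive at age ",
         paste(signif(age[a <= 0], 4), collapse = ", "))
  a
}

#' Support bounds of the randomly varying alpha
#'
#' `log(alpha)` is uniform on `[log a, log(ratio a)]` with
#' `a = alpha log(ratio) / (ratio - 1)`, which makes the mean of alpha equal
#' the target `alpha`; `ratio = 1` degenerates to the constant.
#'
#' @param alpha Target mean alpha (> 0).
#' @param ratio Max/min ratio (>= 1).
#' @return `c(low, high)`.
#' @export
random_alpha_bounds <- function(alpha, ratio) {
  stopifnot(alpha > 0)
  if (ratio < 1) stop("ratio must be >= 1")
  if (ratio == 1) return(c(alpha, alpha))
  a <- alpha * log(ratio) / (ratio - 1)
  c(a, ratio * a)
}

#' Generate a virtual patient cohort
#'
#' Draws, per patient: an age at diagnosis ([sample_ages()]); a per-patient
#' alpha (fixed, age-linear or random per the config); a non-cancer death
#' time by inverse transform from `S*(t | age)^alpha`
#' ([sample_noncancer_time()]); a time to cancer death from the mixture
#' ([sample_cancer_death_time()]); and a censoring time
#' ([sample_censoring_time()]). The death time is
#' `T_D = min(T_ED, T_CD)`, follow-up is `T = min(T_C, T_D)`, and the event
#' indicator is 1 (dead) when `T_C >= T_D`, else 0 (alive); follow-up is
#' finally truncated (as censored) at the analysis horizon `max_followup`.
#'
#' @inheritParams sample_ages
#' @param seed Optional integer seed; a fixed seed makes the cohort
#'   byte-identical on re-run. The caller's RNG state is restored.
#' @param keep_truth Add provenance columns `true_cured` (latent cure
#'   status) and `cause` (`"cancer"`, `"other"`, `"censored"`); these are
#'   never read by the estimation code.
#' @return A cohort data frame with columns `id`, `age`, `x`, `time`,
#'   `event` (plus provenance columns if requested).
#' @export
generate_cohort <- function(config, seed = NULL, keep_truth = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- config$n
  age <- sample_ages(config, n)
  x <- std_age(age)
  a_i <- if (config$b_alpha != 0) {
    alpha_for_age(config, age)
  } else if (config$alpha_ratio > 1) {
    b <- random_alpha_bounds(config$alpha, config$alpha_ratio)
    exp(stats::runif(n, log(b[1]), log(b[2])))
  } else rep(config$alpha, n)
  t_ed <- sample_noncancer_time(config$pop, age, a_i, stats::runif(n))
  t_cd <- sample_cancer_death_time(config, x)
  t_c <- sample_censoring_time(config, n)
  t_d <- pmin(t_ed, t_cd)
  time <- pmin(t_c, t_d)
  event <- as.integer(t_c >= t_d)
  trunc <- time > config$max_followup
  time[trunc] <- config$max_followup
  event[trunc] <- 0L
  out <- data.frame(id = seq_len(n), age = age, x = x, time = time,
                    event = event)
  if (keep_truth) {
    out$true_cured <- is.infinite(t_cd)
    out$cause <- ifelse(event == 0, "censored",
                        ifelse(t_cd <= t_ed, "cancer", "other"))
  }
  out
}
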