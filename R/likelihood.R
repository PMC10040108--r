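# Internal likelihood cores. These work on a plain parameter list
# (alpha, beta0, beta, lambda, gamma, delta, link, no_cure) and, when
# `penalize = TRUE`, replace domain violations (identity-link pi outside
# [0, 1], predicted cell survival outside (0, 1)) by large smooth penalties
# so that quasi-Newton optimisation never sees NaN. The exported wrappers
# validate a `cure_params` object and fail loudly instead.

PEN <- 1e8
T_FLOOR <- 0.5 / 365.25  # events recorded at t = 0 are shifted to half a day

pi_of_x <- function(th, x, penalize) {
  if (th$no_cure) return(list(pi = rep(0, length(x)), pen = 0))
  eta <- th$beta0 + th$beta * x
  if (th$link == "logistic") return(list(pi = stats::plogis(eta), pen = 0))
  pen <- 0
  bad <- eta < 0 | eta > 1
  if (any(bad)) {
    if (!penalize)
      stop(sprintf("identity link: pi outside [0, 1] at x = %s",
                   paste(signif(x[bad], 4), collapse = ", ")))
    pen <- PEN * sum(pmax(eta - 1, 0)^2 + pmax(-eta, 0)^2)
    eta <- pmin(pmax(eta, 1e-10), 1 - 1e-10)
  }
  list(pi = eta, pen = pen)
}

loglik_individual_core <- function(th, cohort, pop, include_expected = TRUE,
                                   penalize = FALSE) {
  t <- cohort$time
  t[cohort$event == 1 & t <= 0] <- T_FLOOR
  px <- pi_of_x(th, cohort$x, penalize)
  pi <- px$pi
  ex <- exp(-th$delta * cohort$x)
  su <- exp(-th$lambda * t^th$gamma * ex)
  rs <- pi + (1 - pi) * su
  lnS <- -(pop_cumhaz(pop, cohort$age + t) - pop_cumhaz(pop, cohort$age))
  ll <- sum(log(rs)) + if (include_expected) th$alpha * sum(lnS) else 0
  dead <- cohort$event == 1
  if (any(dead)) {
    fu <- th$gamma * th$lambda * t[dead]^(th$gamma - 1) * ex[dead] * su[dead]
    hstar <- expected_hazard(pop, cohort$age[dead], t[dead])
    hz <- (1 - pi[dead]) * fu / rs[dead] + th$alpha * hstar
    ll <- ll + sum(log(hz))
  }
  ll <- ll - px$pen
  if (!is.finite(ll)) {
    if (penalize) return(-.Machine$double.xmax / 2)
    stop("non-finite individual log-likelihood at record ",
         which(!is.finite(log(rs)))[1])
  }
  ll
}

loglik_grouped_core <- function(th, lt, dialect = "exact", penalize = FALSE) {
  px <- pi_of_x(th, lt$x, penalize)
  pi <- px$pi
  ex <- exp(-th$delta * lt$x)
  rs1 <- pi + (1 - pi) * exp(-th$lambda * lt$t_start^th$gamma * ex)
  rs2 <- pi + (1 - pi) * exp(-th$lambda * lt$t_end^th$gamma * ex)
  r <- rs2 / rs1
  p <- if (dialect == "exact") r * lt$s_exp^th$alpha
       else r + th$alpha * log(lt$s_exp)
  pen <- px$pen
  bad <- !is.finite(p) | p <= 0 | p >= 1
  if (any(bad)) {
    if (!penalize && dialect == "exact")
      stop("predicted interval survival outside (0, 1)")
    pb <- p[bad & is.finite(p)]
    pen <- pen + PEN * (sum(pmax(-pb, 0)^2 + pmax(pb - 1, 0)^2) +
                          sum(!is.finite(p)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  ll <- sum(lt$d * log(1 - p) + (lt$l - lt$d) * log(p)) - pen
  if (!is.finite(ll)) {
    if (penalize) return(-.Machine$double.xmax / 2)
    stop("non-finite grouped log-likelihood")
  }
  ll
}

#' Individual-data log-likelihood of the (corrected) mixture cure model
#'
#' For each record, a death at `t` contributes
#' `log(h_c(t, x) + alpha h*(age + t))`, every record contributes
#' `log RS(t, x) + alpha log S*(t | age)`, where `h_c` is the excess hazard
#' and `S*`, `h*` the general-population survival and hazard. In the
#' conventional model (`alpha = 1`) the expected-survival term
#' `sum(log S*)` is a constant; `include_expected = FALSE` drops it, which
#' changes the value but not the location of the maximum.
#'
#' @param params A [cure_params()] object.
#' @param cohort A cohort data frame (see [as_cohort()]).
#' @param pop A [pop_weibull()] or [pop_lifetable()] object.
#' @param include_expected Keep the `alpha * log S*` term (default `TRUE`, so
#'   conventional and corrected values are comparable).
#' @return The log-likelihood value.
#' @export
individual_loglik <- function(params, cohort, pop, include_expected = TRUE) {
  stopifnot(inherits(params, "cure_params"))
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) stop("empty cohort")
  loglik_individual_core(params_to_theta(params), cohort, pop,
                         include_expected, penalize = FALSE)
}

#' Grouped-data binomial log-likelihood
#'
#' Treats each life-table cell as a binomial experiment: `d` deaths among
#' `l = n - 0.5 w` effective patients with predicted conditional interval
#' observed survival `p`. The model-side interval relative survival is
#' `r = RS(t_end, x) / RS(t_start, x)`; under the `exact` dialect
#' `p = r * s_exp^alpha`, under `printed_first_order`
#' `p = r + alpha * log(s_exp)` (a first-order expansion of the former,
#' adequate when cell survivals are close to 1). Cells whose predicted `p`
#' leaves `(0, 1)` (possible under the first-order dialect) contribute a
#' large smooth penalty rather than `NaN`.
#'
#' @param params A [cure_params()] object.
#' @param lt A [build_life_table()] result (with `s_exp` filled in).
#' @param dialect `"exact"` or `"printed_first_order"`.
#' @return The log-likelihood value.
#' @export
grouped_loglik <- function(params, lt,
                           dialect = c("exact", "printed_first_order")) {
  stopifnot(inherits(params, "cure_params"), inherits(lt, "life_table"))
  dialect <- match.arg(dialect)
  if (any(!is.finite(lt$s_exp)))
    stop("life table lacks expected survival; run ederer2_expected / build_life_table")
  loglik_grouped_core(params_to_theta(params), lt, dialect,
                      penalize = (dialect == "printed_first_order"))
}

params_to_theta <- function(params) {
  list(alpha = params$alpha, beta0 = params$beta0, beta = params$beta,
       lambda = params$lambda, gamma = params$gamma, delta = params$delta,
       link = params$link, no_cure = params$variant == "corrected_no_cure")
}
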