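# Working-scale parametrization for unconstrained quasi-Newton optimisation:
# log(alpha), log(lambda), log(gamma) for the positive parameters; beta0,
# beta, delta untransformed. Which coordinates are free depends on the
# variant and on whether alpha is held fixed.

working_names <- function(variant, free_alpha) {
  nm <- c("log_alpha", "beta0", "beta", "log_lambda", "log_gamma", "delta")
  if (variant == "corrected_no_cure") nm <- setdiff(nm, c("beta0", "beta"))
  if (!free_alpha) nm <- setdiff(nm, "log_alpha")
  nm
}

theta_from_working <- function(w, variant, link, alpha_fixed) {
  g <- function(nm, default) if (nm %in% names(w)) unname(w[nm]) else default
  list(alpha = if ("log_alpha" %in% names(w)) exp(w[["log_alpha"]]) else alpha_fixed,
       beta0 = g("beta0", -Inf), beta = g("beta", 0),
       lambda = exp(w[["log_lambda"]]), gamma = exp(w[["log_gamma"]]),
       delta = g("delta", 0),
       link = link, no_cure = variant == "corrected_no_cure")
}

working_from_params <- function(params, nm) {
  full <- c(log_alpha = log(params$alpha), beta0 = params$beta0,
            beta = params$beta, log_lambda = log(params$lambda),
            log_gamma = log(params$gamma), delta = params$delta)
  full[nm]
}

#' Deterministic starting values for the cure model fit
#'
#' Heuristic: `alpha` starts at 1 and the trend parameters `beta`, `delta`
#' at 0; the cure fraction starts at the empirical relative-survival plateau
#' (last-interval pooled cumulative relative survival, clamped to
#' `[0.05, 0.95]`); the Weibull parameters come from a least-squares line on
#' `log(-log)` of the early cumulative relative survival (after removing the
#' plateau) against `log t`.
#'
#' @param data A cohort data frame or a `life_table`.
#' @param pop Population mortality (required for cohort input, to build the
#'   internal life table).
#' @param variant,link Passed through to [cure_params()].
#' @param max_followup Follow-up horizon used for the internal life table
#'   when `data` is a cohort.
#' @return A [cure_params()] object.
#' @export
initial_values <- function(data, pop = NULL, variant = "corrected",
                           link = "logistic", max_followup = NULL) {
  if (!inherits(data, "life_table")) {
    data <- as_cohort(data)
    if (is.null(pop)) stop("pop is required to derive initial values from a cohort")
    if (is.null(max_followup)) max_followup <- max(data$time)
    rng <- range(data$age)
    data <- build_life_table(data, pop, age_breaks = c(rng[1], rng[2] + 1),
                             interval_width = 1, max_followup = max_followup)
  }
  if (sum(data$d) == 0) stop("degenerate data: no deaths observed")
  rs <- relative_survival_table(data)
  # pool strata: initial-size-weighted mean cumulative RS per interval end
  n0 <- tapply(data$n, data$stratum, max)
  pooled <- sapply(split(rs, rs$t_end), function(s)
    sum(s$cum_rs * n0[as.character(s$stratum)]) / sum(n0[as.character(s$stratum)]))
  tt <- as.numeric(names(pooled))
  o <- order(tt); tt <- tt[o]; pooled <- pooled[o]
  plateau <- min(max(pooled[length(pooled)], 0.05), 0.95)
  if (variant == "corrected_no_cure") plateau <- 0
  su <- (pooled - plateau) / (1 - plateau)
  early <- which(su > 0.001 & su < 0.999 & tt <= max(tt) * 0.75)
  lambda0 <- 0.5; gamma0 <- 1
  if (length(early) >= 2) {
    cf <- stats::coef(stats::lm(log(-log(su[early])) ~ log(tt[early])))
    gamma0 <- min(max(cf[2], 0.2), 5)
    lambda0 <- min(max(exp(cf[1]), 1e-4), 10)
  }
  cure_params(alpha = 1,
              pi60 = if (variant == "corrected_no_cure") NULL else plateau,
              beta = 0, lambda = lambda0, gamma = gamma0, delta = 0,
              link = link, variant = variant)
}

#' Fit a (corrected) mixture cure model by maximum likelihood
#'
#' Maximizes the individual-data likelihood (cohort input; see
#' [individual_loglik()]) or the grouped binomial likelihood (life-table
#' input; see [grouped_loglik()]) with BFGS on a working scale
#' (`log alpha`, `log lambda`, `log gamma` unconstrained; `beta0`, `beta`,
#' `delta` unchanged). Standard errors come from the inverse numerical
#' Hessian at the optimum; 95% Wald intervals are formed on the working
#' scale and back-transformed, so intervals for `alpha`, `lambda`, `gamma`
#' stay positive and the interval for `pi60` stays inside (0, 1) under the
#' logistic link. On non-convergence the fit is retried from up to
#' `restarts` jittered starts (jitter seeded deterministically from the
#' data); a fit that still fails is returned with `converged = FALSE`,
#' never silently.
#'
#' @param data A cohort data frame (individual records) or a
#'   [build_life_table()] result (grouped data).
#' @param pop Population mortality; required for individual-data fits.
#' @param variant `"corrected"` (alpha free), `"conventional"` (alpha fixed
#'   at 1) or `"corrected_no_cure"` (no cured fraction, alpha free).
#' @param link Link for the cure fraction, `"logistic"` or `"identity"`.
#' @param dialect Grouped-likelihood dialect, see [grouped_loglik()].
#' @param init Optional [cure_params()] starting values; defaults to
#'   [initial_values()].
#' @param fix_alpha Optionally hold alpha at a given value (e.g.
#'   `fix_alpha = 1` reproduces the conventional fit from the corrected
#'   variant).
#' @param include_expected Individual likelihood only; see
#'   [individual_loglik()].
#' @param restarts Maximum number of jittered restarts (default 3).
#' @param control Passed to [stats::optim()] (defaults: BFGS,
#'   `maxit = 500`, `reltol = 1e-10`).
#' @return An object of class `cure_fit` with elements `params` (fitted
#'   [cure_params()]), `coef` (natural-scale estimates, standard errors and
#'   95% CI for alpha, pi60, lambda, gamma, beta, delta), `working`
#'   (working-scale estimates, `se` and `vcov`), `loglik`, `converged`,
#'   `n_used`, and bookkeeping fields.
#' @examples
#' cfg <- scenario_preset("breast", alpha = 1.2, n = 2000)
#' coh <- generate_cohort(cfg, seed = 1)
#' lt <- build_life_table(coh, cfg$pop)
#' fit <- fit_cure(lt)
#' fit$coef
#' @export
fit_cure <- function(data, pop = NULL,
                     variant = c("corrected", "conventional", "corrected_no_cure"),
                     link = c("logistic", "identity"),
                     dialect = c("exact", "printed_first_order"),
                     init = NULL, fix_alpha = NULL, include_expected = TRUE,
                     restarts = 3, control = list()) {
  variant <- match.arg(variant)
  link <- match.arg(link)
  dialect <- match.arg(dialect)
  grouped <- inherits(data, "life_table")
  if (!grouped) {
    data <- as_cohort(data)
    if (is.null(pop)) stop("pop is required for individual-data fits")
  }
  alpha_fixed <- if (variant == "conventional") 1 else fix_alpha
  free_alpha <- is.null(alpha_fixed)
  nm <- working_names(variant, free_alpha)
  if (is.null(init))
    init <- initial_values(data, pop, variant = variant, link = link)
  w0 <- working_from_params(init, nm)

  nll <- function(w) {
    names(w) <- nm
    th <- theta_from_working(w, variant, link, alpha_fixed)
    -(if (grouped) loglik_grouped_core(th, data, dialect, penalize = TRUE)
      else loglik_individual_core(th, data, pop, include_expected, penalize = TRUE))
  }
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)

  jitter_seed <- data_seed(data)
  best <- NULL; tries <- 0
  w_try <- w0
  repeat {
    opt <- tryCatch(stats::optim(w_try, nll, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    ok <- !is.null(opt) && opt$convergence == 0 && is.finite(opt$value)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
    if (ok && (is.null(best) || opt$value <= best$value)) { best <- opt; break }
    tries <- tries + 1
    if (tries > restarts) break
    w_try <- w0 + with_seed(jitter_seed + tries,
                            stats::rnorm(length(w0), sd = 0.3))
  }
  if (is.null(best))
    return(failed_fit(nm, variant, link, dialect, grouped, data))

  w_hat <- best$par; names(w_hat) <- nm
  hess <- tryCatch(stats::optimHess(w_hat, nll), error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  se_w <- if (!is.null(vcov) && all(is.finite(diag(vcov))) &&
              all(diag(vcov) > 0)) sqrt(diag(vcov)) else NULL
  converged <- best$convergence == 0 && !is.null(se_w)

  th <- theta_from_working(w_hat, variant, link, alpha_fixed)
  params <- cure_params(alpha = th$alpha,
                        pi60 = if (variant == "corrected_no_cure") NULL
                               else if (link == "logistic") stats::plogis(th$beta0)
                               else min(max(th$beta0, 1e-9), 1 - 1e-9),
                        beta = th$beta, lambda = th$lambda, gamma = th$gamma,
                        delta = th$delta, link = link, variant = variant)

  coef <- natural_coef(w_hat, se_w, nm, link, alpha_fixed, variant)
  structure(list(params = params, coef = coef,
                 working = list(estimate = w_hat, se = se_w, vcov = vcov),
                 loglik = -best$value, converged = converged,
                 n_used = if (grouped) nrow(data) else nrow(data),
                 n_restarts = tries, variant = variant, link = link,
                 dialect = if (grouped) dialect else NA_character_,
                 data_type = if (grouped) "grouped" else "individual"),
            class = "cure_fit")
}

failed_fit <- function(nm, variant, link, dialect, grouped, data) {
  structure(list(params = NULL,
                 coef = natural_coef(stats::setNames(rep(NA_real_, length(nm)), nm),
                                     NULL, nm, link, NULL, variant),
                 working = NULL, loglik = NA_real_, converged = FALSE,
                 n_used = nrow(data), n_restarts = NA_integer_,
                 variant = variant, link = link,
                 dialect = if (grouped) dialect else NA_character_,
                 data_type = if (grouped) "grouped" else "individual"),
            class = "cure_fit")
}

# natural-scale coefficient table with delta-method SEs and back-transformed
# 95% Wald intervals
natural_coef <- function(w, se_w, nm, link, alpha_fixed, variant) {
  z <- stats::qnorm(0.975)
  getw <- function(p) if (p %in% nm) unname(w[p]) else NA_real_
  gets <- function(p) if (!is.null(se_w) && p %in% nm) unname(se_w[p]) else NA_real_
  rows <- list()
  add <- function(parameter, estimate, se, lo, hi)
    rows[[length(rows) + 1]] <<- data.frame(parameter = parameter,
                                            estimate = estimate, se = se,
                                            lo = lo, hi = hi)
  # alpha
  if ("log_alpha" %in% nm) {
    la <- getw("log_alpha"); s <- gets("log_alpha")
    add("alpha", exp(la), exp(la) * s, exp(la - z * s), exp(la + z * s))
  } else add("alpha", if (is.null(alpha_fixed)) NA_real_ else alpha_fixed,
             NA_real_, NA_real_, NA_real_)
  # pi60 (derived from beta0)
  if ("beta0" %in% nm) {
    b0 <- getw("beta0"); s <- gets("beta0")
    if (link == "logistic")
      add("pi60", stats::plogis(b0), stats::dlogis(b0) * s,
          stats::plogis(b0 - z * s), stats::plogis(b0 + z * s))
    else
      add("pi60", b0, s, b0 - z * s, b0 + z * s)
  }
  if ("beta" %in% nm) {
    b <- getw("beta"); s <- gets("beta")
    add("beta", b, s, b - z * s, b + z * s)
  }
  for (p in c("lambda", "gamma")) {
    lp <- paste0("log_", p)
    lv <- getw(lp); s <- gets(lp)
    add(p, exp(lv), exp(lv) * s, exp(lv - z * s), exp(lv + z * s))
  }
  d <- getw("delta"); s <- gets("delta")
  add("delta", d, s, d - z * s, d + z * s)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cure_fit <- function(x, ...) {
  cat(sprintf("Mixture cure model fit (%s variant, %s link, %s data)\n",
              x$variant, x$link, x$data_type))
  cat(sprintf("  log-likelihood %.4f, converged: %s (%s restarts)\n",
              x$loglik, x$converged, x$n_restarts))
  print(x$coef, digits = 4)
  invisible(x)
}

#' @export
coef.cure_fit <- function(object, ...)
  stats::setNames(object$coef$estimate, object$coef$parameter)

#' Write a fit result to JSON
#'
#' Serializes the coefficient table and fit diagnostics as structured text.
#'
#' @param fit A `cure_fit` object.
#' @param file Path to a JSON file.
#' @export
write_fit <- function(fit, file) {
  stopifnot(inherits(fit, "cure_fit"))
  jsonlite::write_json(
    list(variant = fit$variant, link = fit$link, data_type = fit$data_type,
         dialect = fit$dialect, loglik = fit$loglik,
         converged = fit$converged, n_used = fit$n_used, coef = fit$coef),
    file, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(file)
}

# deterministic integer seed derived from the data, for jittered restarts
data_seed <- function(data) {
  s <- if (inherits(data, "life_table")) sum(data$d) + sum(data$n)
       else sum(data$event) + nrow(data)
  as.integer((s * 2654435761) %% 2147483647)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
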