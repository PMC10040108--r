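#' Fit specification for replicate experiments
#'
#' @param data `"grouped"` (life-table binomial likelihood) or
#'   `"individual"`.
#' @param variant,link,dialect Passed to [fit_cure()].
#' @return A list of class `fit_spec`.
#' @export
fit_spec <- function(data = c("grouped", "individual"),
                     variant = c("corrected", "conventional", "corrected_no_cure"),
                     link = c("logistic", "identity"),
                     dialect = c("exact", "printed_first_order")) {
  structure(list(data = match.arg(data), variant = match.arg(variant),
                 link = match.arg(link), dialect = match.arg(dialect)),
            class = "fit_spec")
}

#' Run replicate simulate-then-fit experiments
#'
#' Generates `R` independent cohorts under `config`, fits each with the
#' requested estimator, and returns one row per replicate with the
#' natural-scale estimates, standard errors and 95% CI bounds of alpha,
#' pi60, lambda, gamma, beta and delta. The global `seed` is expanded into
#' one recorded sub-seed per replicate, so any single replicate can be
#' reproduced in isolation; replicate fits that error are returned as
#' `converged = FALSE` rows, never aborting the batch.
#'
#' @param config A [scenario_config()].
#' @param spec A [fit_spec()].
#' @param R Number of replicates.
#' @param seed Integer seed for the whole batch.
#' @return A data frame with columns `rep`, `seed`, `converged`, `loglik`
#'   and `est_* / se_* / lo_* / hi_*` per parameter.
#' @export
run_replicates <- function(config, spec = fit_spec(), R = 1000, seed = 1) {
  stopifnot(inherits(config, "scenario_config"), R >= 1)
  seeds <- with_seed(seed, sample.int(2147483646L, R))
  pars <- c("alpha", "pi60", "lambda", "gamma", "beta", "delta")
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    res <- tryCatch({
      coh <- generate_cohort(config, seed = seeds[r])
      fit <- if (spec$data == "grouped") {
        lt <- build_life_table(coh, config$pop,
                               age_breaks = config$age_breaks,
                               max_followup = config$max_followup)
        fit_cure(lt, variant = spec$variant, link = spec$link,
                 dialect = spec$dialect)
      } else {
        fit_cure(coh, pop = config$pop, variant = spec$variant,
                 link = spec$link)
      }
      cf <- fit$coef
      row <- list(rep = r, seed = seeds[r], converged = fit$converged,
                  loglik = fit$loglik)
      for (p in pars) {
        i <- match(p, cf$parameter)
        row[[paste0("est_", p)]] <- if (is.na(i)) NA_real_ else cf$estimate[i]
        row[[paste0("se_", p)]]  <- if (is.na(i)) NA_real_ else cf$se[i]
        row[[paste0("lo_", p)]]  <- if (is.na(i)) NA_real_ else cf$lo[i]
        row[[paste0("hi_", p)]]  <- if (is.na(i)) NA_real_ else cf$hi[i]
      }
      as.data.frame(row)
    }, error = function(e) {
      row <- list(rep = r, seed = seeds[r], converged = FALSE,
                  loglik = NA_real_)
      for (p in pars)
        for (pre in c("est_", "se_", "lo_", "hi_"))
          row[[paste0(pre, p)]] <- NA_real_
      as.data.frame(row)
    })
    rows[[r]] <- res
  }
  do.call(rbind, rows)
}

#' True parameter values of a scenario
#'
#' @param config A [scenario_config()].
#' @return Named list with `alpha`, `pi60`, `lambda`, `gamma`, `beta`,
#'   `delta`.
#' @export
scenario_truth <- function(config) {
  list(alpha = config$alpha, pi60 = config$pi60, lambda = config$lambda,
       gamma = config$gamma, beta = config$beta, delta = config$delta)
}

#' Monte-Carlo performance indicators
#'
#' Per parameter, over the converged replicates: absolute bias
#' `AB = mean(estimate) - truth`, the standard deviation `SD` of the
#' estimates (denominator `R - 1`), and the coverage `CVR`, the fraction of
#' 95% confidence intervals containing the truth. Non-converged replicates
#' are excluded and counted.
#'
#' @param reps A [run_replicates()] table.
#' @param truth Named list/vector of true values (see [scenario_truth()]);
#'   parameters without a truth or without estimates are skipped.
#' @return A data frame with columns `parameter`, `truth`, `AB`, `SD`,
#'   `CVR`, `n_converged`, `n_total`.
#' @export
performance <- function(reps, truth) {
  ok <- !is.na(reps$converged) & reps$converged
  if (!any(ok)) stop("no converged replicates")
  rows <- list()
  for (p in names(truth)) {
    est <- reps[[paste0("est_", p)]][ok]
    if (is.null(est) || all(is.na(est)) || is.na(truth[[p]])) next
    se <- reps[[paste0("se_", p)]][ok]
    if (all(is.na(se))) next  # parameter was held fixed, not estimated
    lo <- reps[[paste0("lo_", p)]][ok]
    hi <- reps[[paste0("hi_", p)]][ok]
    rows[[p]] <- data.frame(
      parameter = p, truth = truth[[p]],
      AB = mean(est) - truth[[p]], SD = stats::sd(est),
      CVR = mean(lo <= truth[[p]] & truth[[p]] <= hi),
      n_converged = sum(ok), n_total = nrow(reps))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenario grids mirroring the simulation study's result tables
#'
#' Emits the factor grid of one of the six study tables as a list of
#' `(label, config, spec, R)` entries ready for [run_replicates()]:
#' * `T1`: both scenarios x alpha in (2, 1.5, 1.2, 1, 0.8) x grouped /
#'   individual data, corrected model;
#' * `T2`: both scenarios x alpha x conventional / corrected model, grouped;
#' * `T3`: both scenarios x N in (10000, 5000, 2000, 1000, 500) x follow-up
#'   in (5, 10, 15) years, grouped corrected (alpha 1.2 breast-like, 2
#'   lung-like);
#' * `T4`: exponentiated-Weibull violation, theta in (0.25, 0.5, 0.625,
#'   0.8, 1.25, 1.6, 2, 4);
#' * `T5`: age-dependent alpha, slope grids per scenario;
#' * `T6`: random alpha, max/min ratio in (2, 3, 4).
#'
#' @param table_id One of `"T1"` ... `"T6"`.
#' @param R Replicates per cell (default 1000).
#' @param n Cohort size override (default as in the study, 10000).
#' @param age_center Centering constant for `T5` (default `NULL`: the
#'   design's expected age, see [scenario_config()]).
#' @return A list of entries, each a list with elements `label`, `config`,
#'   `spec`, `R`.
#' @export
scenario_grid <- function(table_id = c("T1", "T2", "T3", "T4", "T5", "T6"),
                          R = 1000, n = 10000, age_center = NULL) {
  table_id <- match.arg(table_id)
  alphas <- c(2, 1.5, 1.2, 1, 0.8)
  robust_alpha <- c(breast = 1.2, lung = 2)
  out <- list()
  add <- function(label, config, spec)
    out[[length(out) + 1]] <<- list(label = label, config = config,
                                    spec = spec, R = R)
  switch(table_id,
    T1 = for (sc in c("breast", "lung")) for (a in alphas)
      for (mode in c("grouped", "individual"))
        add(sprintf("%s alpha=%g %s", sc, a, mode),
            scenario_preset(sc, alpha = a, n = n),
            fit_spec(data = mode, variant = "corrected")),
    T2 = for (sc in c("breast", "lung")) for (a in alphas)
      for (v in c("conventional", "corrected"))
        add(sprintf("%s alpha=%g %s", sc, a, v),
            scenario_preset(sc, alpha = a, n = n),
            fit_spec(data = "grouped", variant = v)),
    T3 = for (sc in c("breast", "lung"))
      for (N in c(10000, 5000, 2000, 1000, 500))
        for (fup in c(5, 10, 15))
          add(sprintf("%s N=%d FUP=%d", sc, N, fup),
              scenario_preset(sc, alpha = robust_alpha[[sc]], n = N,
                              max_followup = fup),
              fit_spec(data = "grouped", variant = "corrected")),
    T4 = for (sc in c("breast", "lung"))
      for (th in c(0.25, 0.5, 0.625, 0.8, 1.25, 1.6, 2, 4))
        add(sprintf("%s theta=%g", sc, th),
            scenario_preset(sc, alpha = robust_alpha[[sc]], n = n, theta = th),
            fit_spec(data = "grouped", variant = "corrected")),
    T5 = {
      slopes <- list(breast = c(-0.02, -0.01, -0.005, 0.001, 0.002, 0.005, 0.01),
                     lung = c(-0.08, -0.04, -0.02, 0.01, 0.02, 0.04, 0.05))
      for (sc in c("breast", "lung")) for (b in slopes[[sc]])
        add(sprintf("%s b_alpha=%g", sc, b),
            scenario_preset(sc, alpha = robust_alpha[[sc]], n = n,
                            b_alpha = b, age_center = age_center),
            fit_spec(data = "grouped", variant = "corrected"))
    },
    T6 = for (sc in c("breast", "lung")) for (rho in c(2, 3, 4))
      add(sprintf("%s ratio=%g", sc, rho),
          scenario_preset(sc, alpha = robust_alpha[[sc]], n = n,
                          alpha_ratio = rho),
          fit_spec(data = "grouped", variant = "corrected")))
  out
}

#' Run a whole scenario grid and summarize performance
#'
#' Convenience wrapper: runs [run_replicates()] for every entry of a
#' [scenario_grid()] and binds the [performance()] summaries into one tidy
#' table, with Monte-Carlo standard errors (`SD / sqrt(n_converged)`) so
#' scaled-down runs can be judged with explicit tolerances.
#'
#' @param grid A [scenario_grid()] result (or any list of entries in the
#'   same shape).
#' @param seed Integer seed; each entry gets an offset sub-seed.
#' @return A data frame of performance summaries, one row per (entry,
#'   parameter).
#' @export
run_grid <- function(grid, seed = 1) {
  res <- lapply(seq_along(grid), function(i) {
    e <- grid[[i]]
    reps <- run_replicates(e$config, e$spec, R = e$R, seed = seed + i)
    perf <- performance(reps, scenario_truth(e$config))
    perf$mcse <- perf$SD / sqrt(perf$n_converged)
    cbind(label = e$label, perf)
  })
  do.call(rbind, res)
}
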