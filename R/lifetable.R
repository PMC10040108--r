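#' Validate an individual-record cohort
#'
#' A cohort is a data frame with one row per patient and columns `age` (years
#' at diagnosis), `time` (follow-up in years) and `event` (1 = dead,
#' 0 = alive/censored); a standardized-age column `x` is added if missing.
#'
#' @param cohort A data frame.
#' @return The validated cohort (with `x`).
#' @export
as_cohort <- function(cohort) {
  need <- c("age", "time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(cohort$age)) || any(!is.finite(cohort$time)))
    stop("non-finite age or time in cohort")
  if (any(cohort$time < 0)) stop("negative follow-up time")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (is.null(cohort$x)) cohort$x <- std_age(cohort$age)
  cohort
}

#' Read / write a cohort CSV
#'
#' Columns `age`, `time`, `event` (and optionally `x`, `id`).
#'
#' @param cohort A cohort data frame.
#' @param file Path to a CSV file.
#' @return `read_cohort` returns a validated cohort data frame.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(as_cohort(cohort), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) as_cohort(utils::read.csv(file))

#' Ederer II expected conditional interval survival
#'
#' For one group of patients and a grid of interval bounds, computes the
#' Ederer II estimator of expected survival: for interval `j`, the mean over
#' patients still at risk at its start of their individual conditional
#' population survival `S*(t_j | age) / S*(t_{j-1} | age)`. The product over
#' intervals gives the cumulative Ederer II expected survival.
#'
#' Patients are at risk for interval `j` when their follow-up time is
#' `>= t_{j-1}`; intervals with an empty risk set get `NA` (the table is
#' truncated there).
#'
#' @param cohort A cohort data frame (see [as_cohort()]).
#' @param pop A [pop_weibull()] or [pop_lifetable()] object.
#' @param bounds Interval bounds, `0 = t_0 < t_1 < ... < t_J`.
#' @return A vector of length `J` of expected conditional interval survivals.
#' @export
ederer2_expected <- function(cohort, pop, bounds) {
  cohort <- as_cohort(cohort)
  stopifnot(length(bounds) >= 2, bounds[1] == 0, all(diff(bounds) > 0))
  J <- length(bounds) - 1
  n <- nrow(cohort)
  # H[i, j]: population cumulative hazard of patient i at bound j (0..J)
  H <- outer(cohort$age, bounds, function(a, b) pop_cumhaz(pop, a + b))
  cond <- exp(-(H[, -1, drop = FALSE] - H[, -(J + 1), drop = FALSE]))
  idx <- interval_index(cohort$time, bounds)
  A <- matrix(0, J, J)
  S <- rowsum(cond, idx)
  A[as.integer(rownames(S)), ] <- S
  at_risk <- rev(cumsum(rev(tabulate(idx, nbins = J))))
  num <- vapply(1:J, function(j) sum(A[j:J, j]), numeric(1))
  ifelse(at_risk > 0, num / at_risk, NA_real_)
}

# assign follow-up times to half-open intervals [t_{j-1}, t_j); the terminal
# bound goes to the last interval
interval_index <- function(time, bounds) {
  J <- length(bounds) - 1
  if (any(time < bounds[1] - 1e-12 | time > bounds[J + 1] + 1e-12))
    stop("follow-up times outside [0, max_followup]")
  pmin(findInterval(time, bounds, rightmost.closed = TRUE), J)
}

#' Build a grouped relative-survival life table from a cohort
#'
#' Stratifies the cohort by age class and tabulates, per stratum and annual
#' interval: `n` alive at the start, `d` deaths and `w` censorings within the
#' interval (half-open assignment `[t_{j-1}, t_j)`), the effective number at
#' risk `l = n - 0.5 w` (actuarial half-interval credit for those censored
#' inside the interval; patients censored exactly at `max_followup` survived
#' the whole last interval and keep full credit),
#' the observed conditional interval survival `s_obs = 1 - d / l`, and the
#' Ederer II expected conditional interval survival `s_exp`. Each stratum
#' carries the realized mean age and mean standardized age `x` of its
#' members.
#'
#' @param cohort A cohort data frame (see [as_cohort()]).
#' @param pop A [pop_weibull()] or [pop_lifetable()] object.
#' @param age_breaks Stratum bounds; the default gives the four age classes
#'   40-57, 58-64, 65-69 and 70-74.
#' @param interval_width Interval width in years (default 1).
#' @param max_followup Maximum follow-up in years (default 15).
#' @return An object of class `life_table`: a data frame with columns
#'   `stratum`, `t_start`, `t_end`, `n`, `d`, `w`, `l`, `s_obs`, `s_exp`,
#'   `mean_age`, `x`, plus attributes recording the construction.
#' @export
build_life_table <- function(cohort, pop,
                             age_breaks = c(40, 58, 65, 70, 75),
                             interval_width = 1, max_followup = 15) {
  cohort <- as_cohort(cohort)
  stopifnot(interval_width > 0, max_followup > 0)
  if (any(cohort$time > max_followup + 1e-12))
    stop("follow-up times exceed max_followup")
  J <- ceiling(max_followup / interval_width - 1e-9)
  bounds <- c(seq(0, by = interval_width, length.out = J), max_followup)
  K <- length(age_breaks) - 1
  strat <- findInterval(cohort$age, age_breaks, rightmost.closed = TRUE)
  if (any(strat < 1 | strat > K))
    stop("ages outside the range of age_breaks")
  rows <- list()
  for (k in 1:K) {
    sub <- cohort[strat == k, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("empty stratum [%g, %g) dropped",
                      age_breaks[k], age_breaks[k + 1]))
      next
    }
    idx <- interval_index(sub$time, bounds)
    # censored exactly at the horizon survived the whole last interval:
    # they stay in n throughout but are neither deaths nor within-interval
    # withdrawals, so they carry full (not half) risk credit
    at_end <- sub$event == 0 & sub$time >= max_followup - 1e-12
    d <- tabulate(idx[sub$event == 1], nbins = J)
    w <- tabulate(idx[sub$event == 0 & !at_end], nbins = J)
    n <- nrow(sub) - c(0, cumsum(d + w))[1:J]
    l <- n - 0.5 * w
    s_exp <- ederer2_expected(sub, pop, bounds)
    keep <- n > 0
    rows[[length(rows) + 1]] <- data.frame(
      stratum = sprintf("[%g,%g)", age_breaks[k], age_breaks[k + 1]),
      t_start = bounds[1:J][keep], t_end = bounds[-1][keep],
      n = n[keep], d = d[keep], w = w[keep], l = l[keep],
      s_obs = ifelse(l[keep] > 0, 1 - d[keep] / l[keep], NA_real_),
      s_exp = s_exp[keep],
      mean_age = mean(sub$age), x = mean(sub$x))
  }
  if (!length(rows)) stop("all strata empty")
  lt <- do.call(rbind, rows)
  rownames(lt) <- NULL
  structure(lt, class = c("life_table", "data.frame"),
            interval_width = interval_width, max_followup = max_followup,
            age_breaks = age_breaks)
}

#' Cumulative observed, expected and relative survival per stratum
#'
#' Cumulative products of the observed and Ederer II expected conditional
#' interval survivals, and their ratio — the cumulative relative survival
#' (not clamped, so values slightly above 1 can occur).
#'
#' @param lt A [build_life_table()] result.
#' @return A data frame with columns `stratum`, `t_end`, `cum_obs`,
#'   `cum_exp`, `cum_rs`.
#' @export
relative_survival_table <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  out <- do.call(rbind, lapply(split(as.data.frame(lt), lt$stratum), function(s) {
    s <- s[order(s$t_start), ]
    data.frame(stratum = s$stratum, t_end = s$t_end,
               cum_obs = cumprod(s$s_obs), cum_exp = cumprod(s$s_exp),
               cum_rs = cumprod(s$s_obs) / cumprod(s$s_exp))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a life table CSV
#'
#' Round-trips the life-table columns losslessly; construction metadata
#' (interval width, maximum follow-up) is re-derived from the interval
#' bounds.
#'
#' @param lt A `life_table` object.
#' @param file Path to a CSV file.
#' @return `read_life_table` returns a `life_table` object.
#' @export
write_life_table <- function(lt, file) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  need <- c("stratum", "t_start", "t_end", "n", "d", "w", "l",
            "s_obs", "s_exp", "mean_age", "x")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("life table lacks columns: ", paste(miss, collapse = ", "))
  widths <- df$t_end - df$t_start
  structure(df, class = c("life_table", "data.frame"),
            interval_width = stats::median(widths),
            max_followup = max(df$t_end), age_breaks = NULL)
}
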