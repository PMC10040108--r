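#' General-population ("expected") mortality
#'
#' Expected mortality of the matched general population, used both to compute
#' expected survival in relative-survival analyses and to simulate non-cancer
#' death times. Two sources are supported: a parametric Weibull fitted to
#' population life tables, `S*(a) = exp(-(a / scale)^shape)` from birth, and a
#' tabulated life table with piecewise-constant annual hazards.
#'
#' @param scale Weibull scale in years of age (default 88, a both-sexes
#'   French 2002 life-table fit).
#' @param shape Weibull shape (default 11).
#' @return An object of class `pop_mortality`.
#' @examples
#' pop <- pop_weibull()
#' expected_survival(pop, age = 60, t = 15)
#' @export
pop_weibull <- function(scale = 88, shape = 11) {
  stopifnot(is.numeric(scale), scale > 0, is.numeric(shape), shape > 0)
  structure(list(kind = "parametric_weibull", lambda_p = scale, gamma_p = shape),
            class = "pop_mortality")
}

#' Tabulated population mortality
#'
#' Builds a `pop_mortality` object from a life table giving, per (integer)
#' age, either the hazard (force of mortality, per person-year) or the annual
#' death probability `qx` (converted as `hazard = -log(1 - qx)`). The hazard
#' is treated as constant within each one-year age band, so the cumulative
#' hazard is linearly interpolated within years.
#'
#' @param age Vector of ages (years, strictly increasing, step 1 expected).
#' @param hazard Hazard per person-year at each age (either this or `qx`).
#' @param qx Annual death probability at each age.
#' @return An object of class `pop_mortality`.
#' @export
pop_lifetable <- function(age, hazard = NULL, qx = NULL) {
  if (is.null(hazard) == is.null(qx))
    stop("supply exactly one of `hazard` or `qx`")
  if (!is.null(qx)) {
    if (any(qx < 0 | qx >= 1)) stop("qx must lie in [0, 1)")
    hazard <- -log(1 - qx)
  }
  if (length(age) != length(hazard)) stop("age and hazard lengths differ")
  if (any(!is.finite(age)) || any(!is.finite(hazard)))
    stop("non-finite values in population table")
  o <- order(age)
  age <- age[o]; hazard <- hazard[o]
  if (any(diff(age) <= 0)) stop("ages must be strictly increasing")
  if (any(hazard < 0)) stop("hazards must be non-negative")
  # cumulative hazard from the first tabulated age, at each band start
  widths <- diff(c(age, age[length(age)] + 1))
  cumhaz0 <- c(0, cumsum(hazard * widths))
  structure(list(kind = "tabulated", age = age, hazard = hazard,
                 cumhaz0 = cumhaz0),
            class = "pop_mortality")
}

#' Read a tabulated population life table from CSV
#'
#' Expects columns `age` and either `hazard` (per person-year) or `qx`
#' (annual death probability). Leading comment lines starting with `#` are
#' ignored (they may declare the dialect).
#'
#' @param file Path to a CSV file.
#' @return A `pop_mortality` object.
#' @export
read_pop_table <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  if (!"age" %in% names(df)) stop("population table needs an `age` column")
  if ("hazard" %in% names(df)) pop_lifetable(df$age, hazard = df$hazard)
  else if ("qx" %in% names(df)) pop_lifetable(df$age, qx = df$qx)
  else stop("population table needs a `hazard` or `qx` column")
}

#' @export
print.pop_mortality <- function(x, ...) {
  if (x$kind == "parametric_weibull")
    cat(sprintf("Population mortality: Weibull(scale = %g, shape = %g) from birth\n",
                x$lambda_p, x$gamma_p))
  else
    cat(sprintf("Population mortality: tabulated, ages %g-%g\n",
                min(x$age), max(x$age)))
  invisible(x)
}

# cumulative hazard from birth (or from first tabulated age) at age a; vectorized
pop_cumhaz <- function(pop, a) {
  if (pop$kind == "parametric_weibull") {
    (a / pop$lambda_p)^pop$gamma_p
  } else {
    amin <- pop$age[1]
    amax <- pop$age[length(pop$age)] + 1
    if (any(a < amin - 1e-9 | a > amax + 1e-9))
      stop(sprintf("age outside tabulated range [%g, %g]", amin, amax))
    a <- pmin(pmax(a, amin), amax)
    i <- pmin(findInterval(a, pop$age), length(pop$age))
    pop$cumhaz0[i] + (a - pop$age[i]) * pop$hazard[i]
  }
}

check_age_t <- function(age, t) {
  if (any(!is.finite(age))) stop("age must be finite")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (any(age < 0)) stop("age must be >= 0")
}

#' Expected (general-population) survival conditional on age at diagnosis
#'
#' `S*(t | age) = exp(-[H*(age + t) - H*(age)])`, the probability that a
#' population member alive at `age` survives a further `t` years.
#'
#' @param pop A [pop_weibull()] or [pop_lifetable()] object.
#' @param age Age at diagnosis in years.
#' @param t Years since diagnosis (>= 0).
#' @return Survival probabilities, 1 at `t = 0`.
#' @export
expected_survival <- function(pop, age, t) {
  check_age_t(age, t)
  exp(-(pop_cumhaz(pop, age + t) - pop_cumhaz(pop, age)))
}

#' Expected (general-population) hazard at time t after diagnosis
#'
#' The population force of mortality at attained age `age + t`; for the
#' parametric form `h*(a) = (shape/scale) (a/scale)^(shape-1)`, for tabulated
#' input the piecewise-constant annual hazard.
#'
#' @inheritParams expected_survival
#' @return Hazards per person-year (>= 0).
#' @export
expected_hazard <- function(pop, age, t) {
  check_age_t(age, t)
  a <- age + t
  if (pop$kind == "parametric_weibull") {
    (pop$gamma_p / pop$lambda_p) * (a / pop$lambda_p)^(pop$gamma_p - 1)
  } else {
    amin <- pop$age[1]
    amax <- pop$age[length(pop$age)] + 1
    if (any(a < amin - 1e-9 | a > amax + 1e-9))
      stop(sprintf("age outside tabulated range [%g, %g]", amin, amax))
    a <- pmin(pmax(a, amin), amax - 1e-9)
    pop$hazard[pmin(findInterval(a, pop$age), length(pop$age))]
  }
}

#' Sample a non-cancer death time by inverse transform
#'
#' Solves `S*(t | age)^alpha = u` for `t`: the time to death from causes
#' other than cancer when patients' non-cancer mortality is `alpha` times the
#' population hazard. For the parametric Weibull population this is closed
#' form; for tabulated input the piecewise-linear cumulative hazard is
#' inverted exactly.
#'
#' @inheritParams expected_survival
#' @param alpha Multiplicative excess non-cancer mortality (> 0); may be a
#'   vector matched to `u`.
#' @param u Uniform(0, 1) draws.
#' @return Times in years (>= 0), one per draw.
#' @export
sample_noncancer_time <- function(pop, age, alpha = 1, u) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be > 0")
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("u must lie strictly in (0, 1)")
  check_age_t(age, 0)
  # target cumulative hazard beyond age: H*(age + t) = H*(age) - log(u)/alpha
  H_target <- pop_cumhaz(pop, age) - log(u) / alpha
  if (pop$kind == "parametric_weibull") {
    pop$lambda_p * H_target^(1 / pop$gamma_p) - age
  } else {
    # invert piecewise-linear cumulative hazard; beyond the table the last
    # band's hazard is extended
    n <- length(pop$age)
    i <- findInterval(H_target, pop$cumhaz0, rightmost.closed = FALSE)
    i <- pmin(pmax(i, 1L), n)
    h <- pop$hazard[i]
    if (any(h <= 0 & H_target > pop$cumhaz0[i]))
      stop("cannot invert survival across a zero-hazard band")
    a_death <- pop$age[i] + ifelse(h > 0, (H_target - pop$cumhaz0[i]) / h, 0)
    pmax(a_death - age, 0)
  }
}
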