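#' Standardized age
#'
#' Centering and scaling used for the age covariate throughout the package:
#' `x = (age - 60) / 15`, so that the reference age 60 maps to 0 and one unit
#' of `x` is 15 years.
#'
#' @param age Age at diagnosis in years.
#' @return Standardized age.
#' @export
std_age <- function(age) (age - 60) / 15

#' Mixture cure model parameters
#'
#' Bundles the parameters of the (corrected) mixture cure model:
#' * `alpha`: multiplicative excess non-cancer mortality (fixed at 1 in the
#'   conventional variant);
#' * cure fraction `pi(x)` with intercept given either as `pi60` (value at the
#'   reference age 60) or as `beta0` on the link scale, and trend `beta` per
#'   15 years of age;
#' * Weibull net survival of the uncured
#'   `S_u(t, x) = exp(-lambda t^gamma)^exp(-delta x)`, `lambda` the rate-scale,
#'   `gamma` the shape, `delta` the age effect per 15 years (negative `delta`
#'   means older uncured patients die faster).
#'
#' With the logistic link `pi(x) = 1 / (1 + exp(-beta0 - beta x))`; with the
#' identity link `pi(x) = beta0 + beta x`, which must stay inside `[0, 1]`
#' wherever it is evaluated (an error is raised otherwise, never a clamp).
#' The `corrected_no_cure` variant drops the cured component (`pi == 0`)
#' while keeping `alpha` free.
#'
#' @param alpha Excess non-cancer mortality ratio (> 0).
#' @param pi60 Cure fraction at age 60 (alternative to `beta0`).
#' @param beta0 Intercept on the link scale.
#' @param beta Cure trend per 15 years of age.
#' @param lambda,gamma Weibull rate-scale and shape of uncured survival (> 0).
#' @param delta Age effect on uncured survival per 15 years.
#' @param link `"logistic"` or `"identity"`.
#' @param variant `"corrected"`, `"conventional"` (alpha fixed at 1) or
#'   `"corrected_no_cure"` (no cured fraction, alpha free).
#' @return An object of class `cure_params`.
#' @examples
#' cure_params(alpha = 1.2, pi60 = 0.7, beta = -0.15, lambda = 0.1, gamma = 1.1)
#' @export
cure_params <- function(alpha = 1, pi60 = NULL, beta0 = NULL, beta = 0,
                        lambda, gamma, delta = 0,
                        link = c("logistic", "identity"),
                        variant = c("corrected", "conventional",
                                    "corrected_no_cure")) {
  link <- match.arg(link)
  variant <- match.arg(variant)
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha), alpha > 0,
            is.numeric(lambda), lambda > 0, is.numeric(gamma), gamma > 0,
            is.numeric(beta), is.finite(beta),
            is.numeric(delta), is.finite(delta))
  if (variant == "conventional" && alpha != 1)
    stop("the conventional variant fixes alpha = 1")
  if (variant == "corrected_no_cure") {
    beta0 <- -Inf; pi60 <- 0; beta <- 0
  } else {
    if (is.null(beta0) && is.null(pi60))
      stop("supply `pi60` or `beta0`")
    if (!is.null(beta0) && !is.null(pi60))
      stop("supply only one of `pi60` and `beta0`")
    if (is.null(beta0)) {
      if (link == "logistic") {
        if (pi60 <= 0 || pi60 >= 1) stop("pi60 must lie in (0, 1)")
        beta0 <- stats::qlogis(pi60)
      } else beta0 <- pi60
    }
    pi60 <- if (link == "logistic") stats::plogis(beta0) else beta0
    if (link == "identity" && (pi60 < 0 || pi60 > 1))
      stop("identity link: pi at x = 0 outside [0, 1]")
  }
  structure(list(alpha = alpha, beta0 = beta0, beta = beta, pi60 = pi60,
                 lambda = lambda, gamma = gamma, delta = delta,
                 link = link, variant = variant),
            class = "cure_params")
}

#' @export
print.cure_params <- function(x, ...) {
  cat(sprintf("Cure model parameters (%s variant, %s link)\n", x$variant, x$link))
  cat(sprintf("  alpha = %.4g  pi60 = %.4g  beta = %.4g\n",
              x$alpha, x$pi60, x$beta))
  cat(sprintf("  lambda = %.4g  gamma = %.4g  delta = %.4g\n",
              x$lambda, x$gamma, x$delta))
  invisible(x)
}

#' Serialize / deserialize cure model parameters
#'
#' Writes a `cure_params` object to (or reads one from) a flat JSON
#' key-value file, with explicit `link` and `variant` fields.
#'
#' @param params A `cure_params` object.
#' @param file Path to a JSON file.
#' @return `read_cure_params` returns a `cure_params` object;
#'   `write_cure_params` invisibly returns `file`.
#' @export
write_cure_params <- function(params, file) {
  stopifnot(inherits(params, "cure_params"))
  x <- unclass(params)
  x$pi60 <- NULL
  if (x$variant == "corrected_no_cure") x$beta0 <- NULL
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_cure_params
#' @export
read_cure_params <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  cure_params(alpha = x$alpha, beta0 = x$beta0, beta = x$beta,
              lambda = x$lambda, gamma = x$gamma, delta = x$delta,
              link = x$link, variant = x$variant)
}
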