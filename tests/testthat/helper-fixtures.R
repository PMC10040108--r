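# Shared fixtures: built in code, no files.

POP <- pop_weibull()  # scale 88, shape 11

BREAST <- cure_params(alpha = 1.2, pi60 = 0.7, beta = -0.15,
                      lambda = 0.1, gamma = 1.1, delta = 0)
LUNG <- cure_params(alpha = 2, pi60 = 0.1, beta = -0.75,
                    lambda = 0.9, gamma = 0.8, delta = -0.3)

# a population with zero mortality: expected survival identically 1
POP_NULL <- pop_lifetable(0:120, hazard = rep(0, 121))

# tiny hand-checkable cohort: deaths at 0.5 and 2.5, censored at 1.5
toy_cohort <- function() data.frame(age = c(60, 60, 60),
                                    time = c(0.5, 1.5, 2.5),
                                    event = c(1, 0, 1))

# one-sided Kolmogorov distance between sampled times and a survival function
ks_distance <- function(times, surv_fun) {
  times <- sort(times)
  n <- length(times)
  emp_hi <- 1 - (seq_len(n) - 1) / n   # empirical S just before each point
  emp_lo <- 1 - seq_len(n) / n         # empirical S at each point
  s <- surv_fun(times)
  max(abs(s - emp_hi), abs(s - emp_lo))
}
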