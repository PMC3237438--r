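# Independent oracles, kept free of the package's own fitting code paths.

# OLS by the normal equations (not stats::lm)
ols_oracle <- function(x, y, intercept = TRUE) {
  if (intercept) {
    s <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - s * mean(x)
  } else {
    s <- sum(x * y) / sum(x^2)
    a <- 0
  }
  yhat <- a + s * x
  list(slope = s, intercept = a,
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

# erf by adaptive quadrature of the Gaussian integrand
erf_quadrature <- function(x) {
  vapply(x, function(xx)
    stats::integrate(function(u) 2 / sqrt(pi) * exp(-u^2), 0, xx,
                     rel.tol = 1e-10)$value, 0)
}

# a random but valid model configuration for property-style tests
random_truth <- function() {
  growth <- growth_params(mu = runif(1, 22, 30),
                          sigma_sqrt2 = runif(1, 5, 10),
                          c = runif(1, 0, 0.3),
                          k = runif(1, 0, 8),
                          x_i = runif(1, 0, 0.3))
  t_i <- initiation_time(growth)
  list(growth = growth,
       A = runif(1, 2, 10), b = runif(1, 0.05, 1),
       phases = list(N = phase_params("N", runif(1, 50, 400),
                                      runif(1, 2, 25))),
       times = sort(t_i + runif(6, 0.2, 12)))
}
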