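## Independent numerical oracles, deliberately kept apart from the
## package's solver path.

## Normal probability mass on [a, b] by adaptive quadrature of the
## density (does not touch pnorm).
mass_quadrature <- function(a, b, mu, sigma) {
  stats::integrate(stats::dnorm, a, b, mean = mu, sd = sigma,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

## Fixed-step classical Runge-Kutta integrator. `f` maps a state vector
## to its derivative vector; returns the state at t_end.
rk4_final <- function(f, s0, t_end, n_steps) {
  dt <- t_end / n_steps
  s <- s0
  for (i in seq_len(n_steps)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

## Model-1 self-antigen derivative written out directly from the rate
## equations, independent of the package's rhs functions.
oracle_rhs_self <- function(k2, km2, k3, k4, k6) {
  function(s) {
    x <- s[1]; y <- s[2]; z <- s[3]
    c(k2 * y * z - km2 * x - k3 * x,
      km2 * x - k2 * y * z + k4 * x - k6 * y,
      0)
  }
}

## Absolute-difference expectation for comparisons against truncated
## printed values (testthat's `tolerance` is relative for nonzero targets).
expect_within <- function(actual, expected, tol) {
  testthat::expect_lt(abs(unname(actual) - expected), tol)
}
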