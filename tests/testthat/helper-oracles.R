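# Independent oracles used across the suite. These re-derive quantities by
# brute force (long series sums, numerical quadrature, grid argmax) and
# never call the code paths they are used to check.

# direct summation of the Fickian cumulative-permeation series
fick_series_oracle <- function(Kp, CD, Tlag, t, n_terms = 1e4) {
  n <- seq_len(n_terms)
  s <- sum(((-1)^n / n^2) * exp(-n^2 * pi^2 * (t / Tlag) / 6))
  Kp * CD * (t - Tlag - (12 * Tlag / pi^2) * s)
}

# direct summation of the flux-fraction series
flux_fraction_oracle <- function(tau, n_terms = 1e4) {
  n <- seq_len(n_terms)
  1 + 2 * sum((-1)^n * exp(-n^2 * pi^2 * tau / 6))
}

# trapezoidal mean of a curve over a window
trapz_mean <- function(t, y) {
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) / (max(t) - min(t))
}

# cumulative trapezoid (for flux -> cumulative cross-checks)
cum_trapz <- function(t, y) {
  c(0, cumsum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
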