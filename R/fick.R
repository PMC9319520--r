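#' Fickian cumulative permeation under an infinite dose
#'
#' Series solution of Fick's second law for the cumulative amount of
#' permeant per unit area in the receptor chamber of a diffusion cell under
#' an infinite-dose (constant donor concentration) regimen, assuming the
#' skin behaves as a pseudo-homogeneous membrane under sink conditions:
#'
#' \deqn{Q_R(t) = K_p C_D \left[t - T_{lag} - \frac{12\,T_{lag}}{\pi^2}
#'   \sum_{n \ge 1} \frac{(-1)^n}{n^2}
#'   e^{-n^2\pi^2 t / (6 T_{lag})}\right]}
#'
#' The series is truncated at `n_terms` with an early exit once a term's
#' magnitude drops below 1e-15 of the partial sum. Tiny negative values
#' from roundoff are clamped to zero.
#'
#' @param dp a [diffusion_params()] object.
#' @param t time since application (h); vectorised, all values >= 0.
#' @param n_terms maximum number of series terms (>= 1), default 200.
#'
#' @return Cumulative amount per unit area (ug/cm^2), same length as `t`.
#' @examples
#' dp <- diffusion_params(Kp = 0.0046, CD = 50000, Tlag = 10)
#' fick_cumulative_infinite(dp, t = c(0, 10, 30))
#' @export
fick_cumulative_infinite <- function(dp, t, n_terms = 200L) {
  stopifnot(inherits(dp, "diffusion_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (n_terms < 1) stop("'n_terms' must be at least 1")
  if (dp$Tlag <= 0) stop("'Tlag' must be positive")
  tau <- t / dp$Tlag
  s <- numeric(length(t))
  for (n in seq_len(n_terms)) {
    term <- ((-1)^n / n^2) * exp(-n^2 * pi^2 * tau / 6)
    s <- s + term
    if (max(abs(term)) < 1e-15 * max(abs(s), 1e-300)) break
  }
  q <- dp$Kp * dp$CD * (t - dp$Tlag - (12 * dp$Tlag / pi^2) * s)
  pmax(q, 0)
}

#' Fractional approach of the Fickian flux to steady state
#'
#' Time-differentiating the Fickian cumulative-permeation series gives the
#' flux relative to its steady-state value as a function of time in units
#' of the lag time:
#'
#' \deqn{J(t)/J_{ss} = 1 + 2 \sum_{n \ge 1} (-1)^n
#'   e^{-n^2 \pi^2 (t/T_{lag}) / 6}}
#'
#' A classical rule of thumb follows: at \eqn{t = 2.7\,T_{lag}} the flux has
#' reached about 97.5% of its steady-state value.
#'
#' @param t_over_tlag time in units of the lag time (dimensionless, >= 0);
#'   vectorised.
#' @param n_terms maximum number of series terms, default 200.
#'
#' @return Fraction of the steady-state flux, in `[0, 1]`.
#' @examples
#' fick_flux_fraction(2.7)  # about 0.975
#' @export
fick_flux_fraction <- function(t_over_tlag, n_terms = 200L) {
  if (any(t_over_tlag < 0)) stop("'t_over_tlag' must be non-negative")
  if (n_terms < 1) stop("'n_terms' must be at least 1")
  s <- numeric(length(t_over_tlag))
  for (n in seq_len(n_terms)) {
    term <- (-1)^n * exp(-n^2 * pi^2 * t_over_tlag / 6)
    s <- s + term
    if (max(abs(term)) < 1e-15) break
  }
  f <- 1 + 2 * s
  # the alternating series only Abel-sums to 0 at t = 0; impose the physical value
  f[t_over_tlag == 0] <- 0
  pmin(pmax(f, 0), 1)
}
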