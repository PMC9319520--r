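#' @keywords internal
new_skin_profile <- function(times, QD, QM, QR, J, regimen, params) {
  out <- data.frame(time_h = times, QD = QD, QM = QM, QR = QR, J = J)
  structure(out, regimen = regimen, params = params,
            class = c("skin_profile", "data.frame"))
}

# effective time after the optional onset delay
.t_eff <- function(t, t0) pmax(t - t0, 0)

#' One-compartment skin profile under an infinite dose
#'
#' Evaluates the one-compartment membrane transport model for a constant
#' (zero-order) input rate `R0` per unit area and first-order output
#' constant `kout`:
#' amount in the membrane \eqn{Q_M = (R_0/k_{out})(1 - e^{-k_{out} t})},
#' cumulative amount in the receptor
#' \eqn{Q_R = R_0 t - Q_M}, and flux \eqn{J = k_{out} Q_M}.
#' An onset delay `t0` shifts the time axis: `t` is replaced by
#' `max(t - t0, 0)` throughout.
#'
#' @param sp a [skin_transport_params()] object with `regimen = "infinite"`.
#' @param times sampling times (h), all >= 0.
#'
#' @return A `skin_profile` data frame with columns `time_h`, `QD` (`NA`
#'   for this regimen), `QM`, `QR` (ug/cm^2) and `J` (ug/cm^2/h).
#' @examples
#' sp <- skin_transport_params(R0 = 229, kout = 0.10)
#' infinite_dose_profile(sp, times = c(3, 5, 7, 9, 24, 26, 28, 30))
#' @export
infinite_dose_profile <- function(sp, times) {
  stopifnot(inherits(sp, "skin_transport_params"))
  if (sp$regimen != "infinite") stop("'sp' must describe an infinite-dose regimen")
  if (sp$kout <= 0) stop("'kout' must be positive")
  if (any(times < 0)) stop("'times' must be non-negative")
  te <- .t_eff(times, sp$t0)
  QM <- (sp$R0 / sp$kout) * (1 - exp(-sp$kout * te))
  QR <- sp$R0 * te - QM
  J <- sp$kout * QM
  new_skin_profile(times, QD = NA_real_, QM = QM, QR = QR, J = J,
                   regimen = "infinite", params = sp)
}

# membrane amount per unit dose for the finite-dose model, with the
# analytic limit when kin and kout coincide (relative gap < 1e-8)
.finite_qm_frac <- function(kin, kout, t) {
  if (abs(kin - kout) < 1e-8 * kout) {
    kin * t * exp(-kin * t)
  } else {
    (kin / (kin - kout)) * (exp(-kout * t) - exp(-kin * t))
  }
}

#' One-compartment skin profile under a finite dose
#'
#' Evaluates the one-compartment membrane transport model when the donor
#' depletes with first-order rate constant `kin` from an applied dose `Q0`
#' (per-area form `Q0/S`), and the membrane empties into the receptor with
#' first-order constant `kout`:
#' \eqn{Q_D = (Q_0/S) e^{-k_{in} t}},
#' \eqn{Q_M = \frac{k_{in} Q_0/S}{k_{in}-k_{out}} (e^{-k_{out} t} -
#' e^{-k_{in} t})}, \eqn{Q_R = Q_0/S - Q_D - Q_M}, \eqn{J = k_{out} Q_M}.
#' When `kin` and `kout` coincide (relative difference below 1e-8) the
#' confluent limit \eqn{Q_M = k (Q_0/S)\, t\, e^{-k t}} is used.
#'
#' @param sp a [skin_transport_params()] object with `regimen = "finite"`.
#' @param times sampling times (h), all >= 0.
#'
#' @return A `skin_profile` data frame with per-area columns `QD`, `QM`,
#'   `QR` (ug/cm^2) and `J` (ug/cm^2/h); `QD + QM + QR = Q0/S` at every time.
#' @examples
#' sp <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 100)
#' finite_dose_profile(sp, times = c(0, 12, 54))
#' @export
finite_dose_profile <- function(sp, times) {
  stopifnot(inherits(sp, "skin_transport_params"))
  if (sp$regimen != "finite") stop("'sp' must describe a finite-dose regimen")
  if (is.null(sp$kin) || is.null(sp$Q0)) stop("'kin' and 'Q0' must be set")
  if (sp$kin <= 0 || sp$kout <= 0) stop("rate constants must be positive")
  if (any(times < 0)) stop("'times' must be non-negative")
  te <- .t_eff(times, sp$t0)
  q0a <- sp$Q0 / sp$S
  QD <- q0a * exp(-sp$kin * te)
  QM <- q0a * .finite_qm_frac(sp$kin, sp$kout, te)
  QR <- q0a - QD - QM
  J <- sp$kout * QM
  new_skin_profile(times, QD = QD, QM = QM, QR = QR, J = J,
                   regimen = "finite", params = sp)
}

#' Time and magnitude of the peak finite-dose flux
#'
#' Under the finite-dose regimen the flux rises to a single maximum and
#' then decays. Setting the derivative of the flux to zero gives
#' \deqn{T_{Jmax} = \frac{\ln(k_{out}/k_{in})}{k_{out} - k_{in}}}
#' with the confluent limit \eqn{1/k} when the two constants are equal.
#' The expression is symmetric under exchange of `kin` and `kout`. The peak
#' flux is the finite-dose flux evaluated at that time.
#'
#' @param sp a [skin_transport_params()] object with `regimen = "finite"`,
#'   both rate constants positive.
#'
#' @return A list with elements `TJmax` (h) and `Jmax` (ug/cm^2/h).
#' @examples
#' sp <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 100)
#' peak_flux(sp)
#' @export
peak_flux <- function(sp) {
  stopifnot(inherits(sp, "skin_transport_params"))
  if (sp$regimen != "finite") stop("'sp' must describe a finite-dose regimen")
  if (sp$kin <= 0 || sp$kout <= 0) stop("rate constants must be positive")
  TJmax <- if (abs(sp$kin - sp$kout) < 1e-8 * sp$kout) {
    1 / sp$kout
  } else {
    log(sp$kout / sp$kin) / (sp$kout - sp$kin)
  }
  Jmax <- finite_dose_profile(sp, TJmax + sp$t0)$J
  list(TJmax = TJmax, Jmax = Jmax)
}

#' Time for the infinite-dose flux to reach a given fraction of steady state
#'
#' Inverting the one-compartment infinite-dose flux
#' \eqn{J = R_0 (1 - e^{-k_{out} t})} gives
#' \eqn{t = -\ln(1 - f) / k_{out}}. For `f = 0.975` the multiplier of
#' `1/kout` is 3.689, i.e. the flux reaches 97.5% of steady state after
#' about 3.7 times the `1/kout` value -- the compartmental analogue of the
#' 2.7-lag-time rule of the Fickian description.
#'
#' @param fraction target fraction of the steady-state flux, in `[0, 1)`.
#' @param kout output rate constant (1/h), positive.
#'
#' @return Time (h) to reach the target fraction.
#' @examples
#' time_to_flux_fraction(0.975, kout = 0.10)
#' @export
time_to_flux_fraction <- function(fraction, kout) {
  if (any(fraction < 0 | fraction >= 1))
    stop("'fraction' must lie in [0, 1)")
  if (kout <= 0) stop("'kout' must be positive")
  -log(1 - fraction) / kout
}

#' Permeability coefficient and predicted steady-state plasma concentration
#'
#' The steady-state flux divided by the donor concentration gives the
#' permeability coefficient, \eqn{K_p = J_{ss} / C_D}; under the
#' one-compartment transport model the fitted zero-order rate `R0` plays
#' the role of `Jss`. If the exposed area `S` and the plasma clearance `CL`
#' are supplied, the steady-state plasma concentration
#' \eqn{C_{ss} = J_{ss} S / CL} is also returned, in both ug/mL and ng/mL.
#'
#' @param Jss steady-state flux, or the fitted zero-order input rate `R0`
#'   (ug/cm^2/h).
#' @param CD donor concentration (ug/mL), positive.
#' @param S exposed area (cm^2), optional (required for `Css`).
#' @param CL plasma clearance (mL/h), optional (required for `Css`).
#'
#' @return A list with `Kp` (cm/h) and, when `S` and `CL` are given,
#'   `Css_ug_mL` and `Css_ng_mL`.
#' @examples
#' steady_state_metrics(Jss = 229, CD = 50000, S = 1.45, CL = 1580)
#' @export
steady_state_metrics <- function(Jss, CD, S = NULL, CL = NULL) {
  if (Jss < 0) stop("'Jss' must be non-negative")
  if (!is.numeric(CD) || CD <= 0) stop("'CD' must be positive")
  out <- list(Kp = Jss / CD)
  if (!is.null(S) || !is.null(CL)) {
    if (is.null(S) || is.null(CL)) stop("'S' and 'CL' must be supplied together")
    if (S <= 0) stop("'S' must be positive")
    if (CL <= 0) stop("'CL' must be positive")
    css <- Jss * S / CL
    out$Css_ug_mL <- css
    out$Css_ng_mL <- css * 1000
  }
  out
}

#' Fraction of the applied dose remaining in the skin
#'
#' Evaluates the finite-dose membrane amount relative to the applied dose,
#' \eqn{Q_M(t)/Q_0}, used to predict how much drug is still held in the
#' skin at the end of a transdermal administration.
#'
#' @param kin first-order input rate constant (1/h), positive.
#' @param kout first-order output rate constant (1/h), positive.
#' @param t time since application (h), >= 0; vectorised.
#'
#' @return Fraction of the dose in the skin at `t` (dimensionless).
#' @examples
#' skin_residual_fraction(kin = 0.065, kout = 0.10, t = 54)  # about 0.047
#' @export
skin_residual_fraction <- function(kin, kout, t) {
  if (kin <= 0 || kout <= 0) stop("rate constants must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  .finite_qm_frac(kin, kout, t)
}

#' @export
print.skin_profile <- function(x, ...) {
  cat(sprintf("Skin transport profile (%s dose), %d time points\n",
              attr(x, "regimen"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
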