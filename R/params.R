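#' Fickian membrane diffusion parameters
#'
#' Bundles the parameters of the membrane-diffusion description of skin
#' permeation: the permeability coefficient `Kp`, the donor concentration
#' `CD` and the lag time `Tlag`. The underlying physical constants --
#' partition coefficient `K`, diffusion coefficient `D` and membrane
#' thickness `h` -- are optional; when all three are supplied they must be
#' consistent with `Kp = K * D / h` and `Tlag = h^2 / (6 * D)`.
#'
#' @param Kp permeability coefficient (cm/h), must be positive.
#' @param CD donor (vehicle) concentration (ug/mL), non-negative.
#' @param Tlag lag time (h), must be positive.
#' @param K membrane/vehicle partition coefficient (dimensionless), optional.
#' @param D diffusion coefficient (cm^2/h), optional.
#' @param h membrane thickness (cm), optional.
#'
#' @return An object of class `diffusion_params`.
#' @examples
#' dp <- diffusion_params(Kp = 0.0046, CD = 50000, Tlag = 10)
#' @export
diffusion_params <- function(Kp, CD, Tlag, K = NULL, D = NULL, h = NULL) {
  stopifnot(is.numeric(Kp), length(Kp) == 1L,
            is.numeric(CD), length(CD) == 1L,
            is.numeric(Tlag), length(Tlag) == 1L)
  if (!is.finite(Kp) || Kp <= 0) stop("'Kp' must be a positive, finite number")
  if (!is.finite(CD) || CD < 0) stop("'CD' must be non-negative and finite")
  if (!is.finite(Tlag) || Tlag <= 0) stop("'Tlag' must be a positive, finite number")
  if (!is.null(K) && !is.null(D) && !is.null(h)) {
    if (any(c(K, D, h) <= 0)) stop("'K', 'D' and 'h' must all be positive")
    # consistency of the reduced parameters with the physical constants
    if (abs(Kp - K * D / h) > 1e-9 * Kp)
      stop("inconsistent parameters: Kp must equal K * D / h")
    if (abs(Tlag - h^2 / (6 * D)) > 1e-9 * Tlag)
      stop("inconsistent parameters: Tlag must equal h^2 / (6 * D)")
  }
  structure(list(Kp = Kp, CD = CD, Tlag = Tlag, K = K, D = D, h = h),
            class = "diffusion_params")
}

#' One-compartment skin transport parameters
#'
#' Parameters of the one-compartment description of permeant transport
#' across skin. Under an *infinite dose* regimen the permeant enters the
#' membrane at a constant (zero-order) rate per unit area `R0` and leaves it
#' with first-order rate constant `kout`. Under a *finite dose* regimen the
#' donor depletes with first-order input constant `kin` from an applied dose
#' `Q0`, with the same output constant `kout`. Exactly one of `R0` or the
#' pair (`kin`, `Q0`) must be supplied; this selects the regimen.
#'
#' @param R0 zero-order input rate per unit area (ug/cm^2/h); infinite dose.
#' @param kin first-order input rate constant (1/h); finite dose.
#' @param kout first-order output rate constant (1/h); both regimens.
#' @param Q0 applied dose (ug); finite dose. Per-area quantities use `Q0/S`.
#' @param CD donor concentration (ug/mL), optional; used to derive the
#'   permeability coefficient `Kp = R0 / CD`.
#' @param S exposed skin area (cm^2), default 1.
#' @param t0 onset delay (h) before any permeant crosses, default 0.
#'
#' @return An object of class `skin_transport_params` with a `regimen`
#'   element equal to `"infinite"` or `"finite"`.
#' @examples
#' sp_inf <- skin_transport_params(R0 = 229, kout = 0.10, CD = 50000, S = 1.45)
#' sp_fin <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 20000, S = 1.39)
#' @export
skin_transport_params <- function(R0 = NULL, kin = NULL, kout, Q0 = NULL,
                                  CD = NULL, S = 1, t0 = 0) {
  has_inf <- !is.null(R0)
  has_fin <- !is.null(kin) || !is.null(Q0)
  if (has_inf && has_fin)
    stop("supply either 'R0' (infinite dose) or 'kin' and 'Q0' (finite dose), not both")
  if (!has_inf && !(!is.null(kin) && !is.null(Q0)))
    stop("finite-dose regimen requires both 'kin' and 'Q0'")
  if (!is.numeric(kout) || length(kout) != 1L || !is.finite(kout) || kout < 0)
    stop("'kout' must be a non-negative, finite number")
  if (!is.numeric(S) || length(S) != 1L || S <= 0) stop("'S' must be positive")
  if (!is.numeric(t0) || length(t0) != 1L || t0 < 0) stop("'t0' must be non-negative")
  if (has_inf) {
    if (!is.finite(R0) || R0 < 0) stop("'R0' must be non-negative and finite")
    regimen <- "infinite"
  } else {
    if (!is.finite(kin) || kin < 0) stop("'kin' must be non-negative and finite")
    if (!is.finite(Q0) || Q0 < 0) stop("'Q0' must be non-negative and finite")
    regimen <- "finite"
  }
  if (!is.null(CD) && (!is.numeric(CD) || CD < 0)) stop("'CD' must be non-negative")
  structure(list(R0 = R0, kin = kin, kout = kout, Q0 = Q0, CD = CD, S = S,
                 t0 = t0, regimen = regimen),
            class = "skin_transport_params")
}

#' Two-compartment disposition parameters
#'
#' Macro-parameters of the two-compartment intravenous disposition model:
#' total plasma clearance `CL`, central volume `V1`, total volume of
#' distribution `VT` (`V1 + V2`) and intercompartmental clearance `CLic`.
#'
#' @param CL total plasma clearance (mL/h).
#' @param V1 central compartment volume (mL).
#' @param VT total volume of distribution (mL); must exceed `V1` unless
#'   `CLic = 0`, in which case `VT = V1` is allowed.
#' @param CLic intercompartmental clearance (mL/h), non-negative.
#'
#' @return An object of class `pk_params`.
#' @examples
#' pk <- pk_params(CL = 1580, V1 = 488, VT = 1568, CLic = 3340)
#' @export
pk_params <- function(CL, V1, VT, CLic) {
  vals <- c(CL = CL, V1 = V1, VT = VT, CLic = CLic)
  if (any(!is.finite(vals))) stop("all disposition parameters must be finite")
  if (CL <= 0 || V1 <= 0 || VT <= 0) stop("'CL', 'V1' and 'VT' must be positive")
  if (CLic < 0) stop("'CLic' must be non-negative")
  if (CLic > 0 && VT <= V1)
    stop("'VT' must exceed 'V1' when an intercompartmental clearance is present")
  if (VT < V1) stop("'VT' cannot be smaller than 'V1'")
  structure(list(CL = CL, V1 = V1, VT = VT, CLic = CLic), class = "pk_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Membrane diffusion parameters\n")
  cat(sprintf("  Kp   = %g cm/h\n  CD   = %g ug/mL\n  Tlag = %g h\n",
              x$Kp, x$CD, x$Tlag))
  invisible(x)
}

#' @export
print.skin_transport_params <- function(x, ...) {
  cat(sprintf("Skin transport parameters (%s dose)\n", x$regimen))
  if (x$regimen == "infinite") {
    cat(sprintf("  R0   = %g ug/cm^2/h\n", x$R0))
  } else {
    cat(sprintf("  kin  = %g 1/h\n  Q0   = %g ug\n", x$kin, x$Q0))
  }
  cat(sprintf("  kout = %g 1/h\n  S    = %g cm^2\n  t0   = %g h\n",
              x$kout, x$S, x$t0))
  invisible(x)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment disposition parameters\n")
  cat(sprintf("  CL   = %g mL/h\n  V1   = %g mL\n  VT   = %g mL\n  CLic = %g mL/h\n",
              x$CL, x$V1, x$VT, x$CLic))
  invisible(x)
}
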