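#' @keywords internal
new_fit_result <- function(estimates, std_errors, residuals, objective,
                           converged, n_obs, message = "", alternate = NULL) {
  structure(list(estimates = estimates, std_errors = std_errors,
                 residuals = residuals, objective = objective,
                 converged = converged, n_obs = n_obs, message = message,
                 alternate = alternate),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Nonlinear least-squares fit (%s), n = %d, SSQ = %g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_obs, x$objective))
  tab <- data.frame(estimate = x$estimates,
                    std_error = x$std_errors[names(x$estimates)])
  print(tab)
  if (!is.null(x$alternate))
    cat("Alternate labelling (flip-flop):",
        paste(sprintf("%s = %g", names(x$alternate), x$alternate), collapse = ", "),
        "\n")
  if (nzchar(x$message)) cat("Note:", x$message, "\n")
  invisible(x)
}

#' Serialise a fit result as key-value text
#'
#' @param x a `fit_result`.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_fit_result <- function(x, path) {
  stopifnot(inherits(x, "fit_result"))
  lines <- c("schema: skinpk-fit/1",
             sprintf("converged: %s", tolower(as.character(x$converged))),
             sprintf("n_obs: %d", x$n_obs),
             sprintf("objective: %.10g", x$objective),
             sprintf("estimate.%s: %.10g", names(x$estimates), x$estimates),
             sprintf("std_error.%s: %.10g", names(x$std_errors), x$std_errors))
  writeLines(lines, path)
  invisible(x)
}

# Gauss-Newton standard errors: residual-variance-scaled inverse of J'J,
# with the Jacobian of the residuals taken numerically at the optimum
# (central differences on the natural parameter scale).
.gn_std_errors <- function(resid_fun, par) {
  n <- length(resid_fun(par))
  p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    hj <- max(abs(par[j]), 1e-8) * 1e-6
    up <- dn <- par
    up[j] <- par[j] + hj
    dn[j] <- par[j] - hj
    J[, j] <- (resid_fun(up) - resid_fun(dn)) / (2 * hj)
  }
  r <- resid_fun(par)
  s2 <- sum(r^2) / (n - p)
  info <- crossprod(J)
  se <- tryCatch(sqrt(diag(s2 * solve(info))), error = function(e) rep(NA_real_, p))
  names(se) <- names(par)
  se
}

# shared Levenberg-Marquardt driver: parameters handled on the log scale
# for positivity, standard errors reported on the natural scale
.lm_fit <- function(resid_nat, start_nat, extra_nat = numeric(0)) {
  p_names <- c(names(start_nat), names(extra_nat))
  to_nat <- function(lp) c(exp(lp[seq_along(start_nat)]),
                           lp[-seq_along(start_nat)][seq_along(extra_nat)])
  rf_log <- function(lp) {
    par <- to_nat(lp)
    names(par) <- p_names
    resid_nat(par)
  }
  lp0 <- c(log(start_nat), extra_nat)
  fit <- minpack.lm::nls.lm(
    par = lp0, fn = rf_log,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 200, maxfev = 10000))
  est <- to_nat(fit$par)
  names(est) <- p_names
  rf_nat <- function(par) { names(par) <- p_names; resid_nat(par) }
  se <- .gn_std_errors(rf_nat, est)
  r <- rf_nat(est)
  converged <- fit$info %in% 1:4
  list(estimates = est, std_errors = se, residuals = r,
       objective = sum(r^2), converged = converged,
       message = fit$message)
}

#' Convert receptor-chamber concentrations to cumulative permeated amounts
#'
#' In a Franz diffusion cell a sample volume is withdrawn from the receptor
#' chamber at each time and replaced with fresh medium, diluting the
#' chamber. The cumulative amount of permeant per unit skin area that has
#' crossed the membrane by the n-th sample is reconstructed from the
#' measured concentrations as
#' \deqn{Q_n = (C_n V_R + \sum_{i<n} C_i V_s) / A}
#' where `V_R` is the receptor volume, `V_s` the withdrawn sample volume
#' and `A` the exposed area.
#'
#' @param series a [time_series()] of kind `"receptor_concentration"`
#'   (ug/mL).
#' @param receptor_volume receptor chamber volume (mL).
#' @param sample_volume withdrawn sample volume (mL), smaller than
#'   `receptor_volume`.
#' @param area exposed skin area (cm^2), positive.
#'
#' @return A `time_series` of kind `"cumulative_per_area"` (ug/cm^2).
#' @examples
#' ts <- time_series(c(3, 5, 7), c(1, 1, 1), kind = "receptor_concentration")
#' receptor_concentrations_to_QR(ts, receptor_volume = 9,
#'                               sample_volume = 0.2, area = 1.45)
#' @export
receptor_concentrations_to_QR <- function(series, receptor_volume,
                                          sample_volume, area) {
  stopifnot(inherits(series, "time_series"))
  if (attr(series, "kind") != "receptor_concentration")
    stop("'series' must have kind 'receptor_concentration'")
  if (sample_volume >= receptor_volume)
    stop("'sample_volume' must be smaller than 'receptor_volume'")
  if (sample_volume < 0) stop("'sample_volume' must be non-negative")
  if (area <= 0) stop("'area' must be positive")
  df <- as.data.frame(series)
  out <- lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_h), ]
    carried <- cumsum(c(0, d$value[-nrow(d)])) * sample_volume
    d$value <- (d$value * receptor_volume + carried) / area
    d
  })
  out <- do.call(rbind, out)
  out <- out[order(out$replicate, out$time_h), ]
  time_series(out$time_h, out$value, kind = "cumulative_per_area",
              replicate = out$replicate)
}

# model curves used by the fitters -------------------------------------------

.qr_infinite <- function(t, R0, kout, t0 = 0) {
  te <- pmax(t - t0, 0)
  R0 * te - (R0 / kout) * (1 - exp(-kout * te))
}

.qr_finite <- function(t, kin, kout, Q0) {
  Q0 * (1 - exp(-kin * t) - .finite_qm_frac(kin, kout, t))
}

.flux_finite <- function(t, kin, kout, Q0) {
  kout * Q0 * .finite_qm_frac(kin, kout, t)
}

# pseudo-steady-state line through the last third of the points: the slope
# estimates R0 and the t-axis intercept estimates 1/kout
.init_infinite <- function(t, q) {
  ut <- sort(unique(t))
  keep <- t >= ut[max(1L, ceiling(2 * length(ut) / 3))]
  if (sum(keep) < 2) keep <- rep(TRUE, length(t))
  line <- stats::lm(q[keep] ~ t[keep])
  slope <- unname(stats::coef(line)[2])
  icpt <- unname(stats::coef(line)[1])
  R0 <- if (is.finite(slope) && slope > 0) slope else max(q) / max(t)
  kout <- if (is.finite(icpt) && icpt < 0) R0 / (-icpt) else 10 / max(t)
  c(R0 = R0, kout = kout)
}

#' Fit the infinite-dose one-compartment model to cumulative permeation data
#'
#' Estimates the zero-order input rate `R0` and the output rate constant
#' `kout` of the one-compartment skin transport model by unweighted
#' nonlinear least squares on cumulative receptor amounts,
#' \eqn{Q_R(t) = R_0 t - (R_0/k_{out})(1 - e^{-k_{out} t})}.
#' Starting values come from the pseudo-steady-state line through the last
#' third of the sampling times (slope `R0`, t-axis intercept `1/kout`).
#' Standard errors are the residual-variance-scaled Gauss-Newton values.
#'
#' @param data a [time_series()] of kind `"cumulative_per_area"`; multiple
#'   replicates are stacked into one objective.
#' @param fit_t0 also estimate an onset delay `t0` (h)? Default `FALSE`.
#' @param weighting `"none"` (additive error, default) or `"proportional"`
#'   (residuals divided by the model value).
#'
#' @return A `fit_result` with estimates `R0`, `kout` (and `t0` if
#'   requested).
#' @examples
#' sp <- skin_transport_params(R0 = 229, kout = 0.10)
#' prof <- infinite_dose_profile(sp, c(3, 5, 7, 9, 24, 26, 28, 30))
#' ts <- time_series(prof$time_h, prof$QR, kind = "cumulative_per_area")
#' fit_infinite_dose(ts)
#' @export
fit_infinite_dose <- function(data, fit_t0 = FALSE,
                              weighting = c("none", "proportional")) {
  stopifnot(inherits(data, "time_series"))
  weighting <- match.arg(weighting)
  if (attr(data, "kind") != "cumulative_per_area")
    stop("'data' must have kind 'cumulative_per_area'")
  t <- data$time_h; q <- data$value
  n_par <- 2L + as.integer(fit_t0)
  if (length(unique(t)) < max(3L, n_par + as.integer(fit_t0)))
    stop("need at least ", max(3L, n_par + as.integer(fit_t0)),
         " distinct time points")
  start <- .init_infinite(t, q)
  resid_nat <- function(par) {
    pred <- .qr_infinite(t, par[["R0"]], par[["kout"]],
                         if (fit_t0) par[["t0"]] else 0)
    r <- q - pred
    if (weighting == "proportional") r <- r / pmax(abs(pred), 1e-12)
    r
  }
  extra <- if (fit_t0) c(t0 = 0) else numeric(0)
  fit <- .lm_fit(resid_nat, start, extra)
  new_fit_result(fit$estimates, fit$std_errors, fit$residuals,
                 fit$objective, fit$converged, length(t), fit$message)
}

#' Fit the finite-dose one-compartment model
#'
#' Estimates `kin` and `kout` from finite-dose data: either cumulative
#' receptor amounts (fitting the finite-dose cumulative curve) or flux
#' measurements (fitting the finite-dose flux curve). Both curves are
#' symmetric under exchange of `kin` and `kout` (flip-flop ambiguity), so
#' the result reports the labelling with `kin < kout` as primary and the
#' swapped labelling -- with an identical objective -- in `$alternate`.
#' This labelling convention is deterministic bookkeeping, not a physical
#' claim.
#'
#' @param data a [time_series()] of kind `"cumulative_per_area"` or
#'   `"flux"` (per-area units).
#' @param Q0 applied dose per unit area (ug/cm^2), positive.
#'
#' @return A `fit_result` with estimates `kin`, `kout` and an `alternate`
#'   labelling. Fits whose rate constants diverge (instantaneous-transfer
#'   data) are reported with `converged = FALSE`.
#' @examples
#' sp <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 100)
#' prof <- finite_dose_profile(sp, c(2, 4, 8, 16, 24, 36, 48))
#' ts <- time_series(prof$time_h, prof$QR, kind = "cumulative_per_area")
#' fit_finite_dose(ts, Q0 = 100)
#' @export
fit_finite_dose <- function(data, Q0) {
  stopifnot(inherits(data, "time_series"))
  kind <- attr(data, "kind")
  if (!kind %in% c("cumulative_per_area", "flux"))
    stop("'data' must have kind 'cumulative_per_area' or 'flux'")
  if (Q0 <= 0) stop("'Q0' must be positive")
  t <- data$time_h; y <- data$value
  if (length(unique(t)) < 3L) stop("need at least 3 distinct time points")
  model <- if (kind == "cumulative_per_area") .qr_finite else .flux_finite
  # initial values: kin from the residual-dose relation at the last time,
  # kout from the infinite-dose pseudo-steady-state heuristic
  frac_left <- if (kind == "cumulative_per_area") {
    max(1 - max(y) / Q0, 1e-6)
  } else 0.05
  kin0 <- -log(frac_left) / max(t)
  kout0 <- if (kind == "cumulative_per_area") {
    unname(.init_infinite(t, y)["kout"])
  } else 2 * kin0
  if (!is.finite(kout0) || kout0 <= 0) kout0 <- 2 * kin0
  if (abs(kin0 - kout0) < 0.1 * kout0) kout0 <- 2 * kin0  # break symmetry
  resid_nat <- function(par) y - model(t, par[["kin"]], par[["kout"]], Q0)
  fit <- .lm_fit(resid_nat, c(kin = kin0, kout = kout0))
  est <- fit$estimates; se <- fit$std_errors
  # primary labelling: kin < kout (curves are exchange-symmetric)
  if (est[["kin"]] > est[["kout"]]) {
    est <- c(kin = unname(est[["kout"]]), kout = unname(est[["kin"]]))
    se <- c(kin = unname(se[["kout"]]), kout = unname(se[["kin"]]))
  }
  alternate <- c(kin = unname(est[["kout"]]), kout = unname(est[["kin"]]))
  converged <- fit$converged
  msg <- fit$message
  # rate constants far above the sampling resolution mean the data carry no
  # information about the transfer (instantaneous-transfer degeneracy)
  dt_min <- min(diff(sort(unique(t))))
  if (any(est > 100 / dt_min)) {
    converged <- FALSE
    msg <- "rate constants diverged: transfer is effectively instantaneous on this schedule"
  }
  new_fit_result(est, se, fit$residuals, fit$objective, converged,
                 length(t), msg, alternate = alternate)
}

#' Input rate constant from the residual dose fraction
#'
#' Under first-order donor depletion the fraction of the applied dose still
#' in the vehicle at time `t` is \eqn{e^{-k_{in} t}}; measuring that
#' residual fraction therefore gives \eqn{k_{in} = -\ln(f)/t}. This is how
#' an in vivo `kin` is estimated from the drug recovered from the
#' formulation at the end of an experiment.
#'
#' @param fraction_remaining fraction of the dose remaining, in (0, 1).
#' @param t elapsed time (h), positive.
#'
#' @return First-order input rate constant `kin` (1/h).
#' @examples
#' kin_from_residual_fraction(0.03, 54)  # about 0.065 1/h
#' @export
kin_from_residual_fraction <- function(fraction_remaining, t) {
  if (any(fraction_remaining <= 0 | fraction_remaining >= 1))
    stop("'fraction_remaining' must lie strictly between 0 and 1")
  if (any(t <= 0)) stop("'t' must be positive")
  -log(fraction_remaining) / t
}

#' Non-compartmental AUC of a plasma concentration profile
#'
#' Linear trapezoidal area under the concentration-time curve over the
#' observed range, optionally extrapolated to infinity by log-linear
#' regression of the last `n_tail` positive concentrations (terminal slope
#' `lambda_z`; tail area `C_last / lambda_z`).
#'
#' @param conc a [time_series()] of kind `"plasma_concentration"` with a
#'   single replicate (average replicates first with [mean_time_series()]).
#' @param extrapolate add the extrapolated tail? Default `TRUE`.
#' @param n_tail number of terminal points for the log-linear regression
#'   (>= 2), default 3.
#'
#' @return A list with `auc` (ng*h/mL, extrapolated when requested),
#'   `auc_observed`, `lambda_z` (1/h, `NA` if not estimated) and
#'   `extrapolated` (logical; `FALSE` with a warning when the terminal
#'   concentrations do not allow extrapolation).
#' @examples
#' ts <- time_series(c(0, 1, 2, 4, 8), 100 * exp(-0.3 * c(0, 1, 2, 4, 8)),
#'                   kind = "plasma_concentration")
#' nca_auc(ts)
#' @export
nca_auc <- function(conc, extrapolate = TRUE, n_tail = 3L) {
  stopifnot(inherits(conc, "time_series"))
  if (attr(conc, "kind") != "plasma_concentration")
    stop("'conc' must have kind 'plasma_concentration'")
  if (length(unique(conc$replicate)) > 1L)
    stop("'conc' must hold a single replicate; see mean_time_series()")
  t <- conc$time_h; c_ <- conc$value
  if (length(t) < 2L) stop("need at least 2 points")
  auc_obs <- sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
  lambda_z <- NA_real_
  auc <- auc_obs
  did_extrap <- FALSE
  if (extrapolate) {
    if (n_tail < 2L) stop("'n_tail' must be at least 2")
    tail_idx <- utils::tail(seq_along(t), n_tail)
    if (any(c_[tail_idx] <= 0)) {
      warning("non-positive terminal concentrations: returning observed-range AUC")
    } else {
      sl <- stats::coef(stats::lm(log(c_[tail_idx]) ~ t[tail_idx]))[2]
      if (is.finite(sl) && sl < 0) {
        lambda_z <- unname(-sl)
        auc <- auc_obs + c_[length(c_)] / lambda_z
        did_extrap <- TRUE
      } else {
        warning("terminal phase is not declining: returning observed-range AUC")
      }
    }
  }
  list(auc = auc, auc_observed = auc_obs, lambda_z = lambda_z,
       extrapolated = did_extrap)
}

#' Apparent clearance from dose and AUC
#'
#' \eqn{CL_{app} = \mathrm{dose} / AUC_\infty} for an extravascular
#' administration, with the ug-to-ng unit bridge applied so that a dose in
#' ug and an AUC in ng*h/mL yield a clearance in mL/h.
#'
#' @param dose administered dose (ug), positive.
#' @param auc area under the plasma curve to infinity (ng*h/mL), positive.
#'
#' @return Apparent clearance (mL/h).
#' @examples
#' apparent_clearance(1000, 1000)  # 1000 mL/h
#' @export
apparent_clearance <- function(dose, auc) {
  if (dose <= 0) stop("'dose' must be positive")
  if (auc <= 0) stop("'auc' must be positive")
  dose * 1000 / auc
}

# curve stripping of a bi-exponential: terminal log-linear fit, then a
# log-linear fit of the early-time residuals
.strip_biexp <- function(t, c_) {
  n <- length(t)
  n_tail <- max(3L, ceiling(n / 3))
  tail_idx <- utils::tail(seq_len(n), n_tail)
  fit2 <- stats::lm(log(c_[tail_idx]) ~ t[tail_idx])
  beta <- max(-unname(stats::coef(fit2)[2]), 1e-6)
  B <- exp(unname(stats::coef(fit2)[1]))
  res <- c_ - B * exp(-beta * t)
  early <- which(res > 0 & seq_len(n) < min(tail_idx))
  if (length(early) >= 2) {
    fit1 <- stats::lm(log(res[early]) ~ t[early])
    alpha <- -unname(stats::coef(fit1)[2])
    A <- exp(unname(stats::coef(fit1)[1]))
    if (!is.finite(alpha) || alpha <= beta) { alpha <- 5 * beta; A <- 0.2 * B }
  } else {
    alpha <- 5 * beta
    A <- max(c_[1] - B, 0.2 * B)
  }
  list(A = A, alpha = alpha, B = B, beta = beta)
}

#' Fit a two-compartment model to intravenous-bolus plasma data
#'
#' Fits the bi-exponential solution of the two-compartment disposition
#' model after an intravenous bolus, parameterised by the macro-parameters
#' clearance `CL`, central volume `V1`, total volume `VT = V1 + V2` and
#' intercompartmental clearance `CLic`. Starting values come from curve
#' stripping (terminal log-linear phase, then the early-time residuals).
#' When the data carry no second phase the fit collapses to `VT = V1` with
#' `CLic` at its lower bound; this is flagged in the result message.
#'
#' @param conc a [time_series()] of kind `"plasma_concentration"` (ng/mL),
#'   single replicate, at least 4 distinct times.
#' @param dose intravenous dose (ug), positive.
#'
#' @return A `fit_result` with estimates `CL`, `V1`, `VT`, `CLic`.
#' @examples
#' pk <- pk_params(CL = 1580, V1 = 488, VT = 1568, CLic = 3340)
#' tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
#' cp <- iv_bolus_concentration(pk, dose = 500, times = tt)
#' fit_iv_two_compartment(time_series(tt, cp, "plasma_concentration"), dose = 500)
#' @export
fit_iv_two_compartment <- function(conc, dose) {
  stopifnot(inherits(conc, "time_series"))
  if (attr(conc, "kind") != "plasma_concentration")
    stop("'conc' must have kind 'plasma_concentration'")
  if (dose <= 0) stop("'dose' must be positive")
  t <- conc$time_h; c_ <- conc$value
  if (length(unique(t)) < 4L) stop("need at least 4 distinct time points")
  if (any(c_ <= 0)) stop("concentrations must be positive for this fit")
  # mono-exponential data leave the exchange parameters unidentifiable:
  # report the nested one-compartment solution with CLic at its lower bound
  mono <- stats::lm(log(c_) ~ t)
  if (stats::sd(stats::residuals(mono)) < 1e-6) {
    k10 <- -unname(stats::coef(mono)[2])
    V1 <- 1000 * dose / exp(unname(stats::coef(mono)[1]))
    est <- c(CL = k10 * V1, V1 = V1, VT = V1, CLic = 0)
    rf <- function(par) c_ - (1000 * dose / par[["V1"]]) *
      exp(-(par[["CL"]] / par[["V1"]]) * t)
    se2 <- .gn_std_errors(rf, est[c("CL", "V1")])
    se <- c(CL = unname(se2[["CL"]]), V1 = unname(se2[["V1"]]),
            VT = unname(se2[["V1"]]), CLic = NA_real_)
    r <- rf(est[c("CL", "V1")])
    return(new_fit_result(est, se, r, sum(r^2), TRUE, length(t),
                          "intercompartmental clearance at its lower bound: data are mono-exponential"))
  }
  st <- .strip_biexp(t, c_)
  # macro exponentials -> (CL, V1, VT, CLic); concentrations ng/mL, dose ug
  Aug <- st$A / 1000; Bug <- st$B / 1000
  V1_0 <- dose / (Aug + Bug)
  k21_0 <- (Aug * st$beta + Bug * st$alpha) / (Aug + Bug)
  k10_0 <- st$alpha * st$beta / k21_0
  k12_0 <- max(st$alpha + st$beta - k21_0 - k10_0, 1e-6)
  start <- c(CL = k10_0 * V1_0, V1 = V1_0,
             V2 = max(k12_0 * V1_0 / k21_0, 1e-3 * V1_0),
             CLic = max(k12_0 * V1_0, 1e-6))
  resid_nat <- function(par) {
    pk <- list(CL = par[["CL"]], V1 = par[["V1"]],
               VT = par[["V1"]] + par[["V2"]], CLic = par[["CLic"]])
    c_ - .iv_biexp(pk, dose, t)
  }
  fit <- .lm_fit(resid_nat, start)
  est <- fit$estimates
  out_est <- c(CL = unname(est[["CL"]]), V1 = unname(est[["V1"]]),
               VT = unname(est[["V1"]] + est[["V2"]]),
               CLic = unname(est[["CLic"]]))
  se <- fit$std_errors
  out_se <- c(CL = unname(se[["CL"]]), V1 = unname(se[["V1"]]),
              VT = unname(sqrt(se[["V1"]]^2 + se[["V2"]]^2)),
              CLic = unname(se[["CLic"]]))
  msg <- fit$message
  if (out_est[["CLic"]] < 1e-3 * out_est[["CL"]] ||
      est[["V2"]] < 1e-2 * est[["V1"]])
    msg <- "intercompartmental exchange at its lower bound: data are effectively one-compartment"
  new_fit_result(out_est, out_se, fit$residuals, fit$objective,
                 fit$converged, length(t), msg)
}

#' Plasma concentration after an intravenous bolus (two-compartment model)
#'
#' Closed-form bi-exponential concentration for an IV bolus under the
#' two-compartment disposition model, in ng/mL for a dose in ug and
#' volumes in mL.
#'
#' @param pk a [pk_params()] object.
#' @param dose intravenous dose (ug).
#' @param times sampling times (h).
#' @return Plasma concentrations (ng/mL).
#' @export
iv_bolus_concentration <- function(pk, dose, times) {
  stopifnot(inherits(pk, "pk_params"))
  .iv_biexp(pk, dose, times)
}

#' @keywords internal
.iv_biexp <- function(pk, dose, t) {
  mc <- list(k10 = pk$CL / pk$V1, k12 = pk$CLic / pk$V1,
             k21 = if (pk$VT > pk$V1) pk$CLic / (pk$VT - pk$V1) else 0)
  s <- mc$k10 + mc$k12 + mc$k21
  p <- mc$k10 * mc$k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c0 <- dose / pk$V1 * 1000  # ng/mL
  if (alpha - beta < 1e-12 * alpha) {
    # coincident phases: confluent limit of the bi-exponential
    c0 * exp(-alpha * t) * (1 + (mc$k21 - alpha) * t)
  } else {
    c0 * ((alpha - mc$k21) * exp(-alpha * t) +
            (mc$k21 - beta) * exp(-beta * t)) / (alpha - beta)
  }
}
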