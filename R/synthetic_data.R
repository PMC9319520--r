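#' Measurement noise model for synthetic data
#'
#' Describes the stochastic measurement error added to noise-free model
#' curves by the synthetic-data generators: none, additive Gaussian,
#' proportional Gaussian (constant coefficient of variation), or both
#' combined. Negative simulated measurements are truncated at zero and
#' counted in an attribute of the generated series.
#'
#' @param kind one of `"none"`, `"additive"`, `"proportional"`,
#'   `"combined"`.
#' @param sd_additive additive standard deviation (measurement units).
#' @param cv_proportional proportional coefficient of variation
#'   (dimensionless).
#' @param seed integer seed; a fixed seed makes generation bit-identical.
#'   Replicates draw from distinct seed-derived streams.
#'
#' @return An object of class `noise_model`.
#' @examples
#' noise_model("proportional", cv_proportional = 0.05, seed = 1)
#' @export
noise_model <- function(kind = c("none", "additive", "proportional", "combined"),
                        sd_additive = 0, cv_proportional = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (sd_additive < 0 || cv_proportional < 0)
    stop("noise components must be non-negative")
  structure(list(kind = kind, sd_additive = sd_additive,
                 cv_proportional = cv_proportional, seed = seed),
            class = "noise_model")
}

#' Sampling design of a permeation or plasma-sampling experiment
#'
#' @param schedule sampling times (h), strictly increasing.
#' @param n_replicates number of replicate cells or animals (>= 1).
#' @param regimen `"infinite"` or `"finite"` dosing.
#' @param receptor_volume Franz-cell receptor chamber volume (mL).
#' @param sample_volume withdrawn sample volume per time point (mL).
#' @param area exposed skin area (cm^2).
#' @param refresh_times times (h) at which the donor formulation is
#'   replaced to maintain infinite-dose conditions; metadata only (the
#'   model holds the donor concentration constant by assumption).
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(c(3, 5, 7, 9, 24, 26, 28, 30), n_replicates = 4,
#'                   regimen = "infinite", area = 1.45)
#' @export
experiment_design <- function(schedule, n_replicates = 1L,
                              regimen = c("infinite", "finite"),
                              receptor_volume = 9, sample_volume = 0.2,
                              area = 1, refresh_times = numeric(0)) {
  regimen <- match.arg(regimen)
  if (any(diff(schedule) <= 0)) stop("'schedule' must be strictly increasing")
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  if (area <= 0) stop("'area' must be positive")
  structure(list(schedule = schedule, n_replicates = as.integer(n_replicates),
                 regimen = regimen, receptor_volume = receptor_volume,
                 sample_volume = sample_volume, area = area,
                 refresh_times = refresh_times),
            class = "experiment_design")
}

# replicate-specific sub-seed, kept inside the 32-bit integer range
.replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1009 + r * 9973) %% 2147483647)
}

# draw one replicate's noisy version of a truth vector
.apply_noise <- function(truth, noise, seed_r) {
  if (noise$kind == "none") return(truth)
  if (!is.null(seed_r)) set.seed(seed_r)
  y <- truth
  if (noise$kind %in% c("proportional", "combined"))
    y <- y * (1 + noise$cv_proportional * stats::rnorm(length(y)))
  if (noise$kind %in% c("additive", "combined"))
    y <- y + noise$sd_additive * stats::rnorm(length(y))
  y
}

.truncate_zero <- function(ts) {
  n_trunc <- sum(ts$value < 0)
  ts$value[ts$value < 0] <- 0
  attr(ts, "n_truncated") <- n_trunc
  ts
}

#' Generate synthetic Franz-cell permeation data
#'
#' Evaluates the one-compartment skin transport model (infinite or finite
#' dose, per the regimen in `sp`) at the design's sampling schedule,
#' converts the cumulative receptor amounts to receptor-chamber
#' concentrations with the forward withdrawal/refill dilution (the inverse
#' of [receptor_concentrations_to_QR()]), applies measurement noise to the
#' concentrations, and returns both the noisy concentration series and the
#' cumulative series reconstructed from it.
#'
#' @param sp a [skin_transport_params()] object; its regimen must match
#'   the design's.
#' @param design an [experiment_design()].
#' @param noise a [noise_model()]; default noise-free.
#'
#' @return A list with `concentration` (a `time_series` of receptor
#'   concentrations, ug/mL) and `cumulative` (a `time_series` of
#'   cumulative amounts per area, ug/cm^2), each holding
#'   `design$n_replicates` replicates. With `noise_model("none")` the
#'   cumulative values equal the model curve exactly.
#' @examples
#' sp <- skin_transport_params(R0 = 229, kout = 0.10, CD = 50000, S = 1.45)
#' des <- experiment_design(c(3, 5, 7, 9, 24, 26, 28, 30), 4, "infinite",
#'                          area = 1.45)
#' gen_franz_cell_series(sp, des, noise_model("proportional",
#'                       cv_proportional = 0.05, seed = 1))
#' @export
gen_franz_cell_series <- function(sp, design, noise = noise_model("none")) {
  stopifnot(inherits(sp, "skin_transport_params"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  if (sp$regimen != design$regimen)
    stop("regimen mismatch between parameters and design")
  prof <- if (sp$regimen == "infinite") {
    infinite_dose_profile(sp, design$schedule)
  } else {
    finite_dose_profile(sp, design$schedule)
  }
  qr_truth <- prof$QR
  # forward withdrawal dilution: C_n = (Q_n A - V_s sum_{i<n} C_i) / V_R
  conc_truth <- numeric(length(qr_truth))
  carried <- 0
  for (i in seq_along(qr_truth)) {
    conc_truth[i] <- (qr_truth[i] * design$area - carried) /
      design$receptor_volume
    carried <- carried + conc_truth[i] * design$sample_volume
  }
  reps <- lapply(seq_len(design$n_replicates), function(r) {
    seed_r <- if (is.null(noise$seed)) NULL else .replicate_seed(noise$seed, r)
    .apply_noise(conc_truth, noise, seed_r)
  })
  conc_ts <- time_series(rep(design$schedule, design$n_replicates),
                         unlist(reps), kind = "receptor_concentration",
                         replicate = rep(sprintf("r%d", seq_len(design$n_replicates)),
                                         each = length(design$schedule)))
  conc_ts <- .truncate_zero(conc_ts)
  cum_ts <- receptor_concentrations_to_QR(conc_ts, design$receptor_volume,
                                          design$sample_volume, design$area)
  list(concentration = conc_ts, cumulative = cum_ts)
}

#' Generate synthetic plasma concentration data after transdermal dosing
#'
#' Samples the coupled skin-disposition simulation
#' ([simulate_transdermal_pk()]) at the design's schedule for
#' `n_replicates` animals, applying measurement noise per replicate.
#'
#' @param pk a [pk_params()] object.
#' @param kin,kout skin transport rate constants (1/h).
#' @param dose applied dose (ug).
#' @param design an [experiment_design()] (the Franz-cell fields are
#'   ignored for plasma sampling).
#' @param noise a [noise_model()]; default noise-free.
#'
#' @return A `time_series` of kind `"plasma_concentration"` (ng/mL) with
#'   one replicate per animal.
#' @examples
#' pk <- pk_params(CL = 3126, V1 = 488, VT = 1568, CLic = 3340)
#' des <- experiment_design(c(8, 12, 24, 27, 30, 46, 48, 51, 54), 5, "finite")
#' gen_plasma_series(pk, 0.065, 0.10, 20000, des,
#'                   noise_model("proportional", cv_proportional = 0.15, seed = 1))
#' @export
gen_plasma_series <- function(pk, kin, kout, dose, design,
                              noise = noise_model("none")) {
  stopifnot(inherits(pk, "pk_params"), inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  truth <- simulate_transdermal_pk(pk, kin, kout, dose,
                                   design$schedule)$conc_ng_per_mL
  reps <- lapply(seq_len(design$n_replicates), function(r) {
    seed_r <- if (is.null(noise$seed)) NULL else .replicate_seed(noise$seed, r)
    .apply_noise(truth, noise, seed_r)
  })
  ts <- time_series(rep(design$schedule, design$n_replicates),
                    unlist(reps), kind = "plasma_concentration",
                    replicate = rep(sprintf("r%d", seq_len(design$n_replicates)),
                                    each = length(design$schedule)))
  .truncate_zero(ts)
}

#' Parameter bundles of the rat nortriptyline study
#'
#' Returns the parameter sets of the nortriptyline transdermal worked
#' example as three fixtures:
#' \describe{
#'   \item{in_vitro}{infinite-dose Franz-cell experiment: `R0 = 229`
#'     ug/cm^2/h, `kout = 0.10` 1/h, donor concentration 50,000 ug/mL,
#'     area 1.45 cm^2, receptor 9 mL, sample 0.2 mL, sampling at
#'     3, 5, 7, 9, 24, 26, 28, 30 h with 4 replicate cells and donor gel
#'     refreshed at 9 h.}
#'   \item{in_vivo}{transdermal rat experiment: `kin = 0.065` 1/h (from a
#'     3% residual dose at 54 h), the same `kout = 0.10` 1/h, apparent
#'     clearance 3126 mL/h with the intravenous distribution parameters
#'     (`V1 = 488`, `VT = 1568` mL, `CLic = 3340` mL/h), dose 20,000 ug
#'     (0.4 mL of a 5% m/m gel at density 1 g/mL), area 1.39 cm^2,
#'     sampling at 8, 12, 24, 27, 30, 46, 48, 51, 54 h in 5 animals.}
#'   \item{iv}{intravenous reference: `CL = 1580`, `V1 = 488`,
#'     `VT = 1568` mL, `CLic = 3340` mL/h, bolus dose 500 ug.}
#' }
#'
#' @return A named list of lists with the elements described above,
#'   including ready-made [skin_transport_params()], [pk_params()] and
#'   [experiment_design()] objects.
#' @examples
#' fx <- nortriptyline_fixtures()
#' fx$in_vitro$R0
#' @export
nortriptyline_fixtures <- function() {
  in_vitro <- list(
    R0 = 229, kout = 0.10, CD = 50000, area = 1.45,
    receptor_volume = 9, sample_volume = 0.2,
    schedule = c(3, 5, 7, 9, 24, 26, 28, 30), n_replicates = 4L,
    cv = 0.05)
  in_vitro$sp <- skin_transport_params(R0 = in_vitro$R0, kout = in_vitro$kout,
                                       CD = in_vitro$CD, S = in_vitro$area)
  in_vitro$design <- experiment_design(in_vitro$schedule,
                                       in_vitro$n_replicates, "infinite",
                                       receptor_volume = in_vitro$receptor_volume,
                                       sample_volume = in_vitro$sample_volume,
                                       area = in_vitro$area,
                                       refresh_times = 9)
  in_vivo <- list(
    kin = 0.065, kout = 0.10, CL_app = 3126,
    V1 = 488, VT = 1568, CLic = 3340,
    dose = 20000, area = 1.39,
    residual_fraction = 0.03, residual_time = 54,
    schedule = c(8, 12, 24, 27, 30, 46, 48, 51, 54), n_replicates = 5L,
    cv = 0.15)
  in_vivo$pk <- pk_params(CL = in_vivo$CL_app, V1 = in_vivo$V1,
                          VT = in_vivo$VT, CLic = in_vivo$CLic)
  in_vivo$design <- experiment_design(in_vivo$schedule, in_vivo$n_replicates,
                                      "finite", area = in_vivo$area)
  iv <- list(CL = 1580, V1 = 488, VT = 1568, CLic = 3340, dose = 500)
  iv$pk <- pk_params(CL = iv$CL, V1 = iv$V1, VT = iv$VT, CLic = iv$CLic)
  list(in_vitro = in_vitro, in_vivo = in_vivo, iv = iv)
}
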