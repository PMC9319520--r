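franz_schedule <- c(3, 5, 7, 9, 24, 26, 28, 30)

test_that("receptor sampling correction reconstructs cumulative amounts", {
  one <- time_series(3, 1, "receptor_concentration")
  expect_equal(receptor_concentrations_to_QR(one, 9, 0.2, 1.45)$value,
               9 / 1.45)
  # no withdrawal: C_n * V_R / A at every point
  ts <- time_series(c(3, 5, 7), c(1, 2, 3), "receptor_concentration")
  expect_equal(receptor_concentrations_to_QR(ts, 9, 0, 1.45)$value,
               c(1, 2, 3) * 9 / 1.45)
  # constant concentration accumulates the withdrawn amounts (hand-summed)
  ts3 <- time_series(c(3, 5, 7), c(1, 1, 1), "receptor_concentration")
  expect_equal(receptor_concentrations_to_QR(ts3, 9, 0.2, 1.45)$value,
               c(9, 9.2, 9.4) / 1.45, tolerance = 1e-12)
  expect_error(receptor_concentrations_to_QR(ts3, 9, 9, 1.45), "smaller")
})

test_that("infinite-dose fit recovers generating parameters from noise-free
           data on the study schedule", {
  sp <- skin_transport_params(R0 = 229, kout = 0.10)
  prof <- infinite_dose_profile(sp, franz_schedule)
  fit <- fit_infinite_dose(time_series(franz_schedule, prof$QR,
                                       "cumulative_per_area"))
  expect_true(fit$converged)
  expect_rel_equal(fit$estimates[["R0"]], 229, 1e-6)
  expect_rel_equal(fit$estimates[["kout"]], 0.10, 1e-6)
  expect_lt(fit$objective, 1e-10)
  # onset-delay variant round-trips too
  sp_t0 <- skin_transport_params(R0 = 229, kout = 0.10, t0 = 1.5)
  prof2 <- infinite_dose_profile(sp_t0, franz_schedule)
  fit2 <- fit_infinite_dose(time_series(franz_schedule, prof2$QR,
                                        "cumulative_per_area"), fit_t0 = TRUE)
  expect_rel_equal(fit2$estimates[["t0"]], 1.5, 1e-4)
})

test_that("data on a line through the origin drive the lag to zero", {
  t <- 1:8
  fit <- fit_infinite_dose(time_series(t, 5 * t, "cumulative_per_area"))
  expect_rel_equal(fit$estimates[["R0"]], 5, 1e-3)
  expect_lt(1 / fit$estimates[["kout"]], 0.01)
  expect_error(fit_infinite_dose(time_series(c(1, 2), c(1, 2),
                                             "cumulative_per_area")),
               "distinct time")
})

test_that("finite-dose fit round-trips and reports the flip-flop twin", {
  sp <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 100)
  tt <- c(2, 4, 8, 16, 24, 36, 48)
  prof <- finite_dose_profile(sp, tt)
  fit <- fit_finite_dose(time_series(tt, prof$QR, "cumulative_per_area"),
                         Q0 = 100)
  expect_true(fit$converged)
  expect_rel_equal(sort(fit$estimates), c(0.065, 0.10), 1e-6)
  expect_lte(fit$estimates[["kin"]], fit$estimates[["kout"]])
  expect_equal(unname(fit$alternate),
               unname(fit$estimates[c("kout", "kin")]))
  # exact exchange symmetry of the cumulative curve
  sp_swap <- skin_transport_params(kin = 0.10, kout = 0.065, Q0 = 100)
  expect_equal(finite_dose_profile(sp_swap, tt)$QR, prof$QR)
})

test_that("finite-dose fit flags instantaneous transfer as non-converged", {
  fit <- fit_finite_dose(time_series(1:5, rep(100, 5), "cumulative_per_area"),
                         Q0 = 100)
  expect_false(fit$converged)
})

test_that("finite-dose flux fit recovers the confluent solution", {
  sp <- skin_transport_params(kin = 0.1, kout = 0.1, Q0 = 100)
  tt <- c(2, 4, 8, 12, 20, 30, 45)
  j <- finite_dose_profile(sp, tt)$J
  fit <- fit_finite_dose(time_series(tt, j, "flux"), Q0 = 100)
  expect_rel_equal(fit$estimates, c(0.1, 0.1), 1e-4)
})

test_that("residual-fraction inversion gives the first-order input constant", {
  expect_equal(kin_from_residual_fraction(0.03, 54), 0.0649,
               tolerance = 1e-4 / 0.0649)
  expect_equal(kin_from_residual_fraction(exp(-1), 1), 1)
  expect_equal(kin_from_residual_fraction(0.5, 10), log(2) / 10)
  expect_error(kin_from_residual_fraction(1, 10), "between 0 and 1")
  expect_error(kin_from_residual_fraction(0, 10), "between 0 and 1")
})

test_that("trapezoidal AUC handles constant, sparse and mono-exponential
           profiles", {
  const <- time_series(c(0, 2, 5, 8), rep(3, 4), "plasma_concentration")
  expect_equal(nca_auc(const, extrapolate = FALSE)$auc, 3 * 8)
  two <- time_series(c(0, 1), c(0, 10), "plasma_concentration")
  expect_equal(nca_auc(two, extrapolate = FALSE)$auc, 5)
  tt <- seq(0, 30, by = 0.1)
  mono <- time_series(tt, 100 * exp(-0.2 * tt), "plasma_concentration")
  res <- nca_auc(mono)
  expect_equal(res$auc, 100 / 0.2, tolerance = 0.005)
  expect_equal(res$lambda_z, 0.2, tolerance = 1e-3)
  # non-positive tail refuses extrapolation but returns the observed range
  flat0 <- time_series(c(0, 1, 2, 3), c(10, 5, 1, 0), "plasma_concentration")
  expect_warning(res0 <- nca_auc(flat0), "non-positive")
  expect_false(res0$extrapolated)
  expect_equal(res0$auc, res0$auc_observed)
})

test_that("apparent clearance bridges ug doses to ng*h/mL exposures", {
  expect_equal(apparent_clearance(1000, 1000), 1000)
  expect_error(apparent_clearance(1000, 0), "auc")
  # AUC-to-infinity of a simulated transdermal profile returns the
  # clearance used in the simulation (complete first-order absorption)
  pk <- pk_params(CL = 3126, V1 = 488, VT = 1568, CLic = 3340)
  grid <- seq(0, 400, by = 0.25)
  prof <- simulate_transdermal_pk(pk, 0.065, 0.10, 20000, grid)
  ts <- time_series(grid[-1], prof$conc_ng_per_mL[-1], "plasma_concentration")
  cl_app <- apparent_clearance(20000, nca_auc(ts)$auc)
  expect_rel_equal(cl_app, 3126, 0.02)
})

iv_schedule <- c(0.05, 0.1, 0.2, 0.4, 0.75, 1.5, 3, 6)
pk_iv <- pk_params(CL = 1580, V1 = 488, VT = 1568, CLic = 3340)

test_that("two-compartment IV fit round-trips the reference disposition
           parameters", {
  cp <- iv_bolus_concentration(pk_iv, 500, iv_schedule)
  fit <- fit_iv_two_compartment(time_series(iv_schedule, cp,
                                            "plasma_concentration"), 500)
  expect_true(fit$converged)
  expect_rel_equal(fit$estimates, c(1580, 488, 1568, 3340), 1e-5)
})

test_that("mono-exponential IV data collapse to the one-compartment nested
           case with exchange at its bound", {
  pk1 <- pk_params(1580, 488, 488, 0)
  cp <- iv_bolus_concentration(pk1, 500, iv_schedule)
  fit <- fit_iv_two_compartment(time_series(iv_schedule, cp,
                                            "plasma_concentration"), 500)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["V1"]], fit$estimates[["VT"]])
  expect_equal(fit$estimates[["CLic"]], 0)
  expect_match(fit$message, "lower bound")
  expect_rel_equal(fit$estimates[["CL"]], 1580, 1e-6)
})

test_that("median IV estimates stay within one standard error of truth under
           10% proportional noise", {
  truth <- iv_bolus_concentration(pk_iv, 500, iv_schedule)
  est <- matrix(NA_real_, 100, 4)
  ses <- matrix(NA_real_, 100, 4)
  set.seed(7)
  for (i in 1:100) {
    cp <- truth * (1 + 0.10 * rnorm(length(iv_schedule)))
    if (any(cp <= 0)) next
    fit <- try(suppressWarnings(
      fit_iv_two_compartment(time_series(iv_schedule, cp,
                                         "plasma_concentration"), 500)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    est[i, ] <- fit$estimates
    ses[i, ] <- fit$std_errors
  }
  med <- apply(est, 2, median, na.rm = TRUE)
  mse <- apply(ses, 2, median, na.rm = TRUE)
  expect_true(all(abs(med - c(1580, 488, 1568, 3340)) <= mse))
})

test_that("fit results serialise to key-value text", {
  sp <- skin_transport_params(R0 = 229, kout = 0.10)
  prof <- infinite_dose_profile(sp, franz_schedule)
  fit <- fit_infinite_dose(time_series(franz_schedule, prof$QR,
                                       "cumulative_per_area"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fit_result(fit, path)
  lines <- readLines(path)
  expect_equal(lines[1], "schema: skinpk-fit/1")
  expect_true(any(grepl("^estimate\\.R0:", lines)))
})
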