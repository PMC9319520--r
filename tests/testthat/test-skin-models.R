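sp_inf <- skin_transport_params(R0 = 229, kout = 0.10, CD = 50000, S = 1.45)
sp_fin <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 100)

test_that("infinite-dose profile starts empty and approaches its steady state", {
  p0 <- infinite_dose_profile(sp_inf, 0)
  expect_equal(c(p0$QM, p0$QR, p0$J), c(0, 0, 0))
  p_late <- infinite_dose_profile(sp_inf, 200)
  expect_rel_equal(p_late$QM, 229 / 0.10, 1e-6)   # R0/kout = 2290 ug/cm^2
  expect_rel_equal(p_late$J, 229, 1e-6)           # J -> R0
})

test_that("infinite-dose cumulative amount is the integral of the flux", {
  flux <- function(t) 229 * (1 - exp(-0.10 * t))
  for (t_end in c(5, 15, 40)) {
    q <- infinite_dose_profile(sp_inf, t_end)$QR
    q_num <- stats::integrate(flux, 0, t_end, rel.tol = 1e-10)$value
    expect_rel_equal(q, q_num, 1e-6)
  }
})

test_that("finite-dose profile honours its boundary values and the residual
           worked example", {
  p0 <- finite_dose_profile(sp_fin, 0)
  expect_equal(p0$QD, 100)
  expect_equal(c(p0$QM, p0$QR, p0$J), c(0, 0, 0))
  # the study's skin-residual prediction: 4.7% of the dose at 54 h
  p54 <- finite_dose_profile(sp_fin, 54)
  expect_equal(p54$QM / 100, 0.047, tolerance = 0.001 / 0.047)
  expect_equal(skin_residual_fraction(0.065, 0.10, 54), p54$QM / 100)
})

test_that("confluent kin = kout limit matches the general formula", {
  expect_equal(skin_residual_fraction(0.1, 0.1, 10), 0.1 * 10 * exp(-1))
  # nearly-coincident rates through the general branch agree
  expect_rel_equal(skin_residual_fraction(0.1, 0.1 + 1e-7, 10),
                   0.1 * 10 * exp(-1), 1e-5)
  sp_c <- skin_transport_params(kin = 0.1, kout = 0.1, Q0 = 50)
  expect_equal(peak_flux(sp_c)$TJmax, 10)  # 1/k in the confluent limit
})

test_that("mass balance holds across random parameters and times", {
  set.seed(101)
  for (i in 1:1000) {
    t <- runif(1, 0, 100)
    t0 <- sample(c(0, runif(1, 0, 3)), 1)
    R0 <- runif(1, 1, 500); kout <- 10^runif(1, -2, 0.5)
    sp <- skin_transport_params(R0 = R0, kout = kout, t0 = t0)
    p <- infinite_dose_profile(sp, t)
    expect_lt(abs(p$QR + p$QM - R0 * max(t - t0, 0)),
              1e-9 * max(R0 * t, 1e-12))
    kin <- 10^runif(1, -2, 0.5); Q0 <- runif(1, 10, 1000); S <- runif(1, 0.5, 3)
    spf <- skin_transport_params(kin = kin, kout = kout, Q0 = Q0, S = S)
    pf <- finite_dose_profile(spf, t)
    expect_lt(abs(pf$QD + pf$QM + pf$QR - Q0 / S), 1e-9 * Q0 / S)
    expect_true(all(c(pf$QD, pf$QM, pf$QR) >= 0))
  }
})

test_that("peak flux time matches a fine-grid argmax and is exchange-symmetric", {
  pk <- peak_flux(sp_fin)
  grid <- seq(0, 60, by = 1e-3)
  j <- finite_dose_profile(sp_fin, grid)$J
  expect_equal(pk$TJmax, grid[which.max(j)], tolerance = 2e-3 / 12.3)
  expect_equal(pk$TJmax, 12.3081, tolerance = 1e-4)
  expect_equal(pk$Jmax, max(j), tolerance = 1e-6)
  sp_swap <- skin_transport_params(kin = 0.10, kout = 0.065, Q0 = 100)
  expect_equal(peak_flux(sp_swap)$TJmax, pk$TJmax)
})

test_that("finite-dose flux is unimodal with its maximum at the predicted time", {
  grid <- seq(0, 100, by = 0.05)
  j <- finite_dose_profile(sp_fin, grid)$J
  i_max <- which.max(j)
  expect_true(all(diff(j[1:i_max]) >= -1e-12))
  expect_true(all(diff(j[i_max:length(j)]) <= 1e-12))
})

test_that("time to a flux fraction inverts the rise of the infinite-dose flux", {
  expect_equal(time_to_flux_fraction(0.975, 0.10) * 0.10, 3.689,
               tolerance = 1e-3 / 3.689)
  expect_equal(time_to_flux_fraction(0, 0.1), 0)
  expect_equal(time_to_flux_fraction(0.5, 0.1), log(2) / 0.1)
  expect_error(time_to_flux_fraction(1, 0.1), "\\[0, 1\\)")
  # consistency: the flux at that time is the requested fraction of R0
  t975 <- time_to_flux_fraction(0.975, 0.10)
  expect_rel_equal(infinite_dose_profile(sp_inf, t975)$J, 0.975 * 229, 1e-9)
})

test_that("steady-state metrics reproduce the permeability and plasma
           concentration arithmetic", {
  m <- steady_state_metrics(229, 50000, S = 1.45, CL = 1580)
  expect_equal(m$Kp, 0.00458)
  expect_equal(m$Css_ng_mL, 210.158, tolerance = 1e-5)
  expect_equal(m$Css_ug_mL * 1000, m$Css_ng_mL)
  expect_equal(steady_state_metrics(0, 100, S = 1, CL = 1)$Css_ng_mL, 0)
  expect_error(steady_state_metrics(229, 0), "CD")
})

test_that("finite-dose flux converges to the infinite-dose flux as the donor
           becomes effectively infinite", {
  # Q0 -> Inf with kin * Q0 held at R0
  kin <- 1e-6; Q0 <- 229 / kin
  sp_big <- skin_transport_params(kin = kin, kout = 0.10, Q0 = Q0)
  tt <- c(2, 5, 10, 20, 40)
  j_fin <- finite_dose_profile(sp_big, tt)$J
  j_inf <- infinite_dose_profile(skin_transport_params(R0 = 229, kout = 0.10),
                                 tt)$J
  expect_rel_equal(j_fin, j_inf, 1e-4)
})

test_that("late-time regression on model output recovers the pseudo-steady-state
           line of each description", {
  # compartmental: slope R0, t-intercept 1/kout (t >> 1/kout so the
  # exponential transient is below the regression tolerance)
  tt <- seq(250, 350, by = 5)
  q <- infinite_dose_profile(skin_transport_params(R0 = 229, kout = 0.10), tt)$QR
  line <- stats::lm(q ~ tt)
  expect_rel_equal(unname(coef(line)[2]), 229, 1e-6)
  expect_rel_equal(-unname(coef(line)[1]) / unname(coef(line)[2]), 1 / 0.10, 1e-6)
  # Fickian: slope Kp*CD, t-intercept Tlag
  dp <- diffusion_params(Kp = 0.0046, CD = 50000, Tlag = 10)
  tt2 <- seq(150, 250, by = 5)
  q2 <- fick_cumulative_infinite(dp, tt2)
  line2 <- stats::lm(q2 ~ tt2)
  expect_rel_equal(unname(coef(line2)[2]), 0.0046 * 50000, 1e-6)
  expect_rel_equal(-unname(coef(line2)[1]) / unname(coef(line2)[2]), 10, 1e-6)
})
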