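pk_ref <- pk_params(CL = 1580, V1 = 488, VT = 1568, CLic = 3340)
pk_app <- pk_params(CL = 3126, V1 = 488, VT = 1568, CLic = 3340)

test_that("micro rate constants follow their defining ratios", {
  mc <- derive_micro_constants(pk_ref)
  expect_equal(mc$k10, 1580 / 488)
  expect_equal(mc$k12, 3340 / 488)
  expect_equal(mc$V2, 1080)
  expect_equal(mc$k21, 3340 / 1080)
  # reference arithmetic: k10 = 3.238, k12 = 6.844, k21 = 3.093 1/h
  expect_equal(round(c(mc$k10, mc$k12, mc$k21), 3), c(3.238, 6.844, 3.093))
  mc0 <- derive_micro_constants(pk_params(1580, 488, 488, 0))
  expect_equal(c(mc0$k12, mc0$k21), c(0, 0))
  # micro -> macro -> micro is the identity
  back <- derive_micro_constants(micro_to_pk_params(mc))
  expect_rel_equal(unlist(back[c("k10", "k12", "k21", "V2")]),
                   unlist(mc[c("k10", "k12", "k21", "V2")]), 1e-12)
})

test_that("transdermal simulation starts at zero and conserves mass", {
  tt <- c(0, 1, 4, 12, 24, 54)
  prof <- simulate_transdermal_pk(pk_app, 0.065, 0.10, 20000, tt)
  expect_equal(prof$conc_ng_per_mL[1], 0)
  totals <- prof$A_vehicle_ug + prof$A_skin_ug + prof$A_central_ug +
    prof$A_peripheral_ug + prof$A_eliminated_ug
  expect_rel_equal(totals, rep(20000, length(tt)), 1e-6)
  expect_true(all(as.matrix(prof[, -1]) >= -1e-9))
})

test_that("closed-form and ODE solutions agree across random parameter draws", {
  set.seed(202)
  tt <- seq(0, 54, length.out = 25)
  for (i in 1:50) {
    kin <- 10^runif(1, -2, 1); kout <- 10^runif(1, -2, 1)
    V1 <- runif(1, 100, 1000)
    pk <- pk_params(CL = V1 * 10^runif(1, -1, 1), V1 = V1,
                    VT = V1 * runif(1, 1.2, 5),
                    CLic = V1 * 10^runif(1, -1, 1))
    cf <- simulate_transdermal_pk(pk, kin, kout, 1000, tt)
    od <- simulate_transdermal_pk(pk, kin, kout, 1000, tt, method = "ode")
    expect_lt(max(abs(cf$conc_ng_per_mL - od$conc_ng_per_mL)) /
                max(cf$conc_ng_per_mL), 1e-6)
  }
})

test_that("near-coincident rate constants fall back to the exact propagator", {
  tt <- c(0, 5, 15, 30)
  mc <- derive_micro_constants(pk_app)
  # kout chosen equal to kin: closed form must not blow up
  cf <- simulate_transdermal_pk(pk_app, 0.1, 0.1, 1000, tt)
  od <- simulate_transdermal_pk(pk_app, 0.1, 0.1, 1000, tt, method = "ode")
  expect_lt(max(abs(cf$conc_ng_per_mL - od$conc_ng_per_mL)) /
              max(od$conc_ng_per_mL), 1e-6)
  # no intercompartmental exchange: one disposition phase is zero
  pk0 <- pk_params(CL = 1580, V1 = 488, VT = 488, CLic = 0)
  cf0 <- simulate_transdermal_pk(pk0, 0.065, 0.1, 1000, tt)
  od0 <- simulate_transdermal_pk(pk0, 0.065, 0.1, 1000, tt, method = "ode")
  expect_lt(max(abs(cf0$conc_ng_per_mL - od0$conc_ng_per_mL)) /
              max(od0$conc_ng_per_mL), 1e-6)
})

test_that("the simulated exposure equals dose over clearance", {
  grid <- seq(0, 400, by = 0.5)
  prof <- simulate_transdermal_pk(pk_app, 0.065, 0.10, 20000, grid)
  auc <- sum(diff(grid) * (head(prof$conc_ng_per_mL, -1) +
                             tail(prof$conc_ng_per_mL, -1)) / 2)
  auc <- auc + prof$conc_ng_per_mL[length(grid)] / 0.065  # terminal tail
  expect_rel_equal(auc, 1000 * 20000 / 3126, 0.01)
  fo <- simulate_first_order_absorption_pk(pk_app, 0.065, 20000, grid)
  auc_fo <- sum(diff(grid) * (head(fo$conc_ng_per_mL, -1) +
                                tail(fo$conc_ng_per_mL, -1)) / 2)
  auc_fo <- auc_fo + fo$conc_ng_per_mL[length(grid)] / 0.065
  expect_rel_equal(auc_fo, 1000 * 20000 / 3126, 0.01)
})

test_that("the skin stage of the coupled model is exactly the finite-dose
           membrane model", {
  tt <- seq(0, 54, by = 1)
  S <- 1.39
  prof <- simulate_transdermal_pk(pk_app, 0.065, 0.10, 20000, tt)
  sp <- skin_transport_params(kin = 0.065, kout = 0.10, Q0 = 20000, S = S)
  memb <- finite_dose_profile(sp, tt)
  expect_rel_equal(prof$A_skin_ug[-1], memb$QM[-1] * S, 1e-9)
  # flux out of the skin stage is the finite-dose flux, scaled by area
  expect_rel_equal(0.10 * prof$A_skin_ug[-1] / S, memb$J[-1], 1e-9)
})

test_that("with fast disposition the plasma curve tracks the skin output flux", {
  pk_fast <- pk_params(CL = 1e4, V1 = 100, VT = 150, CLic = 500)
  tt <- seq(0.5, 54, by = 0.5)  # t > 5 / (CL/V1) = 0.05 h
  prof <- simulate_transdermal_pk(pk_fast, 0.065, 0.10, 1000, tt)
  quasi <- 1000 * 0.10 * prof$A_skin_ug / 1e4
  expect_lt(max(abs(prof$conc_ng_per_mL - quasi) / quasi), 0.10)
})

test_that("dropping the skin output stage gives an earlier and higher peak", {
  grid <- seq(0, 54, by = 0.05)
  with_skin <- simulate_transdermal_pk(pk_app, 0.065, 0.10, 20000, grid)
  no_skin <- simulate_first_order_absorption_pk(pk_app, 0.065, 20000, grid)
  expect_lt(grid[which.max(no_skin$conc_ng_per_mL)],
            grid[which.max(with_skin$conc_ng_per_mL)])
  expect_gt(max(no_skin$conc_ng_per_mL), max(with_skin$conc_ng_per_mL))
})

test_that("the first-order absorption comparison model also conserves mass", {
  tt <- c(0, 2, 10, 30, 54)
  fo <- simulate_first_order_absorption_pk(pk_app, 0.065, 5000, tt)
  totals <- fo$A_vehicle_ug + fo$A_central_ug + fo$A_peripheral_ug +
    fo$A_eliminated_ug
  expect_rel_equal(totals, rep(5000, length(tt)), 1e-6)
  od <- simulate_first_order_absorption_pk(pk_app, 0.065, 5000, tt,
                                           method = "ode")
  expect_lt(max(abs(fo$conc_ng_per_mL - od$conc_ng_per_mL)) /
              max(od$conc_ng_per_mL), 1e-6)
})
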