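test_that("a closed system equilibrates to dose over total volume in every state", {
  cmp <- compound_params(ref_phys, ps_fold = 10)
  sys <- assemble_system(ref_phys, cmp)
  sim <- simulate_pbpk(sys, dose_regimen("iv_bolus", dose = 100),
                       horizon = 1000)
  cf <- sim$conc[, ncol(sim$conc)]
  expect_equal(unname(cf), rep(100 / 70, 54), tolerance = 1e-6)

  ## same conservation law on a toy body
  toy <- make_toy_body(n_generic = 2, seed = 9)
  sysy <- assemble_system(toy, compound_params(toy, ps_fold = 5))
  simy <- simulate_pbpk(sysy, dose_regimen("iv_bolus", dose = 30),
                        horizon = 2000)
  vtot <- sum(toy$tissues$V_total) + sum(toy$blood)
  expect_equal(unname(simy$conc[, ncol(simy$conc)]),
               rep(30 / vtot, length(sysy$states)), tolerance = 1e-5)
})

test_that("stiff integration matches the matrix-exponential solution to 1e-6", {
  skip_if_not_installed("Matrix")
  cmp <- compound_params(ref_phys, ps_fold = 1, cl_met_fold = c(iw = 1),
                         uptake_fold = 0.5)
  sys <- assemble_system(ref_phys, cmp)
  reg <- dose_regimen("iv_bolus", dose = 100)
  tt <- exp(seq(log(1e-2), log(10), length.out = 20))
  sim <- simulate_pbpk(sys, reg, times = tt, rtol = 1e-11, atol = 1e-14)
  y0 <- apply_dose(sys, reg)$y0
  for (k in seq_along(tt)) {
    ref <- as.vector(Matrix::expm(sys$A * tt[k]) %*% y0)
    expect_lt(max(abs(sim$conc[, k + 1] - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("forced regimens match the variation-of-constants closed form", {
  cmp <- compound_params(ref_phys, ps_fold = 1, cl_met_fold = c(iw = 0.5))
  sys <- assemble_system(ref_phys, cmp)
  ## time grids stop while the solution is still within ~6 decades of its
  ## peak; beyond that the comparison probes conditioning noise, not solvers
  tt <- exp(seq(log(0.01), log(15), length.out = 25))
  for (reg in list(dose_regimen("iv_infusion", rate = 100),
                   dose_regimen("iv_infusion", rate = 100, t_stop = 5),
                   dose_regimen("po", dose = 100, ka = 1),
                   dose_regimen("po", dose = 100, ka = 0.01))) {
    sim <- simulate_pbpk(sys, reg, times = tt, rtol = 1e-11, atol = 1e-14)
    ref <- solve_analytic(sys, reg, tt)
    expect_lt(sup_rel_dev(sim$conc[, -1], ref), 1e-6)
  }
})

test_that("zero dose yields an identically zero trajectory", {
  sys <- assemble_system(ref_phys, compound_params(ref_phys))
  sim <- simulate_pbpk(sys, dose_regimen("iv_bolus", dose = 0), horizon = 5)
  expect_true(all(sim$conc == 0))
  ## Kp and Vd are undefined (missing), not zero
  expect_true(all(is.na(kp_profile(sim, "brain"))))
  expect_true(all(is.na(vd_profile(sim))))
})

test_that("closed-system mass is conserved through integration to 1e-6 relative", {
  cmp <- compound_params(ref_phys, ps_fold = 0.3, uptake_fold = 1)
  sys <- assemble_system(ref_phys, cmp)
  for (reg in list(dose_regimen("iv_bolus", dose = 100),
                   dose_regimen("po", dose = 100, ka = 1))) {
    sim <- simulate_pbpk(sys, reg, horizon = 50)
    amount <- as.vector(crossprod(sys$V, sim$conc))
    expected <- sim$dose$administered(sim$times)
    keep <- sim$times > 0
    expect_lt(max(abs(amount[keep] - expected[keep]) / expected[keep]), 1e-6)
  }
})

test_that("tissue concentration is the volume-weighted subcompartment mean", {
  sys <- assemble_system(ref_phys, compound_params(ref_phys, ps_fold = 10))
  sim <- simulate_pbpk(sys, dose_regimen("iv_bolus", dose = 100),
                       horizon = 1000)
  last <- ncol(sim$conc)
  ## at closed-system equilibrium every tissue equals the venous plasma
  for (t in c("adipose", "liver", "lung"))
    expect_equal(tissue_concentration(sim, t)[last],
                 unname(sim$conc["vp", last]), tolerance = 1e-6)
  expect_error(tissue_concentration(sim, "tendon"), "unknown tissue")

  ## direct check of the weighting on a synthetic state: concentration 4 in
  ## IW only, IW holding half the tissue volume, gives half the value
  states <- paste0("brain_", c("iw", "ew", "tp", "tc"))
  v <- sys$V[states]
  cvec <- c(4, 0, 0, 0)
  expect_equal(sum(v * cvec) / sum(v), 4 * v[[1]] / sum(v))
})

test_that("Kp and Vd converge to 1 in the closed system and Vd starts at the venous plasma volume", {
  sys <- assemble_system(ref_phys, compound_params(ref_phys, ps_fold = 10))
  sim <- simulate_pbpk(sys, dose_regimen("iv_bolus", dose = 100),
                       horizon = 1000)
  kp <- kp_profile(sim)
  expect_equal(unname(kp[, ncol(kp)]), rep(1, 12), tolerance = 1e-6)
  vd <- vd_profile(sim)
  expect_equal(vd[length(vd)], 1, tolerance = 1e-6)
  ## at t = 0 all drug sits in venous plasma
  expect_equal(vd[1], sys$V[["vp"]] / 70, tolerance = 1e-12)
  ## the classical tally without the portal vein undercounts by ~ V_pv / BW
  vd_lit <- vd_profile(sim, include_portal = FALSE)
  expect_equal(vd_lit[length(vd_lit)],
               1 - (sys$V[["pvp"]] + sys$V[["pvc"]]) / 70, tolerance = 1e-6)
})

test_that("pseudo-steady-state detection finds the closed-system plateau and flags short horizons", {
  sys <- assemble_system(ref_phys, compound_params(ref_phys, ps_fold = 10))
  sim <- simulate_pbpk(sys, dose_regimen("iv_bolus", dose = 100),
                       horizon = 1000)
  det <- detect_pss(sim)
  expect_true(det$converged)
  expect_equal(det$vdss, 1, tolerance = 1e-6)
  expect_equal(unname(det$kpss), rep(1, 12), tolerance = 1e-6)

  ## an open system cut off long before its terminal phase must not report
  cmp <- compound_params(ref_phys, ps_fold = 0.1, cl_met_fold = c(iw = 1))
  syso <- assemble_system(ref_phys, cmp)
  simo <- simulate_pbpk(syso, dose_regimen("iv_bolus", dose = 100),
                        horizon = 0.5)
  expect_error(detect_pss(simo), "longer horizon")
  expect_false(detect_pss(simo, strict = FALSE)$converged)
})

test_that("closed-form Vdss: conservation null vector, infusion stationarity, eigenmode vs simulation", {
  ## closed system: dominant eigenvalue 0, uniform eigenvector, Vdss = 1
  sys <- assemble_system(ref_phys, compound_params(ref_phys, ps_fold = 1))
  cf <- vdss_closed_form(sys, dose_regimen("iv_bolus", dose = 100))
  expect_equal(cf$vdss, 1, tolerance = 1e-8)
  expect_lt(abs(cf$lambda), 1e-9)
  expect_error(vdss_closed_form(sys, dose_regimen("iv_infusion", rate = 100)),
               "closed system")

  ## infusion: at the returned steady state elimination balances the input
  cmp <- compound_params(ref_phys, ps_fold = 1, cl_met_fold = c(iw = 1))
  syso <- assemble_system(ref_phys, cmp)
  reg <- dose_regimen("iv_infusion", rate = 100)
  b <- 100 * syso$input$iv / syso$V
  css <- solve(syso$A, -b)
  elim <- sum(syso$cl_met * syso$fu * css)
  expect_equal(elim, 100, tolerance = 1e-9)

  ## bolus: dominant-eigenmode Vdss matches the simulated plateau within 0.5%
  r <- run_scenario(scenario_spec("iv_bolus", ps_fold = 1,
                                  met_site = "iw", met_fold = 1),
                    ref_phys)
  expect_true(r$converged)
  expect_lt(rel_dev(r$vdss, r$vdss_oracle), 0.005)
})

test_that("hepatic-only metabolism depresses liver Kp below 1 and raises all other tissues above 1", {
  r <- run_scenario(scenario_spec("iv_bolus", ps_fold = 1, met_site = "iw",
                                  met_tissues = "liver", met_fold = 1),
                    ref_phys)
  expect_true(r$converged)
  expect_lt(r$kpss[["liver"]], 1)
  expect_true(all(r$kpss[setdiff(names(r$kpss), "liver")] > 1))
  expect_gt(r$vdss, 1)
})

test_that("results writer emits long-format concentrations, metrics, and a summary", {
  sys <- assemble_system(ref_phys,
                         compound_params(ref_phys, ps_fold = 1,
                                         cl_met_fold = c(iw = 1)))
  sim <- simulate_pbpk(sys, dose_regimen("iv_bolus", dose = 100),
                       horizon = 20, n_points = 40)
  dir <- tempfile("results")
  paths <- write_results(sim, dir)
  long <- read.csv(file.path(dir, "concentrations.csv"))
  expect_equal(nrow(long), 54 * length(sim$times))
  expect_setequal(unique(long$subcompartment),
                  c("iw", "ew", "tp", "tc", "plasma", "cells"))
  met <- read.csv(file.path(dir, "metrics.csv"))
  expect_equal(names(met)[1], "time_h")
  expect_true("Vd_L_per_kg" %in% names(met))
  expect_equal(met$Kp_liver, unname(kp_profile(sim, "liver")),
               tolerance = 1e-8)
  skip_if_not_installed("jsonlite")
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_identical(summ$route, "iv_bolus")
})
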