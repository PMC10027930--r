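# Synthetic-data calibration: the generating truth is the calibrated
# parameter set; datasets carry noise-free plasma and cumulative-urine
# observations produced by the model itself.

test_that("objective is ~zero at the truth and invariant to row order", {
  dsets <- make_truth_datasets()
  truth <- c(vmax_OAT3 = cal_params$processes$OAT3$vmax,
             vmax_NPT1 = cal_params$processes$NPT1$vmax,
             vmax_DPEP1 = cal_params$processes$DPEP1$vmax)
  l0 <- calib_objective(truth, cal_params, ref_phys, dsets)
  expect_lt(l0, 1e-4)
  shuffled <- dsets
  idx <- c(7, 2, 9, 1, 5, 3, 10, 4, 8, 6)
  shuffled[[1]]$observations <- shuffled[[1]]$observations[idx, ]
  expect_equal(calib_objective(truth, cal_params, ref_phys, shuffled), l0)
})

test_that("objective decreases toward the truth along a 1-D slice", {
  dsets <- make_truth_datasets()
  truth_vo <- cal_params$processes$OAT3$vmax
  losses <- vapply(c(0.4, 0.7, 1), function(s) {
    calib_objective(c(vmax_OAT3 = truth_vo * s), cal_params, ref_phys,
                    dsets)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("budget 1 returns the single evaluated candidate", {
  dsets <- make_truth_datasets()
  fit <- calib_fit(cal_params, ref_phys, dsets,
                   bounds = list(vmax_OAT3 = c(1e3, 1e5)),
                   budget = 1, seed = 2)
  expect_equal(nrow(fit$trace), 1)
  expect_equal(unname(fit$par[["vmax_OAT3"]]),
               fit$trace$vmax_OAT3[1])
})

test_that("fit bounds and budget validation", {
  dsets <- make_truth_datasets()
  expect_error(calib_fit(cal_params, ref_phys, dsets,
                         bounds = list(vmax_OAT3 = c(10, 1)), budget = 5),
               "bounds")
  expect_error(calib_fit(cal_params, ref_phys, dsets, bounds = list(),
                         budget = 5), "parameters")
  expect_error(calib_fit(cal_params, ref_phys, dsets,
                         bounds = list(vmax_OAT3 = c(1e3, 1e5)),
                         budget = 0), "budget")
})

test_that("the Vmax triplet is recovered from noise-free synthetic data", {
  dsets <- make_truth_datasets()
  truth <- c(vmax_OAT3 = cal_params$processes$OAT3$vmax,
             vmax_NPT1 = cal_params$processes$NPT1$vmax,
             vmax_DPEP1 = cal_params$processes$DPEP1$vmax)
  bounds <- lapply(as.list(truth), function(v) c(v / 4, v * 4))
  fit <- calib_fit(cal_params, ref_phys, dsets, bounds = bounds,
                   budget = 400, seed = 31, urine_weight = 200)
  rel <- abs(fit$par[names(truth)] - truth) / truth
  expect_true(all(rel < 0.15))
  # the fitted model reproduces the generating AUC_last within 2%
  fitted <- cal_params
  fitted$processes$OAT3$vmax <- fit$par[["vmax_OAT3"]]
  fitted$processes$NPT1$vmax <- fit$par[["vmax_NPT1"]]
  fitted$processes$DPEP1$vmax <- fit$par[["vmax_DPEP1"]]
  reg <- dsets[[1]]$regimen
  auc_fit <- auc_last(simulate_regimen(healthy_model(fitted), reg, 24))
  auc_true <- auc_last(simulate_regimen(healthy_model(), reg, 24))
  expect_equal(auc_fit / auc_true, 1, tolerance = 0.02)
  # and its urinary output is reported with the fit
  expect_gt(fit$urinary_fraction_24h, 0.5)
})

test_that("optimizer is robust across seeds on noise-free data", {
  dsets <- make_truth_datasets()
  truth_vo <- cal_params$processes$OAT3$vmax
  bounds <- list(vmax_OAT3 = c(truth_vo / 4, truth_vo * 4))
  l1 <- calib_fit(cal_params, ref_phys, dsets, bounds, budget = 60,
                  seed = 1)$loss
  l2 <- calib_fit(cal_params, ref_phys, dsets, bounds, budget = 60,
                  seed = 2)$loss
  expect_lt(abs(l1 - l2) / max(l1, l2, 1e-12), 0.5)
})

test_that("the OAT3-inhibition arm isolates filtration and raises exposure", {
  # scalar OAT3 activity multiplier emulates full transporter inhibition
  reg <- dosing_regimen(500, 24, 0.5)
  base <- simulate_regimen(healthy_model(), reg, 24)
  inhib_params <- cal_params
  inhib_params$processes$OAT3$activity_multiplier <- 0
  inhib <- simulate_regimen(healthy_model(inhib_params), reg, 24)
  # exposure increases; renal clearance (urine over AUC) falls to the
  # filtered share because the whole secretory pathway is OAT3-gated
  expect_gt(auc_last(inhib), auc_last(base))
  clr_base <- base$urine_mg[nrow(base)] / auc_last(base)
  clr_inhib <- inhib$urine_mg[nrow(inhib)] / auc_last(inhib)
  expect_lt(clr_inhib, clr_base)
  gfr_L_h <- ref_phys$gfr_mL_min * 60 / 1000 * cal_params$drug$fu
  expect_equal(clr_inhib, gfr_L_h, tolerance = 0.05)
  expect_equal(max(inhib$metabolized_mg), 0)
  # basolateral vs apical capacity are separable by the joint objective:
  # an OAT3 perturbation moves the plasma fit, an NPT1 perturbation of
  # equal size moves only the urine partitioning
  dsets <- make_truth_datasets()
  plasma_only <- lapply(dsets, function(d) {
    d$urine_fraction <- NULL
    d
  })
  d_oat3 <- calib_objective(
    c(vmax_OAT3 = cal_params$processes$OAT3$vmax * 1.5),
    cal_params, ref_phys, plasma_only)
  d_npt1 <- calib_objective(
    c(vmax_NPT1 = cal_params$processes$NPT1$vmax * 1.5),
    cal_params, ref_phys, plasma_only)
  expect_gt(d_oat3, 10 * max(d_npt1, 1e-12))
  with_urine_oat3 <- calib_objective(
    c(vmax_OAT3 = cal_params$processes$OAT3$vmax * 1.5),
    cal_params, ref_phys, dsets)
  with_urine_npt1 <- calib_objective(
    c(vmax_NPT1 = cal_params$processes$NPT1$vmax * 1.5),
    cal_params, ref_phys, dsets)
  expect_gt(with_urine_npt1, d_npt1)  # urine data add NPT1 information
  expect_gt(with_urine_oat3, d_oat3)
})
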