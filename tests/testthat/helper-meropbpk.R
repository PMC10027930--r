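# Shared fixtures: parameter bundles and physiology are loaded once; all
# observed-like data are generated in code from the model itself.

tbl2_params <- load_drug_parameters(meropbpk_config("meropenem.yaml"))
cal_params <- load_drug_parameters(meropbpk_config("meropenem_calibrated.yaml"))
ref_phys <- reference_adult()

healthy_model <- function(params = cal_params, phys = ref_phys) {
  build_model(params$drug, params$processes, phys, params$conventions)
}

ckd_model <- function(egfr, stage, params = cal_params) {
  individual_model(apply_ckd(healthy_individual(), egfr, stage), params)
}

std_dialysis <- dialysis_settings(bfr_mL_min = 200, dfr_mL_min = 500,
                                  koa_mL_min = 188, session_duration_h = 4,
                                  weekly_pattern = c(0, 2, 4))

# mono-exponential reference profile (closed-form oracle input)
monoexp_profile <- function(c0, t_half, times) {
  data.frame(time_h = times,
             conc_mg_L = c0 * exp(-log(2) / t_half * times))
}

# Multiple dose levels make the saturable cell-exit capacities (NPT1,
# DPEP1) identifiable: their Km are approached at therapeutic doses, so
# the dose-dependence of the urinary split carries the absolute levels,
# while the plasma profiles pin the uptake capacity.
make_truth_datasets <- function(params = cal_params,
                                doses = c(100, 500, 2000)) {
  model <- build_model(params$drug, params$processes, ref_phys,
                       params$conventions)
  obs_t <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12)
  urine_t <- c(1, 2, 4, 8, 12, 24)
  lapply(doses, function(dose) {
    reg <- dosing_regimen(dose, 24, 0.5,
                          label = sprintf("%g mg / 30 min", dose))
    prof <- simulate_regimen(model, reg, 24, dt_out_h = 0.05)
    list(
      regimen = reg,
      observations = data.frame(
        time_h = obs_t,
        conc_mg_L = approx(prof$time_h, prof$conc_mg_L, xout = obs_t)$y),
      urine_fraction = data.frame(
        time_h = urine_t,
        fraction = approx(prof$time_h, prof$urine_mg,
                          xout = urine_t)$y / dose)
    )
  })
}
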