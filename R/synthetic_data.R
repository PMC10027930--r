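# Synthetic pseudo-observed clinical datasets: sparse sampling of model
# simulations with multiplicative log-normal observation noise and optional
# digitization jitter on the time axis. These stand in for concentration-
# time profiles digitized from published studies, so every downstream stage
# (evaluation, calibration) is testable without external data.

#' Study design for synthetic data generation
#'
#' @param regimen a [dosing_regimen()].
#' @param setting `"healthy"`, a CKD stage (3/4/5), or `"ihd"`.
#' @param sampling_h sampling grid, h.
#' @param egfr eGFR for CKD/IHD settings (defaults to the stage midpoint).
#' @param dialysis optional [dialysis_settings()] for `"ihd"`.
#' @param n_subjects nominal study size recorded in the metadata.
#' @param label study label.
#' @return An object of class `study_design`.
#' @export
study_design <- function(regimen, setting = "healthy",
                         sampling_h = c(0.25, 0.5, 1, 2, 4, 6, 8),
                         egfr = NULL, dialysis = NULL, n_subjects = 10,
                         label = NULL) {
  if (!identical(setting, "healthy") && !identical(setting, "ihd"))
    ckd_stage(setting)
  if (identical(setting, "ihd") && is.null(dialysis))
    dialysis <- dialysis_settings()
  if (is.null(egfr) && !identical(setting, "healthy")) {
    st <- ckd_stage(if (identical(setting, "ihd")) 5 else setting)
    egfr <- (st$egfr_min + st$egfr_max) / 2
  }
  if (is.null(label)) label <- paste0(setting, ": ", regimen$label)
  structure(list(regimen = regimen, setting = setting,
                 sampling_h = sort(sampling_h), egfr = egfr,
                 dialysis = dialysis, n_subjects = n_subjects,
                 label = label), class = "study_design")
}

# archetype individual for a design (no between-subject variability)
.design_individual <- function(design) {
  ind <- healthy_individual()
  if (!identical(design$setting, "healthy")) {
    stage <- if (identical(design$setting, "ihd")) 5 else design$setting
    ind <- apply_ckd(ind, design$egfr, stage)
  }
  ind
}

#' Generate one synthetic observed study
#'
#' Simulates the design through the PBPK model, samples the profile on the
#' design grid, and applies multiplicative log-normal noise (default CV
#' 15%) plus optional uniform digitization jitter on the sampling times.
#' With the noise off, the dataset equals the model prediction exactly.
#'
#' @param design a [study_design()].
#' @param params drug parameter bundle ([load_drug_parameters()]).
#' @param cv observation coefficient of variation (default 0.15).
#' @param time_jitter_h half-width of uniform time jitter, h (default 0).
#' @param seed integer seed.
#' @param horizon_h optional simulation horizon, h; defaults to covering
#'   both the regimen and the sampling grid. A grid beyond an explicit
#'   horizon is a design error.
#' @return List with `observations` (data.frame `time_h`, `conc_mg_L`),
#'   `urine_fraction` (cumulative fraction of dose at the last sample),
#'   `design`, and `meta`.
#' @export
generate_study <- function(design, params, cv = 0.15, time_jitter_h = 0,
                           seed = 1L, horizon_h = NULL) {
  set.seed(seed)
  ind <- .design_individual(design)
  model <- individual_model(ind, params)
  horizon <- horizon_h %||%
    max(design$sampling_h,
        design$regimen$start_h + design$regimen$n_doses *
          design$regimen$interval_h)
  if (max(design$sampling_h) > horizon)
    stop("design error: sampling grid outside simulation horizon",
         call. = FALSE)
  prof <- simulate_regimen(model, design$regimen, horizon,
                           dialysis = design$dialysis, dt_out_h = 0.05)
  times <- design$sampling_h
  if (time_jitter_h > 0) {
    times <- pmax(min(prof$time_h),
                  pmin(max(prof$time_h),
                       times + runif(length(times), -time_jitter_h,
                                     time_jitter_h)))
    times <- sort(times)
  }
  conc <- approx(prof$time_h, prof$conc_mg_L, xout = times)$y
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    conc <- conc * rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  dose <- design$regimen$dose_mg * design$regimen$n_doses
  fe <- approx(prof$time_h, prof$urine_mg, xout = max(times))$y / dose
  list(
    observations = data.frame(time_h = times, conc_mg_L = conc),
    urine_fraction = data.frame(time_h = max(times), fraction = fe),
    design = design,
    meta = list(label = design$label, dose_mg = design$regimen$dose_mg,
                infusion_h = design$regimen$infusion_h,
                setting = design$setting, n = design$n_subjects,
                cv = cv, seed = seed)
  )
}

#' Packaged suite of study designs
#'
#' Designs covering healthy adults (several doses and infusion durations),
#' CKD stages 3-5 (including 500 mg / 30 min and 1000 mg / 3 h), and two
#' distinct dialysis parameter settings.
#'
#' @return Named list of [study_design()]s.
#' @export
fixture_suite <- function() {
  sparse <- c(0.25, 0.5, 1, 2, 4, 6, 8)
  list(
    healthy_500_30min = study_design(
      dosing_regimen(500, 24, 0.5, label = "500 mg / 30 min"),
      "healthy", sparse),
    healthy_1000_30min = study_design(
      dosing_regimen(1000, 24, 0.5, label = "1000 mg / 30 min"),
      "healthy", sparse),
    healthy_1000_3h = study_design(
      dosing_regimen(1000, 24, 3, label = "1000 mg / 3 h"),
      "healthy", c(0.5, 1, 2, 3, 3.5, 4, 6, 8)),
    ckd3_500_30min = study_design(
      dosing_regimen(500, 24, 0.5, label = "500 mg / 30 min"),
      3, c(0.5, 1, 2, 4, 8, 12)),
    ckd4_1000_3h = study_design(
      dosing_regimen(1000, 24, 3, label = "1000 mg / 3 h"),
      4, c(1, 2, 3, 4, 6, 8, 12, 24)),
    ckd5_500_30min = study_design(
      dosing_regimen(500, 24, 0.5, label = "500 mg / 30 min"),
      5, c(0.5, 1, 2, 4, 8, 12, 24)),
    ihd_a = study_design(
      dosing_regimen(500, 24, 0.5, label = "500 mg / 30 min"),
      "ihd", c(0.5, 1, 2, 4, 6, 8, 12, 24),
      dialysis = dialysis_settings(bfr_mL_min = 200, dfr_mL_min = 500,
                                   koa_mL_min = 188,
                                   session_duration_h = 4,
                                   weekly_pattern = 0)),
    ihd_b = study_design(
      dosing_regimen(1000, 24, 0.5, label = "1000 mg / 30 min"),
      "ihd", c(0.5, 1, 2, 4, 6, 8, 12, 24),
      dialysis = dialysis_settings(bfr_mL_min = 300, dfr_mL_min = 500,
                                   koa_mL_min = 188,
                                   session_duration_h = 3.5,
                                   weekly_pattern = 0))
  )
}
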