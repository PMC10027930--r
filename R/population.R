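# Virtual individuals and populations: demographic scaling, stage-wise
# eGFR sampling, log-normal between-subject variability on
# clearance-determining parameters and on central volume.

#' Healthy archetype individual
#'
#' Wraps the reference physiology into a `virtual_individual` with unit
#' activity multipliers, ready for CKD scaling or population variability.
#'
#' @param physiology a `physiology` object, default [reference_adult()].
#' @return An object of class `virtual_individual`.
#' @export
healthy_individual <- function(physiology = reference_adult()) {
  structure(list(
    id = 1L,
    physiology = physiology,
    egfr = physiology$egfr_normalised,
    stage = NA_integer_,
    activity = c(OAT3 = 1, NPT1 = 1, DPEP1 = 1),
    vmax_multiplier = c(OAT3 = 1, NPT1 = 1, DPEP1 = 1),
    central_volume_multiplier = 1,
    vref_scale = 1
  ), class = "virtual_individual")
}

#' Population specification
#'
#' @param n number of individuals (>= 1).
#' @param stage `"healthy"` or CKD stage 3, 4 or 5. eGFR is sampled
#'   uniformly within the stage range.
#' @param cv_vmax log-normal coefficient of variation applied to each
#'   transporter/enzyme Vmax (mean-preserving), default 0.30.
#' @param cv_central_volume log-normal CV on venous+arterial plasma
#'   volume, default 0.30.
#' @param cv_weight log-normal CV on body weight (organ volumes, flows and
#'   BSA scale with weight), default 0.15.
#' @param seed integer seed recorded in the spec; sampling is reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n, stage = "healthy", cv_vmax = 0.30,
                            cv_central_volume = 0.30, cv_weight = 0.15,
                            seed = 1L) {
  if (n < 1) stop("spec error: n must be >= 1", call. = FALSE)
  if (any(c(cv_vmax, cv_central_volume, cv_weight) < 0))
    stop("spec error: CVs must be >= 0", call. = FALSE)
  if (!identical(stage, "healthy")) ckd_stage(stage)
  structure(list(n = as.integer(n), stage = stage, cv_vmax = cv_vmax,
                 cv_central_volume = cv_central_volume,
                 cv_weight = cv_weight, seed = as.integer(seed)),
            class = "population_spec")
}

# mean-preserving log-normal multiplier(s)
.ln_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# scale the archetype physiology to a body weight (isometric: volumes,
# flows and plasma volumes scale with weight; BSA via Du Bois)
.scale_physiology_weight <- function(phys, weight_kg) {
  s <- weight_kg / phys$weight_kg
  phys$organs$volume_L <- phys$organs$volume_L * s
  phys$organs$blood_flow_L_min <- phys$organs$blood_flow_L_min * s
  phys$lung_volume_L <- phys$lung_volume_L * s
  phys$cardiac_output_L_min <- phys$cardiac_output_L_min * s
  phys$kidney_blood_flow_L_min <- phys$kidney_blood_flow_L_min * s
  phys$venous_plasma_L <- phys$venous_plasma_L * s
  phys$arterial_plasma_L <- phys$arterial_plasma_L * s
  phys$kidney <- lapply(phys$kidney, `*`, s)
  phys$weight_kg <- weight_kg
  phys$bsa_m2 <- bsa_dubois(weight_kg, phys$height_cm)
  phys$gfr_mL_min <- phys$egfr_normalised * phys$bsa_m2 / 1.73
  phys
}

#' Generate a virtual population
#'
#' Reproducible under the spec's seed. For CKD stages, eGFR is sampled
#' uniformly within the stage interval and the intact-nephron and DPEP1
#' scalings applied per individual; log-normal mean-preserving variability
#' is applied to body weight, transporter/enzyme Vmax and central plasma
#' volume.
#'
#' @param spec a [population_spec()].
#' @param physiology archetype physiology, default [reference_adult()].
#' @return List of `virtual_individual` objects.
#' @export
generate_population <- function(spec, physiology = reference_adult()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n
  weights <- physiology$weight_kg * .ln_mult(n, spec$cv_weight)
  vcent <- .ln_mult(n, spec$cv_central_volume)
  m_oat3 <- .ln_mult(n, spec$cv_vmax)
  m_npt1 <- .ln_mult(n, spec$cv_vmax)
  m_dpep <- .ln_mult(n, spec$cv_vmax)
  egfrs <- if (identical(spec$stage, "healthy")) {
    rep(physiology$egfr_normalised, n)
  } else {
    st <- ckd_stage(spec$stage)
    runif(n, st$egfr_min, st$egfr_max)
  }
  lapply(seq_len(n), function(i) {
    ind <- healthy_individual(
      .scale_physiology_weight(physiology, weights[i]))
    ind$id <- i
    ind$vmax_multiplier <- c(OAT3 = m_oat3[i], NPT1 = m_npt1[i],
                             DPEP1 = m_dpep[i])
    ind$central_volume_multiplier <- vcent[i]
    if (!identical(spec$stage, "healthy")) {
      ind <- apply_ckd(ind, egfrs[i], spec$stage)
    }
    ind
  })
}

#' Build the PBPK model for one virtual individual
#'
#' Applies the individual's activity multipliers, Vmax variability,
#' central-volume multiplier and secretory-volume scale to the drug model.
#'
#' @param individual a `virtual_individual`.
#' @param params drug parameter bundle from [load_drug_parameters()].
#' @return A `pbpk_model`.
#' @export
individual_model <- function(individual, params) {
  procs <- params$processes
  for (nm in names(procs)) {
    act <- individual$activity[[nm]] %||% 1
    procs[[nm]]$activity_multiplier <-
      min(1, procs[[nm]]$activity_multiplier * act)
    procs[[nm]]$vmax <- procs[[nm]]$vmax *
      (individual$vmax_multiplier[[nm]] %||% 1)
  }
  phys <- individual$physiology
  phys$venous_plasma_L <- phys$venous_plasma_L *
    individual$central_volume_multiplier
  phys$arterial_plasma_L <- phys$arterial_plasma_L *
    individual$central_volume_multiplier
  conv <- params$conventions
  conv$vmax_reference_volume_L <- conv$vmax_reference_volume_L *
    individual$vref_scale
  build_model(params$drug, procs, phys, conv)
}

#' Population dump as a data.frame
#'
#' One row per individual with the sampled parameters, suitable for CSV
#' export.
#'
#' @param population list of `virtual_individual`s.
#' @return data.frame.
#' @export
population_table <- function(population) {
  do.call(rbind, lapply(population, function(ind) {
    data.frame(id = ind$id, weight_kg = ind$physiology$weight_kg,
               egfr = ind$egfr, stage = ind$stage,
               gfr_mL_min = ind$physiology$gfr_mL_min,
               act_oat3 = ind$activity[["OAT3"]],
               act_npt1 = ind$activity[["NPT1"]],
               act_dpep1 = ind$activity[["DPEP1"]],
               mult_vmax_oat3 = ind$vmax_multiplier[["OAT3"]],
               mult_vmax_npt1 = ind$vmax_multiplier[["NPT1"]],
               mult_vmax_dpep1 = ind$vmax_multiplier[["DPEP1"]],
               central_volume_multiplier = ind$central_volume_multiplier)
  }))
}
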