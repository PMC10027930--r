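# CKD scaling: intact nephron hypothesis for transporters, DPEP1
# down-regulation, and minimal pathophysiology deltas (kidney volume and
# renal blood flow follow the eGFR ratio).

EGFR_NORMAL <- 106.78  # mL/min/1.73 m2, reference adult male

.ckd_stage_table <- list(
  "3" = list(stage = 3L, egfr_min = 31, egfr_max = 60, dpep1_factor = 0.69),
  "4" = list(stage = 4L, egfr_min = 16, egfr_max = 30, dpep1_factor = 0.64),
  "5" = list(stage = 5L, egfr_min = 1,  egfr_max = 15, dpep1_factor = 0.64)
)

#' CKD stage definition
#'
#' @param stage 3, 4 or 5.
#' @return List with `stage`, eGFR range (mL/min/1.73 m^2) and the DPEP1
#'   down-regulation factor: stage 3 \[31, 60\] and 0.69; stage 4
#'   \[16, 30\] and 0.64; stage 5 \[1, 15\] and 0.64.
#' @export
ckd_stage <- function(stage) {
  key <- as.character(stage)
  if (!key %in% names(.ckd_stage_table))
    stop("domain error: CKD stage must be 3, 4 or 5", call. = FALSE)
  .ckd_stage_table[[key]]
}

#' Transporter scaling factor (intact nephron hypothesis)
#'
#' Renal secretory transporter activity scales proportionally with the
#' impaired filtration rate: `egfr_ckd / 106.78`. Applied identically to
#' the OAT3 and NPT1 activity multipliers.
#'
#' @param egfr_ckd eGFR, mL/min/1.73 m^2 (> 0).
#' @return Unitless factor.
#' @export
transporter_scaling_factor <- function(egfr_ckd) {
  if (any(!is.finite(egfr_ckd)) || any(egfr_ckd <= 0))
    stop("domain error: eGFR must be > 0", call. = FALSE)
  egfr_ckd / EGFR_NORMAL
}

#' DPEP1 scaling factor per CKD stage
#'
#' Renal dehydropeptidase-1 expression falls to 69% of healthy in stage 3
#' and to 64% in stages 4 and 5.
#'
#' @param stage 3, 4 or 5.
#' @return Unitless factor.
#' @export
dpep1_scaling_factor <- function(stage) {
  ckd_stage(stage)$dpep1_factor
}

#' Apply CKD pathophysiology to a healthy individual
#'
#' Sets the absolute GFR from `egfr * BSA / 1.73` (Du Bois BSA), scales the
#' OAT3/NPT1 activity multipliers by the intact-nephron factor, applies the
#' stage-specific DPEP1 factor, and applies the documented pathophysiology
#' deltas: kidney volume (and with it the secretory reference volume) and
#' renal blood flow are reduced by the eGFR ratio. Cardiac output is kept
#' by returning the renal flow difference to the lumped `rest` compartment.
#'
#' @param individual a `virtual_individual` (see [healthy_individual()]).
#' @param egfr_ckd eGFR, mL/min/1.73 m^2; must lie in the stage's range.
#' @param stage CKD stage 3, 4 or 5.
#' @return The scaled `virtual_individual` with a `scaling` element
#'   recording the factors applied.
#' @export
apply_ckd <- function(individual, egfr_ckd, stage) {
  st <- ckd_stage(stage)
  if (egfr_ckd < st$egfr_min || egfr_ckd > st$egfr_max)
    stop("consistency error: eGFR ", egfr_ckd,
         " outside stage ", st$stage, " range [", st$egfr_min, ", ",
         st$egfr_max, "]", call. = FALSE)
  f <- transporter_scaling_factor(egfr_ckd)
  phys <- individual$physiology
  delta_flow <- phys$kidney_blood_flow_L_min * (1 - f)
  phys$kidney_blood_flow_L_min <- phys$kidney_blood_flow_L_min * f
  # conserve cardiac output through the lumped rest compartment
  i_rest <- phys$organs$organ == "rest"
  phys$organs$blood_flow_L_min[i_rest] <-
    phys$organs$blood_flow_L_min[i_rest] + delta_flow
  phys$kidney$volume_L <- phys$kidney$volume_L * f
  phys$kidney$plasma_L <- phys$kidney$plasma_L * f
  phys$kidney$tubule_cell_L <- phys$kidney$tubule_cell_L * f
  phys$kidney$lumen_L <- phys$kidney$lumen_L * f
  phys$gfr_mL_min <- egfr_ckd * phys$bsa_m2 / 1.73
  individual$physiology <- phys
  individual$egfr <- egfr_ckd
  individual$stage <- st$stage
  individual$activity <- c(
    OAT3 = unname(individual$activity[["OAT3"]] * f),
    NPT1 = unname(individual$activity[["NPT1"]] * f),
    DPEP1 = unname(individual$activity[["DPEP1"]] * st$dpep1_factor)
  )
  # transporter capacity also falls with the shrinking secretory volume
  individual$vref_scale <- individual$vref_scale * f
  individual$scaling <- list(
    transporter_scaling_factor = f,
    dpep1_scaling_factor = st$dpep1_factor,
    gfr_mL_min = phys$gfr_mL_min,
    kidney_volume_factor = f,
    renal_flow_factor = f
  )
  individual
}
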