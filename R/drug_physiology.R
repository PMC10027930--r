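#' @useDynLib meropbpk, .registration = TRUE
#' @importFrom stats approx median optimize rlnorm rnorm runif setNames
#' @importFrom utils head tail modifyList read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

# Internal units everywhere below the I/O surface: umol/L, L, min.
# External I/O: mg/L and hours, converted with the molecular weight.

.unit_to_uM <- c("uM" = 1, "umol/L" = 1, "mM" = 1000, "M" = 1e6)

.normalise_value <- function(x, kind, key) {
  if (is.list(x)) {
    v <- x$value
    u <- x$unit %||% ""
  } else {
    v <- x
    u <- ""
  }
  if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
    stop("configuration error: field '", key, "' is not a single number",
         call. = FALSE)
  }
  switch(kind,
    conc = {
      if (u == "") u <- "uM"
      if (!u %in% names(.unit_to_uM)) {
        stop("configuration error: unknown concentration unit '", u,
             "' for '", key, "'", call. = FALSE)
      }
      v * .unit_to_uM[[u]]
    },
    fraction = if (identical(u, "percent")) v / 100 else v,
    plain = v
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drug-specific input parameters
#'
#' Container for the physicochemical and binding parameters that drive
#' tissue distribution and renal handling: molecular weight, acid/base pKa,
#' lipophilicity (logP), aqueous solubility, fraction unbound in plasma and
#' the glomerular-filtration fraction of unbound drug.
#'
#' @param molecular_weight g/mol.
#' @param pka_acid,pka_base acid and base dissociation constants (unitless).
#' @param logP octanol:water partition coefficient (log10).
#' @param water_solubility mg/mL.
#' @param fu fraction unbound in plasma, in (0, 1].
#' @param binding_partner one of `"albumin"`, `"AGP"`, `"none"`.
#' @param gfr_fraction unitless multiplier on glomerular filtration of
#'   unbound drug (>= 0).
#' @param name drug name label.
#' @return An object of class `drug_parameters`.
#' @export
drug_parameters <- function(molecular_weight, pka_acid, pka_base, logP,
                            water_solubility, fu,
                            binding_partner = c("albumin", "AGP", "none"),
                            gfr_fraction = 1, name = "drug") {
  binding_partner <- match.arg(binding_partner)
  if (!is.finite(molecular_weight) || molecular_weight <= 0)
    stop("validation error: molecular_weight must be > 0", call. = FALSE)
  if (!is.finite(fu) || fu <= 0 || fu > 1)
    stop("validation error: fu must be in (0, 1]", call. = FALSE)
  if (!is.finite(gfr_fraction) || gfr_fraction < 0)
    stop("validation error: gfr_fraction must be >= 0", call. = FALSE)
  structure(list(
    name = name, molecular_weight = molecular_weight,
    pka_acid = pka_acid, pka_base = pka_base, logP = logP,
    water_solubility = water_solubility, fu = fu,
    binding_partner = binding_partner, gfr_fraction = gfr_fraction
  ), class = "drug_parameters")
}

#' Michaelis-Menten transport or metabolic process
#'
#' One saturable renal process: OAT3 (basolateral uptake into the proximal
#' tubule cell), NPT1 (apical efflux into the tubular lumen) or DPEP1
#' (intracellular metabolism). `vmax` is referenced to the configurable
#' secretory reference volume (see [load_drug_parameters()]); the activity
#' multiplier is the handle used by disease scaling and inhibition.
#'
#' @param name `"DPEP1"`, `"OAT3"` or `"NPT1"`.
#' @param km Michaelis constant, umol/L (> 0).
#' @param vmax maximum rate, umol/L/min referenced to the secretory
#'   reference volume (>= 0).
#' @param direction one of `"uptake_basolateral"`, `"efflux_apical"`,
#'   `"metabolism_intracellular"`.
#' @param activity_multiplier unitless, in \[0, 1\]; default 1.
#' @return An object of class `mm_process`.
#' @export
mm_process <- function(name = c("DPEP1", "OAT3", "NPT1"), km, vmax,
                       direction = c("uptake_basolateral", "efflux_apical",
                                     "metabolism_intracellular"),
                       activity_multiplier = 1) {
  name <- match.arg(name)
  direction <- match.arg(direction)
  if (!is.finite(km) || km <= 0)
    stop("validation error: km must be > 0 (", name, ")", call. = FALSE)
  if (!is.finite(vmax) || vmax < 0)
    stop("validation error: vmax must be >= 0 (", name, ")", call. = FALSE)
  if (!is.finite(activity_multiplier) || activity_multiplier < 0 ||
      activity_multiplier > 1)
    stop("validation error: activity_multiplier must be in [0, 1]",
         call. = FALSE)
  structure(list(name = name, km = km, vmax = vmax, direction = direction,
                 activity_multiplier = activity_multiplier),
            class = "mm_process")
}

#' Load drug parameters from a YAML configuration
#'
#' Reads a drug parameter file, validates all mandatory keys, normalises
#' units to internal units (umol/L, L, min) and returns the drug object,
#' the list of Michaelis-Menten processes and the model conventions
#' (secretory reference volume, lumen drain rate).
#'
#' @param path path to a YAML file; see the packaged `meropenem.yaml` for
#'   the schema.
#' @return A list with elements `drug` ([drug_parameters()]), `processes`
#'   (named list of [mm_process()]), and `conventions`.
#' @export
load_drug_parameters <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("drug", "processes", "conventions")) {
    if (is.null(cfg[[key]]))
      stop("configuration error: missing key '", key, "'", call. = FALSE)
  }
  d <- cfg$drug
  mandatory <- c("molecular_weight", "pka_acid", "pka_base", "logP",
                 "water_solubility", "fu", "binding_partner", "gfr_fraction")
  miss <- setdiff(mandatory, names(d))
  if (length(miss))
    stop("configuration error: missing key '", miss[1], "'", call. = FALSE)
  drug <- drug_parameters(
    molecular_weight = .normalise_value(d$molecular_weight, "plain",
                                        "molecular_weight"),
    pka_acid = .normalise_value(d$pka_acid, "plain", "pka_acid"),
    pka_base = .normalise_value(d$pka_base, "plain", "pka_base"),
    logP = .normalise_value(d$logP, "plain", "logP"),
    water_solubility = .normalise_value(d$water_solubility, "plain",
                                        "water_solubility"),
    fu = .normalise_value(d$fu, "fraction", "fu"),
    binding_partner = d$binding_partner,
    gfr_fraction = .normalise_value(d$gfr_fraction, "plain", "gfr_fraction"),
    name = d$name %||% "drug"
  )
  processes <- lapply(cfg$processes, function(pr) {
    for (key in c("name", "km", "vmax", "direction")) {
      if (is.null(pr[[key]]))
        stop("configuration error: missing key '", key, "' in process",
             call. = FALSE)
    }
    mm_process(
      name = pr$name,
      km = .normalise_value(pr$km, "conc", paste0(pr$name, ".km")),
      vmax = .normalise_value(pr$vmax, "plain", paste0(pr$name, ".vmax")),
      direction = pr$direction,
      activity_multiplier = pr$activity_multiplier %||% 1
    )
  })
  names(processes) <- vapply(processes, `[[`, "", "name")
  conv <- cfg$conventions
  if (is.null(conv$vmax_reference_volume_L))
    stop("configuration error: missing key 'vmax_reference_volume_L'",
         call. = FALSE)
  conventions <- list(
    vmax_reference_volume_L = conv$vmax_reference_volume_L,
    lumen_drain_per_min = conv$lumen_drain_per_min %||% 0.12
  )
  list(drug = drug, processes = processes, conventions = conventions)
}

#' Serialize drug parameters back to YAML
#'
#' Inverse of [load_drug_parameters()] (values written in internal units);
#' loading the result reproduces the parameter set.
#'
#' @param params list as returned by [load_drug_parameters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drug_parameters <- function(params, path) {
  d <- params$drug
  cfg <- list(
    drug = list(
      name = d$name,
      molecular_weight = d$molecular_weight,
      pka_acid = d$pka_acid, pka_base = d$pka_base, logP = d$logP,
      water_solubility = d$water_solubility,
      binding_partner = d$binding_partner,
      fu = d$fu, gfr_fraction = d$gfr_fraction
    ),
    processes = lapply(unname(params$processes), function(pr) {
      list(name = pr$name, direction = pr$direction,
           km = list(value = pr$km, unit = "uM"),
           vmax = list(value = pr$vmax, unit = "umol/L/min"),
           activity_multiplier = pr$activity_multiplier)
    }),
    conventions = params$conventions
  )
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' Path to a packaged configuration file
#'
#' @param file file name under the package's `extdata` directory, e.g.
#'   `"meropenem.yaml"`.
#' @return Absolute path.
#' @export
meropbpk_config <- function(file) {
  p <- system.file("extdata", file, package = "meropbpk")
  if (!nzchar(p))
    stop("configuration error: packaged file not found: ", file,
         call. = FALSE)
  p
}

# ---- reference physiology ---------------------------------------------------

.organ_names <- c("heart", "brain", "muscle", "adipose", "skin", "bone",
                  "liver", "gut", "spleen", "rest")

# Tissue composition fractions (total water, extracellular water, neutral
# lipid, phospholipid) from standard tissue-composition compilations used by
# perfusion-limited distribution models.
.tissue_composition <- data.frame(
  organ = c("lung", .organ_names),
  fw  = c(0.811, 0.758, 0.770, 0.760, 0.180, 0.718, 0.439, 0.751, 0.718,
          0.788, 0.760),
  few = c(0.336, 0.320, 0.162, 0.118, 0.135, 0.382, 0.100, 0.161, 0.282,
          0.207, 0.200),
  fnl = c(0.0030, 0.0115, 0.0510, 0.0238, 0.7900, 0.0284, 0.0740, 0.0348,
          0.0487, 0.0201, 0.0200),
  fph = c(0.0090, 0.0166, 0.0565, 0.0072, 0.0020, 0.0111, 0.0011, 0.0252,
          0.0163, 0.0198, 0.0100)
)
# plasma composition
.plasma_comp <- list(fw = 0.945, fnl = 0.0035, fph = 0.00225)

#' Body surface area (Du Bois)
#'
#' @param weight_kg body weight, kg.
#' @param height_cm height, cm.
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Reference adult male physiology
#'
#' Organ volumes, blood flows, blood/plasma volumes and kidney sub-volumes
#' for the 30-year, 176 cm, 73 kg reference male, compiled from standard
#' physiology tables. The absolute GFR corresponds to an eGFR of
#' 106.78 mL/min/1.73 m^2 after Du Bois body-surface-area conversion.
#'
#' @return An object of class `physiology` with organ table (volumes in L,
#'   blood flows in L/min), hematocrit, blood volumes, kidney sub-volumes,
#'   GFR (mL/min), demographics and BSA.
#' @export
reference_adult <- function() {
  co_blood <- 6.5 # L/min
  organs <- data.frame(
    organ = .organ_names,
    volume_L = c(0.33, 1.45, 29.0, 14.5, 3.3, 10.5, 1.8, 1.2, 0.15, 5.0),
    blood_flow_L_min = co_blood *
      c(0.04, 0.12, 0.17, 0.05, 0.05, 0.05, 0.065, 0.15, 0.03, 0.085)
  )
  # close the flow balance exactly on the 'rest' compartment
  organs$blood_flow_L_min[organs$organ == "rest"] <-
    co_blood - sum(organs$blood_flow_L_min[organs$organ != "rest"]) -
    co_blood * 0.19 # kidney share
  weight <- 73; height <- 176
  bsa <- bsa_dubois(weight, height)
  egfr <- 106.78
  phys <- structure(list(
    organs = organs,
    lung_volume_L = 0.53,
    cardiac_output_L_min = co_blood,
    kidney_blood_flow_L_min = co_blood * 0.19,
    hematocrit = 0.45,
    venous_plasma_L = 2.17,
    arterial_plasma_L = 0.73,
    kidney = list(volume_L = 0.31, plasma_L = 0.055,
                  tubule_cell_L = 0.06, lumen_L = 0.025),
    gfr_mL_min = egfr * bsa / 1.73,
    egfr_normalised = egfr,
    age = 30, weight_kg = weight, height_cm = height, bsa_m2 = bsa,
    sex = "male"
  ), class = "physiology")
  validate_physiology(phys)
  phys
}

#' Validate a physiology object
#'
#' Checks positivity of all volumes and flows and that organ blood flows
#' (including renal) sum to cardiac output within 1e-6 relative.
#'
#' @param phys a `physiology` object.
#' @return `phys`, invisibly; errors on violation.
#' @export
validate_physiology <- function(phys) {
  vols <- c(phys$organs$volume_L, phys$lung_volume_L, phys$venous_plasma_L,
            phys$arterial_plasma_L, unlist(phys$kidney))
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("physiology validation: all volumes must be > 0", call. = FALSE)
  flows <- c(phys$organs$blood_flow_L_min, phys$kidney_blood_flow_L_min)
  if (any(!is.finite(flows)) || any(flows <= 0))
    stop("physiology validation: all flows must be > 0", call. = FALSE)
  rel <- abs(sum(flows) - phys$cardiac_output_L_min) /
    phys$cardiac_output_L_min
  if (rel > 1e-6)
    stop("physiology validation: organ flows do not sum to cardiac output ",
         "(relative error ", format(rel), ")", call. = FALSE)
  if (phys$gfr_mL_min < 0)
    stop("physiology validation: gfr must be >= 0", call. = FALSE)
  invisible(phys)
}

#' Neutral fraction at plasma pH
#'
#' Henderson-Hasselbalch neutral (un-ionised) fraction for an ampholyte
#' with one acidic and one basic pKa at the given pH.
#'
#' @param pka_acid,pka_base dissociation constants; `NA` disables the term.
#' @param ph pH (default 7.4).
#' @return Fraction neutral, in (0, 1].
#' @export
neutral_fraction <- function(pka_acid, pka_base, ph = 7.4) {
  acid <- if (is.na(pka_acid)) 0 else 10^(ph - pka_acid)
  base <- if (is.na(pka_base)) 0 else 10^(pka_base - ph)
  1 / (1 + acid + base)
}

#' Tissue:plasma partition coefficients
#'
#' Perfusion-limited distribution coefficients from a tissue-composition
#' homogenate scheme of the Poulin-Theil type with an ionisation
#' restriction: the neutral species at pH 7.4 equilibrates with total
#' tissue water and tissue lipids (neutral lipid weighted by P, 30% of
#' phospholipid by P, 70% as water-like), while the ionised species is
#' restricted to extracellular water. For meropenem, which is almost fully
#' ionised at plasma pH, the coefficients approach the extracellular-water
#' fractions, matching its extracellular distribution volume.
#'
#' @param drug a [drug_parameters()] object (`fu` must be > 0).
#' @param physiology a `physiology` object (used only for the organ list;
#'   the coefficients are independent of organ volumes).
#' @return Named vector of positive tissue:plasma coefficients, one per
#'   organ plus `lung` and `kidney`.
#' @export
partition_coefficients <- function(drug, physiology) {
  if (drug$fu <= 0)
    stop("fu must be > 0 for unbound scaling", call. = FALSE)
  fn <- neutral_fraction(drug$pka_acid, drug$pka_base)
  P <- 10^drug$logP
  pc <- .plasma_comp
  denom <- fn * P * (pc$fnl + 0.3 * pc$fph) + pc$fw + 0.7 * pc$fph
  tc <- .tissue_composition
  kp <- drug$fu * (fn * P * (tc$fnl + 0.3 * tc$fph) +
                   fn * (tc$fw - tc$few) + tc$few + 0.7 * tc$fph) / denom
  names(kp) <- tc$organ
  # kidney coefficient from its composition row is used for the lumped
  # kidney compartment's apparent volume
  kidney_row <- data.frame(fw = 0.783, few = 0.273, fnl = 0.0207,
                           fph = 0.0162)
  kp_kid <- drug$fu * (fn * P * (kidney_row$fnl + 0.3 * kidney_row$fph) +
                       fn * (kidney_row$fw - kidney_row$few) +
                       kidney_row$few + 0.7 * kidney_row$fph) / denom
  c(kp, kidney = unname(kp_kid))
}
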