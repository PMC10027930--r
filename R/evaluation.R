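# Model qualification metrics (MRD, GMFE, two-fold classification) and
# local sensitivity analysis of AUC_last.

.check_pairs <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L)
    stop("metric error: predicted and observed must be equal-length, ",
         "non-empty", call. = FALSE)
  if (any(predicted <= 0) || any(observed <= 0))
    stop("metric error: log-domain metrics need strictly positive values; ",
         "pre-filter non-positive observations (filter rule must be logged)",
         call. = FALSE)
}

#' Mean relative deviation of concentration predictions
#'
#' `MRD = 10^x` with `x = sqrt( sum( (log10 c_pred - log10 c_obs)^2 ) / m )`.
#' Always >= 1; equals 1 iff all predictions match the observations.
#'
#' @param predicted,observed positive concentration vectors of equal
#'   length `m`.
#' @return Unitless MRD.
#' @export
mrd <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  10^sqrt(mean((log10(predicted) - log10(observed))^2))
}

#' Geometric mean fold error of PK parameters
#'
#' `GMFE = 10^x` with `x = sum( |log10(pred_i / obs_i)| ) / n`. Symmetric
#' in over- and under-prediction; >= 1 with equality iff exact.
#'
#' @param predicted,observed positive parameter vectors of equal length.
#' @return Unitless GMFE.
#' @export
gmfe <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' Fraction of predictions within two-fold of observations
#'
#' Boundary-inclusive fraction of pairs with `pred/obs` in \[0.5, 2\]. The
#' adequacy threshold used for MRD/GMFE interpretation is exposed as
#' [fold_error_threshold()].
#'
#' @param predicted,observed positive vectors of equal length.
#' @return Fraction in \[0, 1\].
#' @export
two_fold_fraction <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  r <- predicted / observed
  mean(r >= 0.5 & r <= 2.0)
}

#' Adequacy threshold for MRD and GMFE
#'
#' MRD and GMFE values at or below this constant (2.0) are interpreted as
#' adequate model performance.
#'
#' @return 2.0
#' @export
fold_error_threshold <- function() 2.0

#' Pooled or per-study-averaged metric over multiple studies
#'
#' @param studies list of data.frames with `predicted` and `observed`
#'   columns.
#' @param metric `"mrd"` or `"gmfe"`.
#' @param mode `"pooled"` (all pairs together, default) or `"per_study"`
#'   (average of per-study metric values).
#' @return List with `value` and the `mode` recorded.
#' @export
overall_metric <- function(studies, metric = c("mrd", "gmfe"),
                           mode = c("pooled", "per_study")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  f <- if (metric == "mrd") mrd else gmfe
  value <- if (mode == "pooled") {
    pred <- unlist(lapply(studies, `[[`, "predicted"))
    obs <- unlist(lapply(studies, `[[`, "observed"))
    f(pred, obs)
  } else {
    mean(vapply(studies, function(s) f(s$predicted, s$observed), 0))
  }
  list(value = value, metric = metric, mode = mode,
       n_studies = length(studies))
}

# Perturbable parameters for the sensitivity analysis: each entry applies a
# multiplicative factor to one model input.
.perturb_model_input <- function(params, physiology, which, factor) {
  switch(which,
    logP = { params$drug$logP <- params$drug$logP * factor },
    fu = { params$drug$fu <- min(1, params$drug$fu * factor) },
    gfr_fraction = {
      params$drug$gfr_fraction <- params$drug$gfr_fraction * factor },
    gfr = { physiology$gfr_mL_min <- physiology$gfr_mL_min * factor },
    vmax_OAT3 = { params$processes$OAT3$vmax <-
      params$processes$OAT3$vmax * factor },
    vmax_NPT1 = { params$processes$NPT1$vmax <-
      params$processes$NPT1$vmax * factor },
    vmax_DPEP1 = { params$processes$DPEP1$vmax <-
      params$processes$DPEP1$vmax * factor },
    km_OAT3 = { params$processes$OAT3$km <-
      params$processes$OAT3$km * factor },
    kidney_volume = {
      # organ size carries transporter expression with it
      physiology$kidney <- lapply(physiology$kidney, `*`, factor)
      params$conventions$vmax_reference_volume_L <-
        params$conventions$vmax_reference_volume_L * factor
    },
    renal_blood_flow = {
      delta <- physiology$kidney_blood_flow_L_min * (factor - 1)
      physiology$kidney_blood_flow_L_min <-
        physiology$kidney_blood_flow_L_min * factor
      i <- physiology$organs$organ == "rest"
      physiology$organs$blood_flow_L_min[i] <-
        physiology$organs$blood_flow_L_min[i] - delta
    },
    bone_volume = {
      i <- physiology$organs$organ == "bone"
      physiology$organs$volume_L[i] <-
        physiology$organs$volume_L[i] * factor
    },
    stop("unknown sensitivity parameter: ", which, call. = FALSE)
  )
  list(params = params, physiology = physiology)
}

#' Local sensitivity of AUC_last to model parameters
#'
#' Normalised local sensitivity `S = (dAUC/AUC) / (dp/p)` by central
#' difference with a relative step (default 10%), for a 500 mg / 30 min
#' infusion unless another regimen is supplied. A failed perturbed
#' simulation is reported as `NA` for that parameter, not as an error.
#'
#' @param params drug parameter bundle ([load_drug_parameters()]).
#' @param physiology a `physiology` object.
#' @param parameters character vector of parameter names; see Details.
#' @param rel_step relative perturbation (default 0.1).
#' @param regimen a [dosing_regimen()]; default 500 mg over 30 min.
#' @param t_end_h AUC horizon, h.
#' @details Supported parameters: `logP`, `fu`, `gfr_fraction`, `gfr`,
#'   `vmax_OAT3`, `vmax_NPT1`, `vmax_DPEP1`, `km_OAT3`, `kidney_volume`,
#'   `renal_blood_flow`, `bone_volume`.
#' @return data.frame with `parameter` and `sensitivity`.
#' @export
sensitivity_analysis <- function(params, physiology,
                                 parameters = c("logP", "fu", "gfr",
                                                "vmax_OAT3", "vmax_NPT1",
                                                "vmax_DPEP1",
                                                "kidney_volume",
                                                "renal_blood_flow"),
                                 rel_step = 0.1,
                                 regimen = dosing_regimen(500, 24, 0.5),
                                 t_end_h = 24) {
  run_auc <- function(pp, ph) {
    model <- build_model(pp$drug, pp$processes, ph, pp$conventions)
    auc_last(simulate_regimen(model, regimen, t_end_h))
  }
  auc0 <- run_auc(params, physiology)
  sens <- vapply(parameters, function(w) {
    tryCatch({
      up <- .perturb_model_input(params, physiology, w, 1 + rel_step)
      dn <- .perturb_model_input(params, physiology, w, 1 - rel_step)
      (run_auc(up$params, up$physiology) -
         run_auc(dn$params, dn$physiology)) / (2 * rel_step * auc0)
    }, error = function(e) NA_real_)
  }, 0)
  data.frame(parameter = parameters, sensitivity = unname(sens))
}
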