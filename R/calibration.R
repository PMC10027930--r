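# Seeded Monte-Carlo parameter identification: random search with local
# Gaussian refinement in log-parameter space, minimising squared
# log-residuals of plasma concentrations plus weighted squared deviations
# of the urinary excretion fraction.

.apply_candidate <- function(params, candidate) {
  for (nm in names(candidate)) {
    v <- candidate[[nm]]
    switch(nm,
      logP = { params$drug$logP <- v },
      vmax_OAT3 = { params$processes$OAT3$vmax <- v },
      vmax_NPT1 = { params$processes$NPT1$vmax <- v },
      vmax_DPEP1 = { params$processes$DPEP1$vmax <- v },
      stop("unknown calibration parameter: ", nm, call. = FALSE)
    )
  }
  params
}

#' Calibration objective
#'
#' Simulates every dataset design under the candidate parameters and
#' returns the scalar loss: the sum of squared log10 plasma-concentration
#' residuals, plus `urine_weight` times the squared deviation of the
#' simulated cumulative urinary fraction from each dataset's target (at
#' the dataset's reference time). A failed simulation contributes a large
#' penalty instead of aborting the search.
#'
#' @param candidate named numeric vector; supported names `logP`,
#'   `vmax_OAT3`, `vmax_NPT1`, `vmax_DPEP1`.
#' @param params baseline drug parameter bundle.
#' @param physiology a `physiology` object.
#' @param datasets list of datasets, each a list with `regimen`
#'   ([dosing_regimen()]), optional `observations` (data.frame `time_h`,
#'   `conc_mg_L`), optional `urine_fraction` (data.frame `time_h`,
#'   `fraction`), and optional `oat3_activity` (scalar multiplier,
#'   e.g. 0 for the fully inhibited arm).
#' @param urine_weight weight on the urinary-fraction residuals
#'   (default 50; plasma residuals are per-point).
#' @param t_end_h simulation horizon per dataset, h.
#' @param penalty loss assigned to a failed simulation.
#' @return Scalar loss.
#' @export
calib_objective <- function(candidate, params, physiology, datasets,
                            urine_weight = 50, t_end_h = 24,
                            penalty = 1e6) {
  params <- .apply_candidate(params, candidate)
  loss <- 0
  for (ds in datasets) {
    l <- tryCatch({
      procs <- params$processes
      if (!is.null(ds$oat3_activity))
        procs$OAT3$activity_multiplier <- ds$oat3_activity
      model <- build_model(params$drug, procs, physiology,
                           params$conventions)
      prof <- simulate_regimen(model, ds$regimen, t_end_h,
                               dt_out_h = 0.1, rtol = 1e-6, atol = 1e-8)
      li <- 0
      if (!is.null(ds$observations)) {
        pred <- approx(prof$time_h, prof$conc_mg_L,
                       xout = ds$observations$time_h)$y
        keep <- pred > 0 & ds$observations$conc_mg_L > 0
        li <- li + sum((log10(pred[keep]) -
                          log10(ds$observations$conc_mg_L[keep]))^2)
      }
      if (!is.null(ds$urine_fraction)) {
        dose <- ds$regimen$dose_mg * ds$regimen$n_doses
        fe_sim <- approx(prof$time_h, prof$urine_mg,
                         xout = ds$urine_fraction$time_h)$y / dose
        li <- li + urine_weight *
          sum((fe_sim - ds$urine_fraction$fraction)^2)
      }
      li
    }, error = function(e) penalty)
    loss <- loss + l
  }
  loss
}

#' Monte-Carlo parameter identification
#'
#' Seeded random search within box bounds (uniform in log space), followed
#' by local Gaussian refinement around the incumbent with a shrinking step.
#' Reproducible under the seed.
#'
#' @param params baseline drug parameter bundle.
#' @param physiology a `physiology` object.
#' @param datasets see [calib_objective()].
#' @param bounds named list of `c(lower, upper)` per fitted parameter
#'   (finite, positive for Vmax entries).
#' @param budget total number of objective evaluations (>= 1).
#' @param seed integer seed.
#' @param ... passed to [calib_objective()].
#' @return List with `par` (best candidate), `loss`, `trace` (data.frame
#'   of evaluated candidates and losses), and `urinary_fraction_24h` of
#'   the optimum for the first dataset's regimen.
#' @export
calib_fit <- function(params, physiology, datasets, bounds, budget = 200,
                      seed = 1L, ...) {
  if (budget < 1) stop("fit error: budget must be >= 1", call. = FALSE)
  if (!length(bounds)) stop("fit error: no parameters to fit",
                            call. = FALSE)
  lo <- vapply(bounds, `[`, 0, 1); hi <- vapply(bounds, `[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi) ||
      any(lo <= 0))
    stop("fit error: bounds must be finite with 0 < lower < upper",
         call. = FALSE)
  set.seed(seed)
  nm <- names(bounds)
  n_explore <- max(1L, ceiling(budget * 0.5))
  cand <- matrix(NA_real_, nrow = budget, ncol = length(nm),
                 dimnames = list(NULL, nm))
  losses <- numeric(budget)
  llo <- log(lo); lhi <- log(hi)
  best <- NULL; best_loss <- Inf
  for (i in seq_len(budget)) {
    x <- if (i <= n_explore || is.null(best)) {
      exp(runif(length(nm), llo, lhi))
    } else {
      frac <- (i - n_explore) / (budget - n_explore)
      sd <- (lhi - llo) * 0.25 * (1 - 0.9 * frac)
      exp(pmin(pmax(log(best) + rnorm(length(nm), 0, sd), llo), lhi))
    }
    names(x) <- nm
    li <- calib_objective(x, params, physiology, datasets, ...)
    cand[i, ] <- x; losses[i] <- li
    if (li < best_loss) { best <- x; best_loss <- li }
  }
  if (!is.finite(best_loss) || best_loss >= 1e6 * length(datasets))
    stop("fit error: no successful simulation within budget",
         call. = FALSE)
  fitted <- .apply_candidate(params, best)
  model <- build_model(fitted$drug, fitted$processes, physiology,
                       fitted$conventions)
  reg <- datasets[[1]]$regimen
  prof <- simulate_regimen(model, reg, 24, dt_out_h = 0.25)
  fe24 <- prof$urine_mg[nrow(prof)] / (reg$dose_mg * reg$n_doses)
  list(par = best, loss = best_loss,
       trace = data.frame(cand, loss = losses),
       urinary_fraction_24h = fe24)
}
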