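# Whole-body PBPK core: model assembly, piecewise stiff integration across
# infusion and dialysis discontinuities, mass balance accounting.

#' Intravenous dosing regimen
#'
#' @param dose_mg dose per administration, mg (> 0; 0 allowed for the
#'   no-dose limit).
#' @param interval_h dosing interval, h.
#' @param infusion_h infusion duration, h; must satisfy
#'   `0 < infusion_h <= interval_h`.
#' @param n_doses number of administrations.
#' @param start_h time of the first infusion start, h.
#' @param label text label.
#' @return An object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(dose_mg, interval_h, infusion_h, n_doses = 1,
                           start_h = 0, label = NULL) {
  if (!is.finite(dose_mg) || dose_mg < 0)
    stop("validation error: dose_amount must be >= 0", call. = FALSE)
  if (!is.finite(infusion_h) || infusion_h <= 0 || infusion_h > interval_h)
    stop("validation error: need 0 < infusion_duration <= interval",
         call. = FALSE)
  if (n_doses < 1) stop("validation error: n_doses must be >= 1",
                        call. = FALSE)
  if (is.null(label)) {
    label <- sprintf("%g mg q%gh x%d inf %gh", dose_mg, interval_h,
                     n_doses, infusion_h)
  }
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 infusion_h = infusion_h, n_doses = n_doses,
                 start_h = start_h, label = label),
            class = "dosing_regimen")
}

# Dose events as a data.frame of infusion windows (hours).
.dose_windows <- function(regimen) {
  starts <- regimen$start_h + (seq_len(regimen$n_doses) - 1) *
    regimen$interval_h
  data.frame(start_h = starts, end_h = starts + regimen$infusion_h,
             dose_mg = regimen$dose_mg)
}

#' Build a whole-body PBPK model
#'
#' Assembles the ODE parameterisation for the compiled right-hand side:
#' perfusion-limited organ exchange, glomerular filtration of unbound drug,
#' OAT3-mediated uptake into the proximal tubule cell, NPT1-mediated efflux
#' into the tubular lumen, intracellular DPEP1 metabolism, and irreversible
#' lumen-to-urine drainage.
#'
#' @param drug a [drug_parameters()] object.
#' @param processes named list of [mm_process()] objects (must contain
#'   OAT3, NPT1, DPEP1).
#' @param physiology a `physiology` object, e.g. [reference_adult()].
#' @param conventions list with `vmax_reference_volume_L` and
#'   `lumen_drain_per_min` (see [load_drug_parameters()]).
#' @param dialyzer_clearance_L_min dialyzer plasma clearance applied while
#'   a session is on; 0 disables the dialyzer (it can also be supplied at
#'   simulation time through the dialysis schedule).
#' @return An object of class `pbpk_model`.
#' @export
build_model <- function(drug, processes, physiology, conventions,
                        dialyzer_clearance_L_min = 0) {
  validate_physiology(physiology)
  for (nm in c("OAT3", "NPT1", "DPEP1")) {
    if (is.null(processes[[nm]]))
      stop("structural error: process '", nm, "' missing", call. = FALSE)
  }
  kp <- partition_coefficients(drug, physiology)
  org <- physiology$organs
  stopifnot(identical(org$organ, .organ_names))
  plasma_frac <- 1 - physiology$hematocrit
  vref <- conventions$vmax_reference_volume_L
  vk_app <- physiology$kidney$plasma_L +
    kp[["kidney"]] * (physiology$kidney$volume_L -
                      physiology$kidney$plasma_L)
  pv <- c(
    physiology$venous_plasma_L,
    physiology$arterial_plasma_L,
    physiology$lung_volume_L,
    kp[["lung"]],
    org$volume_L,
    kp[.organ_names],
    org$blood_flow_L_min * plasma_frac,
    physiology$cardiac_output_L_min * plasma_frac,
    physiology$kidney_blood_flow_L_min * plasma_frac,
    vk_app,
    physiology$kidney$tubule_cell_L,
    conventions$lumen_drain_per_min,
    drug$fu,
    drug$gfr_fraction * physiology$gfr_mL_min / 1000,
    processes$OAT3$vmax * vref * processes$OAT3$activity_multiplier,
    processes$OAT3$km,
    processes$NPT1$vmax * vref * processes$NPT1$activity_multiplier,
    processes$NPT1$km,
    processes$DPEP1$vmax * vref * processes$DPEP1$activity_multiplier,
    processes$DPEP1$km,
    0,  # infusion rate, set per segment
    dialyzer_clearance_L_min
  )
  if (length(pv) != 49L)
    stop("structural error: inconsistent parameter layout", call. = FALSE)
  state_names <- c("venous", "arterial", "lung", .organ_names,
                   "kidney", "tubule_cell", "lumen",
                   "urine", "metabolized", "dialyzed")
  structure(list(
    parms = pv, state_names = state_names,
    drug = drug, processes = processes, physiology = physiology,
    conventions = conventions, kp = kp
  ), class = "pbpk_model")
}

# One stiff-solver call over a segment with constant infusion/dialyzer input.
.integrate_segment <- function(y, times, parms, rtol, atol) {
  out <- deSolve::lsoda(y = y, times = times, func = "pbpk_derivs",
                        parms = parms, dllname = "meropbpk",
                        initfunc = "pbpk_init", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integration error: lsoda failed (istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  out
}

#' Simulate a dosing regimen
#'
#' Integrates the model over `[0, t_end_h]` with zero-order infusions into
#' venous plasma and, optionally, intermittent dialyzer sessions. The
#' integration is restarted at every infusion and dialysis on/off boundary.
#'
#' @param model a `pbpk_model` from [build_model()].
#' @param regimen a [dosing_regimen()].
#' @param t_end_h simulation horizon, h (must cover the last infusion).
#' @param dialysis optional `dialysis_settings` object; its session
#'   schedule adds a dialyzer elimination flux while sessions are on.
#' @param dt_out_h output grid spacing, h.
#' @param rtol,atol solver tolerances (internal units).
#' @return A `concentration_profile` data.frame with columns `time_h`,
#'   `conc_mg_L` (venous plasma), `urine_mg`, `metabolized_mg`,
#'   `dialyzed_mg`; the full amount trajectory and the administered dose
#'   are kept as attributes for mass-balance checking.
#' @export
simulate_regimen <- function(model, regimen, t_end_h, dialysis = NULL,
                             dt_out_h = 0.1, rtol = 1e-8, atol = 1e-10) {
  dw <- .dose_windows(regimen)
  if (t_end_h < max(dw$end_h))
    stop("t_end must be at least the last infusion end", call. = FALSE)
  sessions <- if (is.null(dialysis)) {
    data.frame(start_h = numeric(), end_h = numeric())
  } else {
    s <- dialysis_sessions(dialysis, t_end_h)
    if (nrow(s) && max(s$end_h) > t_end_h)
      stop("schedule error: session extends past horizon", call. = FALSE)
    s
  }
  clhd_L_min <- if (is.null(dialysis)) 0 else
    dialyzer_clearance(dialysis) / 1000
  mw <- model$drug$molecular_weight

  brk <- sort(unique(c(0, t_end_h, dw$start_h, dw$end_h,
                       sessions$start_h, sessions$end_h)))
  brk <- brk[brk >= 0 & brk <= t_end_h]
  grid <- sort(unique(c(seq(0, t_end_h, by = dt_out_h), brk)))

  y <- setNames(numeric(19L), model$state_names)
  pv <- model$parms
  rows <- vector("list", length(brk) - 1L)
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    mid <- (t0 + t1) / 2
    infusing <- which(dw$start_h <= mid & mid < dw$end_h & dw$dose_mg > 0)
    rate <- if (length(infusing)) {
      sum(dw$dose_mg[infusing] / mw * 1000 /
            (regimen$infusion_h * 60)) # umol/min
    } else 0
    on_dial <- any(sessions$start_h <= mid & mid < sessions$end_h)
    pv[48L] <- rate
    pv[49L] <- if (on_dial) clhd_L_min else 0
    seg_times <- unique(c(t0, grid[grid > t0 & grid < t1], t1)) * 60
    out <- .integrate_segment(y, seg_times, pv, rtol, atol)
    y <- out[nrow(out), -1L]
    keep <- if (i == 1L) seq_len(nrow(out)) else -1L
    rows[[i]] <- out[keep, , drop = FALSE]
  }
  traj <- do.call(rbind, rows)
  colnames(traj) <- c("time_min", model$state_names)
  amount_to_mg <- mw / 1000
  profile <- data.frame(
    time_h = traj[, "time_min"] / 60,
    conc_mg_L = pmax(traj[, "venous"], 0) /
      model$physiology$venous_plasma_L * amount_to_mg,
    urine_mg = traj[, "urine"] * amount_to_mg,
    metabolized_mg = traj[, "metabolized"] * amount_to_mg,
    dialyzed_mg = traj[, "dialyzed"] * amount_to_mg
  )
  attr(profile, "trajectory") <- traj
  attr(profile, "dose_mg") <- regimen$dose_mg * regimen$n_doses
  attr(profile, "mw") <- mw
  attr(profile, "regimen") <- regimen
  class(profile) <- c("concentration_profile", "data.frame")
  profile
}

#' Relative mass-balance error of a completed simulation
#'
#' `|body + urine + metabolized + dialyzed - administered| / administered`
#' evaluated at every output time against the amount infused up to that
#' time; returns the maximum.
#'
#' @param profile a `concentration_profile` from [simulate_regimen()].
#' @return Maximum relative balance error (0 for a zero dose).
#' @export
mass_balance <- function(profile) {
  traj <- attr(profile, "trajectory")
  if (is.null(traj)) stop("profile lacks a trajectory attribute",
                          call. = FALSE)
  reg <- attr(profile, "regimen")
  mw <- attr(profile, "mw")
  if (reg$dose_mg * reg$n_doses == 0) return(0)
  dw <- .dose_windows(reg)
  t_h <- traj[, "time_min"] / 60
  infused_mg <- vapply(t_h, function(tt) {
    sum(pmin(pmax(tt - dw$start_h, 0), reg$infusion_h) /
          reg$infusion_h * dw$dose_mg)
  }, 0)
  total_umol <- rowSums(traj[, -1L, drop = FALSE])
  total_mg <- total_umol * mw / 1000
  ok <- infused_mg > 0
  max(abs(total_mg[ok] - infused_mg[ok]) / infused_mg[ok])
}

#' Write or read a concentration profile as tidy CSV
#'
#' Columns: `time_h, conc_mg_L, urine_mg, metabolized_mg, dialyzed_mg`.
#'
#' @param profile a `concentration_profile`.
#' @param path CSV path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile)[, c("time_h", "conc_mg_L", "urine_mg",
                                       "metabolized_mg", "dialyzed_mg")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  out <- read.csv(path)
  class(out) <- c("concentration_profile", "data.frame")
  out
}
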