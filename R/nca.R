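# Non-compartmental analysis of sampled concentration profiles.

.check_profile_times <- function(times) {
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
    stop("input error: times must be strictly increasing", call. = FALSE)
}

#' Area under the curve to the last observation
#'
#' Linear trapezoidal rule over the observed points, from the first to the
#' last sample.
#'
#' @param profile data.frame with `time_h` and `conc_mg_L` (>= 2 points).
#' @return AUC_last in mg·h/L.
#' @export
auc_last <- function(profile) {
  t <- profile$time_h; c <- profile$conc_mg_L
  .check_profile_times(t)
  sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)
}

#' Maximum concentration and its time
#'
#' @param profile data.frame with `time_h` and `conc_mg_L` (>= 1 point).
#' @return Named vector `c(cmax = mg/L, tmax = h)`; ties resolved to the
#'   earliest time.
#' @export
cmax_tmax <- function(profile) {
  i <- which.max(profile$conc_mg_L) # earliest maximum on ties
  c(cmax = profile$conc_mg_L[i], tmax = profile$time_h[i])
}

#' Terminal half-life by log-linear regression
#'
#' Fits `log(conc) ~ time` on the terminal window: the last `n_terminal`
#' points, or all points after `after_h` if that yields more points.
#'
#' @param profile data.frame with `time_h` and `conc_mg_L`.
#' @param n_terminal minimum number of terminal points (default 3).
#' @param after_h optional start of the terminal window, h (e.g. the end
#'   of the last infusion).
#' @return Half-life in h.
#' @export
terminal_half_life <- function(profile, n_terminal = 3, after_h = NULL) {
  t <- profile$time_h; c <- profile$conc_mg_L
  idx <- seq.int(max(1L, length(t) - n_terminal + 1L), length(t))
  if (!is.null(after_h)) {
    idx2 <- which(t > after_h)
    if (length(idx2) > length(idx)) idx <- idx2
  }
  tt <- t[idx]; cc <- c[idx]
  if (length(tt) < 3L || any(cc <= 0))
    stop("estimation error: need >= 3 positive terminal concentrations",
         call. = FALSE)
  slope <- stats::coef(stats::lm(log(cc) ~ tt))[[2]]
  if (slope >= 0)
    stop("estimation error: non-declining terminal phase", call. = FALSE)
  log(2) / -slope
}

#' NCA summary table for a set of profiles
#'
#' @param profiles named list of profiles.
#' @param after_h optional terminal-window start passed to
#'   [terminal_half_life()].
#' @return data.frame with columns `id, auc_last, cmax, tmax, t_half`.
#' @export
nca_table <- function(profiles, after_h = NULL) {
  do.call(rbind, lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    cm <- cmax_tmax(p)
    th <- tryCatch(terminal_half_life(p, after_h = after_h),
                   error = function(e) NA_real_)
    data.frame(id = id, auc_last = auc_last(p), cmax = cm[["cmax"]],
               tmax = cm[["tmax"]], t_half = th)
  }))
}
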