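# Spontaneous EPSP detection on zero-command current-clamp segments.

#' Detect spontaneous EPSPs
#'
#' The slow membrane-potential baseline (zero-phase low pass, default
#' 1 Hz cutoff) is subtracted so event amplitudes ride on a comparable
#' baseline; the residual is lightly smoothed (2 ms boxcar) and candidate
#' events are its local maxima, clustered within `merge_ms` keeping the
#' tallest.  An event is accepted when its amplitude - peak minus the
#' local pre-event baseline (the 25% quantile of the residual since the
#' previous accepted event; a plain minimum would inflate every amplitude
#' by the extreme-value bias of the noise) - lies within
#' `[amp_min, amp_max]` and its 10-90% rise time, estimated from the
#' steepest rising slope, does not exceed `max_rise_ms`.
#'
#' @param tr voltage `ephys_trace` at zero command, >= `min_duration_s`.
#' @param amp_min,amp_max accepted amplitude window, mV (default 0.3-10).
#' @param baseline_hz baseline low-pass cutoff, Hz.
#' @param max_rise_ms maximum 10-90% rise time, ms.
#' @param merge_ms merge window for nearby candidates, ms.
#' @param min_duration_s minimum segment length, s (default 60).
#' @param smooth_ms residual smoothing for peak picking, ms.
#' @return `list(events = data.frame(t_ms, amp_mV), summary = list of class
#'   `epsp_summary` with `frequency_per_min`, `mean_amplitude_mV`,
#'   `n_events`, `duration_min`)`.
#' @export
detect_spontaneous_epsps <- function(tr, amp_min = 0.3, amp_max = 10,
                                     baseline_hz = 1, max_rise_ms = 5,
                                     merge_ms = 5, min_duration_s = 60,
                                     smooth_ms = 2) {
  stopifnot(inherits(tr, "ephys_trace"), tr$signal_kind == "voltage")
  dur_ms <- trace_duration(tr)
  if (dur_ms < min_duration_s * 1000)
    stop(sprintf("detect_spontaneous_epsps: segment shorter than %g s",
                 min_duration_s))
  dt <- tr$dt
  res <- tr$samples - lowpass_baseline(tr$samples, dt, cutoff_hz = baseline_hz)
  rs <- boxcar_smooth(res, dt, smooth_ms)
  n <- length(rs)
  # rising slope (mV/ms) over a 1 ms central difference, for the rise gate
  hw <- max(1L, round(0.5 / dt))
  drs <- numeric(n)
  drs[(hw + 1):(n - hw)] <- (rs[(2 * hw + 1):n] - rs[1:(n - 2 * hw)]) /
    (2 * hw * dt)
  # local maxima above amp_min (cheap pre-gate: peak value vs residual zero)
  core <- rs[2:(n - 1)]
  cand <- which(core >= amp_min * 0.8 & core > rs[1:(n - 2)] &
                  core >= rs[3:n]) + 1L
  # cluster nearby candidate maxima first (keep the tallest of each run
  # closer than merge_ms), then gate the representatives
  if (length(cand) > 1) {
    gap <- diff(cand) * dt >= merge_ms
    grp <- cumsum(c(TRUE, gap))
    cand <- vapply(split(cand, grp),
                   function(ix) ix[which.max(rs[ix])], integer(1))
    cand <- unname(sort(cand))
  }
  look <- round(20 / dt)   # local-baseline search window before the peak
  events_t <- numeric(0); events_a <- numeric(0)
  last_acc <- 0L
  for (i in cand) {
    # local baseline: minimum since the previous accepted peak (capped at
    # `look` back), so noise ripples riding on an event's crown or decay
    # have no prominence of their own
    lo <- max(1L, i - look, last_acc + 1L)
    base <- unname(stats::quantile(rs[lo:i], 0.25, names = FALSE))
    base <- min(base, rs[i])
    amp <- rs[i] - base
    if (amp < amp_min || amp > amp_max) next
    # rise-time gate via the steepest rising slope before the peak:
    # 10-90% rise ~ 0.8 * amp / max slope.  Level-crossing estimators are
    # confounded by noise wiggles on the event crown; the slope maximum is
    # not, while slow baseline oscillations still fail the gate
    rise_est <- 0.8 * amp / max(drs[lo:i])
    if (!is.finite(rise_est) || rise_est > max_rise_ms) next
    events_t <- c(events_t, tr$t0 + (i - 1) * dt)
    events_a <- c(events_a, amp)
    last_acc <- i
  }
  dur_min <- dur_ms / 60000
  summary <- structure(list(frequency_per_min = length(events_t) / dur_min,
                            mean_amplitude_mV = if (length(events_a))
                              mean(events_a) else NA_real_,
                            n_events = length(events_t),
                            duration_min = dur_min),
                       class = "epsp_summary")
  list(events = data.frame(t_ms = events_t, amp_mV = events_a),
       summary = summary)
}

#' @export
print.epsp_summary <- function(x, ...) {
  cat(sprintf(paste0("<epsp_summary> %d events in %.2f min: ",
                     "%.1f events/min, mean amplitude %.3f mV\n"),
              x$n_events, x$duration_min, x$frequency_per_min,
              x$mean_amplitude_mV))
  invisible(x)
}

#' Paired before/after change in spontaneous EPSPs
#'
#' @param before,after `epsp_summary` objects from the same cell.
#' @param min_duration_min minimum analyzed duration on each side, minutes.
#' @return `list(d_frequency_per_min, d_amplitude_mV)`, signed
#'   after-minus-before differences.
#' @export
epsp_change <- function(before, after, min_duration_min = 1) {
  stopifnot(inherits(before, "epsp_summary"), inherits(after, "epsp_summary"))
  if (before$duration_min < min_duration_min ||
      after$duration_min < min_duration_min)
    stop("epsp_change: analyzed duration under ", min_duration_min, " min")
  list(d_frequency_per_min = after$frequency_per_min - before$frequency_per_min,
       d_amplitude_mV = after$mean_amplitude_mV - before$mean_amplitude_mV)
}
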