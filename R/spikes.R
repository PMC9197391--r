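# Spike detection and phase-plot threshold estimation.
#
# A spike is registered at the first sample where the smoothed dV/dt
# exceeds the criterion (default 1.5 mV/ms, i.e. 0.00015 V per sample at
# 10 kHz) provided the following 2 ms contain an excursion of at least
# 20 mV above the crossing voltage (peak gate, rejects noise crossings).
# The voltage at the crossing sample is the per-spike firing threshold.
# Detection is derivative-based, hence invariant to DC offsets.

#' Detect action potentials in a current-clamp trace
#'
#' @param tr voltage `ephys_trace`.
#' @param dvdt_threshold onset criterion in mV/ms (default 1.5).
#' @param peak_gate_mV minimum excursion above the crossing voltage within
#'   `gate_ms` for a crossing to count as a spike (default 20 mV).
#' @param gate_ms look-ahead for the peak gate, ms (default 2).
#' @param lockout_ms refractory lockout after a detection, ms (default 2).
#' @param upstroke_dvdt dV/dt level that qualifies as an AP rising phase,
#'   mV/ms (default 30); detection anchors on crossings of this gate and
#'   backtracks to the onset criterion, which keeps single upstrokes from
#'   being counted twice and tolerates strong pulse drive whose charging
#'   slope exceeds `dvdt_threshold`.
#' @param backtrack_ms how far before the upstroke the take-off may lie, ms.
#' @return A list of class `spike_train`: `spike_times` (ms), `thresholds`
#'   (mV at each take-off), `dvdt_threshold`.
#' @export
detect_spikes <- function(tr, dvdt_threshold = 1.5, peak_gate_mV = 20,
                          gate_ms = 2, lockout_ms = 2, upstroke_dvdt = 30,
                          backtrack_ms = 3) {
  stopifnot(inherits(tr, "ephys_trace"), tr$signal_kind == "voltage")
  if (dvdt_threshold <= 0) stop("detect_spikes: dvdt_threshold must be > 0")
  x <- tr$samples
  dt <- tr$dt
  d <- smoothed_derivative(x, dt)
  n <- length(x)
  gate <- max(1L, round(gate_ms / dt))
  lock <- max(1L, round(lockout_ms / dt))
  back <- max(1L, round(backtrack_ms / dt))
  # upward crossings of the upstroke gate: unambiguous AP rising phases
  up <- which(d[-1] >= upstroke_dvdt & d[-n] < upstroke_dvdt) + 1L
  times <- numeric(0); thr <- numeric(0)
  last_end <- 0L
  for (i in up) {
    if (i <= last_end) next
    # backtrack to the take-off: first sample at or above the onset
    # criterion after the last sub-criterion sample; if the approach never
    # drops below the criterion (strong pulse drive) use the local slope
    # minimum instead
    b <- max(1L, i - back)
    seg <- d[b:i]
    low <- which(seg < dvdt_threshold)
    take <- if (length(low)) min(b + low[length(low)], i) else
      b - 1L + which.min(seg)
    hi <- min(n, i + gate)
    if (max(x[i:hi]) - x[take] < peak_gate_mV) next
    times <- c(times, tr$t0 + (take - 1) * dt)
    thr <- c(thr, x[take])
    # re-arm only after repolarization below this spike's threshold
    ipk <- i - 1L + which.max(x[i:hi])
    j <- ipk
    while (j < n && x[j] >= x[take]) j <- j + 1L
    last_end <- max(j, ipk) + lock
  }
  structure(list(spike_times = times, thresholds = thr,
                 dvdt_threshold = dvdt_threshold, dt = dt, t0 = tr$t0),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spike(s); dV/dt criterion %g mV/ms\n",
              length(x$spike_times), x$dvdt_threshold))
  invisible(x)
}

#' Phase plot of one action potential
#'
#' Pairs (V, dV/dt) along a window around one spike; the starting point of
#' the loop - the first crossing of the dV/dt criterion - is the firing
#' threshold.
#'
#' @param tr voltage `ephys_trace`.
#' @param spike_time take-off time of the spike (from [detect_spikes()]), ms.
#' @param window numeric pair, ms around `spike_time` (default `c(-5, 5)`).
#' @param dvdt_threshold onset criterion in mV/ms.
#' @return A list of class `phase_plot`: `V`, `dVdt`, `threshold_point`
#'   (`c(V, dVdt)` at the first criterion crossing, or `NULL` if none).
#' @export
phase_plot <- function(tr, spike_time, window = c(-5, 5),
                       dvdt_threshold = 1.5) {
  stopifnot(inherits(tr, "ephys_trace"), tr$signal_kind == "voltage")
  dur <- trace_duration(tr)
  a <- max(tr$t0, spike_time + window[1])
  b <- min(tr$t0 + dur, spike_time + window[2])
  if (b - a < 1 || spike_time < tr$t0 || spike_time > tr$t0 + dur)
    stop("phase_plot: window exceeds trace")
  w <- extract_window(tr, a, b)
  d <- smoothed_derivative(w$samples, w$dt)
  # starting point of the loop: first sample of the contiguous
  # super-criterion run that contains the upstroke (anchoring on the run
  # ignores isolated noise crossings earlier in the window)
  imax <- which.max(d)
  tp <- NULL
  if (d[imax] >= dvdt_threshold) {
    low <- which(d[seq_len(imax)] < dvdt_threshold)
    idx <- if (length(low)) low[length(low)] + 1L else 1L
    tp <- c(V = w$samples[idx], dVdt = d[idx])
  }
  structure(list(V = w$samples, dVdt = d, threshold_point = tp,
                 dvdt_threshold = dvdt_threshold, t = trace_times(w)),
            class = "phase_plot")
}

#' @export
print.phase_plot <- function(x, ...) {
  if (is.null(x$threshold_point))
    cat("<phase_plot> no criterion crossing (no spike in window)\n")
  else
    cat(sprintf("<phase_plot> threshold %.2f mV at dV/dt %.2f mV/ms\n",
                x$threshold_point[["V"]], x$threshold_point[["dVdt"]]))
  invisible(x)
}

# Locate the step window of an iv_step sweep from its command channel.
# Returns c(on, off) sample indices or NULL for a flat command.
step_window <- function(sw) {
  cmd <- sw$command$samples
  # baseline from the leading samples (commands start at baseline)
  base <- stats::median(cmd[seq_len(max(1L, round(0.05 * length(cmd))))])
  dev <- which(abs(cmd - base) > 1e-6 + 0.01 * max(abs(cmd - base)))
  if (length(dev) == 0) return(NULL)
  c(dev[1], dev[length(dev)])
}

#' Firing threshold from the 60 pA step
#'
#' Phase-plot threshold of the first spike evoked by the +60 pA sweep of an
#' I-V recording (the step at which cells most consistently spike).  If the
#' 60 pA sweep exists but evokes no spike the function returns `NA` with a
#' diagnostic attribute rather than silently substituting another step.
#'
#' @param rec an I-V `ephys_recording`.
#' @param step_pA which step to use, pA (default 60).
#' @param dvdt_threshold onset criterion, mV/ms.
#' @return Threshold voltage in mV, or `NA` with attribute `diagnostic`.
#' @export
firing_threshold_60pA <- function(rec, step_pA = 60, dvdt_threshold = 1.5) {
  stopifnot(inherits(rec, "ephys_recording"))
  amps <- vapply(rec$sweeps, function(s) s$step_amplitude, numeric(1))
  k <- which(abs(amps - step_pA) < 1e-6)
  if (length(k) == 0)
    stop(sprintf("firing_threshold_60pA: no %g pA sweep present", step_pA))
  sw <- rec$sweeps[[k[1]]]
  st <- detect_spikes(sw$signal, dvdt_threshold = dvdt_threshold)
  if (length(st$spike_times) == 0) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf("no spike in the %g pA sweep", step_pA)
    return(out)
  }
  pp <- phase_plot(sw$signal, st$spike_times[1],
                   dvdt_threshold = dvdt_threshold)
  if (is.null(pp$threshold_point)) {
    out <- NA_real_
    attr(out, "diagnostic") <- "no criterion crossing in phase-plot window"
    return(out)
  }
  unname(pp$threshold_point[["V"]])
}
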