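# Domain containers for intracellular recordings.
#
# Units are fixed package-wide: voltage mV, current pA, time ms,
# resistance MOhm (seal resistance alone is carried in GOhm, as printed on
# amplifiers).  Sample i of a trace covers the half-open interval
# [t0 + i*dt, t0 + (i+1)*dt).

CLAMP_MODES    <- c("current_clamp", "voltage_clamp")
CONDITIONS     <- c("before", "after_stim", "rest_post", "drug", "unstim_control")
PROTOCOL_TAGS  <- c("iv_step", "presyn_train", "spontaneous", "stim_train")
SIGNAL_KINDS   <- c("voltage", "current")

#' Uniformly sampled signal trace
#'
#' The atomic container: an ordered numeric series with a fixed sampling
#' interval.  Voltage traces are in mV, current traces in pA; `dt` and `t0`
#' are in ms.
#'
#' @param samples numeric vector, all finite, non-empty.
#' @param dt sampling interval in ms (> 0); 0.1 ms corresponds to the 10 kHz
#'   acquisition rate the protocols assume.
#' @param signal_kind `"voltage"` or `"current"`.
#' @param t0 time of the first sample in ms.
#' @return An object of class `ephys_trace`.
#' @export
trace <- function(samples, dt, signal_kind = c("voltage", "current"), t0 = 0) {
  signal_kind <- match.arg(signal_kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace: samples must be non-empty")
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop(sprintf("trace: non-finite sample at index %d", bad))
  }
  if (!is.finite(dt) || dt <= 0) stop("trace: dt must be a positive number")
  structure(list(samples = samples, dt = dt, signal_kind = signal_kind,
                 t0 = t0),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s, %d samples, dt = %g ms, duration = %g ms\n",
              x$signal_kind, length(x$samples), x$dt, trace_duration(x)))
  invisible(x)
}

#' Trace duration in ms
#' @param tr an `ephys_trace`.
#' @return duration in ms (`length(samples) * dt`).
#' @export
trace_duration <- function(tr) length(tr$samples) * tr$dt

#' Trace sample times
#' @param tr an `ephys_trace`.
#' @return numeric vector of sample start times in ms.
#' @export
trace_times <- function(tr) tr$t0 + (seq_along(tr$samples) - 1) * tr$dt

#' Extract a half-open time window from a trace
#'
#' Returns the samples whose start times fall in `[t_start, t_end)`.
#' Windowing composes: applying two windows equals applying their
#' intersection.
#'
#' @param tr an `ephys_trace`.
#' @param t_start,t_end window bounds in ms; must satisfy
#'   `t0 <= t_start < t_end <= t0 + duration`.
#' @return An `ephys_trace` with `t0 = t_start` (snapped to the sample grid).
#' @export
extract_window <- function(tr, t_start, t_end) {
  stopifnot(inherits(tr, "ephys_trace"))
  dur <- trace_duration(tr)
  if (t_start < tr$t0 - 1e-9 || t_end > tr$t0 + dur + 1e-9 || t_start >= t_end)
    stop(sprintf("extract_window: [%g, %g) out of range [%g, %g)",
                 t_start, t_end, tr$t0, tr$t0 + dur))
  i0 <- ceiling((t_start - tr$t0) / tr$dt - 1e-9)        # first sample >= t_start
  i1 <- ceiling((t_end   - tr$t0) / tr$dt - 1e-9) - 1    # last sample  <  t_end
  if (i1 < i0) stop("extract_window: window contains no samples")
  trace(tr$samples[(i0 + 1L):(i1 + 1L)], tr$dt, tr$signal_kind,
        t0 = tr$t0 + i0 * tr$dt)
}

#' One sweep: a measured signal plus its command
#'
#' In current clamp the measured signal is voltage and the command is
#' current; in voltage clamp the measured signal is current.  Both traces
#' must share `dt` and length.
#'
#' @param signal measured `ephys_trace`.
#' @param command command-channel `ephys_trace` (current for current clamp).
#' @param protocol_tag one of `"iv_step"`, `"presyn_train"`, `"spontaneous"`,
#'   `"stim_train"`.
#' @param step_amplitude step amplitude in pA for `iv_step` sweeps, else `NA`.
#' @return An object of class `ephys_sweep`.
#' @export
sweep <- function(signal, command, protocol_tag, step_amplitude = NA_real_) {
  stopifnot(inherits(signal, "ephys_trace"), inherits(command, "ephys_trace"))
  if (!protocol_tag %in% PROTOCOL_TAGS)
    stop("sweep: unknown protocol_tag '", protocol_tag, "'")
  if (abs(signal$dt - command$dt) > 1e-12)
    stop("sweep: signal and command dt differ")
  if (length(signal$samples) != length(command$samples))
    stop("sweep: signal and command length differ")
  structure(list(signal = signal, command = command,
                 protocol_tag = protocol_tag,
                 step_amplitude = as.numeric(step_amplitude)),
            class = "ephys_sweep")
}

#' A recording: ordered sweeps from one cell under one condition
#'
#' @param cell_id opaque identifier string.
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param condition one of `r paste0('"', CONDITIONS, '"', collapse = ", ")`;
#'   a closed vocabulary so group statistics cannot silently mix cohorts.
#' @param sweeps list of [sweep()] objects sharing `dt`.
#' @param opsin_expressing logical flag (provenance metadata).
#' @param leak_pA,seal_Gohm optional scalars used by [qc_recording()];
#'   `NA` means not measured.
#' @return An object of class `ephys_recording`.
#' @export
recording <- function(cell_id, clamp_mode, condition, sweeps,
                      opsin_expressing = FALSE,
                      leak_pA = NA_real_, seal_Gohm = NA_real_) {
  clamp_mode <- match.arg(clamp_mode, CLAMP_MODES)
  condition <- match.arg(condition, CONDITIONS)
  if (length(sweeps) == 0L) stop("recording: needs at least one sweep")
  if (!all(vapply(sweeps, inherits, logical(1), "ephys_sweep")))
    stop("recording: sweeps must be ephys_sweep objects")
  dts <- vapply(sweeps, function(s) s$signal$dt, numeric(1))
  if (max(dts) - min(dts) > 1e-12)
    stop("recording: all sweeps must share dt")
  expected <- if (clamp_mode == "current_clamp") "voltage" else "current"
  kinds <- vapply(sweeps, function(s) s$signal$signal_kind, character(1))
  if (!all(kinds == expected))
    stop(sprintf("recording: %s recordings must carry %s-signal sweeps",
                 clamp_mode, expected))
  structure(list(cell_id = as.character(cell_id), clamp_mode = clamp_mode,
                 condition = condition, sweeps = sweeps,
                 opsin_expressing = isTRUE(opsin_expressing),
                 leak_pA = as.numeric(leak_pA),
                 seal_Gohm = as.numeric(seal_Gohm)),
            class = "ephys_recording")
}

#' @export
print.ephys_recording <- function(x, ...) {
  cat(sprintf("<ephys_recording> cell %s, %s, %s, %d sweep(s), dt = %g ms\n",
              x$cell_id, x$clamp_mode, x$condition, length(x$sweeps),
              recording_dt(x)))
  invisible(x)
}

#' Sampling interval of a recording (ms)
#' @param rec an `ephys_recording`.
#' @export
recording_dt <- function(rec) rec$sweeps[[1]]$signal$dt

#' A simultaneously recorded pair of cells
#'
#' @param pre,post `ephys_recording` objects sharing `dt`; `pre` is the
#'   (putative) presynaptic cell.
#' @param alignment_offset offset in ms added to the `post` time base to
#'   align it with `pre` (0 for simultaneously triggered sweeps).
#' @param pair_id optional identifier; defaults to "pre&post" cell ids.
#' @return An object of class `ephys_pair`.
#' @export
pair_recording <- function(pre, post, alignment_offset = 0, pair_id = NULL) {
  stopifnot(inherits(pre, "ephys_recording"), inherits(post, "ephys_recording"))
  if (abs(recording_dt(pre) - recording_dt(post)) > 1e-12)
    stop("pair_recording: pre and post dt differ")
  if (is.null(pair_id)) pair_id <- paste0(pre$cell_id, "&", post$cell_id)
  structure(list(pair_id = as.character(pair_id), pre = pre, post = post,
                 alignment_offset = as.numeric(alignment_offset)),
            class = "ephys_pair")
}

#' @export
print.ephys_pair <- function(x, ...) {
  cat(sprintf("<ephys_pair> %s: pre %s (%d sweeps) / post %s (%d sweeps)\n",
              x$pair_id, x$pre$cell_id, length(x$pre$sweeps),
              x$post$cell_id, length(x$post$sweeps)))
  invisible(x)
}
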