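# F-I excitability metrics, rheobase, input resistance, resting potential.

#' F-I curve and rheobase from an I-V step recording
#'
#' Per step: spike count within the step window; mean instantaneous
#' frequency (mean of 1000/ISI over consecutive spike pairs, `NA` with
#' fewer than two spikes); frequency of the first two spikes
#' (1000/first ISI).  Rheobase is the smallest step amplitude evoking at
#' least one spike (`NA` if none).
#'
#' @param rec an I-V `ephys_recording` (current clamp, `iv_step` sweeps).
#' @param dvdt_threshold spike-detection criterion, mV/ms.
#' @return A list of class `fi_curve`: `table` (data.frame with columns
#'   `step_pA`, `n_spikes`, `mean_if_Hz`, `first2_Hz`), `rheobase_pA`.
#' @export
fi_curve <- function(rec, dvdt_threshold = 1.5) {
  stopifnot(inherits(rec, "ephys_recording"))
  iv <- Filter(function(s) s$protocol_tag == "iv_step", rec$sweeps)
  if (length(iv) == 0) stop("fi_curve: recording has no iv_step sweeps")
  amps <- vapply(iv, function(s) s$step_amplitude, numeric(1))
  if (anyNA(amps)) stop("fi_curve: iv_step sweeps missing step annotations")
  rows <- lapply(seq_along(iv), function(i) {
    sw <- iv[[i]]
    win <- step_window(sw)
    st <- detect_spikes(sw$signal, dvdt_threshold = dvdt_threshold)
    times <- st$spike_times
    if (!is.null(win)) {
      t_on <- sw$signal$t0 + (win[1] - 1) * sw$signal$dt
      t_off <- sw$signal$t0 + win[2] * sw$signal$dt
      times <- times[times >= t_on & times < t_off]
    }
    n <- length(times)
    isi <- diff(times)
    data.frame(step_pA = amps[i], n_spikes = n,
               mean_if_Hz = if (n >= 2) mean(1000 / isi) else NA_real_,
               first2_Hz = if (n >= 2) 1000 / isi[1] else NA_real_)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$step_pA), , drop = FALSE]
  rownames(tab) <- NULL
  firing <- tab$step_pA[tab$n_spikes >= 1]
  structure(list(table = tab,
                 rheobase_pA = if (length(firing)) min(firing) else NA_real_),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("<fi_curve> %d steps, rheobase %s pA\n",
              nrow(x$table), format(x$rheobase_pA)))
  print(x$table)
  invisible(x)
}

#' Input resistance from subthreshold I-V steps
#'
#' For each spike-free step in `[fit_range]` pA, the steady-state voltage
#' is the mean over the last `ss_ms` of the step; input resistance is the
#' ordinary least-squares slope of steady-state V against injected I
#' (mV/pA, reported in MOhm), not forced through the resting point.
#' Resting potential is the median of all zero-command samples.
#'
#' @param rec an I-V `ephys_recording`.
#' @param fit_range pA range of usable steps (default -100 to 40).
#' @param ss_ms steady-state window at the end of each step, ms
#'   (default 100, avoiding the charging transient).
#' @param dvdt_threshold spike-detection criterion for sweep exclusion.
#' @return A list of class `passive_props`: `input_resistance_Mohm`,
#'   `resting_potential_mV`, `fit_points` (data.frame `I_pA`, `V_mV`),
#'   `n_excluded_spiking`.
#' @export
input_resistance <- function(rec, fit_range = c(-100, 40), ss_ms = 100,
                             dvdt_threshold = 1.5) {
  stopifnot(inherits(rec, "ephys_recording"))
  iv <- Filter(function(s) s$protocol_tag == "iv_step", rec$sweeps)
  if (length(iv) == 0) stop("input_resistance: no iv_step sweeps")
  pts_I <- numeric(0); pts_V <- numeric(0)
  zero_samples <- numeric(0)
  n_spiking <- 0L
  for (sw in iv) {
    a <- sw$step_amplitude
    win <- step_window(sw)
    zero_idx <- which(sw$command$samples == 0)
    zero_samples <- c(zero_samples, sw$signal$samples[zero_idx])
    if (is.na(a) || a < fit_range[1] || a > fit_range[2]) next
    st <- detect_spikes(sw$signal, dvdt_threshold = dvdt_threshold)
    if (length(st$spike_times) > 0) { n_spiking <- n_spiking + 1L; next }
    if (is.null(win)) {
      if (a != 0) next
      win <- c(1L, length(sw$signal$samples))
    }
    k <- max(1L, round(ss_ms / sw$signal$dt))
    lo <- max(win[1], win[2] - k + 1L)
    pts_I <- c(pts_I, a)
    pts_V <- c(pts_V, mean(sw$signal$samples[lo:win[2]]))
  }
  if (length(pts_I) < 3)
    stop("input_resistance: fewer than 3 usable subthreshold steps")
  fit <- lm(pts_V ~ pts_I)
  r_mohm <- unname(coef(fit)[2]) * 1000  # mV/pA -> MOhm
  structure(list(input_resistance_Mohm = r_mohm,
                 resting_potential_mV = if (length(zero_samples))
                   stats::median(zero_samples) else NA_real_,
                 fit_points = data.frame(I_pA = pts_I, V_mV = pts_V),
                 n_excluded_spiking = n_spiking),
            class = "passive_props")
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf("<passive_props> Rm = %.1f MOhm (%d fit points), Vrest = %.2f mV\n",
              x$input_resistance_Mohm, nrow(x$fit_points),
              x$resting_potential_mV))
  invisible(x)
}

#' Resting potential of a zero-command segment
#'
#' The sample median of spontaneous membrane activity without current
#' injection - robust to sparse synaptic events riding on the baseline.
#'
#' @param tr voltage `ephys_trace` recorded at zero command.
#' @param min_duration_s minimum accepted segment length, seconds
#'   (default 10).
#' @return Resting potential, mV.
#' @export
resting_potential <- function(tr, min_duration_s = 10) {
  stopifnot(inherits(tr, "ephys_trace"), tr$signal_kind == "voltage")
  if (trace_duration(tr) < min_duration_s * 1000)
    stop(sprintf("resting_potential: segment shorter than %g s",
                 min_duration_s))
  stats::median(tr$samples)
}
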