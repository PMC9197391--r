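# Parameter containers for the synthetic-trace generator, and the
# condition-dependent effect model.

#' Intrinsic neuron parameters for the EIF simulator
#'
#' The membrane model is an exponential integrate-and-fire cell; once the
#' trajectory escapes past `V_T + 5*Delta_T` a stereotyped action-potential
#' template (built by [spike_template()], take-off voltage exactly `V_T`) is
#' spliced in and the membrane resets.  Defaults (C 40 pF, i.e. a ~11 ms membrane time constant) describe a layer-2/3
#' pyramidal cell matching the passive values the analyses are designed to
#' recover: Rm 278 MOhm, resting -73 mV, threshold -41 mV.
#'
#' @param C membrane capacitance, pF.
#' @param R input resistance, MOhm.
#' @param E_rest resting potential, mV.
#' @param V_T spike-onset threshold, mV (must satisfy `V_reset < V_T < 0`).
#' @param Delta_T spike sharpness, mV.
#' @param V_reset post-spike reset potential, mV.
#' @param t_ref absolute refractory period, ms.
#' @param ap_peak action-potential peak voltage for the template, mV.
#' @return A list of class `neuron_params` including the spike template.
#' @export
neuron_params <- function(C = 40, R = 278, E_rest = -73, V_T = -41,
                          Delta_T = 1, V_reset = -58, t_ref = 3,
                          ap_peak = 30) {
  stopifnot(C > 0, R > 0, Delta_T > 0, t_ref > 0)
  if (!(V_reset < V_T && V_T < 0))
    stop("neuron_params: need V_reset < V_T < 0")
  p <- list(C = C, R = R, E_rest = E_rest, V_T = V_T, Delta_T = Delta_T,
            V_reset = V_reset, t_ref = t_ref, ap_peak = ap_peak)
  p$spike_template <- spike_template(V_T, ap_peak, V_reset)
  class(p) <- "neuron_params"
  p
}

#' Stereotyped action-potential waveform
#'
#' Exponentially accelerating rise from `V_T` to `peak` over `t_rise` ms
#' (initial slope `slope0` mV/ms, just above the default spike-detection
#' criterion so the phase-plot threshold estimate lands at take-off), then
#' an exponential fall to `V_reset` over `t_fall` ms.  The first sample
#' equals `V_T` exactly.
#'
#' @param V_T take-off voltage, mV.
#' @param peak peak voltage, mV.
#' @param V_reset terminal voltage, mV.
#' @param dt_ms sample interval, ms.
#' @param t_rise,t_fall rise and fall durations, ms.
#' @param slope0 initial rise slope, mV/ms.
#' @return numeric vector of template samples (first sample `V_T`).
#' @export
spike_template <- function(V_T, peak = 30, V_reset = -58, dt_ms = 0.1,
                           t_rise = 1, t_fall = 1.5, slope0 = 2) {
  stopifnot(peak > V_T, V_reset < V_T)
  amp <- peak - V_T
  # solve (amp * a)/(exp(a*t_rise) - 1) = slope0 for the rise rate a
  f <- function(a) amp * a / (exp(a * t_rise) - 1) - slope0
  a <- stats::uniroot(f, c(1e-6, 60 / t_rise))$root
  t_up <- seq(0, t_rise, by = dt_ms)
  rise <- V_T + amp * (exp(a * t_up) - 1) / (exp(a * t_rise) - 1)
  tau_d <- t_fall / log((peak - V_reset) / 0.5)
  t_dn <- seq(dt_ms, t_fall, by = dt_ms)
  fall <- V_reset + (peak - V_reset) * exp(-t_dn / tau_d)
  c(rise, fall)
}

#' Synapse parameters (Tsodyks-Markram short-term depression)
#'
#' Mean amplitude of the n-th response in a train at inter-pulse interval
#' `dt` is `q * U * R_n` with `R_1 = 1` and
#' `R_(n+1) = 1 - (1 - (1-U) R_n) exp(-dt/tau_rec)` (see
#' [tm_amplitudes()]).  Individual trials fail (zero response) with
#' probability `failure_p` per pulse.
#'
#' @param q unitary response amplitude: pA in EPSC mode, mV in EPSP mode.
#' @param latency synaptic latency from presynaptic spike take-off, ms.
#' @param tau_rise,tau_decay kernel time constants, ms (`tau_decay > tau_rise`).
#' @param U release fraction per spike, in (0, 1].
#' @param tau_rec recovery time constant of the releasable pool, ms.
#' @param failure_p per-pulse failure probability.
#' @param plasticity_scale condition-dependent multiplier on `q` (set by
#'   [apply_effect()]).
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(q = 28, latency = 2, tau_rise = 0.5,
                           tau_decay = 4, U = 0.5, tau_rec = 200,
                           failure_p = 0.3, plasticity_scale = 1) {
  stopifnot(q > 0, latency >= 0, tau_decay > tau_rise, tau_rise > 0,
            U >= 0, U <= 1, failure_p >= 0, failure_p <= 1,
            tau_rec > 0, plasticity_scale > 0)
  structure(list(q = q, latency = latency, tau_rise = tau_rise,
                 tau_decay = tau_decay, U = U, tau_rec = tau_rec,
                 failure_p = failure_p, plasticity_scale = plasticity_scale),
            class = "synapse_params")
}

#' Analytic Tsodyks-Markram amplitude series
#'
#' @param syn a `synapse_params`.
#' @param n_pulses number of pulses in the train.
#' @param rate_hz train rate, Hz.
#' @return numeric vector of mean (non-failure) amplitudes
#'   `q * plasticity_scale * U * R_n`.
#' @export
tm_amplitudes <- function(syn, n_pulses, rate_hz) {
  stopifnot(n_pulses >= 1, rate_hz > 0)
  dt <- 1000 / rate_hz
  R <- numeric(n_pulses)
  R[1] <- 1
  if (n_pulses > 1) {
    for (n in 1:(n_pulses - 1)) {
      R[n + 1] <- 1 - (1 - (1 - syn$U) * R[n]) * exp(-dt / syn$tau_rec)
    }
  }
  syn$q * syn$plasticity_scale * syn$U * R
}

#' Background synaptic barrage parameters
#'
#' Spontaneous activity is modeled as a Poisson train of PSP-shaped events
#' with truncated-lognormal amplitudes.  The truncation floor (0.05 mV)
#' keeps sub-detection events in the trace so detector specificity is
#' testable; defaults put roughly 90 events/min at or above the 0.3 mV
#' detection floor.
#'
#' @param rate_per_min total event rate, events/min (detectable and not).
#' @param meanlog,sdlog lognormal amplitude parameters (mV scale); the
#'   defaults put the amplitude median at the 0.3 mV detection floor, so
#'   about half the barrage (~80/min) is detectable.
#' @param amp_min,amp_max amplitude truncation bounds, mV.
#' @param tau_rise,tau_decay PSP kernel time constants, ms.
#' @return A list of class `barrage_params`.
#' @export
barrage_params <- function(rate_per_min = 160, meanlog = log(0.3),
                           sdlog = 0.6, amp_min = 0.05, amp_max = 10,
                           tau_rise = 1, tau_decay = 30) {
  stopifnot(rate_per_min >= 0, amp_min > 0, amp_max > amp_min,
            tau_decay > tau_rise, tau_rise > 0)
  structure(list(rate_per_min = rate_per_min, meanlog = meanlog,
                 sdlog = sdlog, amp_min = amp_min, amp_max = amp_max,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "barrage_params")
}

#' Protocol description for the simulator
#'
#' @param kind `"iv_steps"`, `"presyn_train"`, `"stim_train"` or
#'   `"spontaneous"`.
#' @param step_range pA pair, inclusive range of `iv_steps` amplitudes
#'   (default -100 to 160).
#' @param step_increment pA increment (default 20; must divide the range).
#' @param step_duration ms of current injection per step (default 500).
#' @param pre_ms,post_ms baseline before / tail after the step or train, ms.
#' @param train_rate pulse rate in Hz for train protocols (default 20).
#' @param n_pulses number of pulses per train (default 10).
#' @param pulse_width ms per pulse (default 5).
#' @param pulse_amplitude pA per pulse (default 500).
#' @param on_duration,off_duration stim_train duty cycle, ms (4 s on / 10 s
#'   rest).
#' @param total_duration total length for `spontaneous` and `stim_train`, ms.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("iv_steps", "presyn_train", "stim_train",
                                   "spontaneous"),
                          step_range = c(-100, 160), step_increment = 20,
                          step_duration = 500, pre_ms = 100, post_ms = 400,
                          train_rate = 20, n_pulses = 10, pulse_width = 5,
                          pulse_amplitude = 500,
                          on_duration = 4000, off_duration = 10000,
                          total_duration = 60000) {
  kind <- match.arg(kind)
  stopifnot(step_duration > 0, train_rate > 0, pulse_width > 0,
            n_pulses >= 1, total_duration > 0, pre_ms >= 0, post_ms >= 0)
  if (kind == "iv_steps") {
    span <- diff(step_range)
    if (span < 0 || abs(span / step_increment - round(span / step_increment)) > 1e-9)
      stop("protocol_spec: step_increment must divide the step range")
  }
  structure(list(kind = kind, step_range = step_range,
                 step_increment = step_increment,
                 step_duration = step_duration, pre_ms = pre_ms,
                 post_ms = post_ms, train_rate = train_rate,
                 n_pulses = n_pulses, pulse_width = pulse_width,
                 pulse_amplitude = pulse_amplitude,
                 on_duration = on_duration, off_duration = off_duration,
                 total_duration = total_duration),
            class = "protocol_spec")
}

#' Condition-dependent effect of the stimulation protocol
#'
#' Phenomenological summary of what prolonged 10 Hz co-stimulation changes:
#' input resistance scales up, the firing threshold hyperpolarizes, the
#' spontaneous EPSP barrage speeds up and grows, and the evoked unitary
#' response follows a biphasic depression-then-rebound.  Defaults are the
#' group means the analyses are designed to recover: Rm x305/278,
#' threshold -2.7 mV, EPSP rate x127/90 and amplitude x0.41/0.38, evoked
#' scale 1 -> 8/14 -> 20/14 across before / after_stim / rest_post.
#'
#' Intrinsic and spontaneous shifts apply under `after_stim` and
#' `rest_post`; `before` and `unstim_control` are identity, and `drug`
#' (an ERG-channel blocker washed in after stimulation) reverts the
#' intrinsic shifts to identity.
#'
#' @param rm_scale multiplier on input resistance.
#' @param threshold_shift additive shift on `V_T`, mV.
#' @param epsp_rate_scale multiplier on barrage rate.
#' @param epsp_amp_scale multiplier on barrage amplitude.
#' @param evoked_scale_by_condition named numeric vector mapping conditions
#'   to multipliers on the synaptic `plasticity_scale`.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(rm_scale = 305 / 278, threshold_shift = -2.7,
                        epsp_rate_scale = 127 / 90,
                        epsp_amp_scale = 0.41 / 0.38,
                        evoked_scale_by_condition = c(before = 1,
                                                      after_stim = 8 / 14,
                                                      rest_post = 20 / 14)) {
  stopifnot(rm_scale > 0, epsp_rate_scale > 0, epsp_amp_scale > 0,
            all(evoked_scale_by_condition > 0))
  structure(list(rm_scale = rm_scale, threshold_shift = threshold_shift,
                 epsp_rate_scale = epsp_rate_scale,
                 epsp_amp_scale = epsp_amp_scale,
                 evoked_scale_by_condition = evoked_scale_by_condition),
            class = "effect_spec")
}

#' Identity effect (no stimulation-induced change)
#' @return An `effect_spec` whose every scale is 1 and shift 0.
#' @export
effect_spec_identity <- function() {
  effect_spec(rm_scale = 1, threshold_shift = 0, epsp_rate_scale = 1,
              epsp_amp_scale = 1,
              evoked_scale_by_condition = c(before = 1, after_stim = 1,
                                            rest_post = 1))
}

#' Apply a condition's effect to generator parameters
#'
#' Pure function: returns adjusted copies of `neuron_params`,
#' `synapse_params` or `barrage_params` for the requested condition.
#'
#' @param base a `neuron_params`, `synapse_params` or `barrage_params`.
#' @param effect an `effect_spec`.
#' @param condition a condition label from the closed vocabulary.
#' @return Adjusted parameter object of the same class.
#' @export
apply_effect <- function(base, effect, condition) {
  stopifnot(inherits(effect, "effect_spec"))
  if (!condition %in% CONDITIONS)
    stop("apply_effect: unknown condition '", condition, "'")
  shifted <- condition %in% c("after_stim", "rest_post")
  if (inherits(base, "neuron_params")) {
    if (!shifted) return(base)
    return(neuron_params(C = base$C, R = base$R * effect$rm_scale,
                         E_rest = base$E_rest,
                         V_T = base$V_T + effect$threshold_shift,
                         Delta_T = base$Delta_T, V_reset = base$V_reset,
                         t_ref = base$t_ref, ap_peak = base$ap_peak))
  }
  if (inherits(base, "synapse_params")) {
    sc <- effect$evoked_scale_by_condition
    if (!condition %in% names(sc)) {
      if (condition %in% c("unstim_control", "drug")) return(base)
      stop("apply_effect: condition '", condition,
           "' missing from evoked_scale_by_condition")
    }
    out <- base
    out$plasticity_scale <- base$plasticity_scale * unname(sc[[condition]])
    return(out)
  }
  if (inherits(base, "barrage_params")) {
    if (!shifted) return(base)
    out <- base
    out$rate_per_min <- base$rate_per_min * effect$epsp_rate_scale
    out$meanlog <- base$meanlog + log(effect$epsp_amp_scale)
    return(out)
  }
  stop("apply_effect: unsupported parameter object")
}
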