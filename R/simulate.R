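# Synthetic-trace generator.  Every simulation takes a seed, routes all
# randomness through R's RNG, and returns a ground-truth bundle next to the
# traces so the analysis stages can be tested against known answers.
#
# Two regimes:
#   * stepped / pulsed current-clamp protocols run through the EIF
#     integrator in src/eif.cpp (spikes, phase-plot loops, Ohmic steps);
#   * zero-command spontaneous segments are built as linear superpositions
#     of PSP kernels on E_rest (the subthreshold regime is Ohmic, so the
#     superposition is the closed-form solution and the event amplitudes
#     are exact ground truth for the detector).
# Measurement noise is additive Gaussian on the recorded trace.

DEFAULT_DT <- 0.1  # ms; 10 kHz acquisition

#' Normalized double-exponential PSP/PSC kernel
#'
#' `K(t) = exp(-t/tau_decay) - exp(-t/tau_rise)`, scaled to peak 1, sampled
#' at `dt_ms` out to `8 * tau_decay`.
#'
#' @param tau_rise,tau_decay time constants, ms.
#' @param dt_ms sample interval, ms.
#' @return numeric vector.
#' @export
psp_kernel <- function(tau_rise, tau_decay, dt_ms = DEFAULT_DT) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  t <- seq(0, 8 * tau_decay, by = dt_ms)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

run_eif <- function(params, I, dt_ms, V0 = NULL) {
  if (is.null(V0)) V0 <- params$E_rest
  eif_integrate(I, dt_ms, params$C, params$R, params$E_rest, params$V_T,
                params$Delta_T, params$V_reset, params$t_ref,
                params$spike_template, V0)
}

iv_step_amplitudes <- function(protocol) {
  seq(protocol$step_range[1], protocol$step_range[2],
      by = protocol$step_increment)
}

# Command-current vectors for one protocol: list(commands, tags, step_amps).
protocol_commands <- function(protocol, dt_ms) {
  p <- protocol
  if (p$kind == "iv_steps") {
    amps <- iv_step_amplitudes(p)
    n <- round((p$pre_ms + p$step_duration + p$post_ms) / dt_ms)
    on <- round(p$pre_ms / dt_ms) + 1L
    off <- round((p$pre_ms + p$step_duration) / dt_ms)
    cmds <- lapply(amps, function(a) {
      x <- numeric(n); x[on:off] <- a; x
    })
    list(commands = cmds, tags = rep("iv_step", length(amps)),
         step_amps = amps)
  } else if (p$kind == "presyn_train") {
    ipi <- 1000 / p$train_rate
    span <- (p$n_pulses - 1) * ipi + p$pulse_width
    n <- round((p$pre_ms + span + p$post_ms) / dt_ms)
    x <- numeric(n)
    for (k in seq_len(p$n_pulses)) {
      a <- round((p$pre_ms + (k - 1) * ipi) / dt_ms) + 1L
      b <- min(n, a + round(p$pulse_width / dt_ms) - 1L)
      x[a:b] <- p$pulse_amplitude
    }
    list(commands = list(x), tags = "presyn_train", step_amps = NA_real_)
  } else if (p$kind == "stim_train") {
    cyc <- p$on_duration + p$off_duration
    n <- round(p$total_duration / dt_ms)
    x <- numeric(n)
    ipi <- 1000 / p$train_rate
    t_on <- seq(0, p$total_duration - 1e-9, by = cyc)
    for (s in t_on) {
      pulses <- seq(s, min(s + p$on_duration, p$total_duration) - 1e-9, by = ipi)
      for (tp in pulses) {
        a <- round(tp / dt_ms) + 1L
        b <- min(n, a + round(p$pulse_width / dt_ms) - 1L)
        if (a <= n) x[a:b] <- p$pulse_amplitude
      }
    }
    list(commands = list(x), tags = "stim_train", step_amps = NA_real_)
  } else {
    n <- round(p$total_duration / dt_ms)
    list(commands = list(numeric(n)), tags = "spontaneous",
         step_amps = NA_real_)
  }
}

#' Simulate a single-cell current-clamp recording
#'
#' Runs the EIF membrane model over the command currents prescribed by the
#' protocol, splices spike templates at threshold escape, and adds Gaussian
#' observation noise.  The same seed always yields an identical recording.
#'
#' @param params a [neuron_params()].
#' @param protocol a [protocol_spec()].
#' @param noise_sd observation noise SD, mV (default 0.1, chosen so the
#'   0.3 mV EPSP detection floor sits at roughly 3 SD).
#' @param seed integer seed fixing all randomness.
#' @param cell_id identifier for the emitted recording.
#' @param condition condition label.
#' @param dt_ms sample interval, ms.
#' @param opsin_expressing metadata flag.
#' @param leak_pA,seal_Gohm QC metadata for the emitted recording.
#' @return `list(recording =` [recording()]`, truth = list(...))`; the truth
#'   carries exact template take-off times per sweep plus the generating
#'   parameters.
#' @export
simulate_neuron <- function(params, protocol, noise_sd = 0.1, seed = 1,
                            cell_id = "sim", condition = "before",
                            dt_ms = DEFAULT_DT, opsin_expressing = FALSE,
                            leak_pA = 10, seal_Gohm = 2) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "protocol_spec"))
  if (noise_sd < 0) stop("simulate_neuron: noise_sd must be >= 0")
  set.seed(seed)
  pc <- protocol_commands(protocol, dt_ms)
  sweeps <- vector("list", length(pc$commands))
  spike_times <- vector("list", length(pc$commands))
  for (i in seq_along(pc$commands)) {
    I <- pc$commands[[i]]
    sim <- run_eif(params, I, dt_ms)
    v <- sim$V
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    spike_times[[i]] <- (sim$spike_idx - 1) * dt_ms
    sweeps[[i]] <- sweep(trace(v, dt_ms, "voltage"),
                         trace(I, dt_ms, "current"),
                         protocol_tag = pc$tags[i],
                         step_amplitude = pc$step_amps[i])
  }
  rec <- recording(cell_id, "current_clamp", condition, sweeps,
                   opsin_expressing = opsin_expressing,
                   leak_pA = leak_pA, seal_Gohm = seal_Gohm)
  truth <- list(spike_times = spike_times, true_threshold = params$V_T,
                true_R = params$R, true_E_rest = params$E_rest,
                params = params, protocol = protocol, noise_sd = noise_sd,
                seed = seed)
  list(recording = rec, truth = truth)
}

# Draw a Poisson barrage over [0, duration_ms): grid-snapped times (ms) and
# truncated-lognormal amplitudes (mV).
draw_barrage_events <- function(barrage, duration_ms, dt_ms) {
  lambda <- barrage$rate_per_min * duration_ms / 60000
  n <- rpois(1, lambda)
  if (n == 0) return(list(t = numeric(0), amp = numeric(0)))
  t <- sort(runif(n, 0, duration_ms))
  t <- (round(t / dt_ms)) * dt_ms
  plo <- stats::plnorm(barrage$amp_min, barrage$meanlog, barrage$sdlog)
  phi <- stats::plnorm(barrage$amp_max, barrage$meanlog, barrage$sdlog)
  amp <- stats::qlnorm(runif(n, plo, phi), barrage$meanlog, barrage$sdlog)
  list(t = t, amp = amp)
}

spontaneous_voltage <- function(E_rest, events, barrage, duration_ms,
                                noise_sd, dt_ms) {
  n <- round(duration_ms / dt_ms)
  k <- psp_kernel(barrage$tau_rise, barrage$tau_decay, dt_ms)
  v <- add_kernel_events(n, as.integer(round(events$t / dt_ms)) + 1L,
                         events$amp, k)
  v <- v + E_rest
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  v
}

#' Simulate a paired recording
#'
#' Two protocol kinds are supported.
#'
#' `"spontaneous"`: both cells receive a Poisson PSP barrage at zero
#' command; a fraction `shared_input_fraction` of the barrage rate is
#' common input (identical event times and amplitudes in both cells), the
#' remainder private.  This realizes correlated spontaneous activity of
#' both connected and unconnected pairs.
#'
#' `"presyn_train"`: the presynaptic cell is driven with the pulse train
#' (current clamp, EIF spikes); if a synapse is present, each presynaptic
#' spike triggers - with per-pulse failures and Tsodyks-Markram
#' within-train depression - a postsynaptic response at `synapse$latency`
#' ms.  In `"EPSC"` mode the postsynaptic channel is a voltage-clamp
#' current trace (inward = negative); in `"EPSP"` mode a current-clamp
#' voltage trace.
#'
#' @param pre_params,post_params [neuron_params()] for the two cells.
#' @param synapse a [synapse_params()] or `NULL` for an unconnected pair.
#' @param shared_input_fraction fraction of barrage input common to both
#'   cells, in `[0, 1]`.
#' @param protocol a [protocol_spec()] of kind `"spontaneous"` or
#'   `"presyn_train"`.
#' @param seed integer seed.
#' @param n_trials number of train repetitions (presyn_train only).
#' @param mode `"EPSC"` (voltage-clamp postsynaptic channel) or `"EPSP"`.
#' @param barrage a [barrage_params()] (spontaneous only).
#' @param noise_mV voltage observation noise SD, mV.
#' @param noise_pA current observation noise SD, pA (voltage clamp).
#' @param condition condition label stamped on both recordings.
#' @param pair_id identifier.
#' @param opsin_expressing metadata flag.
#' @return `list(pair =` [pair_recording()]`, truth = list(...))`.
#' @export
simulate_pair <- function(pre_params, post_params, synapse = NULL,
                          shared_input_fraction = 0, protocol,
                          seed = 1, n_trials = 30, mode = c("EPSC", "EPSP"),
                          barrage = barrage_params(), noise_mV = 0.1,
                          noise_pA = 3, condition = "before",
                          pair_id = "pair", opsin_expressing = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "protocol_spec"))
  if (shared_input_fraction < 0 || shared_input_fraction > 1)
    stop("simulate_pair: shared_input_fraction must lie in [0, 1]")
  set.seed(seed)
  dt_ms <- DEFAULT_DT

  if (protocol$kind == "spontaneous") {
    dur <- protocol$total_duration
    b_sh <- barrage; b_sh$rate_per_min <- barrage$rate_per_min * shared_input_fraction
    b_pr <- barrage; b_pr$rate_per_min <- barrage$rate_per_min * (1 - shared_input_fraction)
    shared <- draw_barrage_events(b_sh, dur, dt_ms)
    pre_ev <- draw_barrage_events(b_pr, dur, dt_ms)
    post_ev <- draw_barrage_events(b_pr, dur, dt_ms)
    ev_pre <- list(t = c(shared$t, pre_ev$t), amp = c(shared$amp, pre_ev$amp))
    ev_post <- list(t = c(shared$t, post_ev$t), amp = c(shared$amp, post_ev$amp))
    o_pre <- order(ev_pre$t); ev_pre <- lapply(ev_pre, `[`, o_pre)
    o_post <- order(ev_post$t); ev_post <- lapply(ev_post, `[`, o_post)
    v_pre <- spontaneous_voltage(pre_params$E_rest, ev_pre, barrage, dur,
                                 noise_mV, dt_ms)
    v_post <- spontaneous_voltage(post_params$E_rest, ev_post, barrage, dur,
                                  noise_mV, dt_ms)
    mk <- function(v, id) {
      zero <- numeric(length(v))
      recording(id, "current_clamp", condition,
                list(sweep(trace(v, dt_ms, "voltage"),
                           trace(zero, dt_ms, "current"),
                           "spontaneous")),
                opsin_expressing = opsin_expressing)
    }
    pair <- pair_recording(mk(v_pre, paste0(pair_id, "_pre")),
                           mk(v_post, paste0(pair_id, "_post")),
                           pair_id = pair_id)
    truth <- list(kind = "spontaneous", connected = !is.null(synapse),
                  shared_input_fraction = shared_input_fraction,
                  epsp_events_pre = ev_pre, epsp_events_post = ev_post,
                  shared_events = shared,
                  true_E_rest = c(pre = pre_params$E_rest,
                                  post = post_params$E_rest),
                  noise_mV = noise_mV, seed = seed)
    return(list(pair = pair, truth = truth))
  }

  if (protocol$kind != "presyn_train")
    stop("simulate_pair: unsupported protocol kind '", protocol$kind, "'")

  pc <- protocol_commands(protocol, dt_ms)
  I_pre <- pc$commands[[1]]
  nlen <- length(I_pre)
  amp_series <- if (!is.null(synapse))
    tm_amplitudes(synapse, protocol$n_pulses, protocol$train_rate)
  else numeric(0)
  kern <- if (!is.null(synapse))
    psp_kernel(synapse$tau_rise, synapse$tau_decay, dt_ms)
  else NULL

  pre_sweeps <- vector("list", n_trials)
  post_sweeps <- vector("list", n_trials)
  pre_spike_times <- vector("list", n_trials)
  true_amps <- matrix(0, n_trials, protocol$n_pulses)
  event_times <- matrix(NA_real_, n_trials, protocol$n_pulses)
  post_kind <- if (mode == "EPSC") "current" else "voltage"
  post_clamp <- if (mode == "EPSC") "voltage_clamp" else "current_clamp"

  for (tr in seq_len(n_trials)) {
    sim <- run_eif(pre_params, I_pre, dt_ms)
    v_pre <- sim$V + rnorm(nlen, 0, noise_mV)
    st <- (sim$spike_idx - 1) * dt_ms
    pre_spike_times[[tr]] <- st
    pre_sweeps[[tr]] <- sweep(trace(v_pre, dt_ms, "voltage"),
                              trace(I_pre, dt_ms, "current"),
                              "presyn_train")
    post <- numeric(nlen)
    if (!is.null(synapse) && length(st) > 0) {
      np <- min(length(st), protocol$n_pulses)
      ok <- runif(np) >= synapse$failure_p
      a <- amp_series[seq_len(np)] * ok
      true_amps[tr, seq_len(np)] <- a
      et <- st[seq_len(np)] + synapse$latency
      event_times[tr, seq_len(np)] <- et
      sgn <- if (mode == "EPSC") -1 else 1
      post <- add_kernel_events(nlen, as.integer(round(et / dt_ms)) + 1L,
                                sgn * a, kern)
    }
    if (mode == "EPSC") {
      post <- post + rnorm(nlen, 0, noise_pA)
      post_sweeps[[tr]] <- sweep(trace(post, dt_ms, "current"),
                                 trace(numeric(nlen), dt_ms, "voltage"),
                                 "presyn_train")
    } else {
      post <- post + post_params$E_rest + rnorm(nlen, 0, noise_mV)
      post_sweeps[[tr]] <- sweep(trace(post, dt_ms, "voltage"),
                                 trace(numeric(nlen), dt_ms, "current"),
                                 "presyn_train")
    }
  }
  pre_rec <- recording(paste0(pair_id, "_pre"), "current_clamp", condition,
                       pre_sweeps, opsin_expressing = opsin_expressing)
  post_rec <- recording(paste0(pair_id, "_post"), post_clamp, condition,
                        post_sweeps, opsin_expressing = opsin_expressing)
  pair <- pair_recording(pre_rec, post_rec, pair_id = pair_id)
  truth <- list(kind = "presyn_train", connected = !is.null(synapse),
                mode = mode, pre_spike_times = pre_spike_times,
                evoked_amplitude_series = amp_series,
                true_amplitudes = true_amps, event_times = event_times,
                latency = if (!is.null(synapse)) synapse$latency else NA_real_,
                failure_p = if (!is.null(synapse)) synapse$failure_p else NA_real_,
                noise_pA = noise_pA, noise_mV = noise_mV, seed = seed)
  list(pair = pair, truth = truth)
}

#' Simulate trial x pulse evoked amplitude tables
#'
#' Amplitude-level view of the evoked train (no traces): mean amplitude of
#' pulse n follows the Tsodyks-Markram depletion recursion, each trial adds
#' Gaussian measurement noise, and each pulse independently fails (true
#' zero) with probability `failure_p`.
#'
#' @param synapse a [synapse_params()].
#' @param n_pulses pulses per train.
#' @param rate_hz train rate, Hz (> 0).
#' @param n_trials number of trains.
#' @param noise_sd amplitude measurement noise SD (pA or mV).
#' @param seed integer seed.
#' @return `list(amplitudes = n_trials x n_pulses matrix,
#'   truth = list(amp_series, failures, ...))`.
#' @export
simulate_evoked_train <- function(synapse, n_pulses = 10, rate_hz = 20,
                                  n_trials = 30, noise_sd = 1, seed = 1) {
  stopifnot(inherits(synapse, "synapse_params"), n_pulses >= 1)
  if (rate_hz <= 0) stop("simulate_evoked_train: rate must be positive")
  set.seed(seed)
  a <- tm_amplitudes(synapse, n_pulses, rate_hz)
  fail <- matrix(runif(n_trials * n_pulses) < synapse$failure_p,
                 n_trials, n_pulses)
  amps <- matrix(rep(a, each = n_trials), n_trials, n_pulses)
  amps[fail] <- 0
  amps <- amps + matrix(rnorm(n_trials * n_pulses, 0, noise_sd),
                        n_trials, n_pulses)
  list(amplitudes = amps,
       truth = list(amp_series = a, failures = fail,
                    failure_p = synapse$failure_p, noise_sd = noise_sd,
                    seed = seed))
}

#' Generate a synthetic cohort of recorded pairs
#'
#' Default cohort mirrors the study design: 28 pairs of which 7 are
#' monosynaptically connected.  Each pair gets, per condition, an evoked
#' block (presynaptic 20 Hz train, postsynaptic voltage clamp) and a
#' zero-command spontaneous block for correlation/EPSP analysis.  Connected
#' pairs receive a larger shared-input fraction than unconnected ones.
#'
#' @param n_pairs number of pairs (default 28).
#' @param n_connected number of connected pairs (default 7;
#'   `<= n_pairs`).
#' @param conditions condition labels to simulate per pair.
#' @param seed master seed; per-pair seeds are derived from it.
#' @param dir if non-`NULL`, write the cohort there
#'   (`pair_XX/<condition>/{evoked,spont}/...` plus `manifest.csv`).
#' @param n_trials evoked train repetitions per condition.
#' @param spontaneous_s spontaneous segment length per condition, seconds
#'   (0 skips the spontaneous block).
#' @param effect an [effect_spec()] applied per condition.
#' @param neuron,synapse,barrage base parameter objects.
#' @param shared_connected,shared_unconnected shared-input fractions.
#' @param noise_mV,noise_pA observation noise levels.
#' @param include_iv also simulate an I-V step recording per cell
#'   (intrinsic-analysis stage); off by default to keep cohorts light.
#' @return `list(pairs = nested list [[pair]][[condition]] of
#'   `list(evoked, spont, iv_pre, iv_post)` simulation results,
#'   manifest = data.frame, dir = dir)`.
#' @export
generate_cohort <- function(n_pairs = 28, n_connected = 7,
                            conditions = "before", seed = 1, dir = NULL,
                            n_trials = 30, spontaneous_s = 60,
                            effect = effect_spec(),
                            neuron = neuron_params(),
                            synapse = synapse_params(),
                            barrage = barrage_params(),
                            shared_connected = 0.4,
                            shared_unconnected = 0.15,
                            noise_mV = 0.1, noise_pA = 3,
                            include_iv = FALSE) {
  if (n_connected > n_pairs)
    stop("generate_cohort: n_connected must not exceed n_pairs")
  set.seed(seed)
  connected <- logical(n_pairs)
  connected[sample.int(n_pairs, n_connected)] <- TRUE
  pair_seeds <- sample.int(.Machine$integer.max - 1, n_pairs)
  if (anyDuplicated(pair_seeds)) stop("generate_cohort: seed collision")

  spont_proto <- if (spontaneous_s > 0)
    protocol_spec("spontaneous", total_duration = spontaneous_s * 1000)
  else NULL
  train_proto <- protocol_spec("presyn_train")
  iv_proto <- protocol_spec("iv_steps")
  pairs <- vector("list", n_pairs)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    pid <- sprintf("pair_%02d", i)
    percond <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      syn_c <- if (connected[i]) apply_effect(synapse, effect, cond) else NULL
      bar_c <- apply_effect(barrage, effect, cond)
      neu_c <- apply_effect(neuron, effect, cond)
      sf <- if (connected[i]) shared_connected else shared_unconnected
      sub_seed <- (pair_seeds[i] + 7919L * ci) %% (.Machine$integer.max - 1L)
      ev <- simulate_pair(neuron, neu_c, synapse = syn_c,
                          shared_input_fraction = sf,
                          protocol = train_proto, seed = sub_seed,
                          n_trials = n_trials, mode = "EPSC",
                          barrage = bar_c, noise_mV = noise_mV,
                          noise_pA = noise_pA, condition = cond,
                          pair_id = pid)
      sp <- NULL
      if (spontaneous_s > 0) {
        sp <- simulate_pair(neuron, neu_c, synapse = syn_c,
                            shared_input_fraction = sf,
                            protocol = spont_proto,
                            seed = sub_seed + 1L, mode = "EPSC",
                            barrage = bar_c, noise_mV = noise_mV,
                            noise_pA = noise_pA, condition = cond,
                            pair_id = pid)
      }
      iv <- NULL
      if (include_iv) {
        iv <- list(
          pre = simulate_neuron(neu_c, iv_proto, noise_sd = noise_mV,
                                seed = sub_seed + 2L,
                                cell_id = paste0(pid, "_pre"),
                                condition = cond),
          post = simulate_neuron(neu_c, iv_proto, noise_sd = noise_mV,
                                 seed = sub_seed + 3L,
                                 cell_id = paste0(pid, "_post"),
                                 condition = cond))
      }
      percond[[cond]] <- list(evoked = ev, spont = sp, iv = iv)
      a1 <- if (connected[i]) tm_amplitudes(syn_c, 1, train_proto$train_rate) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pid, condition = cond, seed = sub_seed,
        connected = connected[i], shared_fraction = sf,
        true_A1 = a1,
        true_mean_epsc1 = a1 * (1 - if (connected[i]) synapse$failure_p else 0),
        stringsAsFactors = FALSE)
    }
    pairs[[i]] <- percond
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("generate_cohort: cannot create '", dir, "'")
    for (i in seq_len(n_pairs)) {
      pid <- sprintf("pair_%02d", i)
      for (cond in conditions) {
        base <- file.path(dir, pid, cond)
        write_pair_recording(pairs[[i]][[cond]]$evoked$pair,
                             file.path(base, "evoked"), overwrite = TRUE)
        if (!is.null(pairs[[i]][[cond]]$spont))
          write_pair_recording(pairs[[i]][[cond]]$spont$pair,
                               file.path(base, "spont"), overwrite = TRUE)
        if (!is.null(pairs[[i]][[cond]]$iv)) {
          write_recording(pairs[[i]][[cond]]$iv$pre$recording,
                          file.path(base, "iv_pre"), overwrite = TRUE)
          write_recording(pairs[[i]][[cond]]$iv$post$recording,
                          file.path(base, "iv_post"), overwrite = TRUE)
        }
      }
    }
    data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  }
  list(pairs = pairs, manifest = manifest, dir = dir)
}
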