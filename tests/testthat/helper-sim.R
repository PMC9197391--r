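# Shared fixtures for the test suite.  Everything is generated in code; no
# stored data.

# High-Rm configuration used by the threshold / F-I assays: rheobase ~48 pA,
# so the 60 pA phase-plot step is suprathreshold across the tested V_T grid.
excitable_params <- function(V_T = -41, ...) {
  neuron_params(C = 40, R = 650, V_T = V_T, ...)
}

# One 60 pA I-V sweep (fast: single step).
proto_60 <- function() {
  protocol_spec("iv_steps", step_range = c(60, 60), step_increment = 20)
}

# Subthreshold-only I-V protocol for passive-property assays.
proto_passive <- function() {
  protocol_spec("iv_steps", step_range = c(-100, 40), step_increment = 20)
}

# A current-clamp iv_step sweep with spike templates spliced at known times
# (ms); used to test F-I arithmetic against hand-placed spikes.
make_spike_sweep <- function(spike_times_ms, step_amp = 80,
                             duration_ms = 1000, step_on = 100,
                             step_off = 600, baseline = -70, dt = 0.1) {
  n <- round(duration_ms / dt)
  v <- rep(baseline, n)
  tpl <- spike_template(V_T = -41, V_reset = -58, dt_ms = dt)
  ramp_n <- 200L   # 20 ms sub-criterion approach ramp (1.45 mV/ms)
  for (t in spike_times_ms) {
    i <- round(t / dt) + 1L
    ramp_idx <- max(1L, i - ramp_n):(i - 1L)
    v[ramp_idx] <- seq(baseline, -41, length.out = length(ramp_idx) + 1L)[
      seq_along(ramp_idx)]
    idx <- i:min(n, i + length(tpl) - 1L)
    v[idx] <- tpl[seq_along(idx)]
    tail_idx <- (idx[length(idx)] + 1L):min(n, idx[length(idx)] + 50L)
    v[tail_idx] <- baseline + (v[idx[length(idx)]] - baseline) *
      exp(-(seq_along(tail_idx)) / 20)
  }
  cmd <- numeric(n)
  cmd[(round(step_on / dt) + 1L):round(step_off / dt)] <- step_amp
  sweep(trace(v, dt, "voltage"), trace(cmd, dt, "current"),
        "iv_step", step_amplitude = step_amp)
}

# Tiny valid recording for IO / QC tests.
tiny_recording <- function(n_sweeps = 3, n = 200, dt = 0.1, seed = 1,
                           leak_pA = 10, seal_Gohm = 2) {
  set.seed(seed)
  sweeps <- lapply(seq_len(n_sweeps), function(i) {
    sweep(trace(rnorm(n, -70, 0.5), dt, "voltage"),
          trace(rep(c(0, 20, 0), c(n / 4, n / 2, n / 4)), dt, "current"),
          "iv_step", step_amplitude = 20)
  })
  recording("cell1", "current_clamp", "before", sweeps,
            leak_pA = leak_pA, seal_Gohm = seal_Gohm)
}

# Independent Tsodyks-Markram oracle (straight transcription of the
# recursion, kept separate from the package implementation).
tm_oracle <- function(q, U, tau_rec, n_pulses, rate_hz) {
  dt <- 1000 / rate_hz
  R <- 1
  out <- numeric(n_pulses)
  for (n in seq_len(n_pulses)) {
    out[n] <- q * U * R
    R <- 1 - (1 - (1 - U) * R) * exp(-dt / tau_rec)
  }
  out
}

# Brute-force exact two-sided Wilcoxon signed-rank p (2^n enumeration).
wilcoxon_brute <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  lo <- mean(Ws <= W + 1e-9)
  hi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Brute-force exact two-sided Mann-Whitney p (all group assignments).
mann_whitney_brute <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  combos <- utils::combn(N, na)
  Ws <- apply(combos, 2, function(ix) sum(r[ix]))
  lo <- mean(Ws <= W + 1e-9)
  hi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(lo, hi))
}
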