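# Evoked responses, connection classification, PPR, spontaneous EPSPs.

fake_response <- function(mean1, noise_sd, latency, n_trials = 30) {
  structure(list(mode = "EPSC", n_trials = n_trials, n_pulses = 2,
                 mean_amplitudes = c(mean1, NA), mean_epsc1 = mean1,
                 mean_epsc2 = NA_real_, latency = latency,
                 noise_sd = noise_sd, pair_id = "fake"),
            class = "evoked_response")
}

test_that("classification follows the amplitude and latency criteria", {
  expect_true(classify_connection(fake_response(15, 3, 2.3))$connected)
  expect_false(classify_connection(fake_response(4, 3, 2))$connected)  # 4 < 4.5
  expect_false(classify_connection(fake_response(15, 3, 3.5))$connected)
  expect_false(classify_connection(fake_response(15, 3, 0.9))$connected)
  expect_true(classify_connection(fake_response(15, 3, 1.0))$connected)
  expect_false(classify_connection(fake_response(15, 3, NA))$connected)
  expect_error(classify_connection(fake_response(15, NA, 2)), "noise_sd")
  expect_error(classify_connection(fake_response(15, 3, 2, n_trials = 5)),
               "trials")
  # population rule inverts the latency criterion
  expect_true(classify_connection(fake_response(15, 3, 4),
                                  rule = "population")$connected)
  expect_false(classify_connection(fake_response(15, 3, 1.5),
                                   rule = "population")$connected)
})

test_that("the decision boundary is exactly k * noise_sd and monotone", {
  for (k in c(1, 1.5, 2)) {
    for (amp in c(4.49, 4.5, 4.51) * k / 1.5) {
      call <- classify_connection(fake_response(amp, 3, 2), k = k)
      expect_identical(call$connected, amp > k * 3)
      expect_equal(call$threshold_used, k * 3)
    }
  }
  # monotone in amplitude, anti-monotone in noise
  dec <- vapply(seq(1, 10, by = 0.5), function(a)
    classify_connection(fake_response(a, 3, 2))$connected, logical(1))
  expect_false(any(diff(dec) < 0))
})

test_that("evoked responses recover the generator's analytic means", {
  syn <- synapse_params()   # q 28, U 0.5 -> A1 = 14 pA; failure_p 0.3
  sp <- simulate_pair(neuron_params(), neuron_params(), synapse = syn,
                      protocol = protocol_spec("presyn_train"),
                      seed = 42, n_trials = 30, mode = "EPSC")
  resp <- evoked_response(sp$pair)
  expect_equal(resp$n_pulses, 10L)
  expect_equal(dim(resp$trial_amplitudes), c(30L, 10L))
  # mean including failures ~ (1 - 0.3) * 14 = 9.8
  expect_lt(abs(resp$mean_epsc1 - 14 * 0.7) / (14 * 0.7), 0.15)
  expect_lt(abs(resp$latency - 2), 1)
  expect_true(classify_connection(resp)$connected)
  # averaging-with-failures identity against truth labels
  truth_mean <- mean(sp$truth$true_amplitudes[, 1])
  fail_rate <- mean(sp$truth$true_amplitudes[, 1] == 0)
  nonfail <- mean(sp$truth$true_amplitudes[sp$truth$true_amplitudes[, 1] > 0, 1])
  expect_equal(truth_mean, (1 - fail_rate) * nonfail, tolerance = 1e-12)
  expect_lt(abs(resp$mean_epsc1 - truth_mean) / truth_mean, 0.12)
})

test_that("a zero-synapse pair measures a null response", {
  sp <- simulate_pair(neuron_params(), neuron_params(), synapse = NULL,
                      protocol = protocol_spec("presyn_train"),
                      seed = 43, n_trials = 30, mode = "EPSC")
  resp <- evoked_response(sp$pair)
  sem <- resp$noise_sd / sqrt(resp$n_trials)
  expect_lt(abs(resp$mean_epsc1), 3 * sem)
  expect_false(classify_connection(resp)$connected)
})

test_that("EPSP mode yields 10 pulse-aligned amplitudes per trial", {
  syn <- synapse_params(q = 0.6, failure_p = 0)
  sp <- simulate_pair(neuron_params(), neuron_params(), synapse = syn,
                      protocol = protocol_spec("presyn_train"),
                      seed = 8, n_trials = 12, mode = "EPSP")
  resp <- evoked_response(sp$pair)
  expect_identical(resp$mode, "EPSP")
  expect_equal(resp$n_pulses, 10L)
  expect_equal(dim(resp$trial_amplitudes), c(12L, 10L))
  expect_gt(resp$mean_epsc1, 0.3)
})

test_that("PPR follows the ratio-of-means rule", {
  m <- cbind(rep(10, 20), rep(10, 20))
  expect_equal(paired_pulse_ratio(m), 1)
  m2 <- cbind(rep(10, 20), rep(14, 20))   # facilitating pattern
  expect_gt(paired_pulse_ratio(m2), 1)
  expect_error(paired_pulse_ratio(cbind(rep(0, 20), rep(1, 20))),
               "noise floor")
  # generator oracle: U = 0.5, tau_rec = 200 ms, 20 Hz
  tab <- simulate_evoked_train(synapse_params(), n_trials = 500,
                               noise_sd = 1, seed = 3)
  expect_lt(abs(paired_pulse_ratio(tab$amplitudes) -
                  (1 - 0.5 * exp(-0.25))), 0.03)
})

test_that("spontaneous EPSP detection: floor, ceiling and degenerate input", {
  set.seed(1)
  flat <- trace(rnorm(6e5, -73, 0.05), 0.1, "voltage")
  det <- detect_spontaneous_epsps(flat)
  expect_lte(det$summary$frequency_per_min, 2)
  expect_error(detect_spontaneous_epsps(trace(rep(-73, 100), 0.1, "voltage")),
               "shorter")
  expect_error(detect_spontaneous_epsps(flat, baseline_hz = 100),
               "Nyquist")
  # events of 0.2 mV only: below the 0.3 mV acceptance floor
  bar <- barrage_params(rate_per_min = 60, meanlog = log(0.2), sdlog = 1e-6,
                        amp_min = 0.199, amp_max = 0.201)
  sp <- simulate_pair(neuron_params(), neuron_params(),
                      protocol = protocol_spec("spontaneous",
                                               total_duration = 60000),
                      seed = 21, barrage = bar)
  det2 <- detect_spontaneous_epsps(sp$pair$pre$sweeps[[1]]$signal)
  expect_lte(det2$summary$n_events, 2)   # noise-level false-positive budget
  # hard invariant: accepted amplitudes lie in [0.3, 10]
  if (nrow(det2$events))
    expect_true(all(det2$events$amp_mV >= 0.3 & det2$events$amp_mV <= 10))
})

test_that("detector recovers a known event train", {
  bar <- barrage_params(rate_per_min = 100, meanlog = log(0.8), sdlog = 0.45,
                        amp_min = 0.4, amp_max = 2)
  sp <- simulate_pair(neuron_params(), neuron_params(),
                      protocol = protocol_spec("spontaneous",
                                               total_duration = 120000),
                      seed = 11, barrage = bar)
  det <- detect_spontaneous_epsps(sp$pair$pre$sweeps[[1]]$signal)
  tru <- sp$truth$epsp_events_pre
  hit <- vapply(tru$t, function(t)
    any(det$events$t_ms >= t & det$events$t_ms - t <= 12), logical(1))
  fp <- vapply(det$events$t_ms, function(t)
    !any(tru$t <= t & t - tru$t <= 12), logical(1))
  expect_gte(mean(hit), 0.9)
  expect_gte(1 - mean(fp), 0.9)
  expect_lt(abs(det$summary$frequency_per_min - length(tru$t) / 2) /
              (length(tru$t) / 2), 0.1)
  expect_true(all(det$events$amp_mV >= 0.3 & det$events$amp_mV <= 10))
})

test_that("epsp_change reports signed paired deltas", {
  s1 <- structure(list(frequency_per_min = 90, mean_amplitude_mV = 0.38,
                       n_events = 90, duration_min = 1),
                  class = "epsp_summary")
  s2 <- structure(list(frequency_per_min = 127, mean_amplitude_mV = 0.41,
                       n_events = 127, duration_min = 1),
                  class = "epsp_summary")
  expect_equal(epsp_change(s1, s1), list(d_frequency_per_min = 0,
                                         d_amplitude_mV = 0))
  d <- epsp_change(s1, s2)
  expect_equal(d$d_frequency_per_min, 37)
  expect_equal(d$d_amplitude_mV, 0.03)
  s3 <- s1; s3$duration_min <- 0.5
  expect_error(epsp_change(s3, s2), "duration")
})
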