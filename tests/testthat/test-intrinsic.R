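# Spike detection, phase plots, F-I metrics, passive properties.

test_that("a constant trace has no spikes and a ramp no threshold point", {
  flat <- trace(rep(-70, 5000), 0.1, "voltage")
  expect_length(detect_spikes(flat)$spike_times, 0L)
  ramp <- trace(seq(-70, -40, length.out = 5000), 0.1, "voltage")
  expect_length(detect_spikes(ramp)$spike_times, 0L)
  pp <- phase_plot(ramp, 250)
  expect_null(pp$threshold_point)
})

test_that("noiseless detection recovers template take-offs and thresholds", {
  sim <- simulate_neuron(excitable_params(), proto_60(), noise_sd = 0,
                         seed = 1)
  truth <- sim$truth$spike_times[[1]]
  st <- detect_spikes(sim$recording$sweeps[[1]]$signal)
  expect_length(st$spike_times, length(truth))
  expect_true(all(abs(st$spike_times - truth) <= 0.2))
  expect_true(all(abs(st$thresholds - -41) <= 0.5))
})

test_that("detection is invariant to a DC offset", {
  sim <- simulate_neuron(excitable_params(), proto_60(), noise_sd = 0.1,
                         seed = 3)
  tr <- sim$recording$sweeps[[1]]$signal
  st1 <- detect_spikes(tr)
  tr2 <- tr; tr2$samples <- tr$samples + 17.3
  st2 <- detect_spikes(tr2)
  expect_equal(st1$spike_times, st2$spike_times)
  expect_equal(st2$thresholds - st1$thresholds,
               rep(17.3, length(st1$thresholds)))
})

test_that("noisy detection stays near-perfect (10-seed check)", {
  f1 <- vapply(1:10, function(s) {
    sim <- simulate_neuron(excitable_params(), proto_60(), noise_sd = 0.1,
                           seed = s)
    truth <- sim$truth$spike_times[[1]]
    st <- detect_spikes(sim$recording$sweeps[[1]]$signal)
    hits <- sum(vapply(truth, function(t)
      any(abs(st$spike_times - t) <= 1), logical(1)))
    2 * hits / (length(truth) + length(st$spike_times))
  }, numeric(1))
  expect_true(all(f1 >= 0.99))
})

test_that("phase plot threshold point lies on the curve at the criterion", {
  sim <- simulate_neuron(excitable_params(), proto_60(), noise_sd = 0,
                         seed = 1)
  tr <- sim$recording$sweeps[[1]]$signal
  t1 <- detect_spikes(tr)$spike_times[1]
  pp <- phase_plot(tr, t1)
  expect_false(is.null(pp$threshold_point))
  expect_lt(abs(pp$threshold_point[["V"]] - -41), 0.5)
  expect_gte(pp$threshold_point[["dVdt"]], 1.5)
  # translation of the time axis leaves the estimate unchanged
  tr2 <- tr; tr2$t0 <- tr$t0 + 1234.5
  pp2 <- phase_plot(tr2, t1 + 1234.5)
  expect_equal(pp2$threshold_point, pp$threshold_point)
  expect_error(phase_plot(tr, -100), "window")
})

test_that("firing_threshold_60pA recovers truth and flags edge cases", {
  sim <- simulate_neuron(excitable_params(V_T = -41), proto_60(),
                         noise_sd = 0, seed = 1)
  expect_lt(abs(firing_threshold_60pA(sim$recording) - -41), 0.5)
  # default 278 MOhm cell: rheobase above 60 pA -> absent with diagnostic
  sub <- simulate_neuron(neuron_params(), proto_60(), noise_sd = 0, seed = 1)
  thr <- firing_threshold_60pA(sub$recording)
  expect_true(is.na(thr))
  expect_match(attr(thr, "diagnostic"), "no spike")
  # recording without a 60 pA sweep -> error
  other <- simulate_neuron(neuron_params(),
                           protocol_spec("iv_steps", step_range = c(-20, 0)),
                           noise_sd = 0, seed = 1)
  expect_error(firing_threshold_60pA(other$recording), "no 60")
})

test_that("fi_curve arithmetic matches hand-placed spikes", {
  sw <- make_spike_sweep(c(200, 250, 350))  # within the 100-600 ms step
  rec <- recording("c", "current_clamp", "before", list(sw))
  fi <- fi_curve(rec)
  expect_equal(fi$table$n_spikes, 3L)
  expect_equal(fi$table$mean_if_Hz, mean(c(20, 10)))   # ISIs 50, 100 ms
  expect_equal(fi$table$first2_Hz, 20)
  expect_equal(fi$rheobase_pA, 80)
  # degenerate: single spike
  rec1 <- recording("c", "current_clamp", "before",
                    list(make_spike_sweep(300)))
  fi1 <- fi_curve(rec1)
  expect_equal(fi1$table$n_spikes, 1L)
  expect_true(is.na(fi1$table$mean_if_Hz))
  expect_true(is.na(fi1$table$first2_Hz))
})

test_that("noiseless F-I is monotone and rheobase drops with the effect", {
  sim <- simulate_neuron(excitable_params(), protocol_spec("iv_steps"),
                         noise_sd = 0, seed = 1)
  fi <- fi_curve(sim$recording)
  expect_true(all(diff(fi$table$n_spikes) >= 0))
  expect_equal(fi$rheobase_pA, 60)
  after <- apply_effect(excitable_params(), effect_spec(), "after_stim")
  sim2 <- simulate_neuron(after, protocol_spec("iv_steps"), noise_sd = 0,
                          seed = 1)
  fi2 <- fi_curve(sim2$recording)
  expect_lte(fi2$rheobase_pA, fi$rheobase_pA)
  expect_gte(mean(fi2$table$n_spikes), mean(fi$table$n_spikes))
})

test_that("input resistance is exact without noise and robust with it", {
  sim <- simulate_neuron(neuron_params(R = 278), proto_passive(),
                         noise_sd = 0, seed = 1)
  pp <- input_resistance(sim$recording)
  expect_lt(abs(pp$input_resistance_Mohm - 278) / 278, 1e-3)
  expect_equal(pp$resting_potential_mV, -73, tolerance = 1e-6)
  # 10 noisy seeds within 5% (the 50-seed version runs in acceptance)
  err <- vapply(1:10, function(s) {
    sim <- simulate_neuron(neuron_params(R = 278), proto_passive(),
                           noise_sd = 0.1, seed = s)
    abs(input_resistance(sim$recording)$input_resistance_Mohm - 278) / 278
  }, numeric(1))
  expect_true(all(err < 0.05))
})

test_that("input_resistance refuses fewer than 3 usable steps", {
  sim <- simulate_neuron(neuron_params(),
                         protocol_spec("iv_steps", step_range = c(-20, 0)),
                         noise_sd = 0, seed = 1)
  rec <- sim$recording
  rec$sweeps <- rec$sweeps[1]
  expect_error(input_resistance(rec), "fewer than 3")
})

test_that("resting potential is the median and robust to sparse events", {
  flat <- trace(rep(-73, 1.2e5), 0.1, "voltage")
  expect_equal(resting_potential(flat), -73)
  short <- trace(rep(-73, 100), 0.1, "voltage")
  expect_error(resting_potential(short), "shorter")
  # EPSPs riding on -73: median moves < 0.3 mV at ~100 events/min
  sp <- simulate_pair(neuron_params(), neuron_params(),
                      protocol = protocol_spec("spontaneous",
                                               total_duration = 60000),
                      seed = 4)
  vr <- resting_potential(sp$pair$pre$sweeps[[1]]$signal, min_duration_s = 10)
  expect_lt(abs(vr - -73), 0.3)
})
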