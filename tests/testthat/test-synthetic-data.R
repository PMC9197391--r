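# Generator: EIF membrane, spike templates, TM trains, effects, cohorts.

test_that("noiseless subthreshold steps are exactly Ohmic", {
  for (R in c(150, 278, 400)) {
    p <- neuron_params(R = R)
    proto <- protocol_spec("iv_steps", step_range = c(-20, -20))
    sim <- simulate_neuron(p, proto, noise_sd = 0, seed = 1)
    v <- sim$recording$sweeps[[1]]$signal$samples
    ss <- mean(v[5001:6000])        # last 100 ms of the 500 ms step
    expect_equal(ss - p$E_rest, R * -20 / 1000, tolerance = 1e-6)
  }
})

test_that("the I-V protocol produces 14 tagged sweeps from -100 to 160 pA", {
  sim <- simulate_neuron(neuron_params(), protocol_spec("iv_steps"),
                         noise_sd = 0, seed = 1)
  rec <- sim$recording
  expect_length(rec$sweeps, 14L)
  amps <- vapply(rec$sweeps, function(s) s$step_amplitude, numeric(1))
  expect_equal(amps, seq(-100, 160, by = 20))
  expect_true(all(vapply(rec$sweeps, function(s) s$protocol_tag,
                         character(1)) == "iv_step"))
})

test_that("same seed gives byte-identical recordings", {
  a <- simulate_neuron(excitable_params(), proto_60(), seed = 7)
  b <- simulate_neuron(excitable_params(), proto_60(), seed = 7)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  d <- withr::local_tempdir()
  write_recording(a$recording, file.path(d, "a"))
  write_recording(b$recording, file.path(d, "b"))
  for (f in dir(file.path(d, "a")))
    expect_identical(unname(tools::md5sum(file.path(d, "a", f))),
                     unname(tools::md5sum(file.path(d, "b", f))))
})

test_that("spike template take-off equals V_T and truth marks it", {
  p <- excitable_params(V_T = -42.5)
  expect_lt(abs(p$spike_template[1] - -42.5), 0.01)
  sim <- simulate_neuron(p, proto_60(), noise_sd = 0, seed = 1)
  st <- sim$truth$spike_times[[1]]
  expect_gt(length(st), 0)
  v <- sim$recording$sweeps[[1]]$signal$samples
  idx <- round(st / 0.1) + 1
  expect_true(all(abs(v[idx] - -42.5) < 0.01))
})

test_that("negative noise_sd and bad shared fraction are rejected", {
  expect_error(simulate_neuron(neuron_params(), proto_60(), noise_sd = -1),
               "noise_sd")
  expect_error(simulate_pair(neuron_params(), neuron_params(),
                             shared_input_fraction = 1.5,
                             protocol = protocol_spec("spontaneous")),
               "shared_input_fraction")
})

test_that("TM amplitude series matches the independent recursion oracle", {
  syn <- synapse_params(q = 28, U = 0.5, tau_rec = 200)
  expect_equal(tm_amplitudes(syn, 10, 20), tm_oracle(28, 0.5, 200, 10, 20))
  # frozen closed form: R_2 = 1 - 0.5 exp(-0.25)
  expect_equal(tm_amplitudes(syn, 2, 20)[2] / tm_amplitudes(syn, 2, 20)[1],
               1 - 0.5 * exp(-0.25), tolerance = 1e-12)
  # U -> 0 limit: PPR -> 1
  syn0 <- synapse_params(U = 1e-8)
  a <- tm_amplitudes(syn0, 2, 20)
  expect_equal(a[2] / a[1], 1, tolerance = 1e-6)
})

test_that("evoked train tables: failures and convergence", {
  syn <- synapse_params(failure_p = 1)
  tab <- simulate_evoked_train(syn, n_trials = 20, noise_sd = 0, seed = 1)
  expect_true(all(tab$amplitudes == 0))
  expect_error(simulate_evoked_train(synapse_params(), rate_hz = 0), "rate")
  # trial means converge to the analytic series within 3 SEM at 200 trials
  syn <- synapse_params(failure_p = 0)
  tab <- simulate_evoked_train(syn, n_trials = 200, noise_sd = 1, seed = 11)
  m <- colMeans(tab$amplitudes)
  sem <- apply(tab$amplitudes, 2, sd) / sqrt(200)
  expect_true(all(abs(m - tab$truth$amp_series) <= 3 * sem + 1e-9))
})

test_that("apply_effect reproduces the programmed shifts exactly", {
  eff <- effect_spec()          # rm x 305/278, threshold -2.7, ...
  base <- neuron_params(R = 278, V_T = -41)
  shifted <- apply_effect(base, eff, "after_stim")
  expect_equal(shifted$R, 305, tolerance = 1e-12)
  expect_equal(shifted$V_T, -43.7, tolerance = 1e-12)
  # identity effect changes nothing
  same <- apply_effect(base, effect_spec_identity(), "after_stim")
  expect_equal(same$R, base$R)
  expect_equal(same$V_T, base$V_T)
  # before / unstim_control are identity under any effect
  expect_equal(apply_effect(base, eff, "before")$R, 278)
  # evoked scaling: A1 means 14 -> 8 -> 20 pA across conditions
  syn <- synapse_params(q = 28, U = 0.5)
  a1 <- vapply(c("before", "after_stim", "rest_post"), function(cond)
    tm_amplitudes(apply_effect(syn, eff, cond), 1, 20), numeric(1))
  expect_equal(unname(a1), c(14, 8, 20), tolerance = 1e-9)
  expect_error(apply_effect(base, eff, "sideways"), "condition")
})

test_that("connected pairs log a postsynaptic event at the synaptic latency", {
  sp <- simulate_pair(neuron_params(), neuron_params(),
                      synapse = synapse_params(q = 30, latency = 2,
                                               failure_p = 0),
                      protocol = protocol_spec("presyn_train"),
                      seed = 3, n_trials = 3)
  for (tr in 1:3) {
    st <- sp$truth$pre_spike_times[[tr]]
    expect_length(st, 10L)
    expect_equal(sp$truth$event_times[tr, ], st + 2)
  }
  expect_true(all(sp$truth$true_amplitudes > 0))
})

test_that("fully shared input with no observation noise gives r = 1", {
  sp <- simulate_pair(neuron_params(), neuron_params(),
                      shared_input_fraction = 1,
                      protocol = protocol_spec("spontaneous",
                                               total_duration = 60000),
                      seed = 5, noise_mV = 0)
  r <- pair_correlation(sp$pair, window_min = 1)$coefficient
  expect_gte(r, 0.95)
})

test_that("generate_cohort honours the design and is deterministic", {
  co <- generate_cohort(n_pairs = 28, n_connected = 7, seed = 2,
                        n_trials = 2, spontaneous_s = 0)
  expect_equal(nrow(co$manifest), 28L)
  expect_equal(sum(co$manifest$connected), 7L)
  co2 <- generate_cohort(n_pairs = 28, n_connected = 7, seed = 2,
                         n_trials = 2, spontaneous_s = 0)
  expect_identical(co$manifest, co2$manifest)
  expect_error(generate_cohort(n_pairs = 2, n_connected = 3), "n_connected")
  one <- generate_cohort(n_pairs = 1, n_connected = 0, seed = 1,
                         n_trials = 2, spontaneous_s = 0)
  expect_false(one$manifest$connected)
})
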