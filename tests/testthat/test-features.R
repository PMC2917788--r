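make_trace <- function(v, dt = 0.1, stim = 10) {
  trace(v, sampling_interval_ms = dt, stimulus_time_ms = stim)
}

flat_trace <- function(level = 0, dt = 0.1, stim = 10, len_ms = 130) {
  make_trace(rep(level, len_ms / dt + 1), dt, stim)
}

test_that("sweep averaging is a pointwise mean of the trailing window", {
  tr <- simulate_sweep(noiseless_params(), "baseline")
  expect_equal(average_sweeps(list(tr, tr, tr))$voltage_mV, tr$voltage_mV)

  consts <- purrr::map(1:3, function(k) flat_trace(k))
  expect_equal(average_sweeps(consts)$voltage_mV,
               rep(2, length(consts[[1]])))
  # only the last `window` sweeps contribute
  expect_equal(average_sweeps(c(list(flat_trace(100)), consts))$voltage_mV,
               rep(2, length(consts[[1]])))

  expect_error(average_sweeps(consts[1:2]), class = "fepsp_feature_error")
  bad <- flat_trace(1, dt = 0.2, len_ms = 130)
  expect_error(average_sweeps(list(consts[[1]], consts[[2]], bad)),
               class = "fepsp_feature_error")
})

test_that("averaging reduces noise variance by the window size", {
  set.seed(7)
  p <- synth_params(a_fast_mV = 0, a_nmda_mV = 0, noise_sd_mV = 0.05,
                    trial_cv = 0)
  single <- numeric(300)
  avg <- numeric(300)
  for (i in 1:300) {
    sw <- purrr::map(1:3, function(k) simulate_sweep(p, "baseline"))
    single[i] <- sw[[1]]$voltage_mV[500]
    avg[i] <- average_sweeps(sw)$voltage_mV[500]
  }
  expect_equal(var(avg) / var(single), 1 / 3, tolerance = 0.35)
})

test_that("baseline estimation uses the pre-stimulus window", {
  expect_equal(estimate_baseline(flat_trace(0)),
               list(baseline_mV = 0, noise_sd_mV = 0))
  tr <- flat_trace(0.1)
  expect_equal(estimate_baseline(tr)$baseline_mV, 0.1)
  expect_equal(estimate_baseline(tr)$noise_sd_mV, 0)

  set.seed(1)
  v <- rnorm(1301, sd = 0.02)
  noisy <- make_trace(v)
  expect_equal(estimate_baseline(noisy)$noise_sd_mV, 0.02, tolerance = 0.15)
  # only the first 100 samples (10 ms) enter
  expect_equal(estimate_baseline(noisy)$baseline_mV, mean(v[1:100]))

  expect_error(estimate_baseline(make_trace(rep(0, 1301), stim = 3)),
               class = "fepsp_feature_error")
})

test_that("peak measurement finds the negative extremum in the window", {
  flat <- flat_trace(0)
  pk <- measure_peak(flat)
  expect_equal(pk$peak_amplitude_mV, 0)
  expect_equal(pk$latency_to_peak_ms, 0.5) # window start
  expect_equal(pk$qc, "no_response")

  # pure fast kernel: latency equals the closed-form kernel peak time
  dt <- 0.004
  t <- seq(0, 130, by = dt)
  v <- -0.7 * biexp_kernel(t - 10, 0.5, 2)
  tr <- make_trace(v, dt = dt)
  pk <- measure_peak(tr)
  expect_equal(pk$latency_to_peak_ms, biexp_peak_time(0.5, 2),
               tolerance = dt)
  expect_equal(pk$peak_amplitude_mV, -0.7, tolerance = 1e-4)

  expect_error(measure_peak(flat, search_window_ms = c(0.5, 500)),
               class = "fepsp_feature_error")
})

test_that("duration follows the declared threshold rule", {
  expect_equal(measure_duration(flat_trace(0))$duration_ms, 0)

  # 10 ms square pulse far above threshold
  t <- seq(0, 130, by = 0.1)
  v <- ifelse(t > 12 & t <= 22, -1, 0)
  du <- measure_duration(make_trace(v))
  expect_equal(du$duration_ms, 10, tolerance = 0.11)

  # offset waits for a full sub-threshold millisecond: a 0.5 ms dip back
  # to baseline inside the response must not end it
  v2 <- ifelse(t > 12 & t <= 22, -1, 0)
  v2[t > 15 & t <= 15.5] <- 0
  expect_equal(measure_duration(make_trace(v2))$duration_ms, 10,
               tolerance = 0.11)
})

test_that("AUC is the rectified area from the peak to the window end", {
  expect_equal(measure_auc(flat_trace(0)), 0)

  # triangle: -1 mV at the peak decaying linearly to 0 over 10 ms
  t <- seq(0, 130, by = 0.1)
  v <- numeric(length(t))
  ramp <- t >= 12 & t <= 22
  v[ramp] <- -1 * (1 - (t[ramp] - 12) / 10)
  v[t > 10 & t < 12] <- -(t[t > 10 & t < 12] - 10) / 2
  tr <- make_trace(v)
  expect_equal(measure_auc(tr), 5, tolerance = 1e-6)

  expect_error(measure_auc(make_trace(rep(0, 500))),
               class = "fepsp_feature_error")
})

test_that("AUC is baseline-invariant and features are 1-homogeneous", {
  p <- noiseless_params(a_nmda_mV = 0.3)
  tr <- simulate_sweep(p, "gaba_block")
  f1 <- feature_set(tr)

  shifted <- trace(tr$voltage_mV + 0.3, tr$sampling_interval_ms,
                   tr$stimulus_time_ms, tr$meta)
  f2 <- feature_set(shifted)
  expect_equal(f2$auc_mV_ms, f1$auc_mV_ms, tolerance = 1e-9)
  expect_equal(f2$peak_amplitude_mV, f1$peak_amplitude_mV)

  scaled <- trace(tr$voltage_mV * 2.5, tr$sampling_interval_ms,
                  tr$stimulus_time_ms, tr$meta)
  f3 <- feature_set(scaled)
  expect_equal(f3$peak_amplitude_mV, 2.5 * f1$peak_amplitude_mV)
  expect_equal(f3$auc_mV_ms, 2.5 * f1$auc_mV_ms)
  expect_equal(f3$latency_to_peak_ms, f1$latency_to_peak_ms)
  expect_equal(f3$duration_ms, f1$duration_ms)
})

test_that("trapezoid AUC matches adaptive quadrature on the generative form", {
  p <- noiseless_params(a_fast_mV = 0.8, a_nmda_mV = 0.25,
                        tau_decay_fast_ms = 6, tau_decay_nmda_ms = 45)
  tr <- simulate_sweep(p, "gaba_block")
  pk <- measure_peak(tr)
  auc <- measure_auc(tr)
  oracle <- stats::integrate(
    function(t) -oracle_waveform(p, t, "gaba_block"),
    lower = pk$latency_to_peak_ms, upper = 100,
    rel.tol = 1e-10, subdivisions = 2000L)$value
  expect_equal(auc, oracle, tolerance = 1e-3)
})
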