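test_that("the control preset closes on all six calibration targets", {
  p <- preset_params("control", noise_sd_mV = 0, trial_cv = 0)
  proto <- protocol_spec()

  base <- simulate_sweep(p, "baseline")
  gb <- simulate_sweep(p, "gaba_block")
  full <- simulate_sweep(p, "gaba_nmda_block")
  f_base <- feature_set(base, proto)
  f_gb <- feature_set(gb, proto)
  f_full <- feature_set(full, proto)

  expect_equal(f_base$peak_amplitude_mV, -0.71, tolerance = 0.02)
  expect_equal(f_base$latency_to_peak_ms, 2)
  expect_equal(f_base$duration_ms, 4.1, tolerance = 1e-9)
  expect_equal(f_gb$duration_ms, 96, tolerance = 1e-9)
  expect_equal(gaba_contribution(f_base$auc_mV_ms, f_gb$auc_mV_ms),
               85.4, tolerance = 0.005)
  expect_equal(nmda_contribution(f_gb$auc_mV_ms, f_full$auc_mV_ms),
               62.7, tolerance = 0.005)
})

test_that("a zero NMDA target returns a zero NMDA amplitude", {
  p <- calibrate_preset(list(peak_mV = -0.7, latency_ms = 2, nmda_pct = 0),
                        noise_sd_mV = 0, trial_cv = 0,
                        slice_cv_fast = 0, slice_cv_nmda = 0)
  expect_equal(p$a_nmda_mV, 0)
  expect_equal(
    feature_set(simulate_sweep(p, "baseline"))$peak_amplitude_mV,
    -0.7, tolerance = 0.02)
})

test_that("calibrated GABA contribution survives an independent integration", {
  p <- preset_params("control", noise_sd_mV = 0, trial_cv = 0)
  # brute-force trapezoid on the hand-written generative waveform,
  # independent of the package's kernels and AUC code
  tg <- seq(0, 100, by = 0.002)
  v_base <- -oracle_waveform(p, tg, "baseline")
  v_gb <- -oracle_waveform(p, tg, "gaba_block")
  pk_b <- tg[which.max(v_base)]
  pk_g <- tg[which.max(v_gb)]
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  auc_b <- trapz(tg[tg >= pk_b], v_base[tg >= pk_b])
  auc_g <- trapz(tg[tg >= pk_g], v_gb[tg >= pk_g])
  expect_equal(100 * (auc_g - auc_b) / auc_g, 85.4, tolerance = 0.01)
})

test_that("inconsistent calibration targets are rejected", {
  expect_error(calibrate_preset(list(gaba_pct = 120)),
               class = "fepsp_calibration_error")
  expect_error(calibrate_preset(list(peak_mV = 0.5)),
               class = "fepsp_calibration_error")
  expect_error(calibrate_preset(list(duration_baseline_ms = 50,
                                     duration_gaba_block_ms = 10)),
               class = "fepsp_calibration_error")
  expect_error(calibrate_preset(list(rise_time = 1)),
               class = "fepsp_calibration_error")
  expect_error(preset_params("OHT-99wk"), class = "fepsp_parameter_error")
})
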