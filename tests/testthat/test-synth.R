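test_that("pharmacology algebra holds for noise-free sweeps", {
  p <- noiseless_params(a_nmda_mV = 0.4)
  p0 <- noiseless_params(a_nmda_mV = 0)

  # D-AP5 on top of GABA blockade is the same as removing the NMDA
  # component from the disinhibited response
  full <- simulate_sweep(p, "gaba_nmda_block")
  gb0 <- simulate_sweep(p0, "gaba_block")
  expect_equal(full$voltage_mV, gb0$voltage_mV)

  # without gating, baseline equals the disinhibited response
  base <- simulate_sweep(p, "baseline")
  gb <- simulate_sweep(p, "gaba_block")
  g <- gating_envelope(trace_times <- (seq_along(gb$voltage_mV) - 1) * 0.1 -
                         gb$stimulus_time_ms,
                       p$gate_time_ms, p$gate_width_ms, p$gate_floor)
  post <- trace_times >= 0
  expect_equal(base$voltage_mV[post], (gb$voltage_mV * g)[post],
               tolerance = 1e-12)

  # fully silent generator gives a flat zero trace
  flat <- simulate_sweep(noiseless_params(a_fast_mV = 0, a_nmda_mV = 0),
                         "baseline")
  expect_equal(flat$voltage_mV, rep(0, length(flat)))

  expect_error(simulate_sweep(p, "washout"))
})

test_that("slice recordings follow the stimulation schedule deterministically", {
  p <- synth_params()
  sl <- simulate_slice_recording(p, protocol_spec(),
                                 meta = list(slice_id = "A"), seed = 11)
  conds <- vapply(sl$sweeps, function(tr) tr$meta$condition, character(1))
  # 20 min baseline and GABA epochs at 20 s spacing, 10 min D-AP5 epoch
  expect_equal(as.integer(table(conds)[conditions()]), c(60L, 60L, 30L))
  times <- vapply(sl$sweeps, function(tr) tr$meta$sweep_time_s, numeric(1))
  expect_equal(times, seq(0, by = 20, length.out = 150))

  sl2 <- simulate_slice_recording(p, protocol_spec(),
                                  meta = list(slice_id = "A"), seed = 11)
  expect_identical(purrr::map(sl$sweeps, "voltage_mV"),
                   purrr::map(sl2$sweeps, "voltage_mV"))
})

test_that("slice-level scalings are drawn once and shared across epochs", {
  p <- noiseless_params(a_nmda_mV = 0.4, slice_cv_fast = 0.3,
                        slice_cv_nmda = 0.4)
  sl <- simulate_slice_recording(p, short_protocol(),
                                 meta = list(slice_id = "A"), seed = 3)
  conds <- vapply(sl$sweeps, function(tr) tr$meta$condition, character(1))
  # noise-free: all sweeps within one epoch identical
  for (cc in conditions()) {
    vs <- purrr::map(sl$sweeps[conds == cc], "voltage_mV")
    expect_true(all(vapply(vs, identical, logical(1), vs[[1]])))
  }
  # the D-AP5 trace equals the unit-scale one multiplied by the slice's
  # fast scaling; the same factor links the disinhibited traces after the
  # NMDA part is accounted for, i.e. scalings persist across epochs
  unit_full <- simulate_sweep(p, "gaba_nmda_block")
  slice_full <- sl$sweeps[conds == "gaba_nmda_block"][[1]]
  ratio <- slice_full$voltage_mV[unit_full$voltage_mV != 0] /
    unit_full$voltage_mV[unit_full$voltage_mV != 0]
  expect_equal(ratio, rep(sl$info$scale_fast, length(ratio)),
               tolerance = 1e-10)

  p_n <- noiseless_params(a_fast_mV = 1e-9, a_nmda_mV = 0.4)
  unit_nmda <- simulate_sweep(p_n, "gaba_block")
  slice_gb <- sl$sweeps[conds == "gaba_block"][[1]]
  nmda_part <- slice_gb$voltage_mV -
    slice_full$voltage_mV # pure scaled NMDA component
  keep <- abs(unit_nmda$voltage_mV) > 1e-6
  ratio_n <- nmda_part[keep] / unit_nmda$voltage_mV[keep]
  expect_equal(ratio_n, rep(sl$info$scale_nmda, length(ratio_n)),
               tolerance = 1e-4)
})

test_that("measured peak variance follows the noise and trial tiers", {
  p <- synth_params(a_fast_mV = 0.7, a_nmda_mV = 0, noise_sd_mV = 0.01,
                    trial_cv = 0.1, slice_cv_fast = 0, slice_cv_nmda = 0)
  set.seed(99)
  amps <- replicate(400, {
    tr <- simulate_sweep(p, "gaba_block")
    measure_peak(tr)$peak_amplitude_mV
  })
  expected_var <- p$noise_sd_mV^2 + (p$trial_cv * abs(mean(amps)))^2
  expect_equal(var(amps), expected_var, tolerance = 0.25)
})

test_that("cohort simulation is seed-reproducible", {
  spec <- cohort_spec("OHT", 32, "operated", n_slices = 2,
                      params = synth_params(), seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_cohort(spec, short_protocol(), dir = d1)
  m2 <- simulate_cohort(spec, short_protocol(), dir = d2)
  expect_equal(m1$sweeps$file, m2$sweeps$file)
  for (f in m1$sweeps$file[c(1, 15, 40)]) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # operated-eye input is recorded from the right (crossed) hemisphere
  expect_true(all(m1$sweeps$hemisphere == "right"))
})

test_that("intensity calibration returns the 75%-of-plateau point", {
  p <- noiseless_params()
  grid <- seq(0.05, 5, by = 0.05)
  i75 <- io_curve_calibrate(p, grid, i50 = 0.5, hill = 2)
  # invert the Hill response analytically (oracle)
  s_max <- 5^2 / (5^2 + 0.5^2)
  x <- 0.75 * s_max
  expect_equal(i75, 0.5 * sqrt(x / (1 - x)), tolerance = 1e-3)

  # scale invariance: amplitude of the waveform does not matter
  p2 <- noiseless_params(a_fast_mV = 1.4, a_nmda_mV = 0.6)
  expect_equal(io_curve_calibrate(p2, grid, i50 = 0.5, hill = 2), i75,
               tolerance = 1e-9)

  expect_error(io_curve_calibrate(p, seq(0.05, 0.6, by = 0.05)),
               "saturation", class = "fepsp_calibration_error")
})
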