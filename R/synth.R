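#' Generative parameters for synthetic sweeps
#'
#' The synthetic evoked response is the sum of a fast non-NMDA biexponential
#' component and a slow NMDA biexponential component, multiplied by a
#' gating envelope representing intact GABAergic inhibition (active in the
#' baseline condition only), plus Gaussian recording noise:
#' `V(t) = -(A_f K_fast(t) + A_n K_nmda(t)) G(t) + noise`. Amplitudes carry
#' multiplicative lognormal variability at two levels: independent
#' per-trial jitter on each component (`trial_cv`), and per-slice factors
#' drawn once per recording — a common amplitude scale (`slice_cv_fast`)
#' and an NMDA-to-fast balance ratio (`slice_cv_nmda`,
#' `slice_nmda_meanlog`) that carries the between-slice spread of the
#' receptor contributions.
#'
#' @param a_fast_mV Fast (non-NMDA) component peak scale, mV (> 0).
#' @param tau_rise_fast_ms,tau_decay_fast_ms Fast-component time constants,
#'   ms, rise < decay.
#' @param a_nmda_mV NMDA component peak scale, mV (>= 0; the component
#'   removed by D-AP5).
#' @param tau_rise_nmda_ms,tau_decay_nmda_ms NMDA-component time constants,
#'   ms, rise < decay.
#' @param gate_time_ms,gate_width_ms,gate_floor Gating-envelope parameters;
#'   see [gating_envelope()].
#' @param noise_sd_mV Per-sample Gaussian noise SD, mV.
#' @param trial_cv Trial-to-trial amplitude coefficient of variation (< 1).
#' @param slice_cv_fast Between-slice coefficient of variation of the
#'   overall response amplitude (< 1); scales both components together.
#' @param slice_cv_nmda Between-slice coefficient of variation of the
#'   NMDA-to-fast balance ratio (< 1); this is what spreads the
#'   per-slice receptor contributions.
#' @param slice_nmda_meanlog Optional log-scale location of the lognormal
#'   balance ratio. The default (`NULL`) centres the ratio at mean 1;
#'   calibrated presets set it so the cohort-mean contribution equals the
#'   calibration target exactly (see [preset_params()]).
#' @return An object of class `fepsp_synth_params`.
#' @export
synth_params <- function(a_fast_mV = 0.7,
                         tau_rise_fast_ms = 0.5, tau_decay_fast_ms = 2,
                         a_nmda_mV = 0.3,
                         tau_rise_nmda_ms = 2, tau_decay_nmda_ms = 40,
                         gate_time_ms = 3, gate_width_ms = 1,
                         gate_floor = 0.05,
                         noise_sd_mV = 0.02, trial_cv = 0.05,
                         slice_cv_fast = 0.2, slice_cv_nmda = 0.3,
                         slice_nmda_meanlog = NULL) {
  check_taus(tau_rise_fast_ms, tau_decay_fast_ms)
  check_taus(tau_rise_nmda_ms, tau_decay_nmda_ms)
  if (!is_scalar_num(a_fast_mV) || a_fast_mV < 0) {
    stop_fepsp("a_fast_mV must be nonnegative", "fepsp_parameter_error")
  }
  if (!is_scalar_num(a_nmda_mV) || a_nmda_mV < 0) {
    stop_fepsp("a_nmda_mV must be nonnegative", "fepsp_parameter_error")
  }
  if (!is_scalar_num(gate_floor) || gate_floor < 0 || gate_floor > 1) {
    stop_fepsp("gate_floor must lie in [0, 1]", "fepsp_parameter_error")
  }
  for (nm in c("noise_sd_mV", "trial_cv", "slice_cv_fast", "slice_cv_nmda")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v < 0) {
      stop_fepsp(paste0(nm, " must be nonnegative"), "fepsp_parameter_error")
    }
  }
  if (trial_cv >= 1 || slice_cv_fast >= 1 || slice_cv_nmda >= 1) {
    stop_fepsp("coefficients of variation must be < 1",
               "fepsp_parameter_error")
  }
  if (!is.null(slice_nmda_meanlog) && !is_scalar_num(slice_nmda_meanlog)) {
    stop_fepsp("slice_nmda_meanlog must be NULL or a finite number",
               "fepsp_parameter_error")
  }
  structure(
    list(a_fast_mV = a_fast_mV, tau_rise_fast_ms = tau_rise_fast_ms,
         tau_decay_fast_ms = tau_decay_fast_ms, a_nmda_mV = a_nmda_mV,
         tau_rise_nmda_ms = tau_rise_nmda_ms,
         tau_decay_nmda_ms = tau_decay_nmda_ms,
         gate_time_ms = gate_time_ms, gate_width_ms = gate_width_ms,
         gate_floor = gate_floor, noise_sd_mV = noise_sd_mV,
         trial_cv = trial_cv, slice_cv_fast = slice_cv_fast,
         slice_cv_nmda = slice_cv_nmda,
         slice_nmda_meanlog = slice_nmda_meanlog),
    class = "fepsp_synth_params"
  )
}

#' @export
print.fepsp_synth_params <- function(x, ...) {
  cat("<fepsp_synth_params>\n")
  cat(sprintf("  fast: %.4g mV, tau %g/%.3g ms | NMDA: %.4g mV, tau %g/%.3g ms\n",
              x$a_fast_mV, x$tau_rise_fast_ms, x$tau_decay_fast_ms,
              x$a_nmda_mV, x$tau_rise_nmda_ms, x$tau_decay_nmda_ms))
  cat(sprintf("  gate: t=%.3g ms, width=%g ms, floor=%.3g\n",
              x$gate_time_ms, x$gate_width_ms, x$gate_floor))
  cat(sprintf("  noise sd %g mV | trial cv %g | slice cv fast/nmda %g/%g\n",
              x$noise_sd_mV, x$trial_cv, x$slice_cv_fast, x$slice_cv_nmda))
  invisible(x)
}

# Noise-free mean response at times t (ms) after the stimulus, with
# component amplitudes already scaled. Negative-going.
mean_response <- function(params, t_post, condition,
                          scale_fast = 1, scale_nmda = 1) {
  condition <- match.arg(condition, fepsp_conditions)
  a_f <- params$a_fast_mV * scale_fast
  a_n <- if (condition == "gaba_nmda_block") 0 else
    params$a_nmda_mV * scale_nmda
  g <- gating_envelope(t_post, params$gate_time_ms, params$gate_width_ms,
                       params$gate_floor, active = condition == "baseline")
  v <- -(a_f * biexp_kernel(t_post, params$tau_rise_fast_ms,
                            params$tau_decay_fast_ms) +
           a_n * biexp_kernel(t_post, params$tau_rise_nmda_ms,
                              params$tau_decay_nmda_ms)) * g
  v[t_post < 0] <- 0
  v
}

# Mean-1 lognormal multiplier with the given coefficient of variation,
# drawn from the current RNG stream.
rscale_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one evoked sweep
#'
#' Draws one sweep from the generative model: trial-jittered component
#' amplitudes, the condition's pharmacology (gating active only at
#' baseline; NMDA amplitude zero once D-AP5 is applied), and i.i.d.
#' Gaussian noise over the whole record. Uses the current RNG stream; seed
#' at the slice or cohort level for reproducibility.
#'
#' @param params A [synth_params()].
#' @param condition One of [conditions()].
#' @param sampling_interval_ms Sampling interval, ms.
#' @param stimulus_time_ms Stimulus time, ms from sweep start (>= 5 ms so a
#'   baseline window exists).
#' @param record_length_ms Record length, ms; at least
#'   `stimulus_time_ms + 120`.
#' @param scale_fast,scale_nmda Extra multiplicative amplitude scalings
#'   (slice-level factors; drawn once per slice by
#'   [simulate_slice_recording()]).
#' @param meta Metadata list for the trace (condition is filled in).
#' @return A [trace()].
#' @export
simulate_sweep <- function(params, condition,
                           sampling_interval_ms = 0.1,
                           stimulus_time_ms = 10,
                           record_length_ms = stimulus_time_ms + 120,
                           scale_fast = 1, scale_nmda = 1,
                           meta = list()) {
  condition <- match.arg(condition, fepsp_conditions)
  if (record_length_ms < stimulus_time_ms + 120) {
    stop_fepsp("record_length_ms must be at least stimulus_time_ms + 120 ms",
               "fepsp_parameter_error")
  }
  n <- as.integer(floor(record_length_ms / sampling_interval_ms)) + 1L
  t <- (seq_len(n) - 1) * sampling_interval_ms
  jit <- rscale_cv(2, params$trial_cv)
  v <- mean_response(params, t - stimulus_time_ms, condition,
                     scale_fast = scale_fast * jit[1],
                     scale_nmda = scale_nmda * jit[2])
  if (params$noise_sd_mV > 0) v <- v + rnorm(n, sd = params$noise_sd_mV)
  meta$condition <- condition
  trace(v, sampling_interval_ms, stimulus_time_ms, meta = meta)
}

# Deterministic per-slice seed derivation from a master seed (documented
# splitting rule; stays below 2^31).
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1009 + as.numeric(index) * 7919) %%
               2147483629)
}

#' Simulate a full recording session for one slice
#'
#' Generates one sweep per stimulus at the protocol's interval over the
#' three drug epochs (baseline, GABA blockade, GABA + NMDA blockade).
#' Slice-level factors are drawn once and applied to every sweep of the
#' slice: a lognormal overall amplitude scale (CV `slice_cv_fast`) and a
#' lognormal NMDA-to-fast balance ratio (CV `slice_cv_nmda`, location
#' `slice_nmda_meanlog`). Within-slice contrasts are therefore driven by
#' pharmacology while the between-slice spread of amplitudes and receptor
#' contributions matches the biological tier.
#'
#' @param params A [synth_params()].
#' @param protocol A [protocol_spec()].
#' @param meta Slice metadata (see [trace_meta()]); `condition` and
#'   `sweep_time_s` are filled per sweep.
#' @param seed Optional integer seed (set before any draws).
#' @param stimulus_time_ms,record_length_ms Passed to [simulate_sweep()].
#' @return List with `sweeps` (list of traces in time order), `info`
#'   (one-row tibble of slice metadata and the drawn scalings).
#' @export
simulate_slice_recording <- function(params, protocol = protocol_spec(),
                                     meta = list(), seed = NULL,
                                     stimulus_time_ms = 10,
                                     record_length_ms = stimulus_time_ms + 120) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  scale_fast <- rscale_cv(1, params$slice_cv_fast)
  # the balance ratio multiplies the NMDA component on top of the common
  # amplitude factor; the contribution percentages depend on it alone
  sdlog_n <- sqrt(log1p(params$slice_cv_nmda^2))
  meanlog_n <- params$slice_nmda_meanlog %||% (-sdlog_n^2 / 2)
  balance <- if (params$slice_cv_nmda <= 0) exp(meanlog_n %||% 0) else
    rlnorm(1, meanlog = meanlog_n, sdlog = sdlog_n)
  scale_nmda <- balance * scale_fast
  epochs <- c(baseline = protocol$baseline_min,
              gaba_block = protocol$gaba_block_min,
              gaba_nmda_block = protocol$full_block_min)
  sweep_time <- 0
  sweeps <- list()
  for (cond in names(epochs)) {
    n_sw <- epoch_n_sweeps(protocol, epochs[[cond]])
    for (i in seq_len(n_sw)) {
      m <- meta
      m$sweep_time_s <- sweep_time
      sweeps[[length(sweeps) + 1L]] <- simulate_sweep(
        params, cond, stimulus_time_ms = stimulus_time_ms,
        record_length_ms = record_length_ms,
        scale_fast = scale_fast, scale_nmda = scale_nmda, meta = m
      )
      sweep_time <- sweep_time + protocol$stim_interval_s
    }
  }
  info <- tibble(
    slice_id = as.character(meta$slice_id %||% NA),
    hemisphere = as.character(meta$hemisphere %||% NA),
    eye_input = as.character(meta$eye_input %||% NA),
    group = as.character(meta$group %||% NA),
    timepoint_weeks = as.numeric(meta$timepoint_weeks %||% NA),
    scale_fast = scale_fast, scale_nmda = scale_nmda,
    n_sweeps = length(sweeps)
  )
  list(sweeps = sweeps, info = info)
}

#' Specify a simulated cohort
#'
#' @param group `"AMC"` or `"OHT"`.
#' @param timepoint_weeks 3, 16, or 32 (weeks after intraocular-pressure
#'   elevation, or the age-matched equivalent).
#' @param eye_input `"operated"`, `"unoperated"`, or `"control"`.
#' @param n_slices Number of slices (>= 2).
#' @param params A [synth_params()] (typically a calibrated preset; see
#'   [preset_params()]).
#' @param seed Master seed; per-slice seeds are derived deterministically
#'   from it.
#' @param hemisphere Recording hemisphere; defaults to `"right"` for
#'   operated-eye input and `"left"` otherwise (the retinal projection is
#'   predominantly crossed).
#' @param label Cohort label used in reports; default
#'   `"<group>-<timepoint>wk-<eye or hemisphere>"`.
#' @return An object of class `fepsp_cohort_spec`.
#' @export
cohort_spec <- function(group, timepoint_weeks, eye_input, n_slices, params,
                        seed = 1,
                        hemisphere = if (identical(eye_input, "operated"))
                          "right" else "left",
                        label = NULL) {
  group <- match.arg(group, c("AMC", "OHT"))
  eye_input <- match.arg(eye_input, c("operated", "unoperated", "control"))
  if (!timepoint_weeks %in% c(3, 16, 32)) {
    stop_fepsp("timepoint_weeks must be 3, 16 or 32", "fepsp_parameter_error")
  }
  if (!is_scalar_num(n_slices) || n_slices < 2) {
    stop_fepsp("n_slices must be at least 2", "fepsp_parameter_error")
  }
  if (!inherits(params, "fepsp_synth_params")) {
    stop_fepsp("params must be a fepsp_synth_params", "fepsp_parameter_error")
  }
  label <- label %||% paste0(group, "-", timepoint_weeks, "wk-",
                             if (eye_input == "control") hemisphere else
                               eye_input)
  structure(list(group = group, timepoint_weeks = timepoint_weeks,
                 eye_input = eye_input, hemisphere = hemisphere,
                 n_slices = as.integer(n_slices), params = params,
                 seed = as.integer(seed), label = label),
            class = "fepsp_cohort_spec")
}

#' Simulate a cohort of slice recordings
#'
#' Runs [simulate_slice_recording()] for each slice of the cohort with
#' per-slice seeds derived from the master seed. With `dir` set, sweeps are
#' written as sweep files plus a `manifest.yaml` (read back and validated
#' before returning); with `dir = NULL` the recordings stay in memory.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [protocol_spec()].
#' @param dir Output directory, or `NULL` for an in-memory cohort.
#' @return With `dir`: a validated `fepsp_manifest`. Without: a
#'   `fepsp_cohort` (list of slice recordings plus an `info` tibble).
#' @export
simulate_cohort <- function(spec, protocol = protocol_spec(), dir = NULL) {
  if (!inherits(spec, "fepsp_cohort_spec")) {
    stop_fepsp("spec must be a fepsp_cohort_spec", "fepsp_parameter_error")
  }
  slices <- purrr::map(seq_len(spec$n_slices), function(i) {
    meta <- list(
      slice_id = sprintf("%s_S%02d", spec$label, i),
      hemisphere = spec$hemisphere, eye_input = spec$eye_input,
      group = spec$group, timepoint_weeks = spec$timepoint_weeks
    )
    simulate_slice_recording(spec$params, protocol, meta = meta,
                             seed = derive_seed(spec$seed, i))
  })
  info <- dplyr::bind_rows(purrr::map(slices, "info"))
  info$label <- spec$label
  if (is.null(dir)) {
    return(structure(list(slices = slices, info = info, label = spec$label,
                          protocol = protocol),
                     class = "fepsp_cohort"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sweep_rows <- purrr::map(slices, function(sl) {
    sid <- sl$info$slice_id
    dir.create(file.path(dir, sid), showWarnings = FALSE)
    purrr::imap_dfr(sl$sweeps, function(tr, j) {
      f <- file.path(sid, sprintf("sweep_%04d.tsv", j))
      write_sweep_table(tr, file.path(dir, f))
      tibble(slice_id = sid, hemisphere = sl$info$hemisphere,
             eye_input = sl$info$eye_input, group = sl$info$group,
             timepoint_weeks = sl$info$timepoint_weeks,
             condition = tr$meta$condition,
             sweep_time_s = tr$meta$sweep_time_s, file = f)
    })
  })
  manifest <- structure(
    list(protocol = protocol, sweeps = dplyr::bind_rows(sweep_rows),
         dir = dir),
    class = "fepsp_manifest"
  )
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  read_manifest(file.path(dir, "manifest.yaml"))
}

#' Stimulus-intensity calibration on a simulated input-output curve
#'
#' Emulates the session-start procedure of setting the stimulus intensity
#' to 75% of the intensity-response plateau. Response amplitude is
#' modelled as a saturating Hill function of intensity scaling both
#' component amplitudes; the returned intensity is where the response
#' reaches 75% of its plateau (invariant to the plateau's absolute scale).
#'
#' @param params A [synth_params()].
#' @param intensities Increasing grid of stimulus intensities (arbitrary
#'   units); must reach saturation.
#' @param i50 Intensity of half-maximal response.
#' @param hill Hill coefficient of the intensity-response sigmoid.
#' @param target Fraction of the plateau to return (default 0.75).
#' @return The calibrated stimulus intensity (scalar).
#' @export
io_curve_calibrate <- function(params, intensities, i50 = 0.5, hill = 2,
                               target = 0.75) {
  if (length(intensities) < 4 || any(diff(intensities) <= 0)) {
    stop_fepsp("intensities must be an increasing grid of length >= 4",
               "fepsp_calibration_error")
  }
  # plateau response amplitude = |noiseless baseline peak|
  tfine <- seq(0, 15, by = 0.01)
  plateau <- max(-mean_response(params, tfine, "baseline"))
  s <- intensities^hill / (intensities^hill + i50^hill)
  resp <- plateau * s
  n <- length(resp)
  if ((resp[n] - resp[n - 1]) > 0.01 * resp[n]) {
    stop_fepsp("intensity grid does not reach saturation",
               "fepsp_calibration_error")
  }
  plat_hat <- resp[n]
  if (target * plat_hat < resp[1]) {
    stop_fepsp("intensity grid starts above the target response",
               "fepsp_calibration_error")
  }
  approx(resp, intensities, xout = target * plat_hat, ties = "ordered")$y
}
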