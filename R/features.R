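#' Average consecutive sweeps
#'
#' Pointwise mean of the last `window` sweeps of a list (default 3,
#' mirroring the 3-trial / 60 s waveform-averaging unit of the recording
#' protocol). All sweeps must share sampling interval, stimulus time,
#' length, and condition.
#'
#' @param sweeps List of [trace()] objects in time order.
#' @param window Number of trailing sweeps to average.
#' @return A [trace()]; metadata inherited from the last contributing sweep,
#'   with `n_sweeps_averaged` set.
#' @export
average_sweeps <- function(sweeps, window = 3) {
  if (length(sweeps) < window) {
    stop_fepsp(sprintf("need at least %d sweeps, got %d", window,
                       length(sweeps)), "fepsp_feature_error")
  }
  sweeps <- tail(sweeps, window)
  ref <- sweeps[[1]]
  for (tr in sweeps[-1]) {
    if (length(tr) != length(ref) ||
        abs(tr$sampling_interval_ms - ref$sampling_interval_ms) > 1e-12 ||
        abs(tr$stimulus_time_ms - ref$stimulus_time_ms) > 1e-12) {
      stop_fepsp("sweeps differ in time base, length or stimulus time",
                 "fepsp_feature_error")
    }
    cond <- c(tr$meta$condition, ref$meta$condition)
    if (!anyNA(cond) && cond[1] != cond[2]) {
      stop_fepsp("sweeps from different conditions cannot be averaged",
                 "fepsp_feature_error")
    }
  }
  v <- rowMeans(vapply(sweeps, function(tr) tr$voltage_mV,
                       numeric(length(ref))))
  last <- sweeps[[length(sweeps)]]
  meta <- last$meta
  meta$n_sweeps_averaged <- sum(vapply(sweeps, function(tr)
    tr$meta$n_sweeps_averaged, integer(1)))
  trace(v, ref$sampling_interval_ms, ref$stimulus_time_ms, meta = meta)
}

#' Baseline level and noise from the pre-stimulus window
#'
#' Mean and sample SD of the voltage over `[0, stimulus_time_ms)`; the
#' reference for amplitude, threshold, and AUC measurements. Requires at
#' least 5 ms of pre-stimulus record.
#'
#' @param tr A [trace()].
#' @return Named list: `baseline_mV`, `noise_sd_mV`.
#' @export
estimate_baseline <- function(tr) {
  if (tr$stimulus_time_ms < 5) {
    stop_fepsp("need at least 5 ms of pre-stimulus record",
               "fepsp_feature_error")
  }
  pre <- tr$voltage_mV[trace_times(tr) < tr$stimulus_time_ms]
  list(baseline_mV = mean(pre),
       noise_sd_mV = if (length(pre) > 1) sd(pre) else 0)
}

#' Peak amplitude and latency to peak
#'
#' The fEPSP peak is the minimum of the baseline-subtracted voltage over a
#' post-stimulus search window (default 0.5-10 ms, excluding any
#' stimulus-adjacent transient). Amplitude is reported as a negative value
#' in mV; latency is the time of the extremum relative to the stimulus,
#' earliest sample on ties. A flat window is flagged `"no_response"` with
#' amplitude 0 and latency at the window start.
#'
#' @param tr A [trace()].
#' @param search_window_ms Length-2 post-stimulus window, ms.
#' @param baseline Optional result of [estimate_baseline()] (recomputed
#'   otherwise).
#' @return Named list: `peak_amplitude_mV`, `latency_to_peak_ms`, `qc`.
#' @export
measure_peak <- function(tr, search_window_ms = c(0.5, 10),
                         baseline = NULL) {
  baseline <- baseline %||% estimate_baseline(tr)
  t <- trace_times(tr)
  lo <- tr$stimulus_time_ms + search_window_ms[1]
  hi <- tr$stimulus_time_ms + search_window_ms[2]
  if (hi > trace_end_ms(tr) + 1e-9) {
    stop_fepsp("peak search window extends past the record",
               "fepsp_feature_error")
  }
  idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  v <- tr$voltage_mV[idx] - baseline$baseline_mV
  i_min <- which.min(v) # earliest on ties
  amp <- v[i_min]
  qc <- "ok"
  if (amp >= -max(3 * baseline$noise_sd_mV, .Machine$double.eps^0.5)) {
    qc <- "no_response"
    if (amp > 0) amp <- 0
  }
  list(peak_amplitude_mV = amp,
       latency_to_peak_ms = t[idx[i_min]] - tr$stimulus_time_ms,
       qc = qc)
}

#' Response duration by threshold crossing
#'
#' Duration of the evoked deflection under the declared threshold rule:
#' `theta = max(noise_mult * noise SD, frac_of_peak * |peak amplitude|)`;
#' onset is the first post-stimulus time with `|V - baseline| > theta`,
#' offset the first time after the peak where the signal stays below
#' `theta` for at least `hold_ms` (or the record end). Returns 0 with a QC
#' flag when the trace never crosses threshold.
#'
#' @param tr A [trace()].
#' @param baseline Optional [estimate_baseline()] result.
#' @param peak Optional [measure_peak()] result.
#' @param frac_of_peak Threshold as a fraction of the peak amplitude.
#' @param noise_mult Threshold floor in units of the baseline noise SD.
#' @param hold_ms Time the signal must remain sub-threshold to end the
#'   response, ms.
#' @param search_window_ms Peak search window (used when `peak` is not
#'   supplied).
#' @return Named list: `duration_ms`, `onset_ms`, `offset_ms`, `qc`
#'   (times relative to the stimulus).
#' @export
measure_duration <- function(tr, baseline = NULL, peak = NULL,
                             frac_of_peak = 0.05, noise_mult = 3,
                             hold_ms = 1, search_window_ms = c(0.5, 10)) {
  baseline <- baseline %||% estimate_baseline(tr)
  peak <- peak %||% measure_peak(tr, search_window_ms, baseline)
  theta <- max(noise_mult * baseline$noise_sd_mV,
               frac_of_peak * abs(peak$peak_amplitude_mV))
  t <- trace_times(tr)
  post <- which(t >= tr$stimulus_time_ms - 1e-9)
  v <- abs(tr$voltage_mV[post] - baseline$baseline_mV)
  if (theta <= 0 || !any(v > theta)) {
    return(list(duration_ms = 0, onset_ms = NA_real_, offset_ms = NA_real_,
                qc = "no_response"))
  }
  onset_i <- which(v > theta)[1]
  # first post-stimulus sample at or after the peak
  peak_i <- which(t[post] - tr$stimulus_time_ms >=
                    peak$latency_to_peak_ms - 1e-9)[1]
  dt <- tr$sampling_interval_ms
  hold_n <- as.integer(ceiling(hold_ms / dt))
  below <- v <= theta
  below[seq_len(max(peak_i - 1L, 0L))] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_post <- length(v)
  off_i <- NA_integer_
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    if (r$lengths[k] >= hold_n || ends[k] == n_post) {
      off_i <- starts[k]
      break
    }
  }
  if (is.na(off_i)) off_i <- n_post # still above threshold at record end
  onset_ms <- t[post[onset_i]] - tr$stimulus_time_ms
  offset_ms <- t[post[off_i]] - tr$stimulus_time_ms
  list(duration_ms = offset_ms - onset_ms, onset_ms = onset_ms,
       offset_ms = offset_ms, qc = peak$qc)
}

#' Late-phase area under the curve
#'
#' Trapezoidal integral of the below-baseline deflection, `baseline - V`,
#' from the fEPSP peak to `auc_end_ms` after the stimulus; positive in
#' mV*ms for a negative-going response. The signed integrand is the
#' default because it is unbiased under zero-mean recording noise;
#' `rectified = TRUE` integrates `max(baseline - V, 0)` instead, which is
#' guaranteed nonnegative but acquires a positive noise bias wherever the
#' signal is near baseline. The two are identical on noise-free
#' responses.
#'
#' @param tr A [trace()].
#' @param baseline Optional [estimate_baseline()] result.
#' @param peak Optional [measure_peak()] result.
#' @param auc_end_ms Window end, ms after the stimulus.
#' @param rectified Rectify the below-baseline deflection instead of the
#'   signed default.
#' @param search_window_ms Peak search window (used when `peak` is not
#'   supplied).
#' @return Area in mV*ms (scalar).
#' @export
measure_auc <- function(tr, baseline = NULL, peak = NULL, auc_end_ms = 100,
                        rectified = FALSE, search_window_ms = c(0.5, 10)) {
  baseline <- baseline %||% estimate_baseline(tr)
  peak <- peak %||% measure_peak(tr, search_window_ms, baseline)
  t_end <- tr$stimulus_time_ms + auc_end_ms
  if (t_end > trace_end_ms(tr) + 1e-9) {
    stop_fepsp("record too short for the AUC window", "fepsp_feature_error")
  }
  t <- trace_times(tr)
  t0 <- tr$stimulus_time_ms + peak$latency_to_peak_ms
  idx <- which(t >= t0 - 1e-9 & t <= t_end + 1e-9)
  y <- baseline$baseline_mV - tr$voltage_mV[idx]
  if (rectified) y <- pmax(y, 0)
  pracma::trapz(t[idx], y)
}

#' All response features of one averaged sweep
#'
#' Runs [estimate_baseline()], [measure_peak()], [measure_duration()] and
#' [measure_auc()] on a trace and returns the full feature set as a
#' one-row tibble.
#'
#' @param tr A [trace()] (typically an averaged response).
#' @param protocol A [protocol_spec()] supplying the peak search window and
#'   AUC window end.
#' @return One-row tibble: `peak_amplitude_mV`, `latency_to_peak_ms`,
#'   `duration_ms`, `auc_mV_ms`, `baseline_mV`, `noise_sd_mV`,
#'   `n_sweeps_averaged`, `qc`.
#' @examples
#' tr <- simulate_sweep(synth_params(noise_sd_mV = 0, trial_cv = 0),
#'                      "gaba_block")
#' feature_set(tr)
#' @export
feature_set <- function(tr, protocol = protocol_spec()) {
  b <- estimate_baseline(tr)
  pk <- measure_peak(tr, protocol$peak_window_ms, b)
  du <- measure_duration(tr, b, pk, search_window_ms = protocol$peak_window_ms)
  auc <- measure_auc(tr, b, pk, auc_end_ms = protocol$auc_end_ms,
                     search_window_ms = protocol$peak_window_ms)
  tibble(
    peak_amplitude_mV = pk$peak_amplitude_mV,
    latency_to_peak_ms = pk$latency_to_peak_ms,
    duration_ms = du$duration_ms,
    auc_mV_ms = auc,
    baseline_mV = b$baseline_mV,
    noise_sd_mV = b$noise_sd_mV,
    n_sweeps_averaged = tr$meta$n_sweeps_averaged,
    qc = pk$qc
  )
}
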