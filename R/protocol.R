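#' Recording-session protocol
#'
#' Describes the drug-application timeline and stimulation schedule of a
#' recording session: a stable baseline epoch, a GABA-antagonist epoch
#' (picrotoxin + CGP55845), and a final epoch with the NMDA antagonist
#' D-AP5 added, with single 0.1 ms pulses delivered at a fixed interval
#' throughout. Responses are waveform-averaged in blocks of
#' `avg_window_sweeps` consecutive sweeps, and measurements for each drug
#' condition are taken over the last `analysis_window_min` minutes of the
#' epoch.
#'
#' @param baseline_min Baseline epoch duration, minutes.
#' @param gaba_block_min GABA-antagonist epoch duration, minutes.
#' @param full_block_min D-AP5 (+ GABA antagonists) epoch duration, minutes.
#' @param stim_interval_s Interval between stimuli, seconds.
#' @param pulse_ms Stimulus pulse width, ms (metadata only; the pulse itself
#'   is not modelled).
#' @param avg_window_sweeps Number of consecutive sweeps per waveform
#'   average.
#' @param analysis_window_min Length of the per-epoch analysis window,
#'   minutes (taken from the end of the epoch).
#' @param auc_end_ms End of the late-phase area-under-curve window, ms after
#'   the stimulus.
#' @param peak_window_ms Length-2 numeric, the post-stimulus search window
#'   for the fEPSP peak, ms.
#'
#' @return An object of class `fepsp_protocol` (a validated list).
#' @examples
#' protocol_spec()
#' @export
protocol_spec <- function(baseline_min = 20,
                          gaba_block_min = 20,
                          full_block_min = 10,
                          stim_interval_s = 20,
                          pulse_ms = 0.1,
                          avg_window_sweeps = 3,
                          analysis_window_min = 3,
                          auc_end_ms = 100,
                          peak_window_ms = c(0.5, 10)) {
  p <- list(
    baseline_min = baseline_min, gaba_block_min = gaba_block_min,
    full_block_min = full_block_min, stim_interval_s = stim_interval_s,
    pulse_ms = pulse_ms, avg_window_sweeps = avg_window_sweeps,
    analysis_window_min = analysis_window_min, auc_end_ms = auc_end_ms,
    peak_window_ms = peak_window_ms
  )
  scalars <- setdiff(names(p), "peak_window_ms")
  for (nm in scalars) {
    if (!is_scalar_num(p[[nm]]) || p[[nm]] <= 0) {
      stop_fepsp(paste0("protocol field '", nm, "' must be a positive number"),
                 "fepsp_protocol_error")
    }
  }
  if (!is.numeric(peak_window_ms) || length(peak_window_ms) != 2L ||
      any(!is.finite(peak_window_ms)) || peak_window_ms[1] >= peak_window_ms[2] ||
      peak_window_ms[1] < 0) {
    stop_fepsp("peak_window_ms must be an increasing nonnegative interval",
               "fepsp_protocol_error")
  }
  if (analysis_window_min * 60 / stim_interval_s < avg_window_sweeps) {
    stop_fepsp("analysis window holds fewer sweeps than one averaging block",
               "fepsp_protocol_error")
  }
  structure(p, class = "fepsp_protocol")
}

#' @export
print.fepsp_protocol <- function(x, ...) {
  cat("<fepsp_protocol>\n")
  cat(sprintf("  epochs (min): baseline %g | GABA block %g | +D-AP5 %g\n",
              x$baseline_min, x$gaba_block_min, x$full_block_min))
  cat(sprintf("  stimulation: %g ms pulse every %g s; %d-sweep averages\n",
              x$pulse_ms, x$stim_interval_s, x$avg_window_sweeps))
  cat(sprintf("  analysis: last %g min; AUC to %g ms; peak search %g-%g ms\n",
              x$analysis_window_min, x$auc_end_ms,
              x$peak_window_ms[1], x$peak_window_ms[2]))
  invisible(x)
}

# Number of sweeps in one epoch / in the analysis window.
epoch_n_sweeps <- function(protocol, epoch_min) {
  as.integer(round(epoch_min * 60 / protocol$stim_interval_s))
}

analysis_n_sweeps <- function(protocol) {
  epoch_n_sweeps(protocol, protocol$analysis_window_min)
}
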