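# Shared fixtures: noise-free generator parameters and a shortened
# protocol (3 min per epoch = exactly one 9-sweep analysis window) so
# simulation-heavy tests stay fast without changing any analysis window.

noiseless_params <- function(...) {
  args <- list(...)
  defaults <- list(noise_sd_mV = 0, trial_cv = 0,
                   slice_cv_fast = 0, slice_cv_nmda = 0)
  do.call(synth_params, utils::modifyList(defaults, args))
}

short_protocol <- function(...) {
  protocol_spec(baseline_min = 3, gaba_block_min = 3, full_block_min = 3,
                ...)
}

# Hand-written generative waveform, kept independent of the package's
# kernel/gating code so it can serve as an oracle.
oracle_waveform <- function(p, t, condition) {
  biexp <- function(t, tr, td) {
    tp <- log(td / tr) * tr * td / (td - tr)
    pk <- exp(-tp / td) - exp(-tp / tr)
    ifelse(t < 0, 0, (exp(-t / td) - exp(-t / tr)) / pk)
  }
  a_n <- if (condition == "gaba_nmda_block") 0 else p$a_nmda_mV
  g <- if (condition == "baseline") {
    w0 <- p$gate_width_ms / (2 * log(9))
    p$gate_floor + (1 - p$gate_floor) /
      (1 + exp((t - p$gate_time_ms) / w0))
  } else 1
  -(p$a_fast_mV * biexp(t, p$tau_rise_fast_ms, p$tau_decay_fast_ms) +
      a_n * biexp(t, p$tau_rise_nmda_ms, p$tau_decay_nmda_ms)) * g
}

# Noise-free single-slice sweep set (9 sweeps per condition) for
# contribution tests.
noiseless_slice_sweeps <- function(params, protocol = short_protocol()) {
  simulate_slice_recording(params, protocol,
                           meta = list(slice_id = "S1"), seed = 1)$sweeps
}
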