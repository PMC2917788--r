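#' Normalized biexponential synaptic kernel
#'
#' The standard difference-of-exponentials synaptic waveform,
#' `K(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / K(t*)`, normalized so
#' its peak value is 1 at
#' `t* = log(tau_decay/tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)`.
#' `K(0) = 0`, `K(t) -> 0` as `t -> Inf`, and `K(t) = 0` for `t < 0`.
#'
#' @param t Time(s) since onset, ms (vectorized).
#' @param tau_rise Rise time constant, ms; must be `< tau_decay`.
#' @param tau_decay Decay time constant, ms.
#' @return Unitless kernel values in `[0, 1]`.
#' @examples
#' biexp_peak_time(0.5, 2) # 0.924 ms
#' biexp_kernel(biexp_peak_time(0.5, 2), 0.5, 2) # 1
#' @export
biexp_kernel <- function(t, tau_rise, tau_decay) {
  check_taus(tau_rise, tau_decay)
  tp <- biexp_peak_time(tau_rise, tau_decay)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  k <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak
  k[t < 0] <- 0
  k
}

#' @describeIn biexp_kernel Closed-form time of the kernel peak, ms.
#' @export
biexp_peak_time <- function(tau_rise, tau_decay) {
  check_taus(tau_rise, tau_decay)
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

check_taus <- function(tau_rise, tau_decay) {
  if (!is_scalar_num(tau_rise) || !is_scalar_num(tau_decay) ||
      tau_rise <= 0 || tau_decay <= 0) {
    stop_fepsp("time constants must be positive numbers",
               "fepsp_parameter_error")
  }
  if (tau_rise >= tau_decay) {
    stop_fepsp("tau_rise must be smaller than tau_decay",
               "fepsp_parameter_error")
  }
  invisible(TRUE)
}

#' GABAergic gating envelope
#'
#' A monotone non-increasing logistic envelope that models intact GABAergic
#' inhibition truncating the late phase of the evoked response: 1 for
#' `t << gate_time_ms`, `gate_floor` for `t >> gate_time_ms`, half-transition
#' at `gate_time_ms`, 10-90% transition width `gate_width_ms`. With
#' `active = FALSE` (GABA receptors blocked) it is identically 1.
#'
#' @param t Time(s) since the stimulus, ms (vectorized).
#' @param gate_time_ms Half-transition time, ms.
#' @param gate_width_ms 10-90% transition width, ms.
#' @param gate_floor Late-phase residual in `[0, 1]`.
#' @param active If `FALSE`, inhibition is blocked and the envelope is 1.
#' @return Values in `[gate_floor, 1]`.
#' @export
gating_envelope <- function(t, gate_time_ms, gate_width_ms, gate_floor,
                            active = TRUE) {
  if (!is_scalar_num(gate_time_ms) || gate_time_ms <= 0 ||
      !is_scalar_num(gate_width_ms) || gate_width_ms <= 0) {
    stop_fepsp("gate_time_ms and gate_width_ms must be positive",
               "fepsp_parameter_error")
  }
  if (!is_scalar_num(gate_floor) || gate_floor < 0 || gate_floor > 1) {
    stop_fepsp("gate_floor must lie in [0, 1]", "fepsp_parameter_error")
  }
  if (!active) return(rep(1, length(t)))
  # logistic scale such that the 10->90% drop spans gate_width_ms
  w0 <- gate_width_ms / (2 * log(9))
  f <- 1 / (1 + exp((t - gate_time_ms) / w0))
  gate_floor + (1 - gate_floor) * f
}
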