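#' A single evoked sweep
#'
#' Constructs a `fepsp_trace`: one stimulus-locked extracellular recording on
#' a uniform time base. Voltages are in mV, time in ms from sweep start; the
#' stimulus time is metadata (all latencies downstream are reported relative
#' to it), not a shift of the time axis.
#'
#' @param voltage_mV Numeric vector of finite voltages, mV.
#' @param sampling_interval_ms Sampling interval, ms (0.1 = 10 kHz).
#' @param stimulus_time_ms Stimulus time, ms from sweep start; must lie
#'   within the record.
#' @param meta Named list of sweep metadata; see [trace_meta()]. Unknown
#'   entries are dropped.
#'
#' @return An object of class `fepsp_trace`.
#' @examples
#' tr <- trace(rnorm(1301, sd = 0.02), 0.1, stimulus_time_ms = 10)
#' tr
#' @export
trace <- function(voltage_mV, sampling_interval_ms = 0.1,
                  stimulus_time_ms = 10, meta = list()) {
  if (!is.numeric(voltage_mV) || length(voltage_mV) == 0L) {
    stop_fepsp("voltage_mV must be a non-empty numeric vector",
               "fepsp_trace_error")
  }
  if (any(!is.finite(voltage_mV))) {
    stop_fepsp("voltage_mV contains non-finite values", "fepsp_trace_error")
  }
  if (!is_scalar_num(sampling_interval_ms) || sampling_interval_ms <= 0) {
    stop_fepsp("sampling_interval_ms must be a positive number",
               "fepsp_trace_error")
  }
  end_ms <- (length(voltage_mV) - 1L) * sampling_interval_ms
  if (!is_scalar_num(stimulus_time_ms) || stimulus_time_ms < 0 ||
      stimulus_time_ms > end_ms) {
    stop_fepsp("stimulus_time_ms must lie within the record",
               "fepsp_trace_error")
  }
  structure(
    list(
      voltage_mV = as.numeric(voltage_mV),
      sampling_interval_ms = sampling_interval_ms,
      stimulus_time_ms = stimulus_time_ms,
      meta = do.call(trace_meta, meta)
    ),
    class = "fepsp_trace"
  )
}

#' Sweep metadata
#'
#' Standard metadata attached to a sweep: slice identity, hemisphere, which
#' eye provides the retinal input, experimental group (age-matched control
#' `AMC` or ocular-hypertension `OHT`), weeks after intraocular-pressure
#' elevation, drug condition, and the sweep's wall-clock time within the
#' session. All fields are optional (`NA` when unknown); supplied values are
#' validated against their token sets.
#'
#' @param slice_id Character slice identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @param eye_input `"operated"`, `"unoperated"`, or `"control"`.
#' @param group `"AMC"` or `"OHT"`.
#' @param timepoint_weeks 3, 16, or 32.
#' @param condition One of [conditions()].
#' @param sweep_time_s Nonnegative seconds from session start.
#' @param n_sweeps_averaged Number of raw sweeps averaged into this trace.
#' @return A named list.
#' @export
trace_meta <- function(slice_id = NA_character_, hemisphere = NA_character_,
                       eye_input = NA_character_, group = NA_character_,
                       timepoint_weeks = NA_real_, condition = NA_character_,
                       sweep_time_s = NA_real_, n_sweeps_averaged = 1L) {
  chk_token <- function(x, allowed, nm) {
    x <- as.character(x)
    if (!is.na(x) && !x %in% allowed) {
      stop_fepsp(paste0("meta field '", nm, "' must be one of: ",
                        paste(allowed, collapse = ", ")),
                 "fepsp_trace_error")
    }
    x
  }
  hemisphere <- chk_token(hemisphere, c("left", "right"), "hemisphere")
  eye_input <- chk_token(eye_input, c("operated", "unoperated", "control"),
                         "eye_input")
  group <- chk_token(group, c("AMC", "OHT"), "group")
  condition <- chk_token(condition, fepsp_conditions, "condition")
  timepoint_weeks <- as.numeric(timepoint_weeks)
  if (!is.na(timepoint_weeks) && !timepoint_weeks %in% c(3, 16, 32)) {
    stop_fepsp("meta field 'timepoint_weeks' must be 3, 16 or 32",
               "fepsp_trace_error")
  }
  sweep_time_s <- as.numeric(sweep_time_s)
  if (!is.na(sweep_time_s) && sweep_time_s < 0) {
    stop_fepsp("meta field 'sweep_time_s' must be nonnegative",
               "fepsp_trace_error")
  }
  list(slice_id = as.character(slice_id), hemisphere = hemisphere,
       eye_input = eye_input, group = group,
       timepoint_weeks = timepoint_weeks, condition = condition,
       sweep_time_s = sweep_time_s,
       n_sweeps_averaged = as.integer(n_sweeps_averaged))
}

trace_times <- function(tr) {
  (seq_along(tr$voltage_mV) - 1) * tr$sampling_interval_ms
}

trace_end_ms <- function(tr) {
  (length(tr$voltage_mV) - 1) * tr$sampling_interval_ms
}

#' @export
print.fepsp_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<fepsp_trace> %d samples @ %g ms (%g ms), stimulus at %g ms\n",
              length(x$voltage_mV), x$sampling_interval_ms,
              trace_end_ms(x), x$stimulus_time_ms))
  cat(sprintf("  slice %s | %s | %s | %s | %s wk | %s | t=%gs | avg of %d\n",
              m$slice_id, m$group, m$hemisphere, m$eye_input,
              format(m$timepoint_weeks), m$condition, m$sweep_time_s,
              m$n_sweeps_averaged))
  invisible(x)
}

#' @describeIn trace Convert a trace to a two-column tibble
#'   (`time_ms`, `voltage_mV`).
#' @param x A `fepsp_trace`.
#' @param ... Unused.
#' @export
as_tibble.fepsp_trace <- function(x, ...) {
  tibble(time_ms = trace_times(x), voltage_mV = x$voltage_mV)
}

#' @export
length.fepsp_trace <- function(x) length(x$voltage_mV)

#' Plot a sweep
#'
#' @param object A `fepsp_trace`.
#' @param ... Unused.
#' @return A ggplot: voltage against time with the stimulus marked.
#' @export
autoplot.fepsp_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$voltage_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$stimulus_time_ms,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (mV)",
                  title = object$meta$condition) +
    ggplot2::theme_minimal()
}
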