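#' Read a sweep file
#'
#' Sweep files are plain tab-delimited text: a block of `# key: value`
#' header lines carrying the stimulus time and sweep metadata, a column
#' header line, then two columns `time_ms` and `voltage_mV`. The time
#' column must be uniform (within 1e-9 ms) and is re-expressed as the
#' trace's sampling interval. The only mandatory header key is
#' `stimulus_time_ms`; metadata keys absent from the header are `NA`.
#'
#' @param path Path to a sweep file.
#' @return A [trace()].
#' @seealso [write_sweep_table()]
#' @export
read_sweep_table <- function(path) {
  if (!file.exists(path)) {
    stop_fepsp(paste0("sweep file not found: ", path), "fepsp_format_error")
  }
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx))) {
    stop_fepsp("header lines must precede the data block", "fepsp_format_error")
  }
  hdr <- lines[hdr_idx]
  keys <- sub("^#\\s*([^:]+):.*$", "\\1", hdr)
  vals <- trimws(sub("^#\\s*[^:]+:\\s*", "", hdr))
  names(vals) <- trimws(keys)

  if (!"stimulus_time_ms" %in% names(vals)) {
    stop_fepsp("missing header key: stimulus_time_ms", "fepsp_format_error")
  }
  stim <- suppressWarnings(as.numeric(vals[["stimulus_time_ms"]]))
  if (!is.finite(stim)) {
    stop_fepsp("header key stimulus_time_ms is not numeric",
               "fepsp_format_error")
  }

  body <- lines[-seq_along(hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("time_ms", body[1])) body <- body[-1]
  if (!length(body)) {
    stop_fepsp("sweep file contains no samples", "fepsp_format_error")
  }
  tab <- utils::read.table(text = body, sep = "\t", header = FALSE,
                           colClasses = "numeric", col.names =
                             c("time_ms", "voltage_mV"))
  t <- tab$time_ms
  v <- tab$voltage_mV
  if (any(!is.finite(v))) {
    stop_fepsp("non-finite voltage value in sweep file", "fepsp_format_error")
  }
  if (length(t) > 1) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-9) {
      stop_fepsp("non-uniform time base in sweep file", "fepsp_format_error")
    }
    dt <- dt[1]
  } else {
    dt <- 0.1
  }
  if (abs(t[1]) > 1e-9) {
    stop_fepsp("time column must start at 0 ms", "fepsp_format_error")
  }

  meta_keys <- c("slice_id", "hemisphere", "eye_input", "group",
                 "timepoint_weeks", "condition", "sweep_time_s",
                 "n_sweeps_averaged")
  meta <- list()
  for (k in intersect(meta_keys, names(vals))) {
    meta[[k]] <- if (k %in% c("timepoint_weeks", "sweep_time_s",
                              "n_sweeps_averaged")) {
      as.numeric(vals[[k]])
    } else {
      vals[[k]]
    }
  }
  trace(v, sampling_interval_ms = dt, stimulus_time_ms = stim, meta = meta)
}

#' Write a sweep file
#'
#' Writes a trace in the format read by [read_sweep_table()]. Voltages are
#' written with 17 significant digits so a read/write round trip reproduces
#' them bit-exactly; two writes of the same trace are byte-identical.
#'
#' @param tr A [trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(tr, path) {
  if (!inherits(tr, "fepsp_trace")) {
    stop_fepsp("write_sweep_table() needs a fepsp_trace", "fepsp_format_error")
  }
  m <- tr$meta
  hdr <- c(
    sprintf("# stimulus_time_ms: %.17g", tr$stimulus_time_ms),
    sprintf("# slice_id: %s", m$slice_id),
    sprintf("# hemisphere: %s", m$hemisphere),
    sprintf("# eye_input: %s", m$eye_input),
    sprintf("# group: %s", m$group),
    sprintf("# timepoint_weeks: %s", format(m$timepoint_weeks)),
    sprintf("# condition: %s", m$condition),
    sprintf("# sweep_time_s: %s", format(m$sweep_time_s)),
    sprintf("# n_sweeps_averaged: %d", m$n_sweeps_averaged)
  )
  t <- trace_times(tr)
  rows <- sprintf("%.12g\t%.17g", t, tr$voltage_mV)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, "time_ms\tvoltage_mV", rows), con)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' The manifest is a YAML file with a `protocol` block (fields of
#' [protocol_spec()]) and a `slices` list; each slice carries its metadata
#' and a `sweeps` list of `{file, condition, sweep_time_s}` entries with
#' paths relative to the manifest. Validation checks that every referenced
#' file exists, that all three drug conditions are present with at least 3
#' sweeps each, and that conditions appear in protocol order.
#'
#' @param path Path to a manifest YAML file.
#' @return A `fepsp_manifest`: list with `protocol` (a [protocol_spec()]),
#'   `sweeps` (a tibble, one row per sweep), and `dir` (base directory for
#'   sweep paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_fepsp(paste0("manifest not found: ", path), "fepsp_manifest_error")
  }
  raw <- yaml::read_yaml(path)
  validate_manifest_list(raw, dir = dirname(path))
}

validate_manifest_list <- function(raw, dir) {
  if (is.null(raw$protocol)) {
    stop_fepsp("manifest field missing: protocol", "fepsp_manifest_error")
  }
  if (is.null(raw$slices) || !length(raw$slices)) {
    stop_fepsp("manifest field missing or empty: slices",
               "fepsp_manifest_error")
  }
  proto <- tryCatch(do.call(protocol_spec, raw$protocol), error = function(e) {
    stop_fepsp(paste0("manifest field invalid: protocol (",
                      conditionMessage(e), ")"), "fepsp_manifest_error")
  })

  rows <- purrr::imap(raw$slices, function(sl, i) {
    where <- paste0("slices[", i, "]")
    for (f in c("slice_id", "sweeps")) {
      if (is.null(sl[[f]])) {
        stop_fepsp(paste0("manifest field missing: ", where, ".", f),
                   "fepsp_manifest_error")
      }
    }
    purrr::imap_dfr(sl$sweeps, function(sw, j) {
      for (f in c("file", "condition", "sweep_time_s")) {
        if (is.null(sw[[f]])) {
          stop_fepsp(paste0("manifest field missing: ", where,
                            ".sweeps[", j, "].", f), "fepsp_manifest_error")
        }
      }
      if (!sw$condition %in% fepsp_conditions) {
        stop_fepsp(paste0("manifest field invalid: ", where, ".sweeps[", j,
                          "].condition = ", sw$condition),
                   "fepsp_manifest_error")
      }
      tibble(
        slice_id = as.character(sl$slice_id),
        hemisphere = as.character(sl$hemisphere %||% NA),
        eye_input = as.character(sl$eye_input %||% NA),
        group = as.character(sl$group %||% NA),
        timepoint_weeks = as.numeric(sl$timepoint_weeks %||% NA),
        condition = sw$condition,
        sweep_time_s = as.numeric(sw$sweep_time_s),
        file = sw$file
      )
    })
  })
  sweeps <- dplyr::bind_rows(rows)

  missing <- sweeps$file[!file.exists(file.path(dir, sweeps$file))]
  if (length(missing)) {
    stop_fepsp(paste0("manifest references missing sweep file(s): ",
                      paste(head(missing, 3), collapse = ", ")),
               "fepsp_manifest_error")
  }

  for (sid in unique(sweeps$slice_id)) {
    sub <- sweeps[sweeps$slice_id == sid, ]
    counts <- table(factor(sub$condition, levels = fepsp_conditions))
    low <- names(counts)[counts < 3]
    if (length(low)) {
      stop_fepsp(paste0("slice ", sid, " has fewer than 3 sweeps for ",
                        "condition(s): ", paste(low, collapse = ", ")),
                 "fepsp_manifest_error")
    }
    ord <- sub[order(sub$sweep_time_s), ]
    ranks <- match(ord$condition, fepsp_conditions)
    if (any(diff(ranks) < 0)) {
      stop_fepsp(paste0("slice ", sid, " has conditions out of protocol ",
                        "order (baseline -> gaba_block -> gaba_nmda_block)"),
                 "fepsp_manifest_error")
    }
  }

  structure(list(protocol = proto, sweeps = sweeps, dir = dir),
            class = "fepsp_manifest")
}

#' @export
print.fepsp_manifest <- function(x, ...) {
  cat(sprintf("<fepsp_manifest> %d slices, %d sweep files in %s\n",
              dplyr::n_distinct(x$sweeps$slice_id), nrow(x$sweeps), x$dir))
  invisible(x)
}

#' Write a dataset manifest
#'
#' @param manifest A `fepsp_manifest`.
#' @param path Output path for the YAML file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  proto <- unclass(manifest$protocol)
  slices <- manifest$sweeps |>
    dplyr::group_by(.data$slice_id) |>
    dplyr::group_map(function(df, key) {
      list(
        slice_id = key$slice_id,
        hemisphere = df$hemisphere[1],
        eye_input = df$eye_input[1],
        group = df$group[1],
        timepoint_weeks = df$timepoint_weeks[1],
        sweeps = purrr::pmap(
          list(df$file, df$condition, df$sweep_time_s),
          function(f, cond, ts) list(file = f, condition = cond,
                                     sweep_time_s = ts)
        )
      )
    })
  yaml::write_yaml(list(protocol = proto, slices = slices), path)
  invisible(path)
}

#' Load the sweeps of one slice from a manifest
#'
#' @param manifest A `fepsp_manifest`.
#' @param slice_id Slice to load.
#' @return List of [trace()] objects in sweep-time order.
#' @export
load_slice_sweeps <- function(manifest, slice_id) {
  sub <- manifest$sweeps[manifest$sweeps$slice_id == slice_id, ]
  if (!nrow(sub)) {
    stop_fepsp(paste0("unknown slice_id: ", slice_id), "fepsp_manifest_error")
  }
  sub <- sub[order(sub$sweep_time_s), ]
  purrr::map(file.path(manifest$dir, sub$file), read_sweep_table)
}
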