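#' Select and average the analysis window of one drug epoch
#'
#' Measurements for each condition are taken over the last minutes of the
#' epoch (default 3 min = 9 sweeps at a 20 s interval). The window is
#' split into consecutive blocks of `avg_window_sweeps` (default 3)
#' waveform averages; the block features are averaged to give the
#' condition's feature set, and the full-window mean trace is returned as
#' well.
#'
#' @param sweeps List of [trace()] objects of one condition, time order.
#' @param protocol A [protocol_spec()].
#' @return List: `trace` (mean of the whole window), `block_features`
#'   (tibble, one row per averaging block), `features` (one-row tibble of
#'   block-averaged features).
#' @export
select_analysis_response <- function(sweeps, protocol = protocol_spec()) {
  n_need <- analysis_n_sweeps(protocol)
  if (length(sweeps) < n_need) {
    stop_fepsp(sprintf(
      "epoch too short: analysis window needs %d sweeps, got %d",
      n_need, length(sweeps)), "fepsp_contribution_error")
  }
  win <- tail(sweeps, n_need)
  w <- protocol$avg_window_sweeps
  n_blocks <- n_need %/% w
  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    average_sweeps(win[seq((b - 1) * w + 1, b * w)], window = w)
  })
  block_features <- purrr::map_dfr(blocks, feature_set, protocol = protocol)
  num <- vapply(block_features, is.numeric, logical(1))
  features <- block_features[1, ]
  features[num] <- purrr::map(block_features[num], mean)
  features$n_sweeps_averaged <- as.integer(
    sum(block_features$n_sweeps_averaged))
  features$qc <- if (all(block_features$qc == "ok")) "ok" else
    paste(unique(block_features$qc[block_features$qc != "ok"]),
          collapse = ";")
  list(trace = average_sweeps(win, window = n_need),
       block_features = block_features, features = features)
}

#' GABA-receptor contribution to the fEPSP
#'
#' Fraction of the disinhibited-response area revealed by GABA blockade:
#' `100 * (auc_gaba_block - auc_baseline) / auc_gaba_block` (%). Negative
#' values (blockade reduced the response) are reported, not clamped.
#'
#' @param auc_baseline Late-phase AUC under baseline conditions, mV*ms.
#' @param auc_gaba_block Late-phase AUC under GABA blockade, mV*ms.
#' @return Percent contribution (vectorized).
#' @examples
#' gaba_contribution(0.15, 1) # 85
#' @export
gaba_contribution <- function(auc_baseline, auc_gaba_block) {
  if (any(auc_gaba_block <= 0)) {
    stop_fepsp("undefined contribution: disinhibited AUC must be positive",
               "fepsp_contribution_error")
  }
  100 * (auc_gaba_block - auc_baseline) / auc_gaba_block
}

#' NMDA-receptor contribution to the excitatory fEPSP
#'
#' Fraction of the disinhibited-response area removed by D-AP5:
#' `100 * (auc_gaba_block - auc_full_block) / auc_gaba_block` (%).
#'
#' @param auc_gaba_block Late-phase AUC under GABA blockade, mV*ms.
#' @param auc_full_block Late-phase AUC under GABA + NMDA blockade, mV*ms.
#' @return Percent contribution (vectorized).
#' @examples
#' nmda_contribution(1, 0.46) # 54
#' @export
nmda_contribution <- function(auc_gaba_block, auc_full_block) {
  if (any(auc_gaba_block <= 0)) {
    stop_fepsp("undefined contribution: disinhibited AUC must be positive",
               "fepsp_contribution_error")
  }
  100 * (auc_gaba_block - auc_full_block) / auc_gaba_block
}

#' Normalize a drug-condition measurement to baseline
#'
#' @param feature_drug Measurement under the drug condition.
#' @param feature_baseline The baseline measurement (nonzero).
#' @return `feature_drug / feature_baseline` (vectorized).
#' @export
normalize_to_baseline <- function(feature_drug, feature_baseline) {
  if (any(feature_baseline == 0)) {
    stop_fepsp("cannot normalize to a zero baseline measurement",
               "fepsp_contribution_error")
  }
  feature_drug / feature_baseline
}

#' Per-slice receptor contributions
#'
#' Composes the per-slice analysis: for each of the three drug conditions,
#' select and average the analysis window, extract features, then compute
#' the GABA and NMDA contribution percentages from the condition AUCs and
#' the baseline-normalized peak-amplitude ratios. Out-of-range percentages
#' are flagged in `qc`, never clamped.
#'
#' @param sweeps List of [trace()] objects of one slice (all conditions).
#' @param protocol A [protocol_spec()].
#' @return One-row tibble: slice metadata, the three condition AUCs
#'   (`auc_baseline`, `auc_gaba_block`, `auc_full_block`), `gaba_pct`,
#'   `nmda_pct`, amplitude ratios `amp_ratio_gaba` (GABA block vs baseline)
#'   and `amp_ratio_dap5` (D-AP5 vs GABA block), and `qc`.
#' @export
slice_contributions <- function(sweeps, protocol = protocol_spec()) {
  conds <- vapply(sweeps, function(tr) tr$meta$condition, character(1))
  if (anyNA(conds)) {
    stop_fepsp("every sweep needs a condition in its metadata",
               "fepsp_contribution_error")
  }
  missing <- setdiff(fepsp_conditions, unique(conds))
  if (length(missing)) {
    stop_fepsp(paste0("slice is missing condition epoch(s): ",
                      paste(missing, collapse = ", ")),
               "fepsp_contribution_error")
  }
  sel <- purrr::map(setNames(fepsp_conditions, fepsp_conditions),
                    function(cc) {
                      select_analysis_response(sweeps[conds == cc], protocol)
                    })
  f <- purrr::map(sel, "features")
  auc_b <- f$baseline$auc_mV_ms
  auc_g <- f$gaba_block$auc_mV_ms
  auc_f <- f$gaba_nmda_block$auc_mV_ms
  gaba <- gaba_contribution(auc_b, auc_g)
  nmda <- nmda_contribution(auc_g, auc_f)
  qc <- unique(c(
    unlist(purrr::map(f, "qc")),
    if (gaba < 0 || gaba > 100) "gaba_pct_out_of_range",
    if (nmda < 0 || nmda > 100) "nmda_pct_out_of_range"
  ))
  qc <- setdiff(qc, "ok")
  meta <- sweeps[[1]]$meta
  tibble(
    slice_id = meta$slice_id, group = meta$group,
    timepoint_weeks = meta$timepoint_weeks, hemisphere = meta$hemisphere,
    eye_input = meta$eye_input,
    auc_baseline = auc_b, auc_gaba_block = auc_g, auc_full_block = auc_f,
    gaba_pct = gaba, nmda_pct = nmda,
    amp_ratio_gaba = normalize_to_baseline(
      f$gaba_block$peak_amplitude_mV, f$baseline$peak_amplitude_mV),
    amp_ratio_dap5 = normalize_to_baseline(
      f$gaba_nmda_block$peak_amplitude_mV, f$gaba_block$peak_amplitude_mV),
    qc = if (length(qc)) paste(qc, collapse = ";") else "ok"
  )
}

# Iterate slice -> sweeps over a manifest or in-memory cohort.
map_slices <- function(x, fn) {
  if (inherits(x, "fepsp_manifest")) {
    ids <- unique(x$sweeps$slice_id)
    return(purrr::map_dfr(ids, function(sid)
      fn(load_slice_sweeps(x, sid), x$protocol)))
  }
  if (inherits(x, "fepsp_cohort")) {
    return(purrr::map_dfr(x$slices, function(sl)
      fn(sl$sweeps, x$protocol)))
  }
  stop_fepsp("expected a fepsp_manifest or fepsp_cohort",
             "fepsp_contribution_error")
}

#' Receptor contributions for every slice of a dataset
#'
#' @param x A `fepsp_manifest` (from [read_manifest()] /
#'   [simulate_cohort()]) or an in-memory `fepsp_cohort`.
#' @return Tibble, one row per slice; see [slice_contributions()].
#' @export
cohort_contributions <- function(x) {
  map_slices(x, slice_contributions)
}

#' Condition-level features for every slice of a dataset
#'
#' @param x A `fepsp_manifest` or `fepsp_cohort`.
#' @return Tibble, one row per slice x condition, with the [feature_set()]
#'   columns.
#' @export
extract_features <- function(x) {
  map_slices(x, function(sweeps, protocol) {
    conds <- vapply(sweeps, function(tr) tr$meta$condition, character(1))
    meta <- sweeps[[1]]$meta
    purrr::map_dfr(intersect(fepsp_conditions, unique(conds)), function(cc) {
      sel <- select_analysis_response(sweeps[conds == cc], protocol)
      dplyr::bind_cols(
        tibble(slice_id = meta$slice_id, group = meta$group,
               timepoint_weeks = meta$timepoint_weeks,
               hemisphere = meta$hemisphere, eye_input = meta$eye_input,
               condition = cc),
        sel$features
      )
    })
  })
}
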