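#' Configure a full experiment run
#'
#' @param cohorts List of [cohort_spec()] objects, or preset names (see
#'   [fepsp_presets()]) which are expanded via [preset_cohort_spec()].
#' @param protocol A [protocol_spec()].
#' @param seed Top-level seed; each cohort's master seed is derived from it
#'   deterministically (cohort `i` gets `derive(seed, i)`), so a run is
#'   fully reproducible from this one integer.
#' @param output_dir Directory for the report bundle, or `NULL` to skip
#'   writing files.
#' @return A `fepsp_run_config`.
#' @export
run_config <- function(cohorts, protocol = protocol_spec(), seed = 1,
                       output_dir = NULL) {
  if (!length(cohorts)) {
    stop_fepsp("config needs at least one cohort", "fepsp_config_error")
  }
  cohorts <- purrr::map(cohorts, function(x) {
    if (is.character(x)) x <- preset_cohort_spec(x)
    if (!inherits(x, "fepsp_cohort_spec")) {
      stop_fepsp("cohorts must be cohort_spec objects or preset names",
                 "fepsp_config_error")
    }
    x
  })
  structure(list(cohorts = cohorts, protocol = protocol,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "fepsp_run_config")
}

#' Run the full simulate -> features -> contributions -> stats pipeline
#'
#' Simulates every cohort of the configuration, extracts condition-level
#' features and per-slice receptor contributions, and produces the
#' group-level report tables: group summaries (mean ± SEM, n) of both
#' contribution percentages, paired drug-effect tests per cohort
#' (amplitude, latency, and duration: baseline vs GABA blockade, GABA
#' blockade vs +D-AP5), and — when more than one cohort is present —
#' omnibus ANOVA plus Tukey HSD comparisons of the contributions across
#' cohorts. Slices whose analysis fails are QC-flagged rows, never
#' silently dropped. With an `output_dir`, tables are written as CSV files
#' plus a YAML run log capturing the seed, protocol, and generator
#' parameters.
#'
#' @param config A [run_config()].
#' @return A `fepsp_report`: list of tibbles `features`, `contributions`,
#'   `group_summary`, `paired_effects`, `contribution_stats`, plus `log`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "fepsp_run_config")) {
    stop_fepsp("run_experiment() needs a run_config()", "fepsp_config_error")
  }
  cohorts <- purrr::imap(config$cohorts, function(spec, i) {
    spec$seed <- derive_seed(config$seed, i)
    simulate_cohort(spec, protocol = config$protocol)
  })
  labels <- vapply(cohorts, function(co) co$label, character(1))

  features <- purrr::map2_dfr(cohorts, labels, function(co, lab) {
    dplyr::mutate(extract_features(co), label = lab, .before = 1)
  })
  contributions <- purrr::map2_dfr(cohorts, labels, function(co, lab) {
    rows <- purrr::map_dfr(co$slices, function(sl) {
      tryCatch(slice_contributions(sl$sweeps, config$protocol),
               error = function(e) tibble(
                 slice_id = sl$info$slice_id,
                 qc = paste0("failed: ", conditionMessage(e))))
    })
    dplyr::mutate(rows, label = lab, .before = 1)
  })

  group_summary <- purrr::map_dfr(
    c("gaba_pct", "nmda_pct"), function(v) {
      dplyr::mutate(
        group_summaries(contributions, !!rlang::sym(v), label),
        measurement = v, .before = 1)
    })

  paired_effects <- paired_effect_tables(features)

  contribution_stats <- NULL
  if (length(unique(labels)) >= 2) {
    contribution_stats <- purrr::map_dfr(
      c("gaba_pct", "nmda_pct"), function(v) {
        cg <- compare_groups(contributions, !!rlang::sym(v), label)
        omni <- dplyr::mutate(cg$omnibus, estimate = NA_real_,
                              stars = p_stars(.data$p_value))
        pw <- dplyr::mutate(cg$pairwise, df1 = NA_real_, df2 = NA_real_)
        dplyr::mutate(
          dplyr::bind_rows(
            omni[, c("method", "comparison", "estimate", "statistic",
                     "df1", "df2", "p_value", "stars")],
            pw[, c("method", "comparison", "estimate", "statistic",
                   "df1", "df2", "p_value", "stars")]),
          measurement = v, .before = 1)
      })
  }

  log <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fepsp")),
    protocol = unclass(config$protocol),
    cohorts = purrr::map(config$cohorts, function(sp)
      list(label = sp$label, n_slices = sp$n_slices,
           params = unclass(sp$params)))
  )

  report <- structure(
    list(features = features, contributions = contributions,
         group_summary = group_summary, paired_effects = paired_effects,
         contribution_stats = contribution_stats, log = log),
    class = "fepsp_report"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) {
      if (!is.null(df)) readr::write_csv(df, file.path(config$output_dir, nm))
    }
    wr(features, "features.csv")
    wr(contributions, "contributions.csv")
    wr(group_summary, "group_summary.csv")
    wr(paired_effects, "paired_effects.csv")
    wr(contribution_stats, "contribution_stats.csv")
    yaml::write_yaml(log, file.path(config$output_dir, "run_log.yaml"))
  }
  report
}

# Per-cohort paired drug-effect tables: baseline vs GABA blockade and GABA
# blockade vs +D-AP5, for peak amplitude, latency, and duration.
paired_effect_tables <- function(features) {
  measures <- c(amplitude = "peak_amplitude_mV",
                latency = "latency_to_peak_ms",
                duration = "duration_ms")
  contrasts <- list(
    c("baseline", "gaba_block"),
    c("gaba_block", "gaba_nmda_block")
  )
  purrr::map_dfr(unique(features$label), function(lab) {
    sub <- features[features$label == lab, ]
    wide <- tidyr::pivot_wider(
      sub[, c("slice_id", "condition", unname(measures))],
      names_from = "condition", values_from = unname(measures))
    purrr::map_dfr(names(measures), function(mn) {
      col <- measures[[mn]]
      purrr::map_dfr(contrasts, function(ct) {
        x <- wide[[paste0(col, "_", ct[1])]]
        y <- wide[[paste0(col, "_", ct[2])]]
        res <- paired_t_test(x, y, comparison = paste(ct[2], "vs", ct[1]))
        dplyr::mutate(res, label = lab, measurement = mn,
                      mean_x = mean(x), mean_y = mean(y), .before = 1)
      })
    })
  })
}

#' @export
print.fepsp_report <- function(x, ...) {
  cat("<fepsp_report>\n")
  cat(sprintf("  %d slices in %d cohort(s)\n",
              nrow(x$contributions),
              dplyr::n_distinct(x$contributions$label)))
  print(x$group_summary)
  invisible(x)
}

#' Overlay the three drug-condition responses of a slice
#'
#' Reproduces the standard presentation of the pharmacological dissection:
#' the baseline, GABA-blocked, and GABA+NMDA-blocked averaged responses of
#' one slice overlaid on a common time axis.
#'
#' @param traces Named list of [trace()] objects (names or metadata supply
#'   the condition).
#' @return A ggplot.
#' @export
plot_condition_overlay <- function(traces) {
  df <- purrr::imap_dfr(traces, function(tr, nm) {
    cond <- tr$meta$condition
    if (is.na(cond)) cond <- nm
    dplyr::mutate(as_tibble(tr), condition = cond)
  })
  df$condition <- factor(df$condition, levels = fepsp_conditions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$voltage_mV,
                                   colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(baseline = "black",
                                            gaba_block = "#D55E00",
                                            gaba_nmda_block = "#0072B2")) +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (mV)", colour = NULL) +
    ggplot2::theme_minimal()
}
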