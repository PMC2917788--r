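#' Group summary (mean ± SEM, n)
#'
#' @param values Numeric vector.
#' @param label Group label.
#' @return One-row tibble: `label`, `n`, `mean`, `sem` (sample SD with
#'   `n - 1` denominator over `sqrt(n)`), and `qc`
#'   (`"inference_unavailable"` when `n < 2`).
#' @examples
#' summarize_group(c(1, 2, 3), "demo") # mean 2, sem 0.577
#' @export
summarize_group <- function(values, label = "group") {
  if (!length(values)) {
    stop_fepsp("cannot summarize an empty group", "fepsp_stats_error")
  }
  n <- length(values)
  tibble(label = as.character(label), n = n, mean = mean(values),
         sem = if (n > 1) sd(values) / sqrt(n) else 0,
         qc = if (n >= 2) "ok" else "inference_unavailable")
}

#' Group summaries from a data frame
#'
#' @param data A data frame.
#' @param value Column to summarize (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return Tibble, one [summarize_group()] row per group.
#' @export
group_summaries <- function(data, value, group) {
  data |>
    dplyr::group_by({{ group }}) |>
    dplyr::group_map(function(df, key) {
      summarize_group(dplyr::pull(df, {{ value }}),
                      label = as.character(key[[1]]))
    }) |>
    dplyr::bind_rows()
}

#' Paired t-test on drug-effect measurements
#'
#' Two-sided paired t-test of `y` against `x` on the differences
#' `d = y - x` (t = mean(d) / (sd(d)/sqrt(n)), df = n - 1). Degenerate
#' inputs are handled explicitly: all-zero differences give t = 0, p = 1;
#' nonzero constant differences are flagged.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2); `x` is the
#'   baseline condition.
#' @param comparison Label for the comparison.
#' @return One-row tibble: `method`, `comparison`, `n`, `estimate`
#'   (mean difference), `statistic`, `df`, `p_value`, `qc`.
#' @export
paired_t_test <- function(x, y, comparison = "y vs x") {
  if (length(x) != length(y)) {
    stop_fepsp("paired samples must have equal length", "fepsp_stats_error")
  }
  if (length(x) < 2) {
    stop_fepsp("paired t-test needs n >= 2", "fepsp_stats_error")
  }
  d <- y - x
  n <- length(d)
  if (sd(d) == 0) {
    all_zero <- all(d == 0)
    return(tibble(method = "paired_t", comparison = comparison, n = n,
                  estimate = mean(d),
                  statistic = if (all_zero) 0 else sign(mean(d)) * Inf,
                  df = n - 1,
                  p_value = if (all_zero) 1 else 0,
                  qc = if (all_zero) "ok" else "degenerate_zero_variance"))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  tibble(method = "paired_t", comparison = comparison, n = n,
         estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, qc = "ok")
}

# Accept a data frame + columns or a (possibly named) list of numeric
# vectors; return list(values, labels factor).
as_group_data <- function(data, value, group) {
  if (is.data.frame(data)) {
    vals <- dplyr::pull(data, {{ value }})
    labs <- as.character(dplyr::pull(data, {{ group }}))
  } else if (is.list(data)) {
    labs <- names(data) %||% paste0("g", seq_along(data))
    if (is.null(names(data))) names(data) <- labs
    vals <- unlist(data, use.names = FALSE)
    labs <- rep(names(data), lengths(data))
  } else {
    stop_fepsp("groups must be a data frame or a list of numeric vectors",
               "fepsp_stats_error")
  }
  if (dplyr::n_distinct(labs) < 2) {
    stop_fepsp("need at least 2 groups", "fepsp_stats_error")
  }
  if (any(table(labs) < 2)) {
    stop_fepsp("every group needs n >= 2", "fepsp_stats_error")
  }
  list(values = vals, labels = factor(labs, levels = unique(labs)))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within`,
#' df `(k - 1, N - k)`.
#'
#' @param data A data frame (with `value` and `group` columns, tidy-eval)
#'   or a list of numeric vectors.
#' @param value,group Columns when `data` is a data frame.
#' @return One-row tibble: `method`, `comparison = "omnibus"`, `statistic`
#'   (F), `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(data, value = NULL, group = NULL) {
  g <- as_group_data(data, {{ value }}, {{ group }})
  ow <- stats::oneway.test(values ~ labels,
                           data = data.frame(values = g$values,
                                             labels = g$labels),
                           var.equal = TRUE)
  tibble(method = "anova", comparison = "omnibus",
         statistic = unname(ow$statistic),
         df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
         p_value = ow$p.value)
}

# Pairwise Tukey-Kramer rows from per-group n / mean / within-group MS.
tukey_pairs <- function(ns, means, ms_within, df_within, labels) {
  ns <- unname(ns)
  means <- unname(means)
  k <- length(ns)
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(ms_within / 2 * (1 / ns[i1] + 1 / ns[i2]))
    q <- abs(means[i1] - means[i2]) / se
    tibble(method = "tukey",
           comparison = paste(labels[i2], "vs", labels[i1]),
           estimate = means[i2] - means[i1], statistic = q,
           df = df_within,
           p_value = ptukey(q, nmeans = k, df = df_within,
                            lower.tail = FALSE))
  })
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, with the Tukey-Kramer
#' correction for unequal group sizes:
#' `q = |m_i - m_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`, p from the
#' studentized-range distribution with `k` groups and `N - k` df.
#'
#' @inheritParams one_way_anova
#' @return Tibble, one row per pair: `method`, `comparison`, `estimate`
#'   (mean difference), `statistic` (q), `df`, `p_value`, `stars`
#'   (`*` p < 0.05, `**` p < 0.01).
#' @export
tukey_hsd <- function(data, value = NULL, group = NULL) {
  g <- as_group_data(data, {{ value }}, {{ group }})
  sp <- split(g$values, g$labels)
  ns <- lengths(sp)
  means <- vapply(sp, mean, numeric(1))
  ss_within <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1)))
  df_within <- sum(ns) - length(ns)
  out <- tukey_pairs(ns, means, ss_within / df_within, df_within, names(sp))
  out$stars <- p_stars(out$p_value)
  out
}

#' ANOVA and Tukey HSD from printed summary statistics
#'
#' Reconstructs the one-way ANOVA (and Tukey-Kramer pairwise comparisons)
#' from per-group `n`, `mean`, and `sem` alone — the form in which
#' published tables report group data. Within-group variance is recovered
#' as `s_i^2 = sem_i^2 * n_i`; results are identical to running
#' [one_way_anova()] / [tukey_hsd()] on any raw data with those summaries.
#'
#' @param summaries Tibble with columns `label`, `n`, `mean`, `sem` (as
#'   produced by [summarize_group()]), one row per group; all `n >= 2`.
#' @return A `fepsp_anova` object: list with `summaries`, `omnibus`
#'   (one-row tibble), and `pairwise` (Tukey rows). Supports [tidy()],
#'   [glance()], and [autoplot()].
#' @examples
#' tbl <- tibble::tibble(
#'   label = c("a", "b"), n = c(5, 6), mean = c(1, 2), sem = c(0.2, 0.3))
#' glance(anova_from_summary(tbl))
#' @export
anova_from_summary <- function(summaries) {
  need <- c("label", "n", "mean", "sem")
  if (!all(need %in% names(summaries))) {
    stop_fepsp("summaries needs columns label, n, mean, sem",
               "fepsp_stats_error")
  }
  if (nrow(summaries) < 2) {
    stop_fepsp("need at least 2 groups", "fepsp_stats_error")
  }
  if (any(summaries$n < 2)) {
    stop_fepsp("every group needs n >= 2", "fepsp_stats_error")
  }
  ns <- summaries$n
  means <- summaries$mean
  s2 <- summaries$sem^2 * ns
  N <- sum(ns)
  k <- length(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * s2)
  df1 <- k - 1
  df2 <- N - k
  f <- (ss_between / df1) / (ss_within / df2)
  omnibus <- tibble(method = "anova", comparison = "omnibus",
                    statistic = f, df1 = df1, df2 = df2,
                    p_value = pf(f, df1, df2, lower.tail = FALSE))
  pairwise <- tukey_pairs(ns, means, ss_within / df2, df2, summaries$label)
  pairwise$stars <- p_stars(pairwise$p_value)
  new_fepsp_anova(summaries, omnibus, pairwise)
}

new_fepsp_anova <- function(summaries, omnibus, pairwise) {
  structure(list(summaries = summaries, omnibus = omnibus,
                 pairwise = pairwise),
            class = "fepsp_anova")
}

#' Compare groups of per-slice measurements
#'
#' Group summaries, omnibus one-way ANOVA, and Tukey HSD pairwise
#' comparisons for one measurement across cohorts — the group-level
#' analysis applied to receptor-contribution and amplitude measurements.
#'
#' @param data Data frame, one row per slice.
#' @param value Measurement column (tidy-eval), e.g. `nmda_pct`.
#' @param group Cohort label column (tidy-eval).
#' @return A `fepsp_anova` object (see [anova_from_summary()]).
#' @export
compare_groups <- function(data, value, group) {
  g <- as_group_data(data, {{ value }}, {{ group }})
  summaries <- group_summaries(
    data.frame(values = g$values, labels = g$labels), values, labels)
  omnibus <- one_way_anova(data.frame(values = g$values, labels = g$labels),
                           values, labels)
  pairwise <- tukey_hsd(data.frame(values = g$values, labels = g$labels),
                        values, labels)
  new_fepsp_anova(summaries, omnibus, pairwise)
}

#' @export
print.fepsp_anova <- function(x, ...) {
  cat("<fepsp_anova>\n")
  cat(sprintf("  omnibus: F(%g, %g) = %.3f, p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$statistic,
              x$omnibus$p_value))
  print(x$pairwise[, c("comparison", "estimate", "statistic", "p_value",
                       "stars")])
  invisible(x)
}

#' @describeIn compare_groups Pairwise Tukey rows of a `fepsp_anova`.
#' @param x A `fepsp_anova`.
#' @param ... Unused.
#' @export
tidy.fepsp_anova <- function(x, ...) x$pairwise

#' @describeIn compare_groups One-row omnibus summary of a `fepsp_anova`.
#' @export
glance.fepsp_anova <- function(x, ...) x$omnibus

#' @describeIn compare_groups Mean ± SEM plot of the group summaries.
#' @param object A `fepsp_anova`.
#' @export
autoplot.fepsp_anova <- function(object, ...) {
  s <- object$summaries
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.15) +
    ggplot2::labs(x = NULL, y = "Mean ± SEM") +
    ggplot2::theme_minimal()
}
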