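test_that("group summaries report mean and SEM with the n-1 convention", {
  s <- summarize_group(c(1, 2, 3), "demo")
  expect_equal(s$mean, 2)
  expect_equal(round(s$sem, 3), 0.577)
  expect_equal(s$n, 3)

  s1 <- summarize_group(5, "singleton")
  expect_equal(s1$sem, 0)
  expect_equal(s1$qc, "inference_unavailable")

  expect_error(summarize_group(numeric(0)), class = "fepsp_stats_error")
})

test_that("paired t-test matches hand computation and is symmetric", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # d = (1, 1, 2): mean 4/3, sd 1/sqrt(3) -> t = 4, df = 2
  r <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$statistic, 4)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-4, df = 2))

  flip <- paired_t_test(c(2, 3, 5), c(1, 2, 3))
  expect_equal(flip$statistic, -4)
  expect_equal(flip$p_value, r$p_value)

  const <- paired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(const$qc, "degenerate_zero_variance")

  expect_error(paired_t_test(1:3, 1:4), class = "fepsp_stats_error")
  expect_error(paired_t_test(1, 2), class = "fepsp_stats_error")
})

test_that("one-way ANOVA reproduces the sums-of-squares decomposition", {
  null3 <- one_way_anova(list(c(1, 3), c(2, 2), c(3, 1)))
  expect_equal(null3$statistic, 0)
  expect_equal(null3$p_value, 1)

  # two groups: F equals the square of the pooled two-sample t
  set.seed(21)
  a <- rnorm(8); b <- rnorm(10, mean = 0.5)
  f2 <- one_way_anova(list(a = a, b = b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-12)

  # brute-force SS decomposition oracle on a 3-group dataset
  g <- list(x = rnorm(6), y = rnorm(9, 1), z = rnorm(7, -0.4))
  res <- one_way_anova(g)
  all_v <- unlist(g)
  ssb <- sum(lengths(g) * (vapply(g, mean, 1) - mean(all_v))^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / (length(all_v) - 3))
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)

  expect_error(one_way_anova(list(1:3)), class = "fepsp_stats_error")
  expect_error(one_way_anova(list(1:3, 5)), class = "fepsp_stats_error")
})

test_that("Tukey HSD agrees with the pooled t in the two-group case", {
  set.seed(33)
  a <- rnorm(7); b <- rnorm(12, 0.8)
  tk <- tukey_hsd(list(a = a, b = b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk$statistic, abs(unname(tt$statistic)) * sqrt(2),
               tolerance = 1e-12)
  expect_equal(tk$p_value, tt$p.value, tolerance = 1e-9)

  ident <- tukey_hsd(list(u = c(1, 2, 3), v = c(1, 2, 3), w = c(1, 2, 3)))
  expect_true(all(ident$p_value == 1))
})

test_that("Tukey HSD matches stats::TukeyHSD and is label-permutation safe", {
  set.seed(8)
  df <- data.frame(
    value = c(rnorm(9), rnorm(11, 0.6), rnorm(8, 1.1)),
    grp = rep(c("a", "b", "c"), c(9, 11, 8))
  )
  ours <- tukey_hsd(df, value, grp)
  ref <- stats::TukeyHSD(stats::aov(value ~ grp, df))$grp
  expect_equal(sort(ours$p_value), sort(unname(ref[, "p adj"])),
               tolerance = 1e-8)
  expect_equal(sort(abs(ours$estimate)), sort(abs(unname(ref[, "diff"]))),
               tolerance = 1e-12)

  perm <- df[order(df$value), ]
  ours2 <- tukey_hsd(perm, value, grp)
  expect_equal(
    ours$p_value[order(ours$comparison)],
    ours2$p_value[order(ours2$comparison)], tolerance = 1e-12)
})

test_that("summary-statistics ANOVA is exactly equivalent to the raw-data one", {
  base <- anova_from_summary(tibble::tibble(
    label = c("a", "b", "c"), n = c(2, 2, 2),
    mean = c(2, 2, 2), sem = c(1, 0, 1)))
  expect_equal(glance(base)$statistic, 0)
  expect_equal(glance(base)$p_value, 1)

  set.seed(55)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    g <- purrr::map(seq_len(k), function(i)
      rnorm(sample(3:12, 1), mean = runif(1, -1, 1),
            sd = runif(1, 0.3, 2)))
    names(g) <- paste0("g", seq_len(k))
    df <- data.frame(value = unlist(g), grp = rep(names(g), lengths(g)))
    summ <- group_summaries(df, value, grp)
    from_summary <- anova_from_summary(summ)
    raw_omni <- one_way_anova(df, value, grp)
    raw_tukey <- tukey_hsd(df, value, grp)
    expect_equal(glance(from_summary)$statistic, raw_omni$statistic,
                 tolerance = 1e-10)
    expect_equal(glance(from_summary)$p_value, raw_omni$p_value,
                 tolerance = 1e-10)
    expect_equal(tidy(from_summary)$p_value[order(tidy(from_summary)$comparison)],
                 raw_tukey$p_value[order(raw_tukey$comparison)],
                 tolerance = 1e-10)
  }

  expect_error(anova_from_summary(tibble::tibble(
    label = "a", n = 5, mean = 1, sem = 0.1)), class = "fepsp_stats_error")
  expect_error(anova_from_summary(tibble::tibble(
    label = c("a", "b"), n = c(1, 5), mean = c(1, 2), sem = c(0, 0.1))),
    class = "fepsp_stats_error")
})

test_that("the published 32-week contribution table yields the reported contrast", {
  # group means/SEMs as printed: controls left/right, OHT unoperated-eye
  # and operated-eye input; the operated-vs-unoperated comparison is the
  # one reported as significant
  tab <- tibble::tibble(
    label = c("AMC-left", "AMC-right", "OHT-unoperated", "OHT-operated"),
    n = c(15, 13, 12, 14),
    mean = c(57, 62.9, 53, 67),
    sem = c(1.7, 2.6, 2.9, 3))
  res <- anova_from_summary(tab)
  expect_lt(glance(res)$p_value, 0.05)
  pair <- tidy(res)
  oht <- pair[grepl("OHT-operated", pair$comparison) &
                grepl("OHT-unoperated", pair$comparison), ]
  expect_lt(oht$p_value, 0.05)
  expect_equal(oht$stars, "**")
})
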