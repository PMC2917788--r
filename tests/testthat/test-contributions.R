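test_that("contribution formulas reproduce the worked-example ratios", {
  # the published single-slice examples: baseline AUC 15% of the
  # disinhibited AUC gives an 85% GABA contribution; D-AP5 residuals of
  # 46% and 32% give 54% and 68% NMDA contributions
  expect_equal(gaba_contribution(0.15, 1), 85)
  expect_equal(nmda_contribution(1, 0.46), 54)
  expect_equal(nmda_contribution(1, 0.32), 68)

  expect_equal(gaba_contribution(1, 1), 0)
  expect_equal(gaba_contribution(0, 1), 100)
  expect_equal(nmda_contribution(1, 1), 0)
  # reductions below baseline are reported, not clamped
  expect_equal(gaba_contribution(1.2, 1), -20)

  expect_error(gaba_contribution(0.5, 0),
               class = "fepsp_contribution_error")
  expect_error(nmda_contribution(0, 0.5),
               class = "fepsp_contribution_error")
})

test_that("baseline normalization is a plain ratio", {
  expect_equal(round(normalize_to_baseline(-0.8, -0.71), 3), 1.127)
  expect_equal(normalize_to_baseline(2, 2), 1)
  expect_equal(normalize_to_baseline(-0.5, -1), 0.5)
  expect_error(normalize_to_baseline(1, 0),
               class = "fepsp_contribution_error")
})

test_that("the analysis window takes the last nine sweeps as 3x3 averages", {
  proto <- protocol_spec()
  flat <- function(level) {
    trace(rep(level, 1301), 0.1, 10,
          meta = list(condition = "baseline", slice_id = "S"))
  }
  # 60-sweep epoch whose first 51 sweeps are wildly different: they must
  # not influence the analysis window
  sweeps <- c(purrr::map(rep(5, 51), flat), purrr::map(rep(0, 9), flat))
  sel <- select_analysis_response(sweeps, proto)
  expect_equal(sel$trace$voltage_mV, rep(0, 1301))
  expect_equal(nrow(sel$block_features), 3)
  expect_equal(sel$features$n_sweeps_averaged, 9L)

  sel9 <- select_analysis_response(purrr::map(rep(0, 9), flat), proto)
  expect_equal(sel9$trace$voltage_mV, rep(0, 1301))

  expect_error(select_analysis_response(purrr::map(rep(0, 8), flat), proto),
               "analysis window", class = "fepsp_contribution_error")
})

test_that("slice contributions are scale-invariant and well-ordered", {
  p <- noiseless_params(a_nmda_mV = 0.35, gate_floor = 0.04)
  sweeps <- noiseless_slice_sweeps(p)
  res <- slice_contributions(sweeps, short_protocol())

  expect_true(res$auc_baseline <= res$auc_gaba_block)
  expect_true(res$auc_full_block <= res$auc_gaba_block)
  expect_true(res$gaba_pct >= 0 && res$gaba_pct <= 100)
  expect_true(res$nmda_pct >= 0 && res$nmda_pct <= 100)
  expect_equal(res$qc, "ok")

  scaled <- purrr::map(sweeps, function(tr) {
    trace(tr$voltage_mV * 3.7, tr$sampling_interval_ms,
          tr$stimulus_time_ms, tr$meta)
  })
  res2 <- slice_contributions(scaled, short_protocol())
  expect_equal(res2$gaba_pct, res$gaba_pct, tolerance = 1e-9)
  expect_equal(res2$nmda_pct, res$nmda_pct, tolerance = 1e-9)
  expect_equal(res2$auc_gaba_block, 3.7 * res$auc_gaba_block,
               tolerance = 1e-9)
})

test_that("NMDA contribution tracks the generating NMDA amplitude", {
  pcts <- vapply(c(0, 0.15, 0.35, 0.7), function(a_n) {
    sweeps <- noiseless_slice_sweeps(noiseless_params(a_nmda_mV = a_n))
    slice_contributions(sweeps, short_protocol())$nmda_pct
  }, numeric(1))
  expect_equal(pcts[1], 0, tolerance = 1e-6)
  expect_true(all(diff(pcts) > 0))
})

test_that("without gating at baseline the GABA contribution vanishes", {
  p <- noiseless_params(a_nmda_mV = 0.35)
  sweeps <- noiseless_slice_sweeps(p)
  # replace the baseline epoch by disinhibited sweeps relabelled baseline
  disinhibited <- purrr::map(sweeps, function(tr) {
    if (tr$meta$condition == "baseline") {
      gb <- simulate_sweep(p, "gaba_block")
      gb$meta <- tr$meta
      gb
    } else tr
  })
  res <- slice_contributions(disinhibited, short_protocol())
  expect_equal(res$gaba_pct, 0, tolerance = 1e-6)

  # a missing epoch is an error
  no_base <- purrr::keep(sweeps, function(tr)
    tr$meta$condition != "baseline")
  expect_error(slice_contributions(no_base, short_protocol()),
               "baseline", class = "fepsp_contribution_error")
})

test_that("cohort tables carry one row per slice and per condition", {
  spec <- cohort_spec("AMC", 16, "control", n_slices = 3,
                      params = noiseless_params(a_nmda_mV = 0.3,
                                                slice_cv_fast = 0.1,
                                                slice_cv_nmda = 0.1),
                      seed = 2)
  co <- simulate_cohort(spec, short_protocol())
  contrib <- cohort_contributions(co)
  expect_equal(nrow(contrib), 3)
  expect_true(all(contrib$qc == "ok"))

  feats <- extract_features(co)
  expect_equal(nrow(feats), 9)
  expect_setequal(unique(feats$condition), conditions())
  # disinhibition enhances the late phase: every slice's disinhibited AUC
  # exceeds its baseline AUC
  wide <- tidyr::pivot_wider(feats[, c("slice_id", "condition", "auc_mV_ms")],
                             names_from = "condition",
                             values_from = "auc_mV_ms")
  expect_true(all(wide$gaba_block > wide$baseline))
  expect_true(all(wide$gaba_nmda_block < wide$gaba_block))
})
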