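test_that("a perfectly reproducible exposure gives an identity transition matrix", {
  co <- simulate_cohort(sim_scenario("null", 600, seed = 3))
  co <- simulate_repeat_exposure(co, 1, seed = 4)
  tm <- stability_analysis(co, J = 5)
  expect_equal(tm$counts, diag(120, 5), ignore_attr = TRUE)
  expect_equal(tm$retention, rep(1, 5), ignore_attr = TRUE)
})

test_that("an uncorrelated repeat scatters strata uniformly", {
  co <- simulate_cohort(sim_scenario("null", 20000, seed = 5))
  co <- simulate_repeat_exposure(co, 0, seed = 6)
  tm <- stability_analysis(co, J = 5)
  expect_lt(max(abs(tm$proportions - 0.2)), 0.05)
  expect_equal(rowSums(tm$proportions), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(tm$counts), nrow(co))
})

test_that("swapping measurement occasions transposes the transition counts", {
  co <- simulate_cohort(sim_scenario("null", 2000, seed = 7))
  co <- simulate_repeat_exposure(co, 0.5, seed = 8)
  tm <- stability_analysis(co, J = 4)
  sw <- co
  sw$exposure <- co$exposure_repeat
  sw$exposure_repeat <- co$exposure
  tm_sw <- stability_analysis(sw, J = 4)
  expect_identical(tm_sw$counts, t(tm$counts), ignore_attr = TRUE)
})

test_that("stratum retention increases with the test-retest correlation", {
  base <- simulate_cohort(sim_scenario("null", 6000, seed = 9))
  mean_ret <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(r) {
    mean(vapply(1:3, function(s) {
      co <- simulate_repeat_exposure(base, r, seed = 100 * s)
      mean(stability_analysis(co, J = 5)$retention)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ret) > 0))
  expect_equal(mean_ret[5], 1)
})

test_that("a moderately correlated skewed exposure loses most of its bottom stratum", {
  # triglyceride-like setting: right-skewed exposure, r = 0.60, 10 strata
  co <- simulate_cohort(sim_scenario("null", 13500, seed = 11))
  co$exposure <- exp(co$exposure / 2)            # log-normal-like marginal
  co <- simulate_repeat_exposure(co, 0.60, seed = 12)
  tm <- stability_analysis(co, J = 10)
  # far from stable, far from uniform: the qualitative regime in which
  # stratum-1 membership is not reproducible between occasions
  expect_lt(tm$retention[1], 0.6)
  expect_gt(tm$retention[1], 1 / 10)
  expect_equal(rowSums(tm$proportions), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("stability analysis requires a complete repeat measurement", {
  co <- simulate_cohort(sim_scenario("null", 300, seed = 13))
  expect_error(stability_analysis(co, 5), "exposure_repeat")
})

test_that("the NCO report flags selection-induced stratum bias but not a clean cohort", {
  # biased setting: one seed, strong heterogeneity expected on sex
  full <- simulate_cohort(sim_scenario("selection_nco", 25000, seed = 905))
  co <- apply_selection(full)
  rep_bias <- nco_analysis(co, nco_outcomes = "sex", J = 10,
                           m_replicates = 3, seed = 905)
  pm <- rep_bias$outcomes$sex$per_method
  expect_true(pm$residual$flags$heterogeneity_flag ||
                pm$doubly_ranked$flags$heterogeneity_flag)

  # flags are recomputable from the contained estimates
  expect_identical(pm$residual$flags$heterogeneity_flag,
                   cochran_q(pm$residual$set)$p_Q < rep_bias$alpha)
  expect_identical(pm$residual$flags$nonnull_strata_count,
                   sum(pm$residual$set$table$p_value < rep_bias$alpha,
                       na.rm = TRUE))

  # degenerate threshold: every stratum flagged
  rep_all <- nco_analysis(co, nco_outcomes = "sex", J = 4, m_replicates = 1,
                          alpha = 1, seed = 905)
  expect_equal(rep_all$outcomes$sex$per_method$residual$flags$nonnull_strata_count,
               4L)
})

test_that("NCO heterogeneity flags fire at about the nominal rate without selection", {
  flags <- vapply(1:120, function(s) {
    co <- simulate_cohort(sim_scenario("null", 3000, seed = 10000 + s))
    rep0 <- nco_analysis(co, nco_outcomes = "age", J = 5, m_replicates = 2,
                         seed = s)
    c(rep0$outcomes$age$per_method$residual$flags$heterogeneity_flag,
      rep0$outcomes$age$per_method$doubly_ranked$flags$heterogeneity_flag)
  }, logical(2))
  expect_lt(mean(flags[1, ]), 0.15)
  expect_lt(mean(flags[2, ]), 0.15)
  expect_gt(mean(flags), 0.0005)  # not degenerate either
})

test_that("NCO flags are invariant to affine rescaling of the exposure", {
  full <- simulate_cohort(sim_scenario("selection_nco", 8000, seed = 21))
  co <- apply_selection(full)
  r1 <- nco_analysis(co, nco_outcomes = c("age", "sex"), J = 5,
                     m_replicates = 2, seed = 3)
  co2 <- co
  co2$exposure <- 3.2 * co$exposure - 7
  r2 <- nco_analysis(co2, nco_outcomes = c("age", "sex"), J = 5,
                     m_replicates = 2, seed = 3)
  for (outc in c("age", "sex")) {
    for (meth in c("residual", "doubly_ranked")) {
      f1 <- r1$outcomes[[outc]]$per_method[[meth]]
      f2 <- r2$outcomes[[outc]]$per_method[[meth]]
      expect_identical(f1$flags, f2$flags)
      expect_equal(f1$Q$Q, f2$Q$Q, tolerance = 1e-6)
      # stratum membership itself is unchanged
      expect_equal(f1$set$table$n, f2$set$table$n)
    }
  }
})

test_that("reports render deterministically and round-trip their numbers", {
  co <- simulate_cohort(sim_scenario("homogeneous", 600, seed = 31))
  set <- stratified_mr(co, doubly_ranked_strata(co, 3), "outcome_continuous")
  l1 <- render_report(set, "tsv")
  l2 <- render_report(set, "tsv")
  expect_identical(l1, l2)

  path <- withr::local_tempfile(fileext = ".tsv")
  render_report(set, "tsv", path = path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$beta, set$table$beta, tolerance = 1e-6)
  expect_equal(back$se, set$table$se, tolerance = 1e-6)
  expect_equal(back$fs_beta, set$table$fs_beta, tolerance = 1e-6)

  txt <- render_report(set, "text")
  expect_gt(length(txt), 1)
  expect_error(render_report(set, "pdf"), "format")

  # transition matrices render one row per cell, proportions summing to 1
  co <- simulate_repeat_exposure(co, 0.5, seed = 2)
  tm <- stability_analysis(co, J = 3)
  lines_tm <- render_report(tm, "tsv")
  expect_equal(length(lines_tm), 1 + 9)

  # an NCO report with no outcomes renders to a header-only table
  empty <- nco_analysis(co, nco_outcomes = character(0), J = 3,
                        m_replicates = 1)
  expect_equal(length(render_report(empty, "tsv")), 1)
})
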