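test_that("a single stratum reproduces the overall estimate exactly", {
  co <- simulate_cohort(sim_scenario("homogeneous", 1000, seed = 2))
  set <- stratified_mr(co, residual_strata(co, 1), "outcome_continuous")
  expect_equal(set$table$beta[1], set$overall$beta, tolerance = 1e-12)
  expect_equal(set$table$se[1], set$overall$se, tolerance = 1e-12)
})

test_that("stratum estimates recover a homogeneous effect in every stratum", {
  co <- simulate_cohort(sim_scenario("homogeneous", 20000, seed = 3))
  for (a in list(doubly_ranked_strata(co, 5, replicate_seed = 1),
                 residual_strata(co, 5))) {
    set <- stratified_mr(co, a, "outcome_continuous")
    expect_true(all(abs(set$table$beta - 0.5) < 3 * set$table$se))
    expect_lt(abs(set$overall$beta - 0.5), 3 * set$overall$se)
    # first-stage present in all strata
    expect_true(all(is.finite(set$table$fs_beta)))
  }
})

test_that("per-stratum estimation failures are annotated, not fatal", {
  co <- simulate_cohort(sim_scenario("null", 400, seed = 31))
  # an outcome that is one-class inside the bottom stratum only
  a <- residual_strata(co, 4)
  co$rare <- ifelse(a$stratum == 1, 0L, rbinom(400, 1, 0.5))
  set <- suppressWarnings(stratified_mr(co, a, "rare", family = "binary"))
  expect_true(is.na(set$table$beta[1]))
  expect_match(set$table$error[1], "single class")
  expect_true(all(is.finite(set$table$beta[-1])))
})

test_that("Rubin's rules reproduce hand-computed pooling", {
  sets <- lapply(c(1.0, 1.2, 1.4), function(b)
    fake_set(b, ses = 0.2, mean_exposure = 1))  # variance 0.04 each
  pooled <- pool_replicates(sets)
  expect_equal(pooled$table$beta[1], 1.2, tolerance = 1e-12)
  expect_equal(pooled$table$W[1], 0.04, tolerance = 1e-12)
  expect_equal(pooled$table$B[1], 0.04, tolerance = 1e-12)
  expect_equal(pooled$table$T_var[1], 0.04 + (4 / 3) * 0.04,
               tolerance = 1e-12)
  expect_equal(pooled$table$se[1], sqrt(0.09333333333333334),
               tolerance = 1e-8)
  expect_equal(pooled$m, 3L)
})

test_that("pooling identical replicates returns the replicate with B = 0", {
  s <- fake_set(c(0.4, 0.6), ses = c(0.1, 0.2))
  pooled <- pool_replicates(list(s, s, s))
  expect_equal(pooled$table$beta, s$table$beta)
  expect_equal(pooled$table$se, s$table$se, tolerance = 1e-12)
  expect_true(all(pooled$table$B == 0))

  # m = 1: between-replicate variance undefined, treated as 0
  p1 <- pool_replicates(list(s))
  expect_equal(p1$table$T_var, s$table$se^2, tolerance = 1e-12)

  expect_error(pool_replicates(list(s, fake_set(1, 0.1))), "strata")
})

test_that("pooled total variance never falls below the within-replicate variance", {
  set.seed(55)
  for (i in 1:25) {
    m <- sample(2:6, 1)
    J <- sample(2:5, 1)
    sets <- lapply(seq_len(m), function(r)
      fake_set(rnorm(J), ses = runif(J, 0.05, 0.5)))
    pooled <- pool_replicates(sets)
    expect_true(all(pooled$table$T_var >= pooled$table$W))
  }
})

test_that("Cochran's Q matches its closed form and an independent meta-analysis fit", {
  # identical estimates: no heterogeneity at all
  h0 <- cochran_q(fake_set(rep(0.7, 4), ses = rep(0.2, 4)))
  expect_equal(h0$Q, 0)
  expect_equal(h0$p_Q, 1)
  expect_equal(h0$df, 3L)

  # two strata, closed form Q = (1-2)^2 / (0.25 + 0.25) = 2
  h2 <- cochran_q(fake_set(c(1, 2), ses = c(0.5, 0.5)))
  expect_equal(h2$Q, 2, tolerance = 1e-12)

  # random sets against metafor's fixed-effect Q
  set.seed(91)
  for (i in 1:10) {
    J <- sample(3:8, 1)
    b <- rnorm(J)
    se <- runif(J, 0.1, 0.5)
    h <- cochran_q(fake_set(b, ses = se))
    ref <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(h$Q, ref$QE, tolerance = 1e-8)
    expect_equal(h$p_Q, ref$QEp, tolerance = 1e-8)
  }

  expect_error(cochran_q(fake_set(c(1, 2), ses = c(0, 0.5))), "> 0")
  expect_error(cochran_q(fake_set(1, ses = 0.1)), "at least 2")
})

test_that("the IVW trend matches hand-weighted least squares and metafor", {
  # exact linear relation with equal weights: slope recovered exactly
  ht <- trend_test(fake_set(c(1, 2, 3), ses = rep(0.3, 3),
                            mean_exposure = c(2, 4, 6)))
  expect_equal(ht$trend_slope, 0.5, tolerance = 1e-12)

  # hand-chosen triple with weights {4, 1, 4} (ses 0.5, 1, 0.5)
  b <- c(1, 2, 2); x <- c(1, 2, 3); w <- c(4, 1, 4)
  xbar <- sum(w * x) / sum(w); ybar <- sum(w * b) / sum(w)
  slope_hand <- sum(w * (x - xbar) * (b - ybar)) / sum(w * (x - xbar)^2)
  se_hand <- 1 / sqrt(sum(w * (x - xbar)^2))
  ht2 <- trend_test(fake_set(b, ses = c(0.5, 1, 0.5), mean_exposure = x))
  expect_equal(ht2$trend_slope, slope_hand, tolerance = 1e-12)
  expect_equal(ht2$trend_se, se_hand, tolerance = 1e-12)

  ref <- metafor::rma(yi = b, sei = c(0.5, 1, 0.5), mods = ~x, method = "FE")
  expect_equal(ht2$trend_slope, unname(ref$beta[2, 1]), tolerance = 1e-8)
  expect_equal(ht2$trend_se, unname(ref$se[2]), tolerance = 1e-8)

  expect_error(trend_test(fake_set(c(1, 2), ses = c(0.1, 0.1))), "at least 3")
  expect_error(trend_test(fake_set(c(1, 2, 3), ses = rep(0.1, 3),
                                   mean_exposure = rep(1, 3))),
               "constant")
})

test_that("trend p-values are uniform when stratum effects are homogeneous", {
  ps <- vapply(1:300, function(s) {
    co <- simulate_cohort(sim_scenario("homogeneous", 3000, seed = 8000 + s))
    set <- stratified_mr(co, doubly_ranked_strata(co, 4, replicate_seed = s),
                         "outcome_continuous")
    trend_test(set)$p_trend
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the constant genetic effect check flags an exposure-varying instrument effect", {
  # the genetic effect doubles from bottom to top of the distribution
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_scenario("varying_genetic_effect", 20000,
                                       seed = 8500 + s))
    set <- stratified_mr(co, doubly_ranked_strata(co, 10, replicate_seed = s),
                         "age")
    constant_genetic_effect_check(set)$p_Q < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.9)

  expect_error(constant_genetic_effect_check(fake_set(1, 0.1)), "at least 2")
})

test_that("the first-stage heterogeneity check is calibrated (residual) or conservative (doubly-ranked)", {
  ps <- vapply(1:100, function(s) {
    co <- simulate_cohort(sim_scenario("null", 5000, seed = 9000 + s))
    c(constant_genetic_effect_check(
        stratified_mr(co, residual_strata(co, 5), "age"))$p_Q,
      constant_genetic_effect_check(
        stratified_mr(co, doubly_ranked_strata(co, 5, replicate_seed = s),
                      "age"))$p_Q)
  }, numeric(2))
  expect_gt(mean(ps[1, ] < 0.05), 0.005)   # residual: near-nominal
  expect_lt(mean(ps[1, ] < 0.05), 0.12)
  expect_lte(mean(ps[2, ] < 0.05), 0.05)   # doubly-ranked: conservative
})

test_that("mutually impossible stratum/overall estimates are flagged", {
  # all strata protective, overall CI strictly harmful
  s_bad <- fake_set(c(-0.4, -0.5, -0.3), ses = rep(0.1, 3),
                    overall_beta = 0.5, overall_se = 0.05)
  expect_true(nlmrbias:::impossibility_flag(s_bad))
  s_ok <- fake_set(c(-0.4, 0.5, -0.3), ses = rep(0.1, 3),
                   overall_beta = 0.5, overall_se = 0.05)
  expect_false(nlmrbias:::impossibility_flag(s_ok))
  s_null <- fake_set(c(0.4, 0.5, 0.3), ses = rep(0.1, 3),
                     overall_beta = 0.45, overall_se = 0.05)
  expect_false(nlmrbias:::impossibility_flag(s_null))
})
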