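#' Stratified (non-linear) Mendelian randomization
#'
#' Runs the two-stage IV estimator and the first-stage instrument-exposure
#' association within each stratum of an assignment, plus the whole-cohort
#' ("conventional MR") estimate for reference. The per-stratum estimate is the
#' localized average causal effect (LACE) for that stratum. Estimation failure
#' inside a stratum (e.g. a one-class binary outcome) is recorded as an
#' annotation on that stratum, not a fatal error.
#'
#' A consistency check is run on the result: when every stratum point
#' estimate lies on one side of zero while the whole-cohort confidence
#' interval lies entirely on the other, the set is flagged (with a warning) as
#' logically impossible under a causal interpretation of all estimates.
#'
#' @param cohort a cohort data.frame.
#' @param assignment a `stratum_assignment` covering the cohort.
#' @param outcome name of the outcome column.
#' @param family `"auto"` (default: binary iff the column is 0/1),
#'   `"continuous"` or `"binary"`.
#' @param covariates optional character vector of covariate columns.
#' @return A `stratum_estimate_set`: fields `method`, `J`, `outcome`,
#'   `family`, `replicate_id`, `table` (one row per stratum: size, exposure
#'   summaries, LACE `beta`/`se`/CI/p, first-stage `fs_beta`/`fs_se`, `error`),
#'   `overall` ([mr_estimate]) and `impossible` (logical flag).
#' @export
stratified_mr <- function(cohort, assignment, outcome,
                          family = c("auto", "continuous", "binary"),
                          covariates = NULL) {
  family <- match.arg(family)
  check_cohort(cohort, c("id", "instrument_score", "exposure", outcome))
  if (family == "auto")
    family <- if (is_binary01(cohort[[outcome]])) "binary" else "continuous"
  s <- assignment_for(assignment, cohort)
  J <- assignment$n_strata
  summ <- summarize_strata(cohort, assignment)

  est_one <- function(co) {
    if (family == "binary") two_stage_binary(co, outcome, covariates)
    else two_stage_continuous(co, outcome, covariates)
  }
  rows <- lapply(seq_len(J), function(j) {
    co <- cohort[s == j, , drop = FALSE]
    est <- tryCatch(est_one(co), error = function(e) e)
    fs <- tryCatch(iv_exposure_assoc(co, covariates), error = function(e) e)
    err <- NA_character_
    if (inherits(est, "error")) { err <- conditionMessage(est); est <- NULL }
    if (inherits(fs, "error")) {
      err <- paste(stats::na.omit(c(err, conditionMessage(fs))), collapse = "; ")
      fs <- NULL
    }
    data.frame(
      beta = est$beta %||% NA_real_, se = est$se %||% NA_real_,
      ci_low = est$ci_low %||% NA_real_, ci_high = est$ci_high %||% NA_real_,
      p_value = est$p_value %||% NA_real_,
      fs_beta = fs$beta %||% NA_real_, fs_se = fs$se %||% NA_real_,
      fs_p_value = fs$p_value %||% NA_real_,
      error = err)
  })
  tab <- cbind(summ, do.call(rbind, rows))
  overall <- est_one(cohort)
  out <- structure(
    list(method = assignment$method, J = J, outcome = outcome,
         family = family, replicate_id = assignment$replicate_id,
         table = tab, overall = overall),
    class = "stratum_estimate_set")
  out$impossible <- impossibility_flag(out)
  if (out$impossible)
    warning("stratum estimates share a direction that the whole-cohort ",
            "confidence interval excludes: a logical impossibility if all ",
            "estimates have a causal interpretation", call. = FALSE)
  out
}

# TRUE when all stratum point estimates share a sign and the overall CI lies
# entirely on the opposite side of zero
impossibility_flag <- function(set) {
  b <- set$table$beta
  b <- b[!is.na(b)]
  if (length(b) < 2L) return(FALSE)
  ov <- set$overall
  (all(b > 0) && ov$ci_high < 0) || (all(b < 0) && ov$ci_low > 0)
}

#' @export
print.stratum_estimate_set <- function(x, digits = 3, ...) {
  cat(sprintf("Stratified MR: %s method, J = %d, outcome '%s' (%s)\n",
              x$method, x$J, x$outcome, x$family))
  cat("Overall: "); print(x$overall, digits = digits)
  df <- x$table[, c("stratum", "n", "mean_exposure", "beta", "se",
                    "p_value", "fs_beta")]
  print(format(df, digits = digits), row.names = FALSE)
  if (isTRUE(x$impossible))
    cat("NOTE: stratum estimates inconsistent with the overall CI\n")
  invisible(x)
}

#' Per-stratum estimates as a list of `mr_estimate` objects
#'
#' @param set a `stratum_estimate_set` or `pooled_estimate_set`.
#' @param component `"estimate"` (the LACE) or `"first_stage"`.
#' @return A list of [mr_estimate] (NULL for failed strata).
#' @export
stratum_estimates <- function(set, component = c("estimate", "first_stage")) {
  component <- match.arg(component)
  tab <- set$table
  lapply(seq_len(nrow(tab)), function(j) {
    b <- if (component == "estimate") tab$beta[j] else tab$fs_beta[j]
    s <- if (component == "estimate") tab$se[j] else tab$fs_se[j]
    if (is.na(b) || is.na(s)) return(NULL)
    mr_estimate(b, s, n = tab$n[j],
                family = if (component == "estimate") set$family
                         else "continuous",
                estimator = if (inherits(set, "pooled_estimate_set"))
                  "pooled" else "two_stage")
  })
}

#' Pool doubly-ranked replicates with Rubin's rules
#'
#' Combines `m` replicate stratified analyses (same method, strata count and
#' outcome, differing only in tie-breaking seed): per stratum, the pooled
#' estimate is the mean of replicate estimates, the within-replicate variance
#' `W` the mean of squared SEs, the between-replicate variance `B` the sample
#' variance of the estimates, and the total variance `T = W + (1 + 1/m) B`
#' (so pooling never reports less uncertainty than the average replicate).
#' With `m = 1`, `B` is undefined and treated as 0, so the pooled variance is
#' `W`. Confidence intervals and p-values use the normal approximation on
#' `sqrt(T)` (large-m/large-n degrees of freedom). First-stage associations
#' are pooled the same way.
#'
#' @param sets list of `stratum_estimate_set` replicates.
#' @return A `pooled_estimate_set` with the same `table` layout plus columns
#'   `W`, `B`, `T_var`, and fields `m` and `overall`.
#' @export
pool_replicates <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, TRUE, "stratum_estimate_set")))
  ref <- sets[[1]]
  same <- function(f) all(vapply(sets, function(s) identical(s[[f]], ref[[f]]),
                                 TRUE))
  if (!same("J")) stop_("replicates disagree on the number of strata")
  if (!same("method") || !same("outcome") || !same("family"))
    stop_("replicates disagree on method/outcome/family")
  m <- length(sets)
  J <- ref$J
  pool_one <- function(bs, vs) {
    ok <- !is.na(bs) & !is.na(vs)
    if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    bs <- bs[ok]; vs <- vs[ok]; mm <- length(bs)
    W <- mean(vs)
    B <- if (mm > 1L) var(bs) else 0
    Tv <- W + (1 + 1 / mm) * B
    c(mean(bs), W, B, Tv)
  }
  tab <- ref$table
  tab$W <- tab$B <- tab$T_var <- NA_real_
  for (j in seq_len(J)) {
    bs <- vapply(sets, function(s) s$table$beta[j], 0)
    vs <- vapply(sets, function(s) s$table$se[j]^2, 0)
    p <- pool_one(bs, vs)
    tab$beta[j] <- p[1]; tab$W[j] <- p[2]; tab$B[j] <- p[3]
    tab$T_var[j] <- p[4]; tab$se[j] <- sqrt(p[4])
    fb <- vapply(sets, function(s) s$table$fs_beta[j], 0)
    fv <- vapply(sets, function(s) s$table$fs_se[j]^2, 0)
    fp <- pool_one(fb, fv)
    tab$fs_beta[j] <- fp[1]; tab$fs_se[j] <- sqrt(fp[4])
    for (col in c("mean_exposure", "min_exposure", "max_exposure",
                  "mean_instrument"))
      tab[[col]][j] <- mean(vapply(sets, function(s) s$table[[col]][j], 0))
  }
  tab$ci_low <- tab$beta - Z95 * tab$se
  tab$ci_high <- tab$beta + Z95 * tab$se
  tab$p_value <- 2 * pnorm(-abs(tab$beta / tab$se))
  tab$fs_p_value <- 2 * pnorm(-abs(tab$fs_beta / tab$fs_se))
  structure(
    list(method = ref$method, J = J, outcome = ref$outcome,
         family = ref$family, m = m, table = tab, overall = ref$overall),
    class = c("pooled_estimate_set", "stratum_estimate_set"))
}

#' @export
print.pooled_estimate_set <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled stratified MR (Rubin's rules over m = %d replicates)\n",
              x$m))
  NextMethod()
}

# betas and ses of the requested component, dropping failed strata
extract_component <- function(set, component) {
  tab <- set$table
  if (component == "first_stage") {
    data.frame(stratum = tab$stratum, beta = tab$fs_beta, se = tab$fs_se,
               mean_exposure = tab$mean_exposure)
  } else {
    data.frame(stratum = tab$stratum, beta = tab$beta, se = tab$se,
               mean_exposure = tab$mean_exposure)
  }
}

new_heterogeneity <- function(Q = NA_real_, df = NA_integer_, p_Q = NA_real_,
                              trend_slope = NA_real_, trend_se = NA_real_,
                              p_trend = NA_real_, component = "estimate") {
  structure(list(Q = Q, df = df, p_Q = p_Q, trend_slope = trend_slope,
                 trend_se = trend_se, p_trend = p_trend,
                 component = component),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, digits = 4, ...) {
  cat(sprintf("Across-strata heterogeneity (%s)\n", x$component))
  if (!is.na(x$Q))
    cat(sprintf("  Cochran's Q = %.*g on %d df, p = %.3g\n",
                digits, x$Q, x$df, x$p_Q))
  if (!is.na(x$trend_slope))
    cat(sprintf("  IVW trend slope = %.*g (SE %.*g), p = %.3g\n",
                digits, x$trend_slope, digits, x$trend_se, x$p_trend))
  invisible(x)
}

#' Cochran's Q heterogeneity test across stratum estimates
#'
#' Inverse-variance-weighted fixed-effect heterogeneity statistic: with
#' weights \eqn{w_j = 1/se_j^2} and fixed-effect mean
#' \eqn{\hat\theta = \sum w_j \theta_j / \sum w_j},
#' \eqn{Q = \sum w_j (\theta_j - \hat\theta)^2}, referred to a chi-square
#' distribution with `J - 1` degrees of freedom. Under homogeneity (e.g. a
#' constant linear causal effect with no selection) Q is calibrated; strong
#' heterogeneity across negative-control strata signals bias.
#'
#' @param set a `stratum_estimate_set` or `pooled_estimate_set` (J >= 2
#'   estimable strata, all SEs > 0).
#' @param component `"estimate"` (default) or `"first_stage"`.
#' @return A `heterogeneity_result` with `Q`, `df`, `p_Q` filled (trend
#'   fields `NA`).
#' @export
cochran_q <- function(set, component = c("estimate", "first_stage")) {
  component <- match.arg(component)
  d <- extract_component(set, component)
  d <- d[!is.na(d$beta), , drop = FALSE]
  if (nrow(d) < 2L)
    stop_("Cochran's Q needs at least 2 estimable strata (df = J - 1 > 0)")
  if (any(is.na(d$se) | d$se <= 0))
    stop_("all stratum standard errors must be > 0")
  w <- 1 / d$se^2
  theta_hat <- sum(w * d$beta) / sum(w)
  Q <- sum(w * (d$beta - theta_hat)^2)
  df <- nrow(d) - 1L
  new_heterogeneity(Q = Q, df = df, p_Q = pchisq(Q, df, lower.tail = FALSE),
                    component = component)
}

#' Inverse-variance-weighted trend of stratum estimates on stratum exposure
#'
#' Weighted least-squares regression (weights \eqn{1/se_j^2}) of the stratum
#' estimates on the stratum mean exposure, i.e. a fixed-effect
#' meta-regression. The slope is in effect units per exposure unit of the
#' stratum mean; a clear non-zero slope across negative-control strata, or a
#' trend contradicting trial evidence, signals bias. The trend is on the
#' exposure scale (not the stratum index) because that is the scale on which
#' dose-response claims are interpreted.
#'
#' @param set a `stratum_estimate_set` or `pooled_estimate_set` with at least
#'   3 estimable strata and non-constant stratum mean exposures.
#' @param component `"estimate"` (default) or `"first_stage"`.
#' @return A `heterogeneity_result` with `trend_slope`, `trend_se`, `p_trend`
#'   filled (Q fields `NA`).
#' @export
trend_test <- function(set, component = c("estimate", "first_stage")) {
  component <- match.arg(component)
  d <- extract_component(set, component)
  d <- d[!is.na(d$beta), , drop = FALSE]
  if (nrow(d) < 3L) stop_("trend test needs at least 3 estimable strata")
  if (any(is.na(d$se) | d$se <= 0))
    stop_("all stratum standard errors must be > 0")
  if (var(d$mean_exposure) == 0)
    stop_("stratum mean exposures are constant: trend is undefined")
  w <- 1 / d$se^2
  X <- cbind(1, d$mean_exposure)
  XtWX <- crossprod(X, w * X)
  b <- solve(XtWX, crossprod(X, w * d$beta))
  V <- solve(XtWX)          # known-variance (fixed-effect) covariance
  slope <- b[2]
  se <- sqrt(V[2, 2])
  new_heterogeneity(trend_slope = slope, trend_se = se,
                    p_trend = 2 * pnorm(-abs(slope / se)),
                    component = component)
}

#' Check the constant genetic effect assumption
#'
#' Applies [cochran_q()] to the per-stratum first-stage (instrument-exposure)
#' associations. Under the constant genetic effect assumption these slopes are
#' equal across strata; heterogeneity here undermines the residual method in
#' particular, whose validity relies on that assumption.
#'
#' @param set a `stratum_estimate_set` or `pooled_estimate_set` with
#'   first-stage estimates.
#' @return A `heterogeneity_result` for the first-stage component.
#' @export
constant_genetic_effect_check <- function(set) {
  cochran_q(set, component = "first_stage")
}
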