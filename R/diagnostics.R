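#' Negative-control-outcome analysis
#'
#' The primary bias audit for stratified MR. For each negative-control
#' outcome (NCO) — an outcome such as age or sex that cannot be caused by the
#' exposure, so every estimate should be null — it runs conventional
#' (whole-cohort) MR, then stratified MR by the requested methods
#' (doubly-ranked replicates pooled with Rubin's rules), and summarizes the
#' evidence of bias: Cochran's Q across strata, the IVW trend, the constant
#' genetic effect check, and per-outcome flags.
#'
#' Flags per outcome and method: `heterogeneity_flag = (p_Q < alpha)`,
#' `nonnull_strata_count` = number of strata with `p < alpha`, and
#' `impossibility_flag` from the stratum/overall consistency check. All flags
#' are recomputable from the contained estimates.
#'
#' @param cohort a cohort data.frame (already restricted to the analysed
#'   sample; see [apply_selection()]).
#' @param nco_outcomes character vector of NCO column names (families are
#'   inferred: 0/1 columns are treated as binary).
#' @param J number of strata.
#' @param methods subset of `c("residual", "doubly_ranked")`.
#' @param m_replicates number of doubly-ranked replicates to pool (the
#'   residual method is deterministic and run once).
#' @param covariates optional covariate columns.
#' @param alpha flag threshold (default 0.05).
#' @param seed base seed for replicate tie-breaking.
#' @return An `nco_report`: field `outcomes`, a list per NCO with `family`,
#'   `overall` ([mr_estimate]), and per method `set`, `Q`, `trend`,
#'   `cge` (constant-genetic-effect check) and `flags`.
#' @export
nco_analysis <- function(cohort, nco_outcomes = c("age", "sex"), J = 10,
                         methods = c("residual", "doubly_ranked"),
                         m_replicates = 20L, covariates = NULL,
                         alpha = 0.05, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_cohort(cohort, c("id", "instrument_score", "exposure", nco_outcomes))
  if (alpha < 0 || alpha > 1) stop_("alpha must be in [0, 1]")
  res <- lapply(nco_outcomes, function(outc) {
    family <- if (is_binary01(cohort[[outc]])) "binary" else "continuous"
    overall <- if (family == "binary")
      two_stage_binary(cohort, outc, covariates)
    else two_stage_continuous(cohort, outc, covariates)
    per_method <- lapply(methods, function(meth) {
      set <- if (meth == "residual") {
        a <- residual_strata(cohort, J, covariates)
        suppressWarnings(stratified_mr(cohort, a, outc, family, covariates))
      } else {
        reps <- lapply(seq_len(m_replicates), function(i) {
          a <- doubly_ranked_strata(cohort, J, replicate_seed = seed + i)
          suppressWarnings(stratified_mr(cohort, a, outc, family, covariates))
        })
        pool_replicates(reps)
      }
      Q <- tryCatch(cochran_q(set), error = function(e) NULL)
      trend <- tryCatch(trend_test(set), error = function(e) NULL)
      cge <- tryCatch(constant_genetic_effect_check(set),
                      error = function(e) NULL)
      flags <- list(
        heterogeneity_flag = !is.null(Q) && Q$p_Q < alpha,
        nonnull_strata_count = sum(set$table$p_value < alpha, na.rm = TRUE),
        impossibility_flag = impossibility_flag(set))
      list(set = set, Q = Q, trend = trend, cge = cge, flags = flags)
    })
    names(per_method) <- methods
    list(family = family, overall = overall, per_method = per_method)
  })
  names(res) <- nco_outcomes
  structure(list(outcomes = res, J = J, methods = methods,
                 m_replicates = m_replicates, alpha = alpha),
            class = "nco_report")
}

#' @export
print.nco_report <- function(x, digits = 3, ...) {
  cat(sprintf("Negative-control-outcome analysis (J = %d, alpha = %g)\n",
              x$J, x$alpha))
  for (outc in names(x$outcomes)) {
    o <- x$outcomes[[outc]]
    cat(sprintf("\nOutcome '%s' (%s)\n  overall: ", outc, o$family))
    print(o$overall, digits = digits)
    for (meth in names(o$per_method)) {
      pm <- o$per_method[[meth]]
      cat(sprintf("  %s: Q p = %s, trend p = %s, het flag = %s, ",
                  meth,
                  if (is.null(pm$Q)) "NA" else format(pm$Q$p_Q, digits = 3),
                  if (is.null(pm$trend)) "NA"
                  else format(pm$trend$p_trend, digits = 3),
                  pm$flags$heterogeneity_flag))
      cat(sprintf("non-null strata = %d/%d\n",
                  pm$flags$nonnull_strata_count, x$J))
    }
  }
  invisible(x)
}

#' Strata-stability analysis from repeat exposure measurements
#'
#' Stratifies the cohort twice with the same instrument and the same method —
#' once on the baseline exposure, once on the repeat measurement — and
#' cross-classifies stratum membership. With a fluctuating exposure
#' (test-retest correlation well below 1), individuals move strata between
#' occasions, so stratum-specific causal claims that differ sharply between
#' adjacent strata are not credible. The diagonal of the row-normalized
#' matrix is the per-stratum retention.
#'
#' @param cohort a cohort data.frame with `exposure` and `exposure_repeat`.
#' @param J number of strata.
#' @param method `"doubly_ranked"` (default) or `"residual"`.
#' @param replicate_seed tie-breaking seed, shared between the two occasions.
#' @return A `transition_matrix`: `J`, `counts` (J x J, rows = occasion 1),
#'   `proportions` (row-normalized), `retention` (diagonal), `n`.
#' @export
stability_analysis <- function(cohort, J, method = c("doubly_ranked",
                                                     "residual"),
                               replicate_seed = 1L) {
  method <- match.arg(method)
  check_cohort(cohort, c("id", "instrument_score", "exposure"))
  if (is.null(cohort$exposure_repeat) || anyNA(cohort$exposure_repeat))
    stop_("exposure_repeat column missing or incomplete")
  strat <- function(expo) {
    if (method == "doubly_ranked") {
      doubly_ranked_strata(cohort, J, replicate_seed, exposure = expo)
    } else {
      co <- cohort
      co$exposure <- cohort[[expo]]
      residual_strata(co, J)
    }
  }
  s1 <- assignment_for(strat("exposure"), cohort)
  s2 <- assignment_for(strat("exposure_repeat"), cohort)
  counts <- table(factor(s1, levels = seq_len(J)),
                  factor(s2, levels = seq_len(J)))
  counts <- matrix(as.integer(counts), J, J,
                   dimnames = list(occasion1 = seq_len(J),
                                   occasion2 = seq_len(J)))
  props <- counts / rowSums(counts)
  structure(list(J = J, method = method, counts = counts,
                 proportions = props, retention = diag(props),
                 n = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Stratum transition matrix (%s method, J = %d, n = %d)\n",
              x$method, x$J, x$n))
  cat("Row-normalized proportions (rows: occasion 1):\n")
  print(round(x$proportions, digits))
  cat("Retention (diagonal): ",
      paste(format(round(x$retention, digits)), collapse = " "), "\n")
  invisible(x)
}
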