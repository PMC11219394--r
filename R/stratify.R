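#' Stratify a cohort by the residual method
#'
#' Regresses the exposure on the instrument score (plus optional covariates)
#' by least squares; the residuals are the "IV-free" (non-genetic) exposure.
#' Individuals are ranked by residual and cut into `J` quantile strata of
#' near-equal size (differing by at most one), ordered so that stratum 1 holds
#' the lowest IV-free exposure. Ties are broken by stable input order. The
#' exposure is never transformed here; any transformation (e.g. log) is the
#' caller's responsibility.
#'
#' @param cohort a cohort data.frame with `id`, `instrument_score`, `exposure`.
#' @param J number of strata (>= 1); `n >= J` required.
#' @param covariates optional character vector of covariate column names to
#'   include in the residualizing regression (the primary analyses are
#'   unadjusted).
#' @return A `stratum_assignment` with fields `method`, `n_strata`,
#'   `replicate_id`, `id`, `stratum` (and `pre_stratum = NULL`).
#' @export
residual_strata <- function(cohort, J, covariates = NULL) {
  check_cohort(cohort)
  n <- nrow(cohort)
  J <- as.integer(J)
  if (J < 1L) stop_("J must be >= 1")
  if (n < J) stop_("fewer individuals (", n, ") than strata (", J, ")")
  if (var(cohort$instrument_score) == 0)
    stop_("instrument_score has zero variance: residuals are undefined")
  X <- design_matrix(cohort, "instrument_score", covariates)
  res <- fit_ols(cohort$exposure, X)$residuals
  ord <- order(res)                       # stable for ties (radix)
  stratum <- integer(n)
  stratum[ord] <- ceiling(seq_len(n) * J / n)
  new_assignment("residual", J, 1L, cohort$id, stratum, NULL)
}

#' Stratify a cohort by the doubly-ranked method
#'
#' Individuals are ranked by instrument score and split into consecutive
#' pre-strata of size `J` (so `K = floor(N/J)` full pre-strata; with
#' `N = J * K` exactly, e.g. N = 1000 and J = 10 give 100 pre-strata of 10).
#' Within each pre-stratum the participant with the lowest exposure goes to
#' final stratum 1, the next lowest to stratum 2, and so on, so each full
#' pre-stratum contributes exactly one member to every final stratum and the
#' instrument distribution is balanced across final strata. When `J` does not
#' divide `N`, the trailing partial pre-stratum (size `m < J`) assigns its
#' exposure-ranked members to final strata `1..m`, so no individual is
#' dropped. Ties in instrument or exposure are broken by a uniform random
#' permutation seeded by `replicate_seed` — the reason the method is run as
#' multiple replicates.
#'
#' @param cohort a cohort data.frame with `id`, `instrument_score`, `exposure`.
#' @param J number of final strata (>= 1); `n >= J` required.
#' @param replicate_seed integer seed for tie-breaking; with no ties the
#'   assignment does not depend on it.
#' @param exposure name of the exposure column to rank on (default
#'   `"exposure"`; used by the stability analysis to rank on a repeat
#'   measurement).
#' @return A `stratum_assignment` with `pre_stratum` recorded.
#' @export
doubly_ranked_strata <- function(cohort, J, replicate_seed = 1L,
                                 exposure = "exposure") {
  check_cohort(cohort, c("id", "instrument_score", exposure))
  n <- nrow(cohort)
  J <- as.integer(J)
  if (J < 1L) stop_("J must be >= 1")
  if (n < J) stop_("fewer individuals (", n, ") than strata (", J, ")")
  x <- cohort[[exposure]]
  if (anyNA(x) || anyNA(cohort$instrument_score))
    stop_("missing values in instrument_score or ", exposure)
  set.seed(replicate_seed)
  u1 <- runif(n)
  u2 <- runif(n)
  ord <- order(cohort$instrument_score, u1)   # instrument rank, random ties
  pre_sorted <- ((seq_len(n) - 1L) %/% J) + 1L
  # within-pre-stratum exposure rank (random ties) = final stratum
  o2 <- order(pre_sorted, x[ord], u2[ord])
  final <- integer(n)
  final[ord[o2]] <- sequence(tabulate(pre_sorted))
  pre <- integer(n)
  pre[ord] <- pre_sorted
  new_assignment("doubly_ranked", J, as.integer(replicate_seed),
                 cohort$id, final, pre)
}

new_assignment <- function(method, J, replicate_id, id, stratum, pre) {
  structure(
    list(method = method, n_strata = J, replicate_id = replicate_id,
         id = id, stratum = stratum, pre_stratum = pre),
    class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat(sprintf("Stratum assignment: %s method, J = %d, n = %d%s\n",
              x$method, x$n_strata, length(x$id),
              if (!is.null(x$pre_stratum))
                sprintf(", K = %d pre-strata", max(x$pre_stratum)) else ""))
  print(table(stratum = x$stratum))
  invisible(x)
}

# stratum vector aligned to the cohort's rows (errors unless the assignment
# covers the cohort exactly)
assignment_for <- function(assignment, cohort) {
  stopifnot(inherits(assignment, "stratum_assignment"))
  idx <- match(cohort$id, assignment$id)
  if (anyNA(idx) || length(assignment$id) != nrow(cohort))
    stop_("assignment does not cover the cohort (id mismatch)")
  assignment$stratum[idx]
}

#' Per-stratum summaries of exposure and instrument
#'
#' One row per stratum, ordered by stratum index: size, mean/min/max exposure
#' and mean instrument score. Stratum mean exposures are the comparable
#' summary across implementations of the same stratification.
#'
#' @param cohort a cohort data.frame.
#' @param assignment a `stratum_assignment` covering the cohort.
#' @return A data.frame with columns `stratum`, `n`, `mean_exposure`,
#'   `min_exposure`, `max_exposure`, `mean_instrument`.
#' @export
summarize_strata <- function(cohort, assignment) {
  check_cohort(cohort)
  s <- assignment_for(assignment, cohort)
  J <- assignment$n_strata
  out <- data.frame(stratum = seq_len(J))
  by_s <- function(v, f) vapply(seq_len(J), function(j) f(v[s == j]), 0)
  out$n <- tabulate(s, nbins = J)
  if (any(out$n == 0L)) stop_("empty stratum in assignment")
  out$mean_exposure <- by_s(cohort$exposure, mean)
  out$min_exposure <- by_s(cohort$exposure, min)
  out$max_exposure <- by_s(cohort$exposure, max)
  out$mean_instrument <- by_s(cohort$instrument_score, mean)
  out
}
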