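#' Construct an MR estimate object
#'
#' Container for a single instrumental-variable (or first-stage) effect
#' estimate: point estimate, standard error, symmetric 95\% Wald interval and
#' two-sided normal p-value. For binary outcomes `beta` is on the log-odds
#' scale; report `exp(beta)` as an odds ratio.
#'
#' @param beta point estimate (outcome units, or log-odds, per exposure unit).
#' @param se standard error (> 0, or 0 only for degenerate exact fits).
#' @param n number of individuals used.
#' @param family `"continuous"` or `"binary"`.
#' @param estimator label for the estimator that produced it
#'   (`"two_stage"`, `"ratio"`, `"ols"`, `"pooled"`).
#' @return An object of class `mr_estimate` with fields `beta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `family`, `estimator`.
#' @export
mr_estimate <- function(beta, se, n, family = c("continuous", "binary"),
                        estimator = c("two_stage", "ratio", "ols", "pooled")) {
  family <- match.arg(family)
  estimator <- match.arg(estimator)
  if (!is.finite(beta)) stop_("non-finite estimate")
  if (!is.finite(se) || se < 0) stop_("standard error must be finite and >= 0")
  p <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  structure(
    list(beta = beta, se = se,
         ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
         p_value = p, n = as.integer(n),
         family = family, estimator = estimator),
    class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  eff <- if (x$family == "binary") {
    sprintf("log-OR %.*g (OR %.*g)", digits, x$beta, digits, exp(x$beta))
  } else {
    sprintf("beta %.*g", digits, x$beta)
  }
  cat(sprintf("MR estimate (%s, %s outcome, n = %d)\n",
              x$estimator, x$family, x$n))
  cat(sprintf("  %s, SE %.*g, 95%% CI [%.*g, %.*g], p = %.3g\n",
              eff, digits, x$se, digits, x$ci_low, digits, x$ci_high,
              x$p_value))
  invisible(x)
}

#' Wald ratio estimate from reduced-form and first-stage associations
#'
#' Ratio (Wald) instrumental-variable estimator: the instrument-outcome
#' association divided by the instrument-exposure association, with a
#' first-order delta-method standard error
#' \eqn{se^2 = se_{GY}^2/\beta_{GX}^2 + \beta_{GY}^2 se_{GX}^2/\beta_{GX}^4}.
#' With a single instrument and no covariates this equals the two-stage
#' estimate and serves as its algebraic cross-check.
#'
#' @param beta_gy [mr_estimate] for the instrument-outcome regression.
#' @param beta_gx [mr_estimate] for the instrument-exposure regression.
#' @return An [mr_estimate] with `estimator = "ratio"`.
#' @export
ratio_estimate <- function(beta_gy, beta_gx) {
  stopifnot(inherits(beta_gy, "mr_estimate"), inherits(beta_gx, "mr_estimate"))
  if (beta_gx$beta == 0)
    stop_("first-stage (instrument-exposure) slope is zero: ",
          "ratio estimate undefined (weak/null instrument)")
  beta <- beta_gy$beta / beta_gx$beta
  se <- sqrt(beta_gy$se^2 / beta_gx$beta^2 +
               beta_gy$beta^2 * beta_gx$se^2 / beta_gx$beta^4)
  mr_estimate(beta, se, n = min(beta_gy$n, beta_gx$n),
              family = beta_gy$family, estimator = "ratio")
}
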