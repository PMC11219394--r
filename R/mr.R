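#' Instrument-exposure (first-stage) association
#'
#' Least-squares slope of the exposure on the instrument score (plus optional
#' covariates), with model-based standard error and normal-approximation
#' CI/p-value. Run per stratum, this association probes the constant genetic
#' effect assumption: under it, the slope is equal across strata.
#'
#' @param cohort a cohort data.frame.
#' @param covariates optional character vector of covariate columns.
#' @return An [mr_estimate] (`estimator = "ols"`) for the slope on
#'   `instrument_score`.
#' @export
iv_exposure_assoc <- function(cohort, covariates = NULL) {
  check_cohort(cohort)
  if (var(cohort$instrument_score) == 0)
    stop_("instrument_score has zero variance")
  X <- design_matrix(cohort, "instrument_score", covariates)
  fit <- fit_ols(cohort$exposure, X)
  mr_estimate(unname(fit$coef["instrument_score"]),
              unname(fit$se["instrument_score"]),
              n = nrow(cohort), family = "continuous", estimator = "ols")
}

# reduced-form association of an arbitrary column on the instrument (internal)
iv_outcome_assoc <- function(cohort, outcome, covariates = NULL) {
  X <- design_matrix(cohort, "instrument_score", covariates)
  fit <- fit_ols(cohort[[outcome]], X)
  mr_estimate(unname(fit$coef["instrument_score"]),
              unname(fit$se["instrument_score"]),
              n = nrow(cohort), family = "continuous", estimator = "ols")
}

#' Two-stage least squares for a continuous outcome
#'
#' One-sample IV estimation: stage 1 regresses the exposure on the instrument
#' (plus covariates); stage 2 regresses the outcome on the fitted exposure
#' (plus covariates). The standard error is the standard 2SLS one, computed
#' from residuals that use the *observed* exposure (so the generated-regressor
#' correction is built in). With a single instrument and no covariates the
#' estimate equals the Wald ratio `cov(G,Y)/cov(G,X)` exactly.
#'
#' @param cohort a cohort data.frame.
#' @param outcome name of the continuous outcome column.
#' @param covariates optional character vector of covariate columns.
#' @return An [mr_estimate] (`family = "continuous"`, `estimator = "two_stage"`).
#' @export
two_stage_continuous <- function(cohort, outcome, covariates = NULL) {
  check_cohort(cohort, c("id", "instrument_score", "exposure", outcome))
  if (var(cohort$instrument_score) == 0)
    stop_("instrument_score has zero variance")
  y <- cohort[[outcome]]
  n <- nrow(cohort)
  Z <- design_matrix(cohort, "instrument_score", covariates)
  s1 <- fit_ols(cohort$exposure, Z)
  xhat <- drop(Z %*% s1$coef)
  W <- design_matrix(cohort, NULL, covariates)
  W <- cbind(W[, 1, drop = FALSE], exposure = xhat,
             W[, -1, drop = FALSE])
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1L):ncol(W)]]
    stop_("singular second-stage design: ", paste(bad, collapse = ", "))
  }
  b <- qr.coef(qrW, y)
  # IV residuals use the observed exposure, not the fitted one
  Wobs <- W
  Wobs[, "exposure"] <- cohort$exposure
  e <- y - drop(Wobs %*% b)
  sigma2 <- sum(e^2) / (n - ncol(W))
  XtXinv <- chol2inv(qr.R(qrW))[order(qrW$pivot), order(qrW$pivot),
                                drop = FALSE]
  se <- sqrt(sigma2 * XtXinv[2, 2])
  mr_estimate(unname(b["exposure"]), se, n = n,
              family = "continuous", estimator = "two_stage")
}

#' Two-stage residual inclusion for a binary outcome
#'
#' TSRI estimator: stage 1 regresses the exposure on the instrument (plus
#' covariates) by least squares; stage 2 fits a logistic regression of the
#' outcome on the exposure, the stage-1 residual and the covariates. The
#' reported effect is the log-odds coefficient on the exposure. The default
#' standard error is the second-stage model-based one (matching common TSRI
#' practice); `se_method = "bootstrap"` resamples individuals instead.
#'
#' @param cohort a cohort data.frame.
#' @param outcome name of a 0/1 outcome column with both classes present.
#' @param covariates optional character vector of covariate columns.
#' @param se_method `"model"` (default) or `"bootstrap"`.
#' @param bootstrap_reps resamples when `se_method = "bootstrap"`.
#' @param bootstrap_seed seed for the resampling.
#' @return An [mr_estimate] (`family = "binary"`, `estimator = "two_stage"`,
#'   beta on the log-odds scale).
#' @export
two_stage_binary <- function(cohort, outcome, covariates = NULL,
                             se_method = c("model", "bootstrap"),
                             bootstrap_reps = 200L, bootstrap_seed = 1L) {
  se_method <- match.arg(se_method)
  check_cohort(cohort, c("id", "instrument_score", "exposure", outcome))
  y <- cohort[[outcome]]
  if (!is_binary01(y)) stop_("outcome '", outcome, "' is not coded 0/1")
  if (length(unique(y)) < 2L)
    stop_("outcome '", outcome, "' has a single class: ",
          "logistic stage is undefined")
  if (var(cohort$instrument_score) == 0)
    stop_("instrument_score has zero variance")
  fit2 <- tsri_fit(cohort, y, covariates)
  beta <- unname(coef(fit2)["exposure"])
  if (!fit2$converged ||
      any(fitted(fit2) < 1e-10) || any(fitted(fit2) > 1 - 1e-10))
    stop_("logistic second stage did not converge cleanly ",
          "(possible separation on '", outcome, "')")
  se <- if (se_method == "model") {
    unname(sqrt(diag(vcov_glm(fit2))["exposure"]))
  } else {
    set.seed(bootstrap_seed)
    n <- nrow(cohort)
    bs <- vapply(seq_len(bootstrap_reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      co <- cohort[idx, , drop = FALSE]
      unname(coef(tsri_fit(co, co[[outcome]], covariates))["exposure"])
    }, 0)
    sd(bs)
  }
  mr_estimate(beta, se, n = nrow(cohort), family = "binary",
              estimator = "two_stage")
}

tsri_fit <- function(cohort, y, covariates) {
  Z <- design_matrix(cohort, "instrument_score", covariates)
  r1 <- fit_ols(cohort$exposure, Z)$residuals
  D <- design_matrix(cohort, "exposure", covariates)
  D <- cbind(D, stage1_resid = r1)
  suppressWarnings(
    glm.fit2(D, y))
}

# logistic fit on an explicit design matrix, returning a glm-like object
glm.fit2 <- function(X, y) {
  fit <- stats::glm.fit(X, y, family = binomial())
  if (any(is.na(fit$coefficients)))
    stop_("singular design in logistic second stage: ",
          paste(names(fit$coefficients)[is.na(fit$coefficients)],
                collapse = ", "))
  pivot <- fit$qr$pivot
  V <- chol2inv(qr.R(fit$qr))[order(pivot), order(pivot), drop = FALSE]
  nm <- names(fit$coefficients)
  dimnames(V) <- list(nm, nm)
  fit$vcov <- V
  class(fit) <- "glm_fit2"
  fit
}

#' @export
coef.glm_fit2 <- function(object, ...) object$coefficients

#' @export
fitted.glm_fit2 <- function(object, ...) object$fitted.values

vcov_glm <- function(fit) fit$vcov
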