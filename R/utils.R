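# internal helpers shared across modules

# critical value for all normal-approximation CIs (symmetric Wald intervals)
Z95 <- 1.96

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}

# Least squares on an explicit design matrix with named columns.
# Errors on rank deficiency, naming the collinear column; returns coefficients,
# model-based SEs, residuals and sigma^2.
fit_ols <- function(y, X) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_("singular design: column(s) ", paste(bad, collapse = ", "),
          " collinear with the rest of the model")
  }
  coefs <- qr.coef(qrX, y)
  res <- y - drop(X %*% coefs)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(res^2) / df else 0
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  names(se) <- colnames(X)
  list(coef = coefs, se = se, residuals = res, sigma2 = sigma2,
       XtXinv = XtXinv, df = df)
}

# Build a design matrix [intercept, <main>, covariates...] from a cohort.
design_matrix <- function(cohort, main, covariates = NULL) {
  if (!is.null(covariates)) {
    missing_cov <- setdiff(covariates, names(cohort))
    if (length(missing_cov))
      stop_("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  X <- cbind(`(intercept)` = rep(1, nrow(cohort)))
  if (!is.null(main)) {
    X <- cbind(X, as.matrix(cohort[main]))
  }
  if (!is.null(covariates) && length(covariates)) {
    X <- cbind(X, as.matrix(cohort[covariates]))
  }
  storage.mode(X) <- "double"
  X
}

check_cohort <- function(cohort, cols = c("id", "instrument_score", "exposure")) {
  if (!is.data.frame(cohort)) stop_("cohort must be a data.frame")
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop_("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  invisible(cohort)
}

# fixed-precision numeric formatting used by render_report (deterministic)
fmt_num <- function(x, digits = 8) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
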