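# brute-force reference implementations and small fixture builders

make_cohort <- function(g, x, ...) {
  data.frame(id = seq_along(g), instrument_score = g, exposure = x, ...)
}

# naive doubly-ranked stratifier: explicit loops, no vectorized ranking
oracle_doubly_ranked <- function(g, x, J) {
  n <- length(g)
  ord <- order(g)
  blocks <- split(ord, ceiling(seq_along(ord) / J))
  out <- integer(n)
  for (blk in blocks) {
    by_x <- blk[order(x[blk])]
    for (j in seq_along(by_x)) out[by_x[j]] <- j
  }
  out
}

# naive residual stratifier: closed-form simple-regression residuals,
# then quantile groups by the shared ceiling(i*J/n) cut convention
oracle_residual <- function(g, x, J) {
  n <- length(g)
  b <- sum((g - mean(g)) * (x - mean(x))) / sum((g - mean(g))^2)
  a <- mean(x) - b * mean(g)
  res <- x - a - b * g
  out <- integer(n)
  srt <- order(res)
  for (i in seq_len(n)) out[srt[i]] <- ceiling(i * J / n)
  out
}

# a 9-person cohort realizing the doubly-ranked worked example at J = 3:
# participant 1 has the lowest instrument value (hence pre-stratum 1) and the
# second-lowest exposure within that pre-stratum
worked_example_cohort <- function() {
  make_cohort(
    g = c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3, 2.1, 2.2, 2.3),
    x = c(5.0, 3.0, 8.0, 4.0, 6.0, 2.0, 7.0, 1.0, 9.0))
}

# fabricate a stratum_estimate_set directly from per-stratum numbers
fake_set <- function(betas, ses, mean_exposure = seq_along(betas),
                     fs_betas = rep(1, length(betas)),
                     fs_ses = rep(0.1, length(betas)),
                     overall_beta = mean(betas), overall_se = 0.1,
                     method = "doubly_ranked", outcome = "y",
                     family = "continuous", n = 100L) {
  J <- length(betas)
  tab <- data.frame(
    stratum = seq_len(J), n = n,
    mean_exposure = mean_exposure,
    min_exposure = mean_exposure - 1, max_exposure = mean_exposure + 1,
    mean_instrument = 0,
    beta = betas, se = ses,
    ci_low = betas - 1.96 * ses, ci_high = betas + 1.96 * ses,
    p_value = 2 * pnorm(-abs(betas / ses)),
    fs_beta = fs_betas, fs_se = fs_ses,
    fs_p_value = 2 * pnorm(-abs(fs_betas / fs_ses)),
    error = NA_character_)
  structure(
    list(method = method, J = J, outcome = outcome, family = family,
         replicate_id = 1L, table = tab,
         overall = mr_estimate(overall_beta, overall_se, n = n * J,
                               family = family),
         impossible = FALSE),
    class = "stratum_estimate_set")
}
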