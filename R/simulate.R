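#' Simulation configuration for a synthetic MR cohort
#'
#' Defines the causal, measurement and selection structure of a synthetic
#' cohort with a polygenic instrument. The generative model is
#' \deqn{G_i = \sum_k w_k d_{ik}, \quad
#'       X_i = \mu + \alpha(\cdot) G_i + \gamma U_i + \epsilon_i,}
#' with dosages \eqn{d_{ik} \sim Bin(2, f_k)}, confounder
#' \eqn{U_i \sim N(0,1)}, noise \eqn{\epsilon_i \sim N(0, \sigma^2)}.
#' A continuous outcome is linear in X (\eqn{Y = \theta_c X + \gamma U + e}) and
#' a binary outcome logistic in X
#' (\eqn{logit P(D=1) = \theta_0 + \theta_b X + \gamma U}); both share the
#' confounder, so unadjusted observational regressions are confounded while the
#' instrument is valid. Negative-control outcomes — an age-like continuous
#' variable and a sex-like binary variable — are drawn independently of
#' \eqn{G, U, X}, so any non-null MR estimate on them reflects bias.
#' Selection into the analysed sample follows a logistic model in exposure,
#' age (centred), sex and an exposure-by-sex interaction; an intercept of
#' `+Inf` (the default) selects everyone.
#'
#' Under `genetic_effect_mode = "exposure_varying"` the per-score-unit genetic
#' effect \eqn{\alpha} is a monotone (linear, hence piecewise-linear) function
#' of the percentile of the non-genetic part of the exposure, interpolating
#' `genetic_effect_range` from bottom to top; the default `c(2/3, 4/3)` makes
#' the genetic effect at the top of the distribution twice that at the bottom,
#' violating the constant genetic effect assumption.
#'
#' @param n_individuals cohort size before selection.
#' @param n_variants number of instrument variants.
#' @param allele_freqs effect-allele frequencies, strictly in (0,1); recycled
#'   to `n_variants`.
#' @param variant_weights per-allele effects on the exposure (exposure units);
#'   recycled to `n_variants`.
#' @param genetic_effect_mode `"constant"` or `"exposure_varying"`.
#' @param genetic_effect_range multiplier of the genetic effect at the bottom
#'   and top of the non-genetic exposure distribution (`exposure_varying` only).
#' @param exposure_intercept baseline exposure level.
#' @param confounder_effect effect of the standard-normal confounder on the
#'   exposure and on both outcomes.
#' @param exposure_noise_sd SD of the exposure noise term (> 0).
#' @param causal_effect_continuous effect of exposure on the continuous
#'   outcome (outcome units per exposure unit).
#' @param causal_effect_binary effect of exposure on the binary outcome
#'   (log-odds per exposure unit).
#' @param binary_outcome_intercept baseline log-odds of the binary outcome.
#' @param nco_config list `age_mean`, `age_sd`, `sex_prob` for the
#'   negative-control outcomes.
#' @param selection_coeffs list `intercept`, `on_exposure`, `on_age`,
#'   `on_sex`, `on_exposure_x_sex` (log-odds of inclusion; age enters centred
#'   at `age_mean`). `intercept = Inf` disables selection.
#' @param repeat_correlation target test-retest correlation for a repeat
#'   exposure measurement, in \[-1, 1\], or `NA` to skip it at generation time
#'   (see [simulate_repeat_exposure()]).
#' @param keep_dosages keep the dosage matrix as an attribute of the cohort.
#' @param seed integer seed; all randomness flows from it.
#' @return A `sim_config` list, validated.
#' @seealso [sim_scenario()] for the named study scenarios,
#'   [read_sim_config()] to load one from a YAML file.
#' @export
sim_config <- function(n_individuals = 10000L,
                       n_variants = 50L,
                       allele_freqs = seq(0.1, 0.5, length.out = n_variants),
                       variant_weights = 0.1 +
                         0.04 * sin(seq_len(n_variants)),
                       genetic_effect_mode = c("constant", "exposure_varying"),
                       genetic_effect_range = c(2 / 3, 4 / 3),
                       exposure_intercept = 0,
                       confounder_effect = 0.5,
                       exposure_noise_sd = 1,
                       causal_effect_continuous = 0,
                       causal_effect_binary = 0,
                       binary_outcome_intercept = qlogis(0.3),
                       nco_config = list(age_mean = 57, age_sd = 8,
                                         sex_prob = 0.46),
                       selection_coeffs = list(intercept = Inf,
                                               on_exposure = 0,
                                               on_age = 0,
                                               on_sex = 0,
                                               on_exposure_x_sex = 0),
                       repeat_correlation = NA_real_,
                       keep_dosages = FALSE,
                       seed = 1L) {
  genetic_effect_mode <- match.arg(genetic_effect_mode)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    allele_freqs = rep_len(as.numeric(allele_freqs), n_variants),
    variant_weights = rep_len(as.numeric(variant_weights), n_variants),
    genetic_effect_mode = genetic_effect_mode,
    genetic_effect_range = as.numeric(genetic_effect_range),
    exposure_intercept = exposure_intercept,
    confounder_effect = confounder_effect,
    exposure_noise_sd = exposure_noise_sd,
    causal_effect_continuous = causal_effect_continuous,
    causal_effect_binary = causal_effect_binary,
    binary_outcome_intercept = binary_outcome_intercept,
    nco_config = nco_config,
    selection_coeffs = selection_coeffs,
    repeat_correlation = repeat_correlation,
    keep_dosages = isTRUE(keep_dosages),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 1L) stop_("n_individuals must be >= 1")
  if (cfg$n_variants < 0L) stop_("n_variants must be >= 0")
  if (cfg$n_variants > 0L && length(cfg$variant_weights) == 0L)
    stop_("variant_weights must be non-empty when n_variants > 0")
  if (any(!is.finite(cfg$allele_freqs)) ||
      any(cfg$allele_freqs <= 0) || any(cfg$allele_freqs >= 1))
    stop_("allele_freqs must be strictly in (0, 1)")
  if (any(!is.finite(cfg$variant_weights)))
    stop_("variant_weights must be finite")
  scalars <- c(cfg$exposure_intercept, cfg$confounder_effect,
               cfg$exposure_noise_sd, cfg$causal_effect_continuous,
               cfg$causal_effect_binary, cfg$binary_outcome_intercept,
               cfg$genetic_effect_range,
               cfg$nco_config$age_mean, cfg$nco_config$age_sd,
               cfg$nco_config$sex_prob)
  if (any(!is.finite(scalars))) stop_("non-finite model parameter")
  if (cfg$exposure_noise_sd <= 0) stop_("exposure_noise_sd must be > 0")
  if (cfg$nco_config$sex_prob <= 0 || cfg$nco_config$sex_prob >= 1)
    stop_("sex_prob must be in (0, 1)")
  if (length(cfg$genetic_effect_range) != 2L ||
      cfg$genetic_effect_range[2] < cfg$genetic_effect_range[1])
    stop_("genetic_effect_range must be an increasing pair")
  sc <- cfg$selection_coeffs
  need <- c("intercept", "on_exposure", "on_age", "on_sex",
            "on_exposure_x_sex")
  if (!all(need %in% names(sc)))
    stop_("selection_coeffs must contain: ", paste(need, collapse = ", "))
  slopes <- unlist(sc[setdiff(need, "intercept")])
  if (any(!is.finite(slopes))) stop_("selection slope coefficients must be finite")
  if (is.nan(sc$intercept)) stop_("selection intercept must not be NaN")
  if (!is.na(cfg$repeat_correlation) &&
      abs(cfg$repeat_correlation) > 1)
    stop_("repeat_correlation must be in [-1, 1]")
  invisible(cfg)
}

#' Named simulation scenarios used throughout the package
#'
#' Frozen parameterizations of [sim_config()] for the study conditions the
#' package's analyses and tests are built on:
#' \describe{
#'   \item{`null`}{no causal effects, no selection, constant genetic effect —
#'     the calibration scenario for negative-control outcomes.}
#'   \item{`homogeneous`}{a constant linear causal effect of 0.5 on the
#'     continuous outcome and 0.55 log-odds on the binary outcome, no
#'     selection — the scenario in which stratum estimates, pooled estimates
#'     and the overall estimate must agree.}
#'   \item{`selection_nco`}{no causal effects, but inclusion in the analysed
#'     sample depends on the exposure, the sex-like negative control and their
#'     interaction — the collider structure that produces spurious
#'     stratum-specific estimates while leaving the whole-cohort estimate
#'     near-null.}
#'   \item{`varying_genetic_effect`}{no causal effects, no selection, but the
#'     genetic effect on the exposure doubles from the bottom to the top of
#'     the distribution — the violation of the constant genetic effect
#'     assumption that [constant_genetic_effect_check()] should detect.}
#' }
#'
#' @param name scenario name.
#' @param n_individuals cohort size before selection.
#' @param seed integer seed.
#' @param ... further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_scenario <- function(name = c("null", "homogeneous", "selection_nco",
                                  "varying_genetic_effect"),
                         n_individuals = 10000L, seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    null = list(),
    homogeneous = list(causal_effect_continuous = 0.5,
                       causal_effect_binary = 0.55),
    selection_nco = list(
      selection_coeffs = list(intercept = -4.2, on_exposure = 1.5,
                              on_age = 0, on_sex = 0.6,
                              on_exposure_x_sex = -1.0)),
    varying_genetic_effect = list(genetic_effect_mode = "exposure_varying"))
  args <- modifyList(base, list(...))
  do.call(sim_config,
          c(list(n_individuals = n_individuals, seed = seed), args))
}

#' Simulate a cohort with a polygenic instrument
#'
#' Draws a full (pre-selection) cohort under the model described in
#' [sim_config()]. Deterministic given `config$seed`: identical configurations
#' produce byte-identical cohorts.
#'
#' @param config a [sim_config()].
#' @return A data.frame with columns `id`, `instrument_score`, `exposure`,
#'   optionally `exposure_repeat`, `age`, `sex`, `outcome_continuous`,
#'   `outcome_binary`, `selected`; if `config$keep_dosages`, the dosage matrix
#'   is attached as attribute `"dosages"` (columns `v1..vK`).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  K <- config$n_variants
  set.seed(config$seed)

  if (K > 0L) {
    dosages <- matrix(rbinom(n * K, 2L, rep(config$allele_freqs, each = n)),
                      nrow = n, ncol = K,
                      dimnames = list(NULL, paste0("v", seq_len(K))))
    g <- drop(dosages %*% config$variant_weights)
  } else {
    dosages <- matrix(numeric(0), nrow = n, ncol = 0L)
    g <- numeric(n)
  }

  u <- rnorm(n)
  eps <- rnorm(n, sd = config$exposure_noise_sd)
  nongenetic <- config$exposure_intercept + config$confounder_effect * u + eps
  alpha <- if (config$genetic_effect_mode == "constant") {
    rep(1, n)
  } else {
    pct <- (rank(nongenetic, ties.method = "first") - 0.5) / n
    lo <- config$genetic_effect_range[1]
    hi <- config$genetic_effect_range[2]
    lo + (hi - lo) * pct
  }
  x <- nongenetic + alpha * g

  # negative-control outcomes: independent of G, U, X by construction
  age <- rnorm(n, config$nco_config$age_mean, config$nco_config$age_sd)
  sex <- rbinom(n, 1L, config$nco_config$sex_prob)

  y_cont <- config$causal_effect_continuous * x +
    config$confounder_effect * u + rnorm(n)
  lp_bin <- config$binary_outcome_intercept +
    config$causal_effect_binary * x + config$confounder_effect * u
  y_bin <- rbinom(n, 1L, plogis(lp_bin))

  sc <- config$selection_coeffs
  lp_sel <- sc$intercept + sc$on_exposure * x +
    sc$on_age * (age - config$nco_config$age_mean) + sc$on_sex * sex +
    sc$on_exposure_x_sex * x * sex
  selected <- rbinom(n, 1L, plogis(lp_sel))

  cohort <- data.frame(
    id = seq_len(n),
    instrument_score = g,
    exposure = x,
    age = age,
    sex = sex,
    outcome_continuous = y_cont,
    outcome_binary = y_bin,
    selected = selected)

  if (!is.na(config$repeat_correlation)) {
    cohort <- simulate_repeat_exposure(cohort, config$repeat_correlation,
                                       seed = config$seed + 1L)
  }
  if (config$keep_dosages) attr(cohort, "dosages") <- dosages
  cohort
}

#' Add a noisy repeat exposure measurement
#'
#' Attaches an `exposure_repeat` column with population correlation `r` with
#' the exposure and the same marginal distribution (hence the same variance),
#' via a Gaussian-copula construction: the exposure is mapped to normal
#' scores, a correlated normal is drawn, and the result is mapped back through
#' the empirical quantile function of the exposure. `r = 1` reproduces the
#' exposure exactly.
#'
#' @param cohort a cohort data.frame with an `exposure` column.
#' @param r target test-retest correlation in \[-1, 1\] (e.g. 0.60, typical of
#'   fluctuating blood biomarkers such as triglycerides).
#' @param seed integer seed for the fresh noise draw.
#' @return The cohort with an `exposure_repeat` column.
#' @export
simulate_repeat_exposure <- function(cohort, r, seed = 1L) {
  check_cohort(cohort, c("exposure"))
  if (!is.finite(r) || abs(r) > 1) stop_("repeat correlation must be in [-1, 1]")
  x <- cohort$exposure
  n <- length(x)
  if (r == 1) {
    cohort$exposure_repeat <- x
    return(cohort)
  }
  set.seed(seed)
  p1 <- (rank(x, ties.method = "first") - 0.5) / n
  z1 <- qnorm(p1)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  xs <- sort(x)
  grid <- (seq_len(n) - 0.5) / n
  cohort$exposure_repeat <- approx(grid, xs, xout = pnorm(z2), rule = 2)$y
  cohort
}

#' Restrict a cohort to the selected (analysed) sample
#'
#' Keeps rows with `selected == 1`, preserving row order. Selection acts once,
#' at cohort entry: any stratum-level distortion downstream emerges from the
#' stratification methods themselves, it is not injected per stratum.
#'
#' @param cohort a cohort data.frame with a `selected` column.
#' @return The selected rows.
#' @export
apply_selection <- function(cohort) {
  check_cohort(cohort, "selected")
  out <- cohort[cohort$selected == 1, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_("no individuals selected: the selection model excludes everyone")
  out
}

#' Read a simulation configuration from a YAML file
#'
#' Flat keys with nested `nco_config` and `selection_coeffs` sections, matching
#' the arguments of [sim_config()]. A selection intercept given as the string
#' `"Inf"` is accepted.
#'
#' @param path path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$selection_coeffs$intercept))
    raw$selection_coeffs$intercept <- as.numeric(raw$selection_coeffs$intercept)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}
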