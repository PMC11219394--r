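---
title: "Stratified Mendelian randomization and its bias diagnostics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified Mendelian randomization and its bias diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
for a modifiable exposure: because genotypes are fixed at conception, a valid
instrument is unconfounded, and the instrumented (causal) effect of the
exposure on an outcome can be estimated even when the observational
association is confounded. "Non-linear" MR extends this from one whole-cohort
estimate to *localized* estimates within strata of the exposure, asking
whether the causal effect differs between, say, people with low and high
vitamin D. The catch is that one cannot stratify directly on the exposure —
it is a collider descendant of both genotype and confounders — so two
indirect stratification schemes are in use, and both can misbehave. This
package implements the two schemes, the estimators run inside them, and —
its main purpose — the diagnostics that reveal when stratum-specific
estimates are artefacts: negative-control outcomes, heterogeneity and trend
tests, replicate pooling, a first-stage homogeneity check, and a
repeat-measurement stability analysis, together with a synthetic cohort
generator that reproduces the selection mechanism believed to create the
artefacts.

## Stratification schemes

**Residual method** (`residual_strata()`). The exposure $X$ is regressed on
the instrument $G$ (optionally plus covariates); the residuals
$\hat\varepsilon = X - \hat\beta_0 - \hat\beta_1 G$ are the "IV-free"
exposure. Individuals are ranked by $\hat\varepsilon$ and cut into $J$
quantile strata of near-equal size (sizes differ by at most 1, cut rule
$j = \lceil \mathrm{rank} \cdot J / n \rceil$; ties keep input order). The
method is valid only under the *constant genetic effect* assumption — that
the $G \to X$ effect is the same everywhere in the distribution.

**Doubly-ranked method** (`doubly_ranked_strata()`). Individuals are ranked
by $G$ and split into consecutive pre-strata of size $J$ ($K = \lfloor N/J
\rfloor$ full pre-strata, $N = J \times K$ when $J$ divides $N$; 1000
individuals with $J = 10$ give 100 pre-strata of 10). Within each
pre-stratum, the individual with the $j$-th smallest exposure joins final
stratum $j$, so every full pre-stratum contributes one member to each final
stratum and the instrument distribution is balanced across final strata.
Numerical choices:

* *Remainder*: if $J \nmid N$ the trailing partial pre-stratum of size
  $m < J$ sends its exposure-ranked members to final strata $1..m$, so
  nobody is dropped and stratum sizes differ by at most 1.
* *Ties*: tied instrument or exposure values are ordered by a uniform random
  permutation drawn from `replicate_seed`. This is the only randomness in
  the method and the reason it is run as multiple replicates; with no ties
  the assignment is invariant to the seed.

## Estimators

All estimates are returned as `mr_estimate` objects with symmetric Wald 95%
intervals ($\hat\beta \pm 1.96\,\mathrm{se}$) and two-sided normal p-values,
matching how such results are reported in practice.

* `two_stage_continuous()`: two-stage least squares. Stage 1 regresses $X$
  on $G$ (+ covariates), stage 2 regresses $Y$ on $\hat X$ (+ covariates);
  the standard error uses residuals formed with the *observed* exposure, the
  standard 2SLS variance. With a single instrument and no covariates the
  estimate equals the Wald ratio $\mathrm{cov}(G,Y)/\mathrm{cov}(G,X)$
  exactly (asserted to $10^{-10}$ in the tests).
* `two_stage_binary()`: two-stage residual inclusion (TSRI). Stage 1 as
  above; stage 2 is a logistic regression of the outcome on $X$, the stage-1
  residual, and covariates; the estimate is the log-odds coefficient on $X$.
  The default SE is the second-stage model-based one — the convention behind
  most reported TSRI odds ratios — with a nonparametric bootstrap available
  (`se_method = "bootstrap"`). One-class outcomes error; fits whose
  probabilities collapse to 0/1 are reported as separation errors rather
  than returned with meaningless SEs.
* `ratio_estimate()`: the Wald ratio with first-order delta-method SE; used
  as the algebraic cross-check of the two-stage estimator.
* `iv_exposure_assoc()`: the first-stage slope itself, which per stratum is
  the raw material of the constant-genetic-effect check.

## Stratified analysis and inference across strata

`stratified_mr()` runs the estimator and the first-stage association in each
stratum (failures inside a stratum are annotated, not fatal) plus the
whole-cohort estimate. `pool_replicates()` combines doubly-ranked replicates
with Rubin's rules: pooled estimate $= \bar\beta$, within-variance $W$ =
mean squared SE, between-variance $B$ = sample variance of the replicate
estimates, total $T = W + (1 + 1/m)B \geq W$. Degrees of freedom use the
normal approximation (large $m$, large $n$) rather than small-sample
corrections — stratum sample sizes in the intended applications are in the
thousands. With $m = 1$, $B$ is undefined and treated as 0. The residual
method is deterministic and never replicated.

Across strata:

* `cochran_q()` — the inverse-variance-weighted heterogeneity statistic with
  $w_j = 1/\mathrm{se}_j^2$, referred to $\chi^2_{J-1}$.
* `trend_test()` — fixed-effect (known-variance) weighted least squares of
  the stratum estimates on the stratum *mean exposure*, not the stratum
  index: dose-response claims are interpreted on the exposure scale, and the
  slope then has units of effect per exposure unit.
* `constant_genetic_effect_check()` — Cochran's Q applied to the per-stratum
  first-stage slopes. Under the null this is calibrated for the residual
  method (empirically ~0.04 at $\alpha = 0.05$) but *conservative* for the
  doubly-ranked method: ranking on the exposure within instrument pre-strata
  constrains each final stratum's exposure-instrument relation, so the
  observed spread of first-stage slopes is smaller than their nominal SEs
  suggest. A significant result therefore remains evidence against the
  constant genetic effect assumption for either method, but the doubly-ranked
  version has no exact nominal size.
* A consistency guard: when every stratum estimate lies on one side of zero
  and the whole-cohort CI lies entirely on the other, `stratified_mr()`
  warns and flags the set — if all estimates were causal this would be
  logically impossible, so at least some of them are biased.

## Bias diagnostics

`nco_analysis()` is the primary audit. A negative-control outcome (NCO) is
one the exposure cannot cause — an age-like continuous variable and a
sex-like binary variable are the canonical choices — so every estimate on it
should be null and any systematic signal measures bias. For each NCO it runs
conventional MR, both stratification methods (doubly-ranked pooled over
replicates), Q, trend and the first-stage check, and summarizes flags at a
configurable threshold ($\alpha = 0.05$ by default; the choice of threshold
is a reporting convention, not part of the inference). Flags are stored
alongside the estimates they derive from and are exactly recomputable from
them.

`stability_analysis()` addresses a different failure mode: stratum-specific
claims presume stratum membership is a stable attribute, but fluctuating
exposures (blood biomarkers such as triglycerides commonly show test-retest
correlations near 0.6) reshuffle members between measurement occasions. The
function stratifies the same individuals on a baseline and a repeat
measurement with the same instrument and method (one replicate, shared
tie-break seed per occasion) and reports the $J \times J$ transition matrix,
row-normalized, with the diagonal as per-stratum retention. Exchanging the
occasions transposes the counts; retention is monotone in the test-retest
correlation and reaches 1 at $r = 1$.

## The synthetic cohort generator

`simulate_cohort()` draws, per individual: dosages $d_{ik} \sim
\mathrm{Bin}(2, f_k)$ for 50 variants ($f_k$ spread over $0.1$–$0.5$);
an instrument $G_i = \sum_k w_k d_{ik}$ with deterministic, irregular
per-allele weights (mean 0.1, range 0.06–0.14 — an equal-weight score would
collapse onto a coarse grid of allele counts and make stratum membership
hostage to tie-breaking, which real GWAS-weighted scores are not); a
standard-normal confounder $U$; an exposure $X = \mu + \alpha(\cdot) G +
\gamma U + \varepsilon$ with $\gamma = 0.5$ and $\sigma_\varepsilon = 1$
(instrument $R^2 \approx 10\%$, a strong but realistic polygenic score); an
age-like NCO $\sim N(57, 8^2)$ and a sex-like NCO $\sim
\mathrm{Bern}(0.46)$, both independent of $G, U, X$ by construction; a
continuous outcome linear in $X$ and a binary outcome logistic in $X$, both
sharing the confounder; and a selection indicator from a logistic model in
exposure, centred age, sex and exposure$\times$sex. All randomness flows
from one seed; identical configurations give byte-identical cohorts.

Under `genetic_effect_mode = "exposure_varying"` the genetic effect is a
monotone linear (hence piecewise-linear) function of the percentile of the
non-genetic exposure component, interpolating $2/3 \to 4/3$ so the effect at
the top of the distribution is twice that at the bottom — the simplest
testable violation of the constant genetic effect assumption.

`simulate_repeat_exposure()` adds a repeat measurement by a Gaussian copula:
normal scores of the exposure are mixed with fresh noise at correlation $r$
and mapped back through the empirical quantile function, so the marginal
distribution (and variance) is preserved exactly and the correlation target
is hit ($r = 0.60$, the typical triglyceride value, is the calibration case
verified in the tests).

### The selection scenario

Selection acts once, at cohort entry — study recruitment — never per
stratum: any stratum-level distortion must *emerge* from the methods. The
frozen `selection_nco` scenario makes participation increase with the
exposure for both sexes but more steeply for men (log-odds $-4.2 + 1.5X +
0.6\,\mathrm{sex} - 1.0\,X\cdot\mathrm{sex}$, about 35% selected). Because
the two sex-specific participation curves are sigmoids with different
slopes, the post-selection probability of being female is *non-monotone* in
the exposure: collider distortions of opposite direction in different parts
of the exposure range. Locally — within strata — the induced
instrument-NCO associations are substantial, while in the whole cohort they
nearly cancel: the intercept was chosen so the asymptotic whole-cohort TSRI
estimate on the sex NCO is approximately zero. This reproduces, in silico,
the characteristic bias signature: conventional MR on the negative control
near-null and calibrated (~5–8% rejection), stratum-specific estimates
strongly heterogeneous (Q rejects in roughly 70–80% of cohorts per method
at the default sizes). A purely additive or purely monotone selection model
produces the opposite signature — a uniformly biased overall estimate with
homogeneous strata — and is therefore not the interesting case.

What the generator does *not* emulate: linkage disequilibrium and weak or
invalid (pleiotropic) instruments; population stratification; measured
covariate structure such as recruitment centres or genetic principal
components (covariate adjustment is supported, but the simulated covariates
are only age and sex); time-to-event outcomes; non-random missingness.
Passing tests therefore show that the methods and diagnostics behave as
designed under a clean polygenic instrument with selection of the stated
form — not that any particular empirical stratified-MR result is or is not
biased.

## Problem sizes and numerical conventions

The test suite and the acceptance script run: calibration of Q, CI coverage
and the Wald identity on 500 cohorts of $n = 10{,}000$ with $J = 5$; the
selection scenario on 200 cohorts of $n = 25{,}000$ before selection with
$J = 10$; oracle-equivalence of both stratifiers on 120 random instances of
$n \le 200$; null-calibration sweeps at $n$ between 1,500 and 5,000; and
stability analyses at $n = 5{,}000$–$13{,}500$ with $r \in \{0, 0.3, 0.6,
0.9, 1\}$. These sizes were chosen so that Monte-Carlo error is small
relative to the tolerance of each claim (binomial SE $\lesssim 0.01$ on
calibrated rates) while a full run stays in the minutes range on one core.

Other conventions: zero-variance instruments and singular designs are
errors that name the offending column; the weak-instrument guard refuses a
Wald ratio with a zero first-stage; quantile cuts use the
$\lceil iJ/n\rceil$ rule; report rendering prints at fixed precision
("%.8g") so identical objects render byte-identically and re-parse to the
printed precision; delimited output is TSV with `NA` for missing values and
full-precision numerics.

## Known limitations

* The binary-outcome SE is the second-stage model-based one; it ignores
  first-stage uncertainty, which is negligible with strong instruments and
  large strata but optimistic otherwise (use the bootstrap flag in doubt).
* The doubly-ranked first-stage Q is conservative (see above); its p-values
  are interpretable as evidence but not as exact sizes.
* Rubin's-rules intervals use normal degrees of freedom; with very few
  replicates of a heavily tied instrument they can undercover.
* The trend test conditions on stratum mean exposures as fixed; their
  sampling error is second-order at the intended stratum sizes but not zero.
* Negative-control nullity is an assumption about the *real* NCO; the
  generator enforces it by construction, applications must argue it.
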