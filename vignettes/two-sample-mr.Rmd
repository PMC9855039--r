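---
title: "Two-sample Mendelian randomization with mrpipe: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
library(dplyr)
```

## The problem mrpipe addresses

Observational associations between a modifiable exposure (for example a
circulating micronutrient concentration) and a disease outcome are easily
distorted by confounding and reverse causation. Mendelian randomization (MR)
sidesteps both by using genetic variants as instrumental variables: because
alleles are assigned at conception, a variant that raises the exposure acts
like a lifelong, randomized nudge. In the *two-sample* design the two
ingredients come from separate GWAS cohorts — per-SNP effects on the exposure
(`beta_exp`, `se_exp`) from one study, per-SNP effects on a binary disorder
(`beta_out`, `se_out`, log-odds) from another — so the whole analysis runs on
public summary statistics.

A valid instrument must satisfy three assumptions: it is associated with the
exposure (*relevance*), it shares no confounder with the outcome
(*independence*), and it affects the outcome only through the exposure
(*exclusion restriction*). mrpipe implements the full workflow around these
assumptions: instrument selection and harmonization, five causal estimators,
pleiotropy and influence diagnostics, cross-database meta-analysis, power
calculation, and a synthetic-data generator that makes every stage testable
against known ground truth.

## Instrument construction

Candidate instruments pass through an auditable chain; every input SNP ends
up in the audit trail exactly once as kept, proxied, or dropped with a
reason:

1. **Significance**: keep variants with exposure p strictly below
   `p_instrument` (default $5\times10^{-8}$; relaxed thresholds such as
   $5\times10^{-6}$ are common for small exposure GWASs and are plain
   arguments here).
2. **LD clumping** (`ld_clump()`): greedy selection — repeatedly keep the
   smallest-p remaining variant and discard everything with $r^2 >$
   `clump_r2` (default 0.001) within `window_kb` (default 10,000 kb).
   Ties at equal p break lexicographically by SNP id so output is
   deterministic. The LD source is a local matrix or long table; pairs
   absent from it count as $r^2 = 0$, and without positions the distance
   window is ignored (the r² rule is authoritative).
3. **Confounder screen** (`screen_confounders()`): drop variants with a
   recorded confounder association below `conf_p` (default genome-wide,
   configurable — the screening literature rarely states a number). This is
   the algorithmic stand-in for a phenome-scan lookup plus literature
   review; judgment calls (e.g. lipid-related pleiotropy known only from
   publications) enter as rows of the local confounder table.
4. **Instrument strength** (`filter_weak()`): per-SNP
   $F = \beta_{exp}^2 / se_{exp}^2$, keeping $F$ strictly greater than 10
   by default. The strictly-greater reading matches the usual wording of
   the rule; at realistic F (≫ 10) the boundary never matters.
5. **Proxies and harmonization** (`harmonize_data()`): instruments missing
   from the outcome GWAS may be replaced by the highest-$r^2$ proxy with
   $r^2 \ge 0.8$ present there (ties again lexicographic); the proxy's
   alleles are translated through the supplied allele map. Outcome effects
   are then oriented onto the exposure's effect allele: swapped alleles
   negate `beta_out` and complement the frequency, strand flips are
   resolved through base complements, and palindromic A/T and C/G variants
   are either inferred from allele frequencies (default) or dropped.
   Frequency inference compares $|eaf_{exp} - eaf_{out}|$ with
   $|eaf_{exp} - (1 - eaf_{out})|$; variants whose frequency falls in the
   ambiguity window $[0.42, 0.58]$ are dropped, because near 0.5 the two
   orientations are indistinguishable.

## Estimators

All estimators consume a harmonized table and return an `mr_estimate` with
`tidy()`/`glance()` methods; effects are log-odds per exposure unit with an
odds-ratio view.

**Wald ratio** (1 SNP): $\hat\beta_j = \beta_{Yj}/\beta_{Xj}$ with
first-order SE $\sigma_{Yj}/|\beta_{Xj}|$.

**IVW** (`mr_ivw()`): inverse-variance pooling of the Wald ratios, which is
identical to weighted regression of outcome on exposure effects through the
origin with weights $\sigma_{Yj}^{-2}$. Heterogeneity is Cochran's
$Q = \sum_j w_j(\hat\beta_j - \hat\theta)^2$; the random-effect variant
inflates the fixed SE by $\max(1, \sqrt{Q/(J-1)})$ — multiplicative rather
than additive, so it can never report *more* precision than the fixed model.
In `auto` mode the random model is used exactly when the Q p-value falls
below `q_alpha` (0.05 by default; the literature's "significant
heterogeneity" without a number).

**MR-Egger** (`mr_egger()`): the same regression with an intercept, after
orienting all exposure effects positive. The intercept estimates average
directional pleiotropy; the slope remains consistent under InSIDE
(pleiotropy independent of instrument strength). Analytic SEs carry a
multiplicative residual dispersion floored at 1; inference uses a t
reference with $J-2$ df rather than a normal one — at $J \approx 10$
instruments a normal reference would reject a true null intercept about 8%
of the time, and the t correction restores the nominal 5%. Bootstrapped
SEs (the workflow's choice for the slope when the pleiotropy gate fires)
are parametric: summary statistics are redrawn from
$N(\beta, se^2)$, the fit repeated `n_boot` = 1000 times, and the SD of the
slopes reported; the seed is mandatory.

**Weighted median** (`mr_weighted_median()`): the ratio at cumulative
weight 0.5 under the midpoint-interpolation convention
($p_j = \sum_{k\le j} w'_k - w'_j/2$, clamping outside $[p_1, p_J]$),
consistent while valid instruments hold over half the weight. SE by the
same parametric bootstrap.

**Likelihood-based MR** (`mr_max_likelihood()`): maximum likelihood under
$\beta_{Xj} \sim N(\xi_j, \sigma_{Xj}^2)$,
$\beta_{Yj} \sim N(\theta\xi_j, \sigma_{Yj}^2)$. The latent $\xi_j$ profile
out in closed form, $\theta$ is maximised by 1-D quasi-Newton iteration
started at the fixed-effect IVW estimate, and the SE comes from the
numerical curvature of the profile log-likelihood (central differences,
step $10^{-4}(1+|\theta|)$). A dense grid search over $\theta$ reproduces
the optimum to $10^{-6}$ in the tests.

## Diagnostics

**Egger intercept test** (`egger_intercept_test()`) gates the choice of the
primary method. Balanced pleiotropy adds the *same* variance
$\sigma_\alpha^2$ to every instrument's outcome effect, which a
multiplicative dispersion cannot represent when the $\sigma_{Yj}$ differ;
the test therefore models excess residual variation as an additive
component $\tau^2$, solved so the weighted residual sum of squares equals
its degrees of freedom (a Paule–Mandel-style random-effects Egger fit), and
refers the intercept t-statistic to $t_{J-2}$. The package's calibration
tests check that this keeps the test's size inside $[0.03, 0.07]$ under
balanced pleiotropy. The Egger *estimator* keeps its classical SEs; only
the gate test uses the additive form.

**MR-PRESSO** (`mr_presso()`): observed residual sum of squares around
leave-one-out IVW predictions, compared with `n_sim` = 1000 simulated null
datasets (summary statistics redrawn under the no-pleiotropy model with
leave-one-out slopes, and the leave-one-out slopes recomputed per
replicate). Empirical p-values use the add-one correction
$(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$ and can never be exactly zero.
Per-SNP outlier p-values come from each instrument's simulated residual
distribution, Bonferroni-multiplied across $J$, flagged below 0.05. When
outliers are found the causal effect is re-estimated without them and the
percent distortion reported, with an empirical distortion p from 1000
random same-size subsets; the distortion test is reported but never gates
the pipeline, since re-analysis after outlier removal happens regardless.
The test requires more than 3 instruments; below that it reports an
explicit "not evaluable" status, as do the weighted median (> 2) and
likelihood method (> 1) — absent rows are never used to encode a skipped
analysis.

**Leave-one-out** re-estimates with each SNP omitted; scatter, forest and
funnel data tables (and their `plot_mr_*()` ggplot views) expose influence
structure. IVW lines pass through the origin by construction; the Egger
line carries its intercept.

## Decision tree, meta-analysis, evidence

Per (exposure, outcome, database) dataset `analyze_triple()` applies:
one instrument → Wald ratio; three or more instruments with a significant
intercept test → MR-Egger with bootstrap SEs; otherwise IVW with
fixed/random chosen by the Q test. The pleiotropy gate is evaluated before
the heterogeneity gate, matching the order in which the two checks are
described in the standard workflow. Per-database primary estimates are then
pooled across sources (`meta_pool()`): fixed-effect inverse-variance
pooling unless the between-database Q is significant at 0.05, in which case
DerSimonian–Laird random effects
($\tau^2 = \max(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w))$) is used, with
$I^2 = \max(0, (Q - df)/Q)$ reported. A database whose instrument set comes
back empty (e.g. a phenotype absent from one biobank) degrades to a warning
and a meta-analysis over the remaining sources.

Pooled p-values are classified against a Bonferroni threshold
`alpha_family / m_tests`, with `m_tests` defaulting to the number of
exposures times the number of outcomes in the study grid (e.g. 8 × 6 = 48,
for which 0.05/48 displays as 0.001 at one significant figure);
p-values between that threshold and 0.05 count as suggestive. The three
evidence bands partition (0, 1].

**Power** (`mr_power_binary()`): the standard two-sided normal
approximation for a binary outcome — noncentrality
$|\ln OR|\sqrt{n\, r^2_{xz}\, K(1-K)}$ with both rejection tails summed, so
power equals $\alpha$ exactly at $OR = 1$ and is symmetric in
$OR \leftrightarrow 1/OR$.

## The synthetic-data generator

`sim_scenario()` fixes the ground truth: $J$ instruments with
Hardy–Weinberg genotypes $G_{ij} \sim Bin(2, maf_j)$, exposure
$X = \sum_j \gamma_j G_j + \varepsilon$ with $\gamma_j$ chosen so the
instruments jointly explain `r2_xz` of unit exposure variance (an equal
split per SNP by default), and outcome
$Y \sim Bernoulli(\text{expit}(\alpha_0 + \theta X + \sum_j \alpha_j G_j))$
with $\alpha_0$ solved numerically on the realized linear predictor to hit
the target prevalence. The direct effects $\alpha_j$ follow one of four
architectures — none, balanced $N(0, sd^2)$, directional
$N(mean, sd^2)$ on a fraction of instruments, or a single outlier —
and can optionally be coupled to $\gamma_j$ to violate InSIDE. The two
cohorts are always drawn independently (no sample overlap), and marginal
per-SNP GWAS fits (closed-form OLS for the exposure; maximum-likelihood
logistic scoring for the binary outcome, verified against `stats::glm` in
the tests) produce summary statistics in the package's own dialect, so the
generator exercises the same files the reader of real GWAS downloads would
produce.

The reference presets share one parameterization, chosen once to resemble
the ascorbate-style setting the workflow targets: $J = 10$ instruments,
50,000/50,000 cohorts, `r2_xz` = 0.02 (instrument strength $F \approx 100$
per SNP), prevalence 0.1, $\theta = 0.2$. Pleiotropy magnitudes were set
relative to that scale: balanced sd 0.05 (roughly 1.5–2.5× a per-SNP
outcome SE, enough to dominate Q), directional mean 0.02 with sd 0.01
(a subtle directional shift of the size the intercept test should detect),
and an outlier of 10 outcome-SEs.

`simulate_sumstats()` is the summary-level (asymptotic) counterpart: it
draws $\beta_{Xj} \sim N(\gamma_j, se_{Xj})$,
$\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, se_{Yj})$ with the SEs
implied by the scenario. It reproduces exactly the statistical structure
the estimators assume, at a fraction of the cost, and is used for the
large calibration studies (estimator robustness orderings, PRESSO error
rates, intercept-test size); the cohort simulator is used where
finite-sample features matter (estimated SEs, logistic noncollapsibility,
realized prevalence, type-I error and parameter recovery of the full
pipeline). What passing these simulations does *not* show: robustness to
LD misspecification, assay heterogeneity between exposure cohorts,
population stratification, or sample overlap — none of which the
generator models (an optional block-LD mode exists solely to exercise
clumping).

## Numerical choices and degenerate inputs

* Validation is total: malformed summary-statistic rows fail with file
  line numbers, never silently drop; duplicate SNP ids, indels and
  multi-allelic rows are rejected.
* Strict inequalities for the significance and F thresholds.
* All empirical p-values carry the add-one correction; reported p-values
  are clamped away from exact 0 only by floating-point underflow limits.
* Zero exposure effects make the Wald ratio undefined and raise an error
  naming the SNP; a design with no variation in exposure effects makes the
  Egger fit singular and errors.
* Every stochastic step (bootstraps, PRESSO, distortion subsets,
  simulations) takes a seed; `run_study()` derives a distinct child seed
  per (triple, step) from the master seed, records it in the manifest, and
  two runs with the same config are byte-identical.
* Simulation study sizes in the test-suite: oracle equivalences use 200+
  seeded datasets; calibration checks use 500 replicates at the preset
  cohort sizes and 200-replicate robustness comparisons at summary level —
  sizes chosen so Monte-Carlo noise is small against the tolerance being
  asserted.

## A worked example

```{r example}
scenario <- sim_preset("valid", theta = 0.2, seed = 1)
ds <- simulate_sumstats(scenario)
mr_ivw(ds)
glance(mr_egger(ds))
egger_intercept_test(ds)
tidy(mr_presso(ds, n_sim = 500, seed = 2))
meta_pool(list(mr_ivw(ds),
               mr_ivw(simulate_sumstats(scenario, seed = 5))))
mr_power_binary(n = 50000, k_case = 0.1, r2_xz = 0.017, or_true = 1.2)
bonferroni_threshold(0.05, 48)
```

## Known limitations

* LD is supplied, never computed: clumping correctness depends on the
  user's r² table; there is no genotype-panel backend.
* The confounder screen only automates what a local association table
  encodes; curation of which traits count as confounders stays with the
  analyst.
* First-order Wald-ratio SEs ignore exposure-side noise; with weak
  instruments (F near 10) coverage degrades, which the F filter mitigates
  but does not remove.
* Nonlinear exposure-outcome relationships and multivariable extensions
  are out of scope, as are mode-based and contamination-mixture
  estimators.
* The power formula is the standard normal approximation on a
  standardized-exposure scale; it inherits that approximation's optimism
  for very rare outcomes.
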