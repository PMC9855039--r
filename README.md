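# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics, for
epidemiologists asking whether a modifiable exposure (say, a circulating
antioxidant measured in one cohort) causally shifts the risk of a binary
disorder measured in another. Genetic variants serve as instrumental
variables: per-SNP exposure effects β<sub>Xj</sub> (SE σ<sub>Xj</sub>) from
one GWAS are combined with per-SNP outcome log-odds β<sub>Yj</sub> (SE
σ<sub>Yj</sub>) from a non-overlapping GWAS.

The package covers the complete workflow:

* **Instruments** — significance filtering (p < 5×10⁻⁸ by default), greedy
  LD clumping (r² = 0.001, 10,000 kb), confounder screening against a local
  association table, per-SNP strength F = β²<sub>X</sub>/σ²<sub>X</sub>
  with the F > 10 rule, proxy substitution (r² ≥ 0.8), and allele
  harmonization with frequency-based resolution of palindromic SNPs. Every
  input SNP is audited as kept, proxied, or dropped-with-reason.
* **Estimators** — per-SNP Wald ratios β̂<sub>j</sub> = β<sub>Yj</sub>/β<sub>Xj</sub>
  pooled by inverse variance (fixed, or multiplicative random effects when
  Cochran's Q is significant: SE × max(1, √(Q/(J−1)))); MR-Egger regression
  with intercept (average directional pleiotropy) and bootstrapped slope
  SEs; the weighted median; and profile-likelihood MR. Results are tibbles
  via broom-style `tidy()`/`glance()`.
* **Diagnostics** — a calibrated Egger-intercept pleiotropy test, MR-PRESSO
  (global residual-sum-of-squares test, per-SNP outlier test, distortion
  test, all with seeded simulated nulls and add-one empirical p-values),
  leave-one-out, and scatter/forest/funnel tables with ggplot2 views.
* **Meta-analysis & power** — fixed-effect and DerSimonian–Laird pooling of
  per-database estimates with Q and I², the mRnd-style power formula for
  binary outcomes, and Bonferroni evidence classification
  (significant / suggestive / null).
* **Pipeline** — `run_study()` orchestrates the per-database decision tree
  (Wald for 1 SNP; MR-Egger when the intercept test fires; otherwise
  fixed/random IVW by the Q test), the sensitivity suite with explicit
  "not evaluable" gates, outlier-removal re-analysis, cross-database
  meta-analysis, and a deterministic, seed-stamped output bundle.
* **Synthetic data** — `sim_scenario()` / `simulate_cohorts()` /
  `simulate_sumstats()` generate two independent GWAS cohorts (continuous
  exposure, logistic binary outcome) with known causal effect θ, chosen
  instrument strength, and configurable pleiotropy architectures, so the
  whole pipeline is testable without any data download.

## A worked example

```r
library(mrpipe)

scenario <- sim_preset("valid", theta = 0.2, seed = 1)  # truth: log-OR 0.2
ds <- simulate_sumstats(scenario)                        # 10 harmonized SNPs

mr_ivw(ds)
#> <mr_estimate> ivw_fe (10 SNPs)
#>   beta = 0.2686 (SE 0.1038), 95% CI [0.0653, 0.4720], p = 0.00962
#>   OR = 1.308 [1.067, 1.603]
#>   Cochran's Q = 10.796 (df 9), p = 0.29

egger_intercept_test(ds)
#> # A tibble: 1 × 7
#>    nsnp intercept     se  pval     tau2 pleiotropy evaluable
#>   <int>     <dbl>  <dbl> <dbl>    <dbl> <lgl>      <lgl>
#> 1    10    0.0331 0.0643 0.620 0.000223 FALSE      TRUE

mr_power_binary(n = 50000, k_case = 0.1, r2_xz = 0.017, or_true = 1.2)$power
#> [1] 0.3576324

bonferroni_threshold(0.05, 48)$display
#> [1] 0.001
```

The IVW estimate (log-OR 0.27, 95% CI 0.07–0.47) brackets the true
θ = 0.2 for this draw; Cochran's Q (p = 0.29) shows no heterogeneity and
the intercept test no directional pleiotropy (there is none in this
scenario), so the pipeline keeps fixed-effect IVW as the primary method.
An exposure explaining 1.7% of variance gives 36% power to detect OR 1.2
in a 50,000-sample GWAS with 10% cases; with 48 exposure-outcome tests
the Bonferroni threshold 0.05/48 displays as 0.001.

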