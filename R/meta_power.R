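# Cross-database meta-analysis, I-squared, MR power for binary outcomes,
# and the multiple-testing rule.

meta_input <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    assert_columns(estimates, c("beta", "se"), what = "estimates")
    label <- if ("label" %in% names(estimates)) {
      estimates$label
    } else if ("database_id" %in% names(estimates)) {
      estimates$database_id
    } else {
      paste0("study", seq_len(nrow(estimates)))
    }
    return(tibble(beta = estimates$beta, se = estimates$se, label = label))
  }
  tibble(beta = purrr::map_dbl(estimates, "beta"),
         se = purrr::map_dbl(estimates, "se"),
         label = paste0("study", seq_along(estimates)))
}

new_meta_estimate <- function(model, beta, se, k, q, q_df, tau2) {
  crit <- qnorm(0.975)
  q_pval <- if (q_df >= 1) pchisq(q, q_df, lower.tail = FALSE) else NA_real_
  structure(list(
    model = model, beta = beta, se = se,
    ci_low = beta - crit * se, ci_high = beta + crit * se,
    pval = two_sided_p(beta / se),
    or = exp(beta), or_ci_low = exp(beta - crit * se),
    or_ci_high = exp(beta + crit * se),
    k = k, q = q, q_df = q_df, q_pval = q_pval,
    i2 = if (q_df >= 1) i_squared(q, q_df) else NA_real_,
    tau2 = tau2
  ), class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("<mr_meta> %s-effect pooling of %d estimate(s)\n", x$model, x$k))
  cat(sprintf("  beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$beta, x$se, x$or, x$or_ci_low, x$or_ci_high, x$pval))
  if (x$k > 1) {
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
                x$q, x$q_df, x$q_pval, x$i2, x$tau2))
  }
  invisible(x)
}

#' Tidy a pooled meta-analysis estimate
#' @param x An `mr_meta` object.
#' @param ... Unused.
#' @return A one-row tibble in broom conventions.
#' @export
tidy.mr_meta <- function(x, ...) {
  tibble(model = x$model, term = "pooled_effect", estimate = x$beta,
         std.error = x$se, statistic = x$beta / x$se, p.value = x$pval,
         conf.low = x$ci_low, conf.high = x$ci_high, k = x$k)
}

#' Glance at a pooled meta-analysis estimate
#' @param x An `mr_meta` object.
#' @param ... Unused.
#' @return A one-row tibble with pooled effect and heterogeneity statistics.
#' @export
glance.mr_meta <- function(x, ...) {
  tibble(model = x$model, k = x$k, beta = x$beta, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval, or = x$or,
         or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
         q = x$q, q_pval = x$q_pval, i2 = x$i2, tau2 = x$tau2)
}

#' Fixed-effect meta-analysis
#'
#' Inverse-variance pooling of per-database estimates:
#' `beta = sum(b_i/s_i^2) / sum(1/s_i^2)`, `se = (sum s_i^-2)^-1/2`, with
#' between-study Q and I2 attached. A single estimate is returned
#' unchanged (pooling identity).
#'
#' @param estimates A list of `mr_estimate` objects or a data frame with
#'   columns `beta` and `se`.
#' @return An `mr_meta` object with `model = "fixed"`.
#' @export
meta_fixed <- function(estimates) {
  d <- meta_input(estimates)
  k <- nrow(d)
  if (k < 1) abort("meta_fixed needs at least one estimate",
                   class = "mrpipe_config_error")
  w <- 1 / d$se^2
  beta <- sum(w * d$beta) / sum(w)
  q <- sum(w * (d$beta - beta)^2)
  new_meta_estimate("fixed", beta, 1 / sqrt(sum(w)), k, q, k - 1L, tau2 = 0)
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Estimates the between-study variance as
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` with fixed
#' weights `w = se^-2`, then pools with weights `1/(se^2 + tau2)`. Never
#' reports a smaller SE than the fixed-effect pooling of the same inputs.
#'
#' @inheritParams meta_fixed
#' @return An `mr_meta` object with `model = "random"`.
#' @export
meta_random <- function(estimates) {
  d <- meta_input(estimates)
  k <- nrow(d)
  if (k < 2) abort("meta_random needs at least two estimates",
                   class = "mrpipe_insufficient_instruments")
  w <- 1 / d$se^2
  beta_f <- sum(w * d$beta) / sum(w)
  q <- sum(w * (d$beta - beta_f)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (d$se^2 + tau2)
  beta <- sum(ws * d$beta) / sum(ws)
  new_meta_estimate("random", beta, 1 / sqrt(sum(ws)), k, q, k - 1L, tau2)
}

#' Pool estimates with heterogeneity-driven model choice
#'
#' Uses fixed-effect pooling unless the between-database Cochran's Q test is
#' significant at `q_alpha`, in which case the DerSimonian-Laird
#' random-effects model is used.
#'
#' @inheritParams meta_fixed
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @param q_alpha Heterogeneity significance level (default 0.05).
#' @return An `mr_meta` object.
#' @export
meta_pool <- function(estimates, model = c("auto", "fixed", "random"),
                      q_alpha = 0.05) {
  model <- match.arg(model)
  if (model == "fixed") return(meta_fixed(estimates))
  if (model == "random") return(meta_random(estimates))
  fixed <- meta_fixed(estimates)
  if (fixed$k >= 2 && !is.na(fixed$q_pval) && fixed$q_pval < q_alpha) {
    meta_random(estimates)
  } else {
    fixed
  }
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - df)/Q) * 100`; zero when `Q = 0`.
#'
#' @param q Cochran's Q statistic (non-negative).
#' @param df Degrees of freedom (number of estimates minus 1).
#' @return Percentage in \[0, 100\].
#' @export
i_squared <- function(q, df) {
  stopifnot(all(q >= 0), all(df >= 1))
  ifelse(q > 0, pmax(0, (q - df) / q) * 100, 0)
}

#' Statistical power of an MR analysis with a binary outcome
#'
#' Two-sided normal approximation for the Wald test of a log-odds causal
#' effect estimated from a case-control outcome GWAS of size `n` with case
#' fraction `k_case`, instruments explaining a fraction `r2_xz` of exposure
#' variance, against a hypothesized odds ratio `or_true` per exposure SD:
#' the noncentrality is `|ln OR| * sqrt(n * r2_xz * k_case * (1 - k_case))`
#' and power sums both rejection tails. At `or_true = 1` the power equals
#' `alpha` exactly; power is monotone in `n`, `r2_xz` and `|ln OR|` and
#' symmetric under OR -> 1/OR.
#'
#' @param n Outcome-GWAS sample size (vectorised).
#' @param k_case Case fraction in (0, 1).
#' @param r2_xz Variance in exposure explained by the instruments, in
#'   \[0, 1\].
#' @param or_true Hypothesized causal odds ratio (> 0).
#' @param alpha Type-1 error (default 0.05).
#' @return A tibble `n, k_case, r2_xz, or_true, alpha, power`.
#' @export
mr_power_binary <- function(n, k_case, r2_xz, or_true, alpha = 0.05) {
  d <- tibble(n = n, k_case = k_case, r2_xz = r2_xz, or_true = or_true,
              alpha = alpha)
  ok <- d$n > 0 & d$k_case > 0 & d$k_case < 1 & d$r2_xz >= 0 & d$r2_xz <= 1 &
    d$or_true > 0 & d$alpha > 0 & d$alpha < 1
  if (!all(ok)) {
    abort("mr_power_binary: inputs outside their valid domains",
          class = "mrpipe_validation_error")
  }
  b <- log(d$or_true)
  lambda <- abs(b) * sqrt(d$n * d$r2_xz * d$k_case * (1 - d$k_case))
  z <- qnorm(1 - d$alpha / 2)
  d$power <- pnorm(lambda - z) + pnorm(-lambda - z)
  d
}

#' Power grid over a range of odds ratios
#'
#' Convenience wrapper evaluating [mr_power_binary()] over a grid of
#' hypothesized ORs, e.g. for a minimum-detectable-effect table.
#'
#' @inheritParams mr_power_binary
#' @param or Vector of odds ratios to evaluate.
#' @return A tibble with one row per OR.
#' @export
mr_power_grid <- function(n, k_case, r2_xz, or = seq(0.7, 1.5, by = 0.05),
                          alpha = 0.05) {
  mr_power_binary(n = n, k_case = k_case, r2_xz = r2_xz, or_true = or,
                  alpha = alpha)
}

#' Bonferroni-corrected significance threshold
#'
#' Per-test threshold `alpha_family / m`, together with the value rounded
#' to one significant figure for display (e.g. 0.05 over 48 tests displays
#' as 0.001).
#'
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param m Number of tests (>= 1).
#' @return A tibble `alpha_family, m, threshold, display`.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, m) {
  stopifnot(m >= 1, alpha_family > 0, alpha_family < 1)
  thr <- alpha_family / m
  tibble(alpha_family = alpha_family, m = as.integer(m), threshold = thr,
         display = signif(thr, 1))
}
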