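# Summary-data causal estimators. All take a harmonized data frame with
# columns beta_exp, se_exp, beta_out, se_out (and snp), and return an
# `mr_estimate` object with broom-style tidy()/glance() methods.

check_mr_data <- function(data, min_snp = 1, caller = "estimator") {
  assert_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"),
                 what = caller)
  if (nrow(data) < min_snp) {
    abort(glue::glue("{caller} requires at least {min_snp} instrument(s), got {nrow(data)}"),
          class = "mrpipe_insufficient_instruments")
  }
  if (!"snp" %in% names(data)) data$snp <- paste0("snp", seq_len(nrow(data)))
  data
}

new_mr_estimate <- function(method, beta, se, nsnp, snps = NULL,
                            dist = "norm", df = NULL, extras = list()) {
  crit <- if (dist == "t") qt(0.975, df) else qnorm(0.975)
  est <- list(
    method = method, beta = beta, se = se,
    ci_low = beta - crit * se, ci_high = beta + crit * se,
    pval = two_sided_p(beta / se, df = df, dist = dist),
    or = exp(beta), or_ci_low = exp(beta - crit * se),
    or_ci_high = exp(beta + crit * se),
    nsnp = nsnp, snps = snps, dist = dist, df = df
  )
  est <- modifyList(est, extras)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNP%s)\n", x$method, x$nsnp,
              if (x$nsnp == 1) "" else "s"))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", x$or, x$or_ci_low, x$or_ci_high))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n", x$q, x$q_df, x$q_pval))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' Tidy an MR estimate
#'
#' One row per estimated term (the causal effect; for MR-Egger also the
#' intercept), in broom conventions.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `method, term, estimate, std.error,
#'   statistic, p.value, conf.low, conf.high, nsnp`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(method = x$method, term = "causal_effect",
                estimate = x$beta, std.error = x$se,
                statistic = x$beta / x$se, p.value = x$pval,
                conf.low = x$ci_low, conf.high = x$ci_high, nsnp = x$nsnp)
  if (!is.null(x$egger_intercept)) {
    out <- dplyr::bind_rows(out, tibble(
      method = x$method, term = "intercept",
      estimate = x$egger_intercept, std.error = x$egger_intercept_se,
      statistic = x$egger_intercept / x$egger_intercept_se,
      p.value = x$egger_intercept_p,
      conf.low = NA_real_, conf.high = NA_real_, nsnp = x$nsnp))
  }
  out
}

#' Glance at an MR estimate
#'
#' One-row summary with the estimate on both log-odds and odds-ratio scales
#' plus heterogeneity/pleiotropy annotations where available.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
         or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
         q = x$q %||% NA_real_, q_pval = x$q_pval %||% NA_real_,
         i2 = x$i2 %||% NA_real_,
         egger_intercept = x$egger_intercept %||% NA_real_,
         egger_intercept_p = x$egger_intercept_p %||% NA_real_)
}

#' Per-SNP Wald ratio table
#'
#' The building block of the ratio-based estimators: per-SNP causal estimate
#' `beta_ratio = beta_out / beta_exp`, first-order standard error
#' `se_ratio = se_out / |beta_exp|`, and inverse-variance weight
#' `weight = se_ratio^-2`.
#'
#' @param data Harmonized instrument table.
#' @return Tibble `snp, beta_ratio, se_ratio, weight`.
#' @export
wald_ratios <- function(data) {
  data <- check_mr_data(data, 1, "wald_ratios")
  if (any(data$beta_exp == 0)) {
    abort(glue::glue(
      "undefined Wald ratio: zero exposure effect for {paste(data$snp[data$beta_exp == 0], collapse = ', ')}"
    ), class = "mrpipe_estimation_error")
  }
  tibble(snp = data$snp,
         beta_ratio = data$beta_out / data$beta_exp,
         se_ratio = data$se_out / abs(data$beta_exp),
         weight = (abs(data$beta_exp) / data$se_out)^2)
}

#' Wald ratio estimator (single instrument)
#'
#' @param data A one-row harmonized instrument table.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
mr_wald_ratio <- function(data) {
  data <- check_mr_data(data, 1, "mr_wald_ratio")
  if (nrow(data) != 1) {
    abort("mr_wald_ratio takes exactly one instrument; use mr_ivw() for several",
          class = "mrpipe_estimation_error")
  }
  r <- wald_ratios(data)
  new_mr_estimate("wald", r$beta_ratio, r$se_ratio, nsnp = 1, snps = data$snp)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over instruments of `weight * (beta_ratio - theta)^2`, with
#' df = J - 1, an upper-tail chi-square p-value, and
#' I2 = max(0, (Q - df)/Q) * 100 percent.
#'
#' @param ratios Per-SNP ratio table from [wald_ratios()].
#' @param theta The pooled estimate the ratios are compared against.
#' @return Tibble `q, df, pval, i2`.
#' @export
cochran_q <- function(ratios, theta) {
  assert_columns(ratios, c("beta_ratio", "weight"), what = "ratios")
  j <- nrow(ratios)
  if (j < 2) {
    abort("Cochran's Q requires at least 2 instruments",
          class = "mrpipe_insufficient_instruments")
  }
  q <- sum(ratios$weight * (ratios$beta_ratio - theta)^2)
  df <- j - 1L
  tibble(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE),
         i2 = i_squared(q, df))
}

#' Inverse-variance-weighted estimator
#'
#' Pools per-SNP Wald ratios with weights `se_ratio^-2` (equivalently, a
#' weighted regression of outcome on exposure effects through the origin
#' with weights `se_out^-2`). The fixed-effect SE is `(sum w)^-1/2`; the
#' random-effect (multiplicative) SE inflates it by
#' `max(1, sqrt(Q/(J-1)))`, so it never falls below the fixed-effect SE.
#' With `effect_model = "auto"` the random model is used exactly when the
#' Cochran's Q p-value falls below `q_alpha`. A single instrument delegates
#' to the Wald ratio.
#'
#' @param data Harmonized instrument table.
#' @param effect_model `"auto"` (default), `"fixed"`, or `"random"`.
#' @param q_alpha Significance level for the heterogeneity-driven model
#'   choice (default 0.05).
#' @return An `mr_estimate` with method `"ivw_fe"` or `"ivw_re"` (or
#'   `"wald"` for one instrument), carrying Q, its p-value, and I2.
#' @export
mr_ivw <- function(data, effect_model = c("auto", "fixed", "random"),
                   q_alpha = 0.05) {
  effect_model <- match.arg(effect_model)
  data <- check_mr_data(data, 1, "mr_ivw")
  if (nrow(data) == 1) return(mr_wald_ratio(data))
  r <- wald_ratios(data)
  w <- r$weight
  theta <- sum(w * r$beta_ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  het <- cochran_q(r, theta)
  model <- switch(effect_model,
                  fixed = "fixed",
                  random = "random",
                  auto = if (het$pval < q_alpha) "random" else "fixed")
  infl <- max(1, sqrt(het$q / het$df))
  se <- if (model == "random") se_fixed * infl else se_fixed
  new_mr_estimate(if (model == "random") "ivw_re" else "ivw_fe",
                  theta, se, nsnp = nrow(data), snps = data$snp,
                  extras = list(q = het$q, q_df = het$df, q_pval = het$pval,
                                i2 = het$i2, se_fixed = se_fixed))
}

# Weighted least squares of y on x (with intercept), weights w; returns
# coefficients, their SEs under multiplicative dispersion floored at 1,
# and the residual dispersion. Closed-form sums, kept independent of lm()
# so tests can use lm() as the oracle.
wls_fit <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  d <- sw * swxx - swx^2
  if (!is.finite(d) || d <= .Machine$double.eps * sw * swxx) {
    abort("singular regression design: no variation in exposure effects",
          class = "mrpipe_estimation_error")
  }
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swxx * swy - swx * swxy) / d
  res <- y - intercept - slope * x
  df <- length(x) - 2
  sigma2 <- sum(w * res^2) / df
  phi <- max(1, sigma2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(phi * sw / d),
       se_intercept = sqrt(phi * swxx / d),
       sigma2 = sigma2, df = df)
}

egger_orient <- function(data) {
  s <- sign(data$beta_exp)
  s[s == 0] <- 1
  data$beta_out <- data$beta_out * s
  data$beta_exp <- data$beta_exp * s
  data
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept (weights `se_out^-2`), after orienting all instruments to
#' positive exposure effects. The slope is a pleiotropy-robust causal
#' estimate under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. Inference uses a t reference distribution with
#' J - 2 df and residual dispersion floored at 1, which keeps the intercept
#' test calibrated at the small instrument counts typical of these analyses.
#'
#' With `se_method = "bootstrap"` the slope/intercept SEs are the standard
#' deviations over `n_boot` parametric resamples of the summary statistics
#' (each `beta*` drawn from a normal centred on the observed value with its
#' reported SE), seeded for reproducibility.
#'
#' @param data Harmonized instrument table (at least 3 instruments).
#' @param se_method `"analytic"` (default) or `"bootstrap"`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (required when `se_method =
#'   "bootstrap"`).
#' @return An `mr_estimate` with method `"egger"` and intercept fields.
#' @export
mr_egger <- function(data, se_method = c("analytic", "bootstrap"),
                     n_boot = 1000, seed = NULL) {
  se_method <- match.arg(se_method)
  data <- check_mr_data(data, 3, "mr_egger")
  data <- egger_orient(data)
  w <- 1 / data$se_out^2
  fit <- wls_fit(data$beta_exp, data$beta_out, w)
  se_slope <- fit$se_slope
  se_int <- fit$se_intercept
  if (se_method == "bootstrap") {
    if (is.null(seed)) {
      abort("a seed is required for bootstrapped standard errors",
            class = "mrpipe_config_error")
    }
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bx <- rnorm(nrow(data), data$beta_exp, data$se_exp)
        by <- rnorm(nrow(data), data$beta_out, data$se_out)
        f <- tryCatch(wls_fit(bx, by, w), error = function(e) NULL)
        if (is.null(f)) c(NA_real_, NA_real_) else c(f$slope, f$intercept)
      }, numeric(2))
    })
    se_slope <- sd(boots[1, ], na.rm = TRUE)
    se_int <- sd(boots[2, ], na.rm = TRUE)
  }
  new_mr_estimate("egger", fit$slope, se_slope, nsnp = nrow(data),
                  snps = data$snp, dist = "t", df = fit$df,
                  extras = list(
                    egger_intercept = fit$intercept,
                    egger_intercept_se = se_int,
                    egger_intercept_p = two_sided_p(fit$intercept / se_int,
                                                    df = fit$df, dist = "t"),
                    dispersion = max(1, fit$sigma2),
                    se_method = se_method))
}

# Weighted median of values b with weights w, by the cumulative-midpoint
# interpolation convention: after sorting, positions p_j = cumsum(w') - w'/2
# (w' standardized); the estimate interpolates b linearly at p = 0.5, and
# clamps to the extreme value when 0.5 falls outside [p_1, p_J].
weighted_median_value <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  wp <- w / sum(w)
  p <- cumsum(wp) - wp / 2
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  k <- max(which(p < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios (inverse-variance
#' weights), consistent when at least half the weight comes from valid
#' instruments. The SE is a seeded parametric bootstrap: summary statistics
#' are resampled from their sampling distributions, the weighted median
#' recomputed, and the SD over resamples reported.
#'
#' @param data Harmonized instrument table (at least 3 instruments).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed (required).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  data <- check_mr_data(data, 3, "mr_weighted_median")
  if (is.null(seed)) {
    abort("a seed is required for the weighted-median bootstrap SE",
          class = "mrpipe_config_error")
  }
  r <- wald_ratios(data)
  theta <- weighted_median_value(r$beta_ratio, r$weight)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(data), data$beta_exp, data$se_exp)
      by <- rnorm(nrow(data), data$beta_out, data$se_out)
      ok <- bx != 0
      weighted_median_value(by[ok] / bx[ok], (abs(bx[ok]) / data$se_out[ok])^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", theta, sd(boots), nsnp = nrow(data),
                  snps = data$snp)
}

# Profile log-likelihood of theta for the bivariate normal measurement
# model: beta_exp_j ~ N(xi_j, se_exp_j), beta_out_j ~ N(theta xi_j, se_out_j),
# with xi profiled out in closed form.
ml_profile_loglik <- function(theta, data) {
  vx <- data$se_exp^2; vy <- data$se_out^2
  xi <- (data$beta_exp / vx + theta * data$beta_out / vy) /
    (1 / vx + theta^2 / vy)
  -0.5 * sum((data$beta_exp - xi)^2 / vx + (data$beta_out - theta * xi)^2 / vy)
}

#' Likelihood-based MR estimator
#'
#' Maximum likelihood under a measurement model in which each observed
#' exposure effect is normal around a latent true effect and each outcome
#' effect is normal around `theta` times that latent effect. The latent
#' effects are profiled out in closed form and `theta` maximised by 1-D
#' optimisation; the SE comes from the numerical curvature of the profile
#' log-likelihood at the maximum.
#'
#' @param data Harmonized instrument table (at least 2 instruments).
#' @return An `mr_estimate` with method `"max_likelihood"`.
#' @export
mr_max_likelihood <- function(data) {
  data <- check_mr_data(data, 2, "mr_max_likelihood")
  start <- mr_ivw(data, effect_model = "fixed")$beta
  opt <- nlminb(start, function(th) -ml_profile_loglik(th, data))
  if (opt$convergence != 0 && abs(opt$objective) > 1e12) {
    abort(glue::glue("likelihood-based MR failed to converge (code {opt$convergence}: {opt$message})"),
          class = "mrpipe_estimation_error")
  }
  theta <- opt$par
  h <- 1e-4 * (1 + abs(theta))
  curv <- (ml_profile_loglik(theta + h, data) - 2 * ml_profile_loglik(theta, data) +
             ml_profile_loglik(theta - h, data)) / h^2
  if (!is.finite(curv) || curv >= 0) {
    abort("likelihood-based MR: profile log-likelihood is not concave at the optimum",
          class = "mrpipe_estimation_error")
  }
  new_mr_estimate("max_likelihood", theta, sqrt(-1 / curv),
                  nsnp = nrow(data), snps = data$snp)
}
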