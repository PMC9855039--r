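# Pleiotropy and influence diagnostics.

#' MR-Egger intercept test for directional pleiotropy
#'
#' Tests whether the MR-Egger intercept differs from zero; a significant
#' intercept indicates average directional pleiotropy across instruments.
#' With fewer than 3 instruments the test is not evaluable and is reported
#' as such (never as a silent pass).
#'
#' Because balanced pleiotropy adds the *same* variance to every
#' instrument's outcome effect, the test models excess residual variation
#' as an additive component `tau2` (solved so the weighted residual sum of
#' squares matches its degrees of freedom, i.e. a Paule-Mandel style
#' random-effects Egger fit) rather than as a multiplicative dispersion;
#' with a t reference on J - 2 df this keeps the test's size at its nominal
#' level under balanced pleiotropy at the small instrument counts typical
#' of these analyses. The intercept *estimate* coincides with [mr_egger()]
#' when `tau2 = 0`.
#'
#' @param data Harmonized instrument table.
#' @param alpha Significance level for the pleiotropy flag (default 0.05).
#' @return A one-row tibble `nsnp, intercept, se, pval, tau2, pleiotropy,
#'   evaluable`.
#' @export
egger_intercept_test <- function(data, alpha = 0.05) {
  assert_scalar_prob(alpha, "alpha")
  if (nrow(data) < 3) {
    return(tibble(nsnp = nrow(data), intercept = NA_real_, se = NA_real_,
                  pval = NA_real_, tau2 = NA_real_, pleiotropy = NA,
                  evaluable = FALSE))
  }
  data <- egger_orient(data)
  j <- nrow(data)
  df <- j - 2
  fit_at <- function(tau2) {
    f <- wls_fit(data$beta_exp, data$beta_out, 1 / (data$se_out^2 + tau2))
    f$q <- f$sigma2 * df  # weighted residual sum of squares
    f
  }
  f <- fit_at(0)
  tau2 <- 0
  if (f$q > df) {
    tau2 <- uniroot(function(t) fit_at(t)$q - df, c(0, 10),
                    extendInt = "downX", tol = 1e-10)$root
    f <- fit_at(tau2)
  }
  # weights already carry tau2; no further dispersion scaling
  se_int <- f$se_intercept / sqrt(max(1, f$sigma2))
  pval <- two_sided_p(f$intercept / se_int, df = df, dist = "t")
  tibble(nsnp = j, intercept = f$intercept, se = se_int, pval = pval,
         tau2 = tau2, pleiotropy = pval < alpha, evaluable = TRUE)
}

# Leave-one-out IVW slopes through the origin, computed from sums so the
# PRESSO simulation can reuse the same closed form on matrices.
loo_theta <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Computes the observed residual sum of squares of the outcome effects
#' around leave-one-out IVW predictions, compares it against a simulated
#' null (summary statistics redrawn from their sampling distributions under
#' the no-pleiotropy model) for a global test, flags per-SNP outliers from
#' the per-instrument simulated residual distributions with Bonferroni
#' adjustment, and, when outliers are found, re-estimates the causal effect
#' without them and reports the distortion of the estimate.
#'
#' Empirical p-values use the add-one correction `(1 + #exceedances) /
#' (n_sim + 1)` and are therefore never exactly zero. Requires more than 3
#' instruments; with 4 or fewer rows short of that the result is marked not
#' evaluable.
#'
#' @param data Harmonized instrument table.
#' @param n_sim Number of null simulations (default 1000).
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP
#'   p-values (default 0.05).
#' @param seed Simulation seed (required).
#' @param n_distortion Random same-size subsets for the distortion test
#'   (default 1000).
#' @return An object of class `mr_presso`: a list with `status`
#'   (`"ok"`/`"not evaluable"`), `rss_obs`, `global_p`, `outlier_table`
#'   (per-SNP p-values), `outliers`, `estimate_all`,
#'   `estimate_no_outliers`, `distortion_pct`, `distortion_p`, `n_sim`,
#'   `seed`.
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed = NULL,
                      n_distortion = 1000) {
  if (nrow(data) <= 3) {
    return(structure(list(status = "not evaluable",
                          reason = "MR-PRESSO requires more than 3 instruments",
                          nsnp = nrow(data)),
                     class = "mr_presso"))
  }
  data <- check_mr_data(data, 4, "mr_presso")
  if (is.null(seed)) {
    abort("a seed is required for the MR-PRESSO simulations",
          class = "mrpipe_config_error")
  }
  j <- nrow(data)
  w <- 1 / data$se_out^2
  th_loo <- loo_theta(data$beta_exp, data$beta_out, w)
  term_obs <- w * (data$beta_out - th_loo * data$beta_exp)^2
  rss_obs <- sum(term_obs)

  sims <- with_seed(seed, {
    bx <- matrix(rnorm(n_sim * j, rep(data$beta_exp, each = n_sim),
                       rep(data$se_exp, each = n_sim)), n_sim, j)
    by <- matrix(rnorm(n_sim * j, rep(th_loo * data$beta_exp, each = n_sim),
                       rep(data$se_out, each = n_sim)), n_sim, j)
    wmat <- matrix(w, n_sim, j, byrow = TRUE)
    sxy <- rowSums(wmat * bx * by)
    sxx <- rowSums(wmat * bx^2)
    th_star <- (sxy - wmat * bx * by) / (sxx - wmat * bx^2)  # n_sim x j LOO
    term <- wmat * (by - th_star * bx)^2
    list(term = term, rss = rowSums(term))
  })
  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + colSums(sims$term >= matrix(term_obs, n_sim, j, byrow = TRUE))) /
    (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  outliers <- data$snp[p_adj < outlier_alpha]

  estimate_all <- mr_ivw(data)
  estimate_no_outliers <- NULL
  distortion_pct <- NA_real_
  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < j) {
    reduced <- data[!data$snp %in% outliers, , drop = FALSE]
    estimate_no_outliers <- mr_ivw(reduced)
    distortion_pct <- 100 * (estimate_all$beta - estimate_no_outliers$beta) /
      abs(estimate_no_outliers$beta)
    k <- nrow(reduced)
    wxy <- w * data$beta_exp * data$beta_out
    wxx <- w * data$beta_exp^2
    dist_d <- with_seed(derive_seed(seed, "distortion"), {
      vapply(seq_len(n_distortion), function(b) {
        idx <- sample.int(j, k)
        th_sub <- sum(wxy[idx]) / sum(wxx[idx])  # fixed-effect IVW on the subset
        100 * (estimate_all$beta - th_sub) / abs(th_sub)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(dist_d) >= abs(distortion_pct))) /
      (n_distortion + 1)
  }
  structure(list(status = "ok", nsnp = j, rss_obs = rss_obs,
                 global_p = global_p, n_sim = n_sim,
                 outlier_table = tibble(snp = data$snp, term = term_obs,
                                        pval = p_raw, pval_adj = p_adj,
                                        outlier = p_adj < outlier_alpha),
                 outliers = outliers,
                 estimate_all = estimate_all,
                 estimate_no_outliers = estimate_no_outliers,
                 distortion_pct = distortion_pct,
                 distortion_p = distortion_p,
                 outlier_alpha = outlier_alpha, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<mr_presso> not evaluable: %s (J = %d)\n", x$reason, x$nsnp))
    return(invisible(x))
  }
  cat(sprintf("<mr_presso> J = %d, RSS = %.4f, global p = %.4g (%d simulations)\n",
              x$nsnp, x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers: %s; distortion %.1f%% (p = %.3g)\n",
                paste(x$outliers, collapse = ", "), x$distortion_pct,
                x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Tidy the per-SNP MR-PRESSO outlier table
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return The per-SNP outlier tibble (empty when not evaluable).
#' @export
tidy.mr_presso <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble(snp = character(), term = numeric(), pval = numeric(),
                  pval_adj = numeric(), outlier = logical()))
  }
  x$outlier_table
}

#' Glance at an MR-PRESSO result
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return One-row tibble with the global test and distortion summary.
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(status = x$status, nsnp = x$nsnp,
         rss_obs = if (x$status == "ok") x$rss_obs else NA_real_,
         global_p = if (x$status == "ok") x$global_p else NA_real_,
         n_outliers = if (x$status == "ok") length(x$outliers) else NA_integer_,
         distortion_pct = if (x$status == "ok") x$distortion_pct else NA_real_,
         distortion_p = if (x$status == "ok") x$distortion_p else NA_real_)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect J times, omitting one instrument each
#' time, to expose high-influence variants. The re-estimation method is IVW
#' (delegating to the Wald ratio when only one instrument remains).
#'
#' @param data Harmonized instrument table (at least 2 instruments).
#' @param effect_model Passed to [mr_ivw()] (default `"auto"`).
#' @param q_alpha Passed to [mr_ivw()].
#' @return A tibble with one row per omitted SNP: `snp_excluded, method,
#'   nsnp, beta, se, ci_low, ci_high, pval`.
#' @export
mr_leave_one_out <- function(data, effect_model = "auto", q_alpha = 0.05) {
  data <- check_mr_data(data, 2, "mr_leave_one_out")
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    est <- mr_ivw(data[-i, , drop = FALSE], effect_model = effect_model,
                  q_alpha = q_alpha)
    tibble(snp_excluded = data$snp[i], method = est$method, nsnp = est$nsnp,
           beta = est$beta, se = est$se, ci_low = est$ci_low,
           ci_high = est$ci_high, pval = est$pval)
  })
}

#' Data tables behind the standard MR plots
#'
#' Builds the scatter (per-SNP effects with error bars plus fitted lines
#' per method), forest (per-SNP Wald ratios plus pooled rows) and funnel
#' (per-SNP ratio against precision) tables used by the `plot_mr_*`
#' functions and exported as TSVs by [run_study()]. IVW lines pass through
#' the origin; the MR-Egger line carries its intercept.
#'
#' @param data Harmonized instrument table.
#' @param estimates A list of `mr_estimate` objects.
#' @return A list of tibbles `scatter`, `lines`, `forest`, `funnel`.
#' @export
mr_plot_tables <- function(data, estimates) {
  data <- check_mr_data(data, 1, "mr_plot_tables")
  if (length(estimates) == 0) {
    abort("at least one estimate is required", class = "mrpipe_config_error")
  }
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  r <- wald_ratios(data)
  scatter <- tibble(snp = data$snp, beta_exp = data$beta_exp,
                    se_exp = data$se_exp, beta_out = data$beta_out,
                    se_out = data$se_out)
  lines <- purrr::map_dfr(estimates, function(e) {
    tibble(method = e$method, slope = e$beta,
           intercept = e$egger_intercept %||% 0)
  })
  forest <- dplyr::bind_rows(
    tibble(label = r$snp, type = "snp", beta = r$beta_ratio, se = r$se_ratio,
           ci_low = r$beta_ratio - qnorm(0.975) * r$se_ratio,
           ci_high = r$beta_ratio + qnorm(0.975) * r$se_ratio),
    purrr::map_dfr(estimates, function(e) {
      tibble(label = e$method, type = "pooled", beta = e$beta, se = e$se,
             ci_low = e$ci_low, ci_high = e$ci_high)
    })
  )
  funnel <- tibble(snp = r$snp, beta_ratio = r$beta_ratio,
                   precision = 1 / r$se_ratio)
  list(scatter = scatter, lines = lines, forest = forest, funnel = funnel)
}
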