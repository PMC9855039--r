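# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route (lm(), brute-force scans, direct sums) than
# the package implementation they check.

# A random harmonized dataset drawn directly at the summary level.
random_mr_data <- function(j, seed, theta = 0.2, intercept = 0,
                           out_noise_mult = 1) {
  withr::with_seed(seed, {
    beta_exp <- runif(j, 0.05, 0.25) * sample(c(-1, 1), j, replace = TRUE)
    se_exp <- runif(j, 0.004, 0.02)
    se_out <- runif(j, 0.01, 0.05)
    beta_out <- intercept * sign(beta_exp) + theta * beta_exp +
      rnorm(j, 0, se_out * out_noise_mult)
    new_mr_dataset(tibble::tibble(
      snp = sprintf("rs%03d", seq_len(j)),
      beta_exp = beta_exp, se_exp = se_exp,
      beta_out = beta_out, se_out = se_out))
  })
}

# Origin-constrained weighted least squares via lm(): the IVW oracle.
ivw_oracle <- function(data) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = data,
                   weights = 1 / data$se_out^2)
  unname(stats::coef(fit)[1])
}

# Weighted regression with intercept via lm() on positively-oriented
# exposure effects: the MR-Egger oracle.
egger_oracle <- function(data) {
  s <- ifelse(data$beta_exp < 0, -1, 1)
  d <- data.frame(x = data$beta_exp * s, y = data$beta_out * s)
  fit <- stats::lm(y ~ x, data = d, weights = 1 / data$se_out^2)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       sigma = summary(fit)$sigma,
       se = summary(fit)$coefficients[, "Std. Error"])
}

# Brute-force greedy clumping: re-scan the full remaining list each round.
clump_oracle <- function(assocs, ldm, r2_max) {
  remaining <- assocs[order(assocs$pval, assocs$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining$snp[1]
    kept <- c(kept, idx)
    drop <- vapply(remaining$snp, function(s) {
      s != idx && ldm[idx, s] > r2_max
    }, logical(1))
    remaining <- remaining[-1, , drop = FALSE]
    remaining <- remaining[!remaining$snp %in% names(drop)[drop], , drop = FALSE]
  }
  kept
}

# Symmetric random r2 matrix over the given snps.
random_ld_matrix <- function(snps, seed, prob_linked = 0.4) {
  withr::with_seed(seed, {
    j <- length(snps)
    m <- matrix(0, j, j, dimnames = list(snps, snps))
    for (a in seq_len(j - 1)) {
      for (b in (a + 1):j) {
        r2 <- if (runif(1) < prob_linked) runif(1) else 0
        m[a, b] <- m[b, a] <- r2
      }
    }
    diag(m) <- 1
    m
  })
}

# A small well-formed sumstats tibble.
toy_sumstats <- function(n = 3, seed = 1, trait = "trait") {
  withr::with_seed(seed, {
    tibble::tibble(
      snp = sprintf("rs%d", seq_len(n)),
      effect_allele = sample(c("A", "C"), n, replace = TRUE),
      other_allele = "G",
      eaf = runif(n, 0.05, 0.95),
      beta = rnorm(n, 0, 0.1),
      se = runif(n, 0.005, 0.05),
      pval = runif(n, 1e-12, 0.9),
      n = 10000L,
      trait_id = trait
    )
  })
}

# Write a small synthetic multi-database study bundle and return its input
# table for run_study().
study_inputs <- function(dir, n_exp = 2, n_out = 2, n_db = 2, seed0 = 100) {
  rows <- list()
  k <- 0
  for (e in seq_len(n_exp)) for (o in seq_len(n_out)) for (d in seq_len(n_db)) {
    k <- k + 1
    sc <- sim_scenario(n_exposure = 3000, n_outcome = 3000, j = 4,
                       r2_xz = 0.05, theta = 0.2)
    f <- make_two_sample_dataset(sc, seed = seed0 + 7 * e + 3 * o + d,
                                 dir = dir, prefix = paste0("t", k))
    rows[[k]] <- tibble::tibble(
      exposure_id = paste0("exp", e), outcome_id = paste0("out", o),
      database_id = paste0("db", d),
      exposure_path = f$exposure_path, outcome_path = f$outcome_path)
  }
  dplyr::bind_rows(rows)
}
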