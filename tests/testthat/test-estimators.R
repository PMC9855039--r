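one_snp <- function(beta_exp, beta_out, se_out, se_exp = 0.01) {
  new_mr_dataset(tibble::tibble(snp = "rs1", beta_exp = beta_exp,
                                se_exp = se_exp, beta_out = beta_out,
                                se_out = se_out))
}

test_that("the Wald ratio is the outcome effect scaled by the exposure effect", {
  est <- mr_wald_ratio(one_snp(0.5, 0.1, 0.05))
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$nsnp, 1L)
  null <- mr_wald_ratio(one_snp(0.5, 0, 0.05))
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)
  # re-orienting the effect allele leaves the estimate unchanged
  neg <- mr_wald_ratio(one_snp(-0.5, -0.1, 0.05))
  expect_equal(neg$beta, 0.2)
  expect_equal(neg$se, 0.1)
  expect_error(mr_wald_ratio(one_snp(0, 0.1, 0.05)),
               class = "mrpipe_estimation_error")
})

test_that("IVW pools ratios by inverse variance with the expected closed forms", {
  # two identical instruments: theta unchanged, SE shrinks by sqrt(2), Q = 0
  ds <- new_mr_dataset(tibble::tibble(
    snp = c("a", "b"), beta_exp = 1, se_exp = 0.01,
    beta_out = 0.2, se_out = 0.1))
  est <- mr_ivw(ds)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1 / sqrt(2))
  expect_equal(est$q, 0)
  expect_identical(est$method, "ivw_fe")
  # symmetric ratios with equal weights average
  ds2 <- new_mr_dataset(tibble::tibble(
    snp = c("a", "b"), beta_exp = 1, se_exp = 0.01,
    beta_out = c(0.1, 0.3), se_out = 0.1))
  expect_equal(mr_ivw(ds2)$beta, 0.2)
})

test_that("IVW equals origin-constrained weighted least squares on seeded data", {
  for (seed in 1:30) {
    j <- withr::with_seed(seed, sample(2:12, 1))
    ds <- random_mr_data(j, seed)
    est <- mr_ivw(ds, effect_model = "fixed")
    expect_equal(est$beta, ivw_oracle(ds), tolerance = 1e-10)
  }
})

test_that("a single instrument delegates IVW to the Wald ratio exactly", {
  ds <- one_snp(0.4, 0.08, 0.03)
  ivw <- mr_ivw(ds)
  wald <- mr_wald_ratio(ds)
  expect_identical(ivw$method, "wald")
  expect_equal(ivw$beta, wald$beta)
  expect_equal(ivw$se, wald$se)
})

test_that("the random-effect IVW SE never falls below the fixed-effect SE", {
  for (seed in 1:15) {
    ds <- random_mr_data(8, seed, out_noise_mult = withr::with_seed(seed, runif(1, 0.5, 4)))
    fixed <- mr_ivw(ds, "fixed")
    random <- mr_ivw(ds, "random")
    expect_gte(random$se, fixed$se)
    expect_equal(random$beta, fixed$beta)
  }
})

test_that("auto IVW switches to the random model exactly when Q is significant", {
  for (seed in 1:10) {
    ds <- random_mr_data(8, seed, out_noise_mult = 3)
    est <- mr_ivw(ds, "auto", q_alpha = 0.05)
    expect_identical(est$method, if (est$q_pval < 0.05) "ivw_re" else "ivw_fe")
  }
})

test_that("all estimators are invariant to re-orienting any instrument", {
  ds <- random_mr_data(8, seed = 5)
  flip <- withr::with_seed(9, sample(c(1, -1), 8, replace = TRUE))
  ds2 <- ds
  ds2$beta_exp <- ds$beta_exp * flip
  ds2$beta_out <- ds$beta_out * flip
  expect_equal(mr_ivw(ds2, "fixed")$beta, mr_ivw(ds, "fixed")$beta, tolerance = 1e-12)
  expect_equal(mr_egger(ds2)$beta, mr_egger(ds)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(ds2, seed = 1)$beta,
               mr_weighted_median(ds, seed = 1)$beta, tolerance = 1e-12)
  expect_equal(mr_max_likelihood(ds2)$beta, mr_max_likelihood(ds)$beta,
               tolerance = 1e-8)
})

test_that("Cochran's Q matches direct summation and its closed forms", {
  ds <- new_mr_dataset(tibble::tibble(
    snp = letters[1:3], beta_exp = 1, se_exp = 0.01,
    beta_out = 0.2, se_out = 0.1))
  r <- wald_ratios(ds)
  het <- cochran_q(r, 0.2)
  expect_equal(het$q, 0)
  expect_equal(het$i2, 0)
  for (seed in 1:10) {
    ds <- random_mr_data(7, seed)
    r <- wald_ratios(ds)
    theta <- mr_ivw(ds, "fixed")$beta
    oracle <- sum(r$weight * (r$beta_ratio - theta)^2)  # direct summation
    expect_equal(cochran_q(r, theta)$q, oracle, tolerance = 1e-12)
  }
  expect_error(cochran_q(wald_ratios(one_snp(1, 0.2, 0.1)), 0.2),
               class = "mrpipe_insufficient_instruments")
})

test_that("MR-Egger recovers an exact linear law and reduces to IVW without pleiotropy", {
  x <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  exact <- new_mr_dataset(tibble::tibble(
    snp = paste0("s", 1:5), beta_exp = x, se_exp = 0.01,
    beta_out = 0.05 + 0.3 * x, se_out = 0.02))
  est <- mr_egger(exact)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.05, tolerance = 1e-12)
  prop <- new_mr_dataset(tibble::tibble(
    snp = paste0("s", 1:5), beta_exp = x, se_exp = 0.01,
    beta_out = 0.3 * x, se_out = 0.02))
  expect_equal(mr_egger(prop)$beta, mr_ivw(prop, "fixed")$beta, tolerance = 1e-12)
  expect_error(mr_egger(exact[1:2, ]), class = "mrpipe_insufficient_instruments")
  degen <- new_mr_dataset(tibble::tibble(
    snp = paste0("s", 1:4), beta_exp = 0.1, se_exp = 0.01,
    beta_out = c(0.01, 0.02, 0.03, 0.04), se_out = 0.02))
  expect_error(mr_egger(degen), class = "mrpipe_estimation_error")
})

test_that("MR-Egger matches the weighted-regression oracle on seeded data", {
  for (seed in 1:30) {
    j <- withr::with_seed(seed, sample(3:12, 1))
    ds <- random_mr_data(j, seed, intercept = 0.01)
    est <- mr_egger(ds)
    oracle <- egger_oracle(ds)
    expect_equal(est$beta, oracle$slope, tolerance = 1e-10)
    expect_equal(est$egger_intercept, oracle$intercept, tolerance = 1e-10)
    # when the residual dispersion exceeds 1 the analytic SEs coincide with
    # the weighted-lm SEs; otherwise they are the dispersion-floored version
    if (oracle$sigma >= 1) {
      expect_equal(est$se, oracle$se[["x"]], tolerance = 1e-10)
      expect_equal(est$egger_intercept_se, oracle$se[["(Intercept)"]],
                   tolerance = 1e-10)
    } else {
      expect_equal(est$se, oracle$se[["x"]] / oracle$sigma, tolerance = 1e-10)
    }
  }
})

test_that("the bootstrap Egger SE tracks the analytic SE on well-behaved data", {
  ds <- random_mr_data(8, seed = 21, out_noise_mult = 1)
  ds$se_exp <- rep(1e-4, 8)  # negligible exposure noise
  analytic <- mr_egger(ds, se_method = "analytic")
  boot <- mr_egger(ds, se_method = "bootstrap", n_boot = 2000, seed = 77)
  expect_equal(boot$beta, analytic$beta)  # point estimate unaffected
  expect_lt(abs(boot$se - analytic$se) / analytic$se, 0.15)
  expect_error(mr_egger(ds, se_method = "bootstrap"),
               class = "mrpipe_config_error")
})

test_that("the weighted median interpolates cumulative weight midpoints", {
  ds <- new_mr_dataset(tibble::tibble(
    snp = c("a", "b", "c"), beta_exp = 1, se_exp = 0.01,
    beta_out = c(0.1, 0.2, 0.9), se_out = 1))
  expect_equal(mr_weighted_median(ds, seed = 1)$beta, 0.2)
  # a dominant instrument (> 50% of weight) pins the estimate near its ratio
  ds2 <- new_mr_dataset(tibble::tibble(
    snp = c("a", "b", "c"), beta_exp = 1, se_exp = 0.01,
    beta_out = c(0.1, 0.5, 0.9), se_out = c(1, 0.2, 1)))
  est <- mr_weighted_median(ds2, seed = 1)
  # independent evaluation of the interpolation formula
  b <- c(0.1, 0.5, 0.9); w <- c(1, 25, 1) / 27
  p <- cumsum(w) - w / 2
  k <- max(which(p < 0.5))
  oracle <- b[k] + (b[k + 1] - b[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
  expect_equal(est$beta, oracle, tolerance = 1e-12)
  expect_error(mr_weighted_median(ds[1:2, ], seed = 1),
               class = "mrpipe_insufficient_instruments")
})

test_that("likelihood-based MR is exact in the noiseless limit and matches IVW as exposure noise vanishes", {
  x <- c(0.05, 0.1, 0.15, 0.2)
  exact <- new_mr_dataset(tibble::tibble(
    snp = paste0("s", 1:4), beta_exp = x, se_exp = 1e-6,
    beta_out = 0.25 * x, se_out = 1e-6))
  expect_equal(mr_max_likelihood(exact)$beta, 0.25, tolerance = 1e-6)
  ds <- random_mr_data(8, seed = 31)
  ds$se_exp <- ds$se_exp * 1e-6
  expect_equal(mr_max_likelihood(ds)$beta, mr_ivw(ds, "fixed")$beta,
               tolerance = 1e-5)
})

test_that("the profile-likelihood maximum matches a dense grid-search oracle", {
  profile_ll <- function(theta, d) {
    # independent re-derivation of the profiled likelihood
    vx <- d$se_exp^2; vy <- d$se_out^2
    xi <- (d$beta_exp / vx + theta * d$beta_out / vy) / (1 / vx + theta^2 / vy)
    -0.5 * sum((d$beta_exp - xi)^2 / vx + (d$beta_out - theta * xi)^2 / vy)
  }
  for (seed in c(41, 42, 43)) {
    ds <- random_mr_data(6, seed)
    est <- mr_max_likelihood(ds)
    coarse <- seq(est$beta - 0.5, est$beta + 0.5, length.out = 2001)
    ll <- vapply(coarse, profile_ll, numeric(1), d = ds)
    centre <- coarse[which.max(ll)]
    fine <- seq(centre - 0.001, centre + 0.001, by = 1e-6)
    llf <- vapply(fine, profile_ll, numeric(1), d = ds)
    expect_equal(est$beta, fine[which.max(llf)], tolerance = 1e-5)
  }
})

test_that("tidy and glance return broom-shaped summaries", {
  ds <- random_mr_data(6, seed = 3)
  td <- tidy(mr_egger(ds))
  expect_identical(td$term, c("causal_effect", "intercept"))
  gl <- glance(mr_ivw(ds))
  expect_true(all(c("beta", "or", "q", "i2") %in% names(gl)))
  expect_equal(gl$or, exp(gl$beta))
})
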