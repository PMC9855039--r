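small_scenario <- function(..., seed = NULL) {
  sim_scenario(n_exposure = 4000, n_outcome = 4000, j = 5, r2_xz = 0.05,
               seed = seed, ...)
}

test_that("scenario construction validates its domains", {
  expect_s3_class(sim_scenario(), "sim_scenario")
  expect_error(sim_scenario(maf = rep(0.6, 10)), class = "mrpipe_validation_error")
  expect_error(sim_scenario(r2_xz = 1.2), class = "mrpipe_validation_error")
  expect_error(sim_scenario(prevalence = 0), class = "mrpipe_config_error")
  # explicit gammas that would explain >= 100% of variance are infeasible
  expect_error(sim_scenario(j = 2, maf = c(0.4, 0.4), gamma = c(2, 2)),
               class = "mrpipe_validation_error")
  # named presets all construct and simulate
  for (nm in c("valid", "balanced", "directional", "outlier")) {
    ds <- simulate_sumstats(sim_preset(nm, n_exposure = 1000, n_outcome = 1000),
                            seed = 1)
    expect_equal(nrow(ds), 10L)
  }
})

test_that("generation is deterministic: same scenario and seed, identical bytes", {
  sc <- small_scenario()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_two_sample_dataset(sc, seed = 7, dir = d1)
  f2 <- make_two_sample_dataset(sc, seed = 7, dir = d2)
  for (p in c("exposure_path", "outcome_path", "truth_path")) {
    expect_identical(unname(tools::md5sum(f1[[p]])), unname(tools::md5sum(f2[[p]])))
  }
  f3 <- make_two_sample_dataset(sc, seed = 8, dir = withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(f1$exposure_path)),
                         unname(tools::md5sum(f3$exposure_path))))
  expect_identical(simulate_sumstats(sc, seed = 3), simulate_sumstats(sc, seed = 3))
})

test_that("the logistic intercept solver hits the target prevalence", {
  sc <- sim_scenario(n_exposure = 1000, n_outcome = 100000, j = 5,
                     r2_xz = 0.05, prevalence = 0.1)
  co <- simulate_cohorts(sc, seed = 11)
  expect_lt(abs(co$truth$case_fraction - 0.1), 0.01)
  sc2 <- sim_scenario(n_exposure = 1000, n_outcome = 100000, j = 5,
                      r2_xz = 0.05, prevalence = 0.3)
  co2 <- simulate_cohorts(sc2, seed = 11)
  expect_lt(abs(co2$truth$case_fraction - 0.3), 0.01)
})

test_that("instruments explain approximately the target exposure variance", {
  sc <- sim_scenario(n_exposure = 20000, n_outcome = 1000, j = 5, r2_xz = 0.05)
  r2 <- vapply(1:5, function(s) {
    co <- simulate_cohorts(sc, seed = s)
    summary(stats::lm(co$exposure$trait ~ co$exposure$genotypes))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.05) / 0.05, 0.2)
})

test_that("marginal GWAS effect estimates are unbiased for the generative effects", {
  sc <- sim_scenario(n_exposure = 20000, n_outcome = 1000, j = 4, r2_xz = 0.04)
  est <- vapply(1:8, function(s) {
    co <- simulate_cohorts(sc, seed = s + 50)
    summarize_gwas(co$exposure, "continuous")$beta
  }, numeric(4))
  expect_equal(unname(rowMeans(est)), sc$gamma, tolerance = 0.1)
})

test_that("a null causal effect yields null per-SNP outcome associations", {
  sc <- sim_scenario(n_exposure = 1000, n_outcome = 6000, j = 8, theta = 0,
                     r2_xz = 0.03)
  z <- unlist(lapply(1:15, function(s) {
    co <- simulate_cohorts(sc, seed = s + 200)
    ss <- summarize_gwas(co$outcome, "binary")
    ss$beta / ss$se
  }))
  # 120 null z-scores: their mean is within 3.5 sd of zero
  expect_lt(abs(mean(z)), 3.5 / sqrt(length(z)))
  # and the two-sided p-values look uniform
  p <- 2 * pnorm(-abs(z))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("monomorphic SNPs are excluded with a warning", {
  g <- cbind(rs1 = rep(2L, 500), rs2 = rbinom(500, 2, 0.3))
  y <- rnorm(500)
  expect_warning(ss <- summarize_gwas(list(genotypes = g, trait = y),
                                      "continuous"),
                 regexp = "monomorphic")
  expect_identical(ss$snp, "rs2")
})

test_that("exposure and outcome sampling errors are uncorrelated across cohorts", {
  sc <- sim_scenario(n_exposure = 1500, n_outcome = 1500, j = 6, theta = 0,
                     r2_xz = 0.03)
  errs <- lapply(1:120, function(s) {
    co <- simulate_cohorts(sc, seed = s + 400)
    e <- summarize_gwas(co$exposure, "continuous")
    o <- summarize_gwas(co$outcome, "binary")
    idx <- match(o$snp, e$snp)
    cbind(e$beta[idx] - sc$gamma[idx], o$beta)
  })
  m <- do.call(rbind, errs)
  expect_lt(abs(stats::cor(m[, 1], m[, 2])), 0.05)
})

test_that("summary-level simulation reproduces the scenario's moments", {
  sc <- sim_preset("valid", theta = 0.15)
  draws <- vapply(1:300, function(s) {
    ds <- simulate_sumstats(sc, seed = s)
    c(mean(ds$beta_exp - sc$gamma), mean(ds$beta_out - 0.15 * sc$gamma))
  }, numeric(2))
  expect_lt(abs(mean(draws[1, ])), 3e-4)
  expect_lt(abs(mean(draws[2, ])), 1e-3)
  # directional pleiotropy shifts outcome effects by its mean
  scd <- sim_preset("directional", theta = 0)
  shift <- vapply(1:300, function(s) {
    ds <- simulate_sumstats(scd, seed = s)
    mean(ds$beta_out)
  }, numeric(1))
  expect_equal(mean(shift), 0.02, tolerance = 0.15)
})

test_that("scenarios round-trip through YAML", {
  sc <- sim_preset("balanced", j = 4, n_exposure = 1000, n_outcome = 2000)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$gamma, sc$gamma, tolerance = 1e-12)
  expect_equal(back$pleiotropy$sd, 0.05)
  expect_equal(back$n_outcome, 2000L)
})

test_that("replicate studies are tidy, deterministic, and method-complete", {
  sc <- sim_preset("valid", theta = 0.1, n_exposure = 2000, n_outcome = 2000)
  a <- mr_replicate_study(sc, n_reps = 5, seed = 9, level = "summary",
                          methods = c("ivw", "egger", "intercept_test"))
  expect_equal(nrow(a), 15L)
  expect_setequal(unique(a$method),
                  c("ivw_fe", "ivw_re", "egger", "intercept_test")[
                    c("ivw_fe", "ivw_re", "egger", "intercept_test") %in% a$method])
  b <- mr_replicate_study(sc, n_reps = 5, seed = 9, level = "summary",
                          methods = c("ivw", "egger", "intercept_test"))
  expect_identical(a, b)
  expect_error(mr_replicate_study(sc, 2, 1, methods = "nope"),
               class = "mrpipe_config_error")
})
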