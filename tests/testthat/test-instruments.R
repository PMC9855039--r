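test_that("significance filtering is strict and order-preserving", {
  df <- toy_sumstats(3)
  df$pval <- c(1e-6, 5e-6, 1e-5)
  kept <- select_significant(df, 5e-6)
  expect_identical(kept$snp, "rs1")  # strictly below the threshold only
  df$pval <- c(1e-9, 1e-7, 0.5)
  expect_identical(select_significant(df, 5e-8)$snp, "rs1")
  expect_identical(select_significant(df, 0.9)$snp, df$snp)
  aud <- mr_audit(select_significant(df, 5e-8))
  expect_setequal(aud$snp, c("rs2", "rs3"))
  expect_true(all(aud$action == "dropped"))
})

test_that("greedy clumping matches the brute-force oracle on seeded instances", {
  for (seed in 1:25) {
    j <- withr::with_seed(seed, sample(2:12, 1))
    df <- toy_sumstats(j, seed = seed + 100)
    ldm <- random_ld_matrix(df$snp, seed = seed)
    got <- ld_clump(df, ldm, r2_max = 0.1)
    expect_identical(got$snp, clump_oracle(df, ldm, 0.1), label = paste("seed", seed))
  }
})

test_that("clumping keeps only the top hit among correlated pairs and all independent hits", {
  df <- toy_sumstats(2)
  df$pval <- c(1e-9, 1e-10)
  ldm <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(df$snp, df$snp))
  expect_identical(ld_clump(df, ldm, r2_max = 0.001)$snp, "rs2")
  ldm0 <- diag(2); dimnames(ldm0) <- list(df$snp, df$snp)
  expect_equal(nrow(ld_clump(df, ldm0, r2_max = 0.001)), 2L)
})

test_that("the distance window gates clumping when positions are present", {
  df <- toy_sumstats(2)
  df$pval <- c(1e-10, 1e-9)
  df$chr <- c(1, 1)
  df$pos <- c(1e6, 50e6)  # 49 Mb apart, outside a 10,000 kb window
  ldm <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(df$snp, df$snp))
  expect_equal(nrow(ld_clump(df, ldm, r2_max = 0.001, window_kb = 10000)), 2L)
  df$pos <- c(1e6, 2e6)  # inside the window: clumped
  expect_equal(nrow(ld_clump(df, ldm, r2_max = 0.001, window_kb = 10000)), 1L)
})

test_that("panel-unresolved variants are dropped and logged", {
  df <- toy_sumstats(11, seed = 3)
  panel <- df$snp[-7]
  out <- drop_ld_unresolved(df, panel)
  expect_equal(nrow(out), 10L)
  expect_identical(mr_audit(out)$snp, df$snp[7])
  expect_identical(drop_ld_unresolved(df, df$snp)$snp, df$snp)
  none <- drop_ld_unresolved(df, character(0))
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(mr_audit(none)), 11L)
})

test_that("confounder screening equals the set-difference oracle", {
  df <- toy_sumstats(8, seed = 9)
  hits <- tibble::tibble(
    snp = c("rs1", "rs4", "rs4", "rs6", "rs8"),
    trait = c("bmi", "smoking", "ldl", "bmi", "education"),
    pval = c(1e-12, 1e-9, 0.2, 1e-3, 4e-8)
  )
  out <- screen_confounders(df, hits, p_conf = 5e-8)
  oracle <- setdiff(df$snp, unique(hits$snp[hits$pval < 5e-8]))
  expect_identical(out$snp, oracle)
  aud <- mr_audit(out)
  expect_true(any(grepl("smoking", aud$reason[aud$snp == "rs4"])))
  expect_identical(screen_confounders(df, hits[0, ])$snp, df$snp)
})

test_that("weak-instrument filtering uses the strict F > threshold rule", {
  df <- tibble::tibble(snp = c("s1", "s2", "s3"),
                       beta = c(0.1, 0.03, NA), se = c(0.01, 0.01, NA),
                       f_stat = c(100, 9, 10))
  out <- filter_weak(df, f_min = 10)
  expect_identical(out$snp, "s1")           # F = 100 kept; F = 9 and F = 10 dropped
  expect_equal(out$f_stat, 100)
  expect_setequal(mr_audit(out)$snp, c("s2", "s3"))
})

test_that("proxy choice maximizes r2 with lexicographic tie-break", {
  proxies <- tibble::tibble(
    missing_snp = c("rs1", "rs1", "rs2", "rs3", "rs3"),
    proxy_snp = c("rsA", "rsB", "rsC", "rsE", "rsD"),
    r2 = c(0.8, 0.9, 0.5, 0.85, 0.85),
    a1_missing = "A", a1_proxy = "A", a2_missing = "G", a2_proxy = "G"
  )
  avail <- c("rsA", "rsB", "rsC", "rsD", "rsE")
  sub <- substitute_proxies(c("rs1", "rs2", "rs3"), proxies, avail, r2_min = 0.8)
  expect_identical(sub$proxy_snp[sub$snp == "rs1"], "rsB")   # argmax r2
  expect_identical(sub$action[sub$snp == "rs2"], "dropped")  # below r2_min
  expect_identical(sub$proxy_snp[sub$snp == "rs3"], "rsD")   # tie -> lexicographic
  # proxies absent from the outcome GWAS cannot be used
  sub2 <- substitute_proxies("rs1", proxies, available = "rsA", r2_min = 0.8)
  expect_identical(sub2$proxy_snp, "rsA")
})

make_pair <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, beta_y, eaf_y) {
  list(
    exposure = tibble::tibble(snp = "rs1", effect_allele = ea_x,
                              other_allele = oa_x, eaf = eaf_x, beta = 0.1,
                              se = 0.01, pval = 1e-10),
    outcome = tibble::tibble(snp = "rs1", effect_allele = ea_y,
                             other_allele = oa_y, eaf = eaf_y, beta = beta_y,
                             se = 0.02, pval = 0.5)
  )
}

test_that("harmonization flips swapped alleles and resolves strand complements", {
  p <- make_pair("A", "G", 0.3, "G", "A", -0.05, 0.7)
  h <- harmonize_data(p$exposure, p$outcome)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.3)
  expect_true(h$flipped)
  # same variant reported on the other strand: T/C is complementary to A/G
  p2 <- make_pair("A", "G", 0.3, "T", "C", 0.05, 0.3)
  h2 <- harmonize_data(p2$exposure, p2$outcome)
  expect_equal(h2$beta_out, 0.05)
  expect_false(h2$flipped)
  # complementary strand AND swapped: C/T
  p3 <- make_pair("A", "G", 0.3, "C", "T", -0.05, 0.7)
  h3 <- harmonize_data(p3$exposure, p3$outcome)
  expect_equal(h3$beta_out, 0.05)
  expect_true(h3$flipped)
})

test_that("harmonizing an already-aligned pair is the identity", {
  p <- make_pair("A", "G", 0.3, "A", "G", 0.05, 0.31)
  h <- harmonize_data(p$exposure, p$outcome)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.31)
  expect_false(h$flipped)
  expect_equal(h$f_stat, (0.1 / 0.01)^2)
})

test_that("palindromic variants follow the frequency-inference policy", {
  # frequencies incompatible as labelled -> strand flip inferred
  p <- make_pair("A", "T", 0.10, "A", "T", 0.02, 0.88)
  h <- harmonize_data(p$exposure, p$outcome)
  expect_equal(h$beta_out, -0.02)
  expect_equal(h$eaf_out, 0.12)
  # compatible frequencies -> no flip
  p2 <- make_pair("A", "T", 0.10, "A", "T", 0.02, 0.12)
  expect_equal(harmonize_data(p2$exposure, p2$outcome)$beta_out, 0.02)
  # ambiguous frequency zone -> dropped
  p3 <- make_pair("C", "G", 0.5, "C", "G", 0.02, 0.5)
  h3 <- harmonize_data(p3$exposure, p3$outcome)
  expect_equal(nrow(h3), 0L)
  expect_match(mr_audit(h3)$reason, "ambiguous")
  # drop-all policy
  p4 <- make_pair("A", "T", 0.10, "A", "T", 0.02, 0.12)
  h4 <- harmonize_data(p4$exposure, p4$outcome, palindrome_policy = "drop")
  expect_equal(nrow(h4), 0L)
})

test_that("irreconcilable allele sets are dropped with an allele-mismatch reason", {
  p <- make_pair("A", "G", 0.3, "A", "C", 0.05, 0.3)
  h <- harmonize_data(p$exposure, p$outcome)
  expect_equal(nrow(h), 0L)
  expect_match(mr_audit(h)$reason, "allele mismatch")
})

test_that("proxied variants are harmonized on remapped alleles and audited once", {
  exposure <- tibble::tibble(snp = c("rs1", "rs2"), effect_allele = "A",
                             other_allele = "G", eaf = c(0.3, 0.4),
                             beta = c(0.1, 0.12), se = 0.01, pval = 1e-10)
  # rs2 absent from outcome; rsP proxies it with A<->T, G<->C mapping
  outcome <- tibble::tibble(snp = c("rs1", "rsP"), effect_allele = c("A", "T"),
                            other_allele = c("G", "C"), eaf = c(0.3, 0.41),
                            beta = c(0.05, 0.03), se = 0.02, pval = 0.5)
  proxies <- tibble::tibble(missing_snp = "rs2", proxy_snp = "rsP", r2 = 0.95,
                            a1_missing = "A", a1_proxy = "T",
                            a2_missing = "G", a2_proxy = "C")
  h <- harmonize_data(exposure, outcome, proxies = proxies)
  expect_equal(nrow(h), 2L)
  expect_identical(h$proxy_of[h$snp == "rs2"], "rsP")
  expect_equal(h$beta_out[h$snp == "rs2"], 0.03)
  aud <- mr_audit(h)
  expect_equal(sum(aud$snp == "rs2"), 1L)
  expect_identical(aud$action[aud$snp == "rs2"], "proxied")
  # without a proxy table the missing variant is dropped with a reason
  h2 <- harmonize_data(exposure, outcome)
  expect_equal(nrow(h2), 1L)
  expect_match(mr_audit(h2)$reason[mr_audit(h2)$snp == "rs2"], "no adequate proxy")
})

test_that("every input SNP is audited exactly once across a full selection chain", {
  for (seed in c(11, 12, 13)) {
    df <- toy_sumstats(12, seed = seed)
    df$pval <- withr::with_seed(seed, runif(12, 1e-12, 1e-4))
    sig <- select_significant(df, 1e-5)
    ldm <- random_ld_matrix(df$snp, seed = seed)
    clumped <- ld_clump(sig, ldm, r2_max = 0.3)
    hits <- tibble::tibble(snp = df$snp[1:2], trait = "bmi", pval = 1e-10)
    screened <- screen_confounders(clumped, hits, p_conf = 5e-8)
    outcome <- screened
    outcome$beta <- withr::with_seed(seed + 1, rnorm(nrow(outcome), 0, 0.05))
    outcome$pval <- 0.5
    h <- harmonize_data(screened, outcome)
    aud <- mr_audit(h)
    expect_setequal(aud$snp, df$snp)
    expect_equal(anyDuplicated(aud$snp), 0L, label = paste("seed", seed))
    expect_true(all(aud$action %in% c("kept", "proxied", "dropped")))
  }
})

test_that("stored F statistics always equal beta_exp^2 / se_exp^2", {
  for (seed in 1:5) {
    ds <- random_mr_data(8, seed)
    expect_equal(ds$f_stat, (ds$beta_exp / ds$se_exp)^2, tolerance = 1e-14)
  }
})
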