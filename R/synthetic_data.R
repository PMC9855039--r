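# Synthetic two-sample GWAS generator with known ground truth. Two
# non-overlapping cohorts are simulated: an exposure cohort with a
# continuous trait and an outcome cohort with a binary (logistic) disorder,
# so outcome effects are log-odds as in case-control GWASs. A summary-level
# (asymptotic) generator is also provided for fast method-calibration
# studies.

#' Pleiotropy architectures for simulation scenarios
#'
#' Constructors for the `pleiotropy` field of [sim_scenario()]: direct
#' (horizontal) per-SNP effects `alpha_j` of instruments on the outcome.
#'
#' * `pleio_none()`: all `alpha_j = 0` (valid instruments).
#' * `pleio_balanced(sd)`: `alpha_j ~ N(0, sd^2)` (zero-mean pleiotropy,
#'   which leaves IVW consistent).
#' * `pleio_directional(mean, sd, prop)`: a fraction `prop` of instruments
#'   receive `alpha_j ~ N(mean, sd^2)` (biases IVW; with `prop = 1` and
#'   InSIDE holding, MR-Egger remains consistent).
#' * `pleio_outlier(effect, index)`: a single instrument receives a fixed
#'   direct effect; `effect = NULL` defaults to 10 times that SNP's
#'   approximate outcome-GWAS standard error.
#'
#' @param sd,mean Normal parameters of the pleiotropic effects (log-odds
#'   per allele).
#' @param prop Fraction of instruments affected (first `round(prop * j)`
#'   SNPs).
#' @param effect Fixed direct effect of the outlier SNP.
#' @param index Which SNP is the outlier.
#' @return A list describing the pleiotropy model.
#' @name pleiotropy-models
NULL

#' @rdname pleiotropy-models
#' @export
pleio_none <- function() list(model = "none")

#' @rdname pleiotropy-models
#' @export
pleio_balanced <- function(sd = 0.05) list(model = "balanced", sd = sd)

#' @rdname pleiotropy-models
#' @export
pleio_directional <- function(mean = 0.02, sd = 0.01, prop = 1) {
  list(model = "directional", mean = mean, sd = sd, prop = prop)
}

#' @rdname pleiotropy-models
#' @export
pleio_outlier <- function(effect = NULL, index = 1) {
  list(model = "single_outlier", effect = effect, index = index)
}

#' Define a simulation scenario
#'
#' Ground-truth generative parameters for a pair of non-overlapping GWAS
#' cohorts: genotypes are Hardy-Weinberg draws `G ~ Binomial(2, maf)`, the
#' exposure is `X = sum(gamma_j G_j) + e` with the residual scaled so the
#' instruments jointly explain `r2_xz` of unit exposure variance, and the
#' binary outcome is `Y ~ Bernoulli(plogis(a0 + theta X + sum(alpha_j
#' G_j)))` with the intercept `a0` solved numerically to hit the target
#' prevalence. Per-SNP exposure effects default to an equal split of the
#' explained variance across instruments.
#'
#' @param n_exposure,n_outcome Cohort sizes.
#' @param j Number of instruments.
#' @param maf Minor-allele frequencies, length `j`, each in (0.01, 0.5);
#'   default an even spread over \[0.1, 0.4\].
#' @param theta True causal effect (log-odds of outcome per exposure unit).
#' @param r2_xz Fraction of exposure variance explained by the instruments.
#' @param gamma Optional per-SNP exposure effects; derived from `r2_xz`
#'   when `NULL`.
#' @param pleiotropy A pleiotropy model (see [pleio_none()]).
#' @param inside_violation If `TRUE`, pleiotropic effects are made
#'   proportional to instrument strength (violating InSIDE).
#' @param prevalence Baseline case fraction of the outcome in (0, 1).
#' @param seed Default seed for draws from this scenario.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_exposure = 50000, n_outcome = 50000, j = 10,
                         maf = NULL, theta = 0.2, r2_xz = 0.02, gamma = NULL,
                         pleiotropy = pleio_none(), inside_violation = FALSE,
                         prevalence = 0.1, seed = NULL) {
  maf <- maf %||% seq(0.1, 0.4, length.out = j)
  stopifnot(n_exposure > 0, n_outcome > 0, j >= 1, length(maf) == j)
  if (any(maf <= 0.01 | maf >= 0.5)) {
    abort("minor-allele frequencies must lie in (0.01, 0.5)",
          class = "mrpipe_validation_error")
  }
  assert_scalar_prob(prevalence, "prevalence")
  if (r2_xz <= 0 || r2_xz >= 1) {
    abort("r2_xz must lie in (0, 1): instruments cannot explain all exposure variance",
          class = "mrpipe_validation_error")
  }
  v_g <- 2 * maf * (1 - maf)
  if (is.null(gamma)) {
    gamma <- sqrt((r2_xz / j) / v_g)
  } else {
    stopifnot(length(gamma) == j)
    r2_xz <- sum(gamma^2 * v_g)
    if (r2_xz >= 1) {
      abort("infeasible gamma: instruments would explain >= 100% of exposure variance",
            class = "mrpipe_validation_error")
    }
  }
  structure(list(n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome), j = as.integer(j),
                 maf = maf, theta = theta, r2_xz = r2_xz, gamma = gamma,
                 pleiotropy = pleiotropy, inside_violation = inside_violation,
                 prevalence = prevalence, seed = seed),
            class = "sim_scenario")
}

#' Named scenario presets
#'
#' Four reference scenarios used throughout the package's validation:
#' `"valid"` (no pleiotropy), `"balanced"` (zero-mean pleiotropy, SD 0.05),
#' `"directional"` (all instruments, mean 0.02, SD 0.01) and `"outlier"`
#' (one grossly pleiotropic SNP). All share theta = 0.2, J = 10, 50k/50k
#' cohorts, r2 = 0.02 and prevalence 0.1; any field can be overridden via
#' `...`.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
sim_preset <- function(name = c("valid", "balanced", "directional", "outlier"),
                       ...) {
  name <- match.arg(name)
  pl <- switch(name,
               valid = pleio_none(),
               balanced = pleio_balanced(sd = 0.05),
               directional = pleio_directional(mean = 0.02, sd = 0.01),
               outlier = pleio_outlier())
  args <- modifyList(list(pleiotropy = pl), list(...))
  do.call(sim_scenario, args)
}

# Approximate outcome-GWAS SE of a per-allele log-odds effect.
approx_se_out <- function(scenario) {
  v_g <- 2 * scenario$maf * (1 - scenario$maf)
  1 / sqrt(scenario$n_outcome * scenario$prevalence *
             (1 - scenario$prevalence) * v_g)
}

# Draw the realized per-SNP direct effects alpha_j (uses the current RNG
# stream; callers wrap in with_seed()).
draw_pleiotropy <- function(scenario) {
  j <- scenario$j
  pl <- scenario$pleiotropy
  alpha <- switch(pl$model,
    none = rep(0, j),
    balanced = rnorm(j, 0, pl$sd),
    directional = {
      a <- rep(0, j)
      n_aff <- max(1L, round((pl$prop %||% 1) * j))
      a[seq_len(n_aff)] <- rnorm(n_aff, pl$mean, pl$sd)
      a
    },
    single_outlier = {
      a <- rep(0, j)
      eff <- pl$effect %||% (10 * approx_se_out(scenario)[pl$index])
      a[pl$index] <- eff
      a
    },
    abort(glue::glue("unknown pleiotropy model: {pl$model}"),
          class = "mrpipe_config_error")
  )
  if (isTRUE(scenario$inside_violation)) {
    # couple direct effects to instrument strength (InSIDE violated)
    alpha <- alpha * scenario$gamma / mean(scenario$gamma)
  }
  alpha
}

snp_ids <- function(j) sprintf("rs%04d", seq_len(j))

# Maximum-likelihood marginal logistic regression of y on each genotype
# column, all SNPs updated together by Newton (Fisher-scoring) steps on the
# per-SNP 2x2 normal equations. This is the same iteration stats::glm()
# performs for intercept + dosage; solving all columns in one pass keeps
# large simulation studies fast. Columns that fail to converge fall back to
# stats::glm.fit and are flagged if that also fails.
logistic_gwas <- function(g, y, tol = 1e-8, maxit = 25) {
  n <- nrow(g); j <- ncol(g)
  storage.mode(g) <- "double"
  g2 <- g^2
  py <- mean(y)
  b0 <- rep(log(py / (1 - py)), j)
  b1 <- rep(0, j)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- g * rep(b1, each = n)
    eta <- eta + rep(b0, each = n)
    mu <- plogis(eta)
    res <- y - mu
    w <- mu * (1 - mu)
    s0 <- colSums(res)
    s1 <- colSums(g * res)
    i00 <- colSums(w)
    i01 <- colSums(g * w)
    i11 <- colSums(g2 * w)
    det <- i00 * i11 - i01^2
    d0 <- (i11 * s0 - i01 * s1) / det
    d1 <- (i00 * s1 - i01 * s0) / det
    b0 <- b0 + d0
    b1 <- b1 + d1
    if (max(pmax(abs(d0), abs(d1))) < tol) {
      converged <- TRUE
      break
    }
  }
  converged <- rep(converged, j) & is.finite(b1)
  # final information for SEs at the solution
  eta <- sweep(g * rep(b1, each = n), 2, b0, "+")
  w <- plogis(eta) * (1 - plogis(eta))
  i00 <- colSums(w); i01 <- colSums(g * w); i11 <- colSums(g2 * w)
  se <- sqrt(i00 / (i00 * i11 - i01^2))
  for (k in which(!converged)) {
    f <- tryCatch(suppressWarnings(
      stats::glm.fit(cbind(1, g[, k]), y, family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      mu <- f$fitted.values
      info <- crossprod(cbind(1, g[, k]), cbind(1, g[, k]) * (mu * (1 - mu)))
      b1[k] <- f$coefficients[2]
      se[k] <- sqrt(diag(solve(info)))[2]
      converged[k] <- TRUE
    }
  }
  list(beta = b1, se = se, converged = converged)
}

#' Simulate the two non-overlapping GWAS cohorts
#'
#' Draws the exposure cohort (genotypes plus continuous trait) and the
#' outcome cohort (independent genotypes, latent exposure, and binary
#' disease status) of a scenario. The logistic intercept is solved
#' numerically on the realized linear predictor so the case fraction hits
#' the target prevalence.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Seed (defaults to `scenario$seed`).
#' @return A list of class `mr_cohorts` with elements `exposure`
#'   (`genotypes`, `trait`), `outcome` (`genotypes`, `trait`), and `truth`
#'   (realized `alpha`, `gamma`, `theta`, `alpha0`, case fraction).
#' @export
simulate_cohorts <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- seed %||% scenario$seed
  if (is.null(seed)) {
    abort("a seed is required to simulate cohorts", class = "mrpipe_config_error")
  }
  with_seed(seed, {
    j <- scenario$j
    ids <- snp_ids(j)
    alpha <- draw_pleiotropy(scenario)
    sd_e <- sqrt(1 - scenario$r2_xz)

    draw_geno <- function(n) {
      g <- vapply(scenario$maf, function(m) rbinom(n, 2L, m), integer(n))
      colnames(g) <- ids
      g
    }
    g_exp <- draw_geno(scenario$n_exposure)
    x_exp <- as.vector(g_exp %*% scenario$gamma) +
      rnorm(scenario$n_exposure, 0, sd_e)

    g_out <- draw_geno(scenario$n_outcome)
    x_out <- as.vector(g_out %*% scenario$gamma) +
      rnorm(scenario$n_outcome, 0, sd_e)
    lp <- scenario$theta * x_out + as.vector(g_out %*% alpha)
    a0 <- uniroot(function(a) mean(plogis(a + lp)) - scenario$prevalence,
                  c(-40, 40))$root
    y <- rbinom(scenario$n_outcome, 1L, plogis(a0 + lp))

    structure(list(
      exposure = list(genotypes = g_exp, trait = x_exp),
      outcome = list(genotypes = g_out, trait = y),
      truth = list(alpha = alpha, gamma = scenario$gamma,
                   theta = scenario$theta, alpha0 = a0,
                   case_fraction = mean(y), r2_xz = scenario$r2_xz,
                   seed = seed),
      scenario = scenario
    ), class = "mr_cohorts")
  })
}

#' Per-SNP marginal GWAS of a simulated cohort
#'
#' Regresses the trait on each SNP's genotype dosage separately: ordinary
#' least squares for a continuous trait, maximum-likelihood logistic
#' regression for a binary trait (so effects are log-odds per allele).
#' Monomorphic SNPs and non-converged logistic fits are excluded with a
#' warning.
#'
#' @param sample One cohort from [simulate_cohorts()] (a list with
#'   `genotypes` and `trait`).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_id Optional trait label.
#' @return A validated summary-statistics tibble (canonical dialect).
#' @export
summarize_gwas <- function(sample, trait_type = c("continuous", "binary"),
                           trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  g <- sample$genotypes
  y <- sample$trait
  stopifnot(is.matrix(g), nrow(g) == length(y))
  n <- nrow(g)
  ids <- colnames(g) %||% snp_ids(ncol(g))
  eaf <- colMeans(g) / 2
  mono <- eaf <= 0 | eaf >= 1
  if (any(mono)) {
    warn(glue::glue("excluding monomorphic SNP(s): {paste(ids[mono], collapse = ', ')}"))
  }
  keep <- !mono
  if (trait_type == "continuous") {
    gk <- g[, keep, drop = FALSE]
    sg <- colSums(gk); sgg <- colSums(gk^2)
    sy <- sum(y); syy <- sum(y^2)
    sgy <- as.vector(crossprod(gk, y))
    sxx <- sgg - sg^2 / n
    sxy <- sgy - sg * sy / n
    syy_c <- syy - sy^2 / n
    beta <- sxy / sxx
    rss <- pmax(syy_c - beta * sxy, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    pval <- 2 * pt(-abs(beta / se), df = n - 2)
    est <- tibble(snp = ids[keep], beta = beta, se = se, pval = pval)
  } else {
    fit <- logistic_gwas(g[, keep, drop = FALSE], y)
    failed <- ids[keep][!fit$converged]
    if (length(failed) > 0) {
      warn(glue::glue("excluding non-converged logistic fit(s): {paste(failed, collapse = ', ')}"))
    }
    est <- tibble(snp = ids[keep][fit$converged],
                  beta = fit$beta[fit$converged],
                  se = fit$se[fit$converged],
                  pval = 2 * pnorm(-abs(fit$beta / fit$se))[fit$converged])
  }
  est$pval <- pmax(est$pval, .Machine$double.xmin)
  out <- tibble(snp = est$snp, effect_allele = "A", other_allele = "G",
                eaf = eaf[match(est$snp, ids)], beta = est$beta, se = est$se,
                pval = est$pval, n = n,
                trait_id = trait_id %||% trait_type)
  validate_sumstats(out, source = "simulated GWAS")
}

#' Simulate, summarize and write a two-sample dataset
#'
#' End-to-end wrapper: simulates both cohorts, runs the per-SNP GWASs, and
#' writes the exposure and outcome summary-statistics TSVs (readable by
#' [read_sumstats()]) plus a ground-truth JSON. Byte-identical for the same
#' scenario and seed.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Seed (defaults to `scenario$seed`).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return A list with `exposure_path`, `outcome_path`, `truth_path`, and
#'   the realized `truth`.
#' @export
make_two_sample_dataset <- function(scenario, seed = NULL, dir = tempfile(),
                                    prefix = "synthetic") {
  seed <- seed %||% scenario$seed
  cohorts <- simulate_cohorts(scenario, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  exp_ss <- summarize_gwas(cohorts$exposure, "continuous", trait_id = "exposure")
  out_ss <- summarize_gwas(cohorts$outcome, "binary", trait_id = "outcome")
  exposure_path <- file.path(dir, paste0(prefix, "_exposure.tsv"))
  outcome_path <- file.path(dir, paste0(prefix, "_outcome.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_sumstats(exp_ss, exposure_path)
  write_sumstats(out_ss, outcome_path)
  jsonlite::write_json(cohorts$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  list(exposure_path = exposure_path, outcome_path = outcome_path,
       truth_path = truth_path, truth = cohorts$truth)
}

#' Summary-level (asymptotic) two-sample simulation
#'
#' Draws harmonized per-SNP effect pairs directly from their large-sample
#' distributions: `beta_exp_j ~ N(gamma_j, se_exp_j)` and `beta_out_j ~
#' N(theta gamma_j + alpha_j, se_out_j)`, with standard errors implied by
#' the scenario's cohort sizes, allele frequencies and prevalence. This
#' skips individual-level data, making large calibration studies of the
#' estimators cheap, at the cost of the finite-sample features (logistic
#' noncollapsibility, estimated SEs) the cohort simulator retains.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Seed (defaults to `scenario$seed`).
#' @return An `mr_dataset` with a `truth` attribute (realized `alpha`,
#'   `gamma`, `theta`).
#' @export
simulate_sumstats <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- seed %||% scenario$seed
  if (is.null(seed)) {
    abort("a seed is required to simulate summary statistics",
          class = "mrpipe_config_error")
  }
  with_seed(seed, {
    j <- scenario$j
    v_g <- 2 * scenario$maf * (1 - scenario$maf)
    se_exp <- sqrt(pmax(1 - scenario$gamma^2 * v_g, 1e-12) /
                     (scenario$n_exposure * v_g))
    se_out <- approx_se_out(scenario)
    alpha <- draw_pleiotropy(scenario)
    inst <- tibble(
      snp = snp_ids(j), effect_allele = "A", other_allele = "G",
      beta_exp = rnorm(j, scenario$gamma, se_exp), se_exp = se_exp,
      eaf = scenario$maf,
      beta_out = rnorm(j, scenario$theta * scenario$gamma + alpha, se_out),
      se_out = se_out, eaf_out = scenario$maf,
      proxy_of = NA_character_, flipped = FALSE
    )
    ds <- new_mr_dataset(inst, exposure_id = "sim_exposure",
                         outcome_id = "sim_outcome", database_id = "sim")
    attr(ds, "truth") <- list(alpha = alpha, gamma = scenario$gamma,
                              theta = scenario$theta, seed = seed)
    ds
  })
}

#' Write / read a scenario as YAML
#'
#' @param scenario A `sim_scenario`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_scenario()` returns a `sim_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  yaml::write_yaml(unclass(scenario), path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(sim_scenario)))]
  if (!is.null(args$maf)) args$maf <- as.numeric(args$maf)
  if (!is.null(args$gamma)) args$gamma <- as.numeric(args$gamma)
  do.call(sim_scenario, args)
}

#' Replicate a scenario end-to-end and collect estimator results
#'
#' Draws `n_reps` independent datasets from a scenario — at summary level
#' or as full cohorts run through the GWAS and harmonization steps — and
#' applies the requested estimators to each, returning one tidy row per
#' (replicate, method). This is the engine behind the package's
#' calibration and robustness studies (type-I error, bias, CI coverage,
#' method orderings under pleiotropy).
#'
#' @param scenario A `sim_scenario`.
#' @param n_reps Number of independent replicates.
#' @param seed Master seed; each replicate derives its own stream.
#' @param level `"summary"` (fast, asymptotic) or `"cohort"`
#'   (individual-level simulation, per-SNP GWAS, harmonization).
#' @param methods Character vector among `"ivw"` (auto fixed/random),
#'   `"ivw_fe"`, `"egger"`, `"weighted_median"`, `"max_likelihood"`,
#'   `"intercept_test"` (the Egger-intercept pleiotropy test; its
#'   intercept and p-value fill the `beta`/`pval` columns).
#' @param n_boot Bootstrap size for the weighted median.
#' @return A tibble with columns `rep`, the [glance()] columns, and the
#'   scenario's true effect in `theta_true`.
#' @export
mr_replicate_study <- function(scenario, n_reps, seed,
                               level = c("summary", "cohort"),
                               methods = "ivw", n_boot = 500) {
  level <- match.arg(level)
  stopifnot(inherits(scenario, "sim_scenario"), n_reps >= 1)
  known <- c("ivw", "ivw_fe", "egger", "weighted_median", "max_likelihood",
             "intercept_test")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    abort(glue::glue("unknown method(s): {paste(bad, collapse = ', ')}"),
          class = "mrpipe_config_error")
  }
  purrr::map_dfr(seq_len(n_reps), function(r) {
    rs <- derive_seed(seed, paste0("rep-", r))
    ds <- if (level == "summary") {
      simulate_sumstats(scenario, seed = rs)
    } else {
      co <- simulate_cohorts(scenario, seed = rs)
      harmonize_data(summarize_gwas(co$exposure, "continuous",
                                    trait_id = "exposure"),
                     summarize_gwas(co$outcome, "binary",
                                    trait_id = "outcome"))
    }
    purrr::map_dfr(methods, function(m) {
      row <- switch(m,
        ivw = glance(mr_ivw(ds, effect_model = "auto")),
        ivw_fe = glance(mr_ivw(ds, effect_model = "fixed")),
        egger = glance(mr_egger(ds)),
        weighted_median = glance(mr_weighted_median(
          ds, n_boot = n_boot, seed = derive_seed(rs, m))),
        max_likelihood = glance(mr_max_likelihood(ds)),
        intercept_test = {
          it <- egger_intercept_test(ds)
          tibble(method = "intercept_test", nsnp = it$nsnp,
                 beta = it$intercept, se = it$se,
                 ci_low = NA_real_, ci_high = NA_real_, pval = it$pval,
                 or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
                 q = NA_real_, q_pval = NA_real_, i2 = NA_real_,
                 egger_intercept = it$intercept,
                 egger_intercept_p = it$pval)
        })
      dplyr::mutate(row, rep = r, theta_true = scenario$theta, .before = 1)
    })
  })
}
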