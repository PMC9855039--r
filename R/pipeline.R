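# Orchestration of the full per-(exposure, outcome) decision tree:
# per-database estimation with method selection, sensitivity suite,
# outlier-removal re-analysis, cross-database meta-analysis and evidence
# classification.

#' Analysis configuration
#'
#' Collects every threshold and stochastic setting of a study run. Defaults
#' follow the standard two-sample MR workflow: genome-wide instrument
#' significance 5e-8, clumping at r2 = 0.001 within 10,000 kb, F > 10,
#' heterogeneity and pleiotropy gates at 0.05, family-wise alpha 0.05
#' Bonferroni-split across the exposure-outcome grid.
#'
#' @param p_instrument Instrument significance threshold.
#' @param clump_r2,clump_kb LD clumping parameters.
#' @param f_min Weak-instrument F threshold (strictly-greater rule).
#' @param conf_p Confounder-screen significance threshold.
#' @param proxy_r2_min Minimum proxy LD.
#' @param palindrome_policy `"infer"` or `"drop"`.
#' @param q_alpha Cochran's-Q significance level deciding fixed vs random
#'   IVW and fixed vs random meta-analysis.
#' @param intercept_alpha Significance level of the Egger-intercept
#'   pleiotropy gate.
#' @param outlier_alpha MR-PRESSO outlier threshold (Bonferroni-adjusted).
#' @param alpha_family Family-wise error rate.
#' @param m_tests Number of tests for the Bonferroni split; `NULL` derives
#'   `n_exposures * n_outcomes` from the study inputs.
#' @param n_boot Bootstrap resamples for Egger / weighted-median SEs.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Master seed; every stochastic step derives its own child
#'   seed from it, so a run is fully reproducible.
#' @param inputs Optional tibble of study inputs for [run_study()], one row
#'   per (exposure, outcome, database): columns `exposure_id, outcome_id,
#'   database_id, exposure_path, outcome_path` and optional `ld_path,
#'   confounder_path, proxy_path`.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_instrument = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                      f_min = 10, conf_p = 5e-8, proxy_r2_min = 0.8,
                      palindrome_policy = "infer",
                      q_alpha = 0.05, intercept_alpha = 0.05,
                      outlier_alpha = 0.05, alpha_family = 0.05,
                      m_tests = NULL, n_boot = 1000, n_sim = 1000,
                      seed = 1L, inputs = NULL) {
  assert_scalar_prob(p_instrument, "p_instrument")
  assert_scalar_prob(q_alpha, "q_alpha")
  assert_scalar_prob(intercept_alpha, "intercept_alpha")
  assert_scalar_prob(outlier_alpha, "outlier_alpha")
  assert_scalar_prob(alpha_family, "alpha_family")
  assert_scalar_prob(conf_p, "conf_p")
  stopifnot(clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0, f_min > 0,
            proxy_r2_min >= 0, proxy_r2_min <= 1, n_boot >= 2, n_sim >= 2)
  if (is.null(seed)) {
    abort("a master seed is required (bootstraps and MR-PRESSO are stochastic)",
          class = "mrpipe_config_error")
  }
  if (!is.null(inputs)) {
    assert_columns(inputs, c("exposure_id", "outcome_id", "database_id",
                             "exposure_path", "outcome_path"),
                   what = "study inputs")
  }
  structure(list(p_instrument = p_instrument, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min, conf_p = conf_p,
                 proxy_r2_min = proxy_r2_min,
                 palindrome_policy = palindrome_policy, q_alpha = q_alpha,
                 intercept_alpha = intercept_alpha,
                 outlier_alpha = outlier_alpha, alpha_family = alpha_family,
                 m_tests = m_tests, n_boot = n_boot, n_sim = n_sim,
                 seed = as.integer(seed), inputs = inputs),
            class = "mr_config")
}

triple_label <- function(data) {
  paste(attr(data, "exposure_id") %||% "exposure",
        attr(data, "outcome_id") %||% "outcome",
        attr(data, "database_id") %||% "db", sep = "|")
}

not_evaluable_row <- function(method, nsnp, reason) {
  tibble(method = method, status = "not evaluable", nsnp = nsnp,
         beta = NA_real_, se = NA_real_, ci_low = NA_real_,
         ci_high = NA_real_, pval = NA_real_, or = NA_real_,
         or_ci_low = NA_real_, or_ci_high = NA_real_, note = reason)
}

estimate_row <- function(est, status = "ok") {
  tibble(method = est$method, status = status, nsnp = est$nsnp,
         beta = est$beta, se = est$se, ci_low = est$ci_low,
         ci_high = est$ci_high, pval = est$pval, or = est$or,
         or_ci_low = est$or_ci_low, or_ci_high = est$or_ci_high,
         note = NA_character_)
}

#' Analyze one (exposure, outcome, database) dataset
#'
#' Applies the method-selection decision tree: a single instrument gives
#' the Wald ratio; with 3 or more instruments a significant Egger-intercept
#' test routes the primary analysis to MR-Egger with bootstrapped SEs;
#' otherwise the primary analysis is IVW, fixed- or random-effect according
#' to the Cochran's Q p-value. The sensitivity suite runs the estimators
#' their instrument counts allow (likelihood-based MR for J > 1, weighted
#' median for J > 2, MR-PRESSO for J > 3, leave-one-out for J >= 2);
#' methods below their gate are reported explicitly as not evaluable.
#'
#' @param data A harmonized `mr_dataset` (or compatible tibble).
#' @param cfg An [mr_config()].
#' @return A list of class `mr_analysis`: `primary` (an `mr_estimate`),
#'   `primary_reason` (which branch fired), `sensitivity` (tidy tibble of
#'   all methods incl. not-evaluable markers), `intercept_test`, `presso`,
#'   `loo`, and `nsnp`.
#' @export
analyze_triple <- function(data, cfg = mr_config()) {
  j <- nrow(data)
  if (j == 0) {
    aud <- mr_audit(data)
    detail <- if (nrow(aud) > 0) {
      paste0(": ", paste(glue::glue("{aud$snp} ({aud$reason})"), collapse = "; "))
    } else ""
    abort(paste0("no instruments left for ", triple_label(data), detail),
          class = "mrpipe_empty_dataset")
  }
  label <- triple_label(data)
  it <- egger_intercept_test(data, alpha = cfg$intercept_alpha)
  if (j == 1) {
    primary <- mr_wald_ratio(data)
    reason <- "single instrument: Wald ratio"
  } else if (isTRUE(it$evaluable) && isTRUE(it$pleiotropy)) {
    primary <- mr_egger(data, se_method = "bootstrap", n_boot = cfg$n_boot,
                        seed = derive_seed(cfg$seed, paste0(label, "|egger")))
    reason <- "Egger intercept test significant: MR-Egger with bootstrap SE"
  } else {
    primary <- mr_ivw(data, effect_model = "auto", q_alpha = cfg$q_alpha)
    reason <- if (primary$method == "ivw_re") {
      "no pleiotropy flag; significant heterogeneity: random-effect IVW"
    } else {
      "no pleiotropy flag; no significant heterogeneity: fixed-effect IVW"
    }
  }

  sens <- list(estimate_row(primary, status = "primary"))
  sens <- c(sens, list(
    if (j >= 2) {
      estimate_row(mr_max_likelihood(data))
    } else {
      not_evaluable_row("max_likelihood", j, "requires more than 1 SNP")
    },
    if (j >= 3) {
      estimate_row(mr_weighted_median(data, n_boot = cfg$n_boot,
                                      seed = derive_seed(cfg$seed, paste0(label, "|wm"))))
    } else {
      not_evaluable_row("weighted_median", j, "requires more than 2 SNPs")
    }
  ))
  presso <- mr_presso(data, n_sim = cfg$n_sim,
                      outlier_alpha = cfg$outlier_alpha,
                      seed = derive_seed(cfg$seed, paste0(label, "|presso")))
  if (presso$status == "ok") {
    sens <- c(sens, list(estimate_row(presso$estimate_all) |>
                           dplyr::mutate(method = "presso_raw")))
  } else {
    sens <- c(sens, list(not_evaluable_row("presso", j, "requires more than 3 SNPs")))
  }
  loo <- if (j >= 2) mr_leave_one_out(data, q_alpha = cfg$q_alpha) else NULL
  plot_tables <- mr_plot_tables(data, list(primary))

  structure(list(primary = primary, primary_reason = reason,
                 sensitivity = dplyr::bind_rows(sens),
                 intercept_test = it, presso = presso, loo = loo,
                 plot_tables = plot_tables,
                 nsnp = j, label = label,
                 exposure_id = attr(data, "exposure_id"),
                 outcome_id = attr(data, "outcome_id"),
                 database_id = attr(data, "database_id")),
            class = "mr_analysis")
}

#' Re-analyze a dataset after removing MR-PRESSO outliers
#'
#' @param data The harmonized dataset.
#' @param presso_result An `mr_presso` result for `data`.
#' @param cfg An [mr_config()].
#' @return A list `removed` (SNP ids), `before`, `after` (both
#'   `mr_analysis`; `after` is `NULL` when there was nothing to remove or
#'   removal would empty the dataset).
#' @export
rerun_without_outliers <- function(data, presso_result, cfg = mr_config()) {
  before <- analyze_triple(data, cfg)
  if (presso_result$status != "ok" || length(presso_result$outliers) == 0) {
    return(list(removed = character(0), before = before, after = NULL))
  }
  keep <- !data$snp %in% presso_result$outliers
  if (!any(keep)) {
    warn("removing all flagged outliers would leave no instruments; keeping original results")
    return(list(removed = character(0), before = before, after = NULL))
  }
  reduced <- data[keep, , drop = FALSE]
  for (a in c("exposure_id", "outcome_id", "database_id")) {
    attr(reduced, a) <- attr(data, a)
  }
  list(removed = presso_result$outliers, before = before,
       after = analyze_triple(reduced, cfg))
}

#' Classify pooled evidence against the multiple-testing rule
#'
#' `significant` when the pooled p-value is below `alpha_family / m`;
#' `suggestive` when it lies in \[threshold, 0.05); `null` otherwise. The
#' three bands partition (0, 1].
#'
#' @param pval Pooled p-value(s).
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param m Number of tests.
#' @return Character vector of labels.
#' @export
classify_evidence <- function(pval, alpha_family = 0.05, m = 1) {
  thr <- alpha_family / m
  dplyr::case_when(pval < thr ~ "significant",
                   pval < 0.05 ~ "suggestive",
                   TRUE ~ "null")
}

#' Pool per-database estimates and classify the evidence
#'
#' Meta-analyzes the per-database primary estimates (fixed effects, or
#' DerSimonian-Laird random effects when the between-database Q is
#' significant at `q_alpha`) and classifies the pooled p-value.
#'
#' @param estimates List of `mr_estimate` objects (or a tibble with `beta`,
#'   `se`), one per database.
#' @param cfg An [mr_config()]; `m_tests` must be set (or supplied via
#'   `m`).
#' @param m Number of tests (defaults to `cfg$m_tests`, then 1).
#' @return A list `meta` (`mr_meta`) and `evidence` (one-row tibble
#'   `label, pval, threshold, alpha_family, m`).
#' @export
pool_and_classify <- function(estimates, cfg = mr_config(), m = NULL) {
  meta <- meta_pool(estimates, model = "auto", q_alpha = cfg$q_alpha)
  m <- m %||% cfg$m_tests %||% 1
  thr <- bonferroni_threshold(cfg$alpha_family, m)
  list(meta = meta,
       evidence = tibble(label = classify_evidence(meta$pval,
                                                   cfg$alpha_family, m),
                         pval = meta$pval, threshold = thr$threshold,
                         alpha_family = cfg$alpha_family, m = as.integer(m)))
}

read_optional <- function(path, reader) {
  if (is.null(path) || is.na(path) || !nzchar(path)) NULL else reader(path)
}

build_triple_dataset <- function(row, cfg) {
  exposure <- read_sumstats(row$exposure_path, trait_id = row$exposure_id)
  outcome <- read_sumstats(row$outcome_path, trait_id = row$outcome_id)
  inst <- select_significant(exposure, cfg$p_instrument)
  ld <- read_optional(row$ld_path %||% NA, function(p)
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE))
  if (!is.null(ld)) {
    inst <- ld_clump(inst, ld, r2_max = cfg$clump_r2, window_kb = cfg$clump_kb)
  }
  conf <- read_optional(row$confounder_path %||% NA, read_confounder_table)
  if (!is.null(conf)) inst <- screen_confounders(inst, conf, p_conf = cfg$conf_p)
  proxies <- read_optional(row$proxy_path %||% NA, read_proxy_table)
  ds <- harmonize_data(inst, outcome, proxies = proxies,
                       palindrome_policy = cfg$palindrome_policy,
                       r2_min = cfg$proxy_r2_min,
                       exposure_id = row$exposure_id,
                       outcome_id = row$outcome_id,
                       database_id = row$database_id)
  filter_weak_ds <- filter_weak(ds, f_min = cfg$f_min)
  for (a in c("exposure_id", "outcome_id", "database_id")) {
    attr(filter_weak_ds, a) <- attr(ds, a)
  }
  filter_weak_ds
}

#' Run a full multi-database MR study
#'
#' For every (exposure, outcome, database) row of `cfg$inputs`: reads the
#' summary statistics, builds the harmonized instrument set (significance
#' filter, optional LD clumping and confounder screen, proxy substitution,
#' harmonization, F filter), and runs [analyze_triple()]. Primary estimates
#' are then pooled per (exposure, outcome) across whichever databases
#' succeeded, and the pooled p-value classified against the Bonferroni
#' rule (`m_tests` defaults to the number of exposures times the number of
#' outcomes in the grid). Databases whose dataset ends up empty degrade to
#' a warning and a meta-analysis over the remaining sources.
#'
#' The run is deterministic given the config and master seed; when
#' `out_dir` is given, tidy TSVs (`per_database`, `sensitivity`, `meta`,
#' `evidence`, `leave_one_out`, `presso_summary`, `presso_outliers`,
#' `audit`, and the scatter/forest/funnel plot tables) plus a
#' `manifest.json` recording inputs, thresholds and seeds are written
#' there.
#'
#' @param cfg An [mr_config()] with `inputs`.
#' @param out_dir Optional output directory.
#' @return A list of class `mr_study`: `per_database`, `sensitivity`,
#'   `meta`, `evidence`, `analyses` (named list of `mr_analysis`),
#'   `failures`, `manifest`.
#' @export
run_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "mr_config"))
  if (is.null(cfg$inputs)) {
    abort("cfg$inputs is required to run a study", class = "mrpipe_config_error")
  }
  inputs <- as_tibble(cfg$inputs)
  missing_files <- inputs$exposure_path[!file.exists(inputs$exposure_path)]
  missing_files <- c(missing_files,
                     inputs$outcome_path[!file.exists(inputs$outcome_path)])
  if (length(missing_files) > 0) {
    abort(paste0("missing input file(s):\n",
                 paste(" -", unique(missing_files), collapse = "\n")),
          class = "mrpipe_io_error")
  }
  m_tests <- cfg$m_tests %||%
    (dplyr::n_distinct(inputs$exposure_id) * dplyr::n_distinct(inputs$outcome_id))

  analyses <- list()
  failures <- tibble(exposure_id = character(), outcome_id = character(),
                     database_id = character(), error = character())
  for (i in seq_len(nrow(inputs))) {
    row <- as.list(inputs[i, ])
    key <- paste(row$exposure_id, row$outcome_id, row$database_id, sep = "|")
    res <- tryCatch({
      ds <- build_triple_dataset(row, cfg)
      analyze_triple(ds, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warn(glue::glue("analysis failed for {key}: {conditionMessage(res)}"))
      failures <- dplyr::bind_rows(failures, tibble(
        exposure_id = row$exposure_id, outcome_id = row$outcome_id,
        database_id = row$database_id, error = conditionMessage(res)))
    } else {
      analyses[[key]] <- res
    }
  }

  if (length(analyses) == 0) {
    abort(paste0("every database analysis failed:\n",
                 paste(" -", failures$database_id, failures$error,
                       collapse = "\n")),
          class = "mrpipe_empty_dataset")
  }
  per_database <- purrr::map_dfr(analyses, function(a) {
    dplyr::bind_cols(tibble(exposure_id = a$exposure_id,
                            outcome_id = a$outcome_id,
                            database_id = a$database_id),
                     glance(a$primary),
                     tibble(primary_reason = a$primary_reason))
  })
  sensitivity <- purrr::map_dfr(analyses, function(a) {
    dplyr::bind_cols(tibble(exposure_id = a$exposure_id,
                            outcome_id = a$outcome_id,
                            database_id = a$database_id)[rep(1, nrow(a$sensitivity)), ],
                     a$sensitivity)
  })

  pairs <- unique(per_database[c("exposure_id", "outcome_id")])
  meta_rows <- list(); evidence_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    sel <- purrr::keep(analyses, function(a) {
      a$exposure_id == pairs$exposure_id[i] && a$outcome_id == pairs$outcome_id[i]
    })
    pc <- pool_and_classify(purrr::map(sel, "primary"), cfg, m = m_tests)
    meta_rows[[i]] <- dplyr::bind_cols(pairs[i, ], glance(pc$meta))
    evidence_rows[[i]] <- dplyr::bind_cols(pairs[i, ], pc$evidence)
  }
  meta <- dplyr::bind_rows(meta_rows)
  evidence <- dplyr::bind_rows(evidence_rows)

  manifest <- list(
    package = "mrpipe",
    version = as.character(utils::packageVersion("mrpipe")),
    seed = cfg$seed,
    m_tests = m_tests,
    thresholds = cfg[c("p_instrument", "clump_r2", "clump_kb", "f_min",
                       "conf_p", "proxy_r2_min", "palindrome_policy",
                       "q_alpha", "intercept_alpha", "outlier_alpha",
                       "alpha_family", "n_boot", "n_sim")],
    inputs = inputs,
    failures = failures
  )
  study <- structure(list(per_database = per_database,
                          sensitivity = sensitivity, meta = meta,
                          evidence = evidence, analyses = analyses,
                          failures = failures, manifest = manifest),
                     class = "mr_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  w(study$per_database, "per_database")
  w(study$sensitivity, "sensitivity")
  w(study$meta, "meta")
  w(study$evidence, "evidence")
  diag_tabs <- list(leave_one_out = list(), presso_summary = list(),
                    presso_outliers = list(), scatter_data = list(),
                    forest_data = list(), funnel_data = list(),
                    audit = list())
  for (key in names(study$analyses)) {
    a <- study$analyses[[key]]
    id <- tibble(exposure_id = a$exposure_id, outcome_id = a$outcome_id,
                 database_id = a$database_id)
    if (!is.null(a$loo)) {
      diag_tabs$leave_one_out[[key]] <-
        dplyr::bind_cols(id[rep(1, nrow(a$loo)), ], a$loo)
    }
    diag_tabs$presso_summary[[key]] <- dplyr::bind_cols(id, glance(a$presso))
    pt <- tidy(a$presso)
    if (nrow(pt) > 0) {
      diag_tabs$presso_outliers[[key]] <- dplyr::bind_cols(id[rep(1, nrow(pt)), ], pt)
    }
    for (tab in c("scatter", "forest", "funnel")) {
      tt <- a$plot_tables[[tab]]
      diag_tabs[[paste0(tab, "_data")]][[key]] <-
        dplyr::bind_cols(id[rep(1, nrow(tt)), ], tt)
    }
  }
  for (nm in c("leave_one_out", "presso_summary", "presso_outliers",
               "scatter_data", "forest_data", "funnel_data")) {
    tab <- dplyr::bind_rows(diag_tabs[[nm]])
    if (nrow(tab) > 0) w(tab, nm)
  }
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("<mr_study> %d database analyses, %d exposure-outcome pairs\n",
              nrow(x$per_database), nrow(x$meta)))
  print(x$evidence)
  invisible(x)
}
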