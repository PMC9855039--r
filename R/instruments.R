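# Instrument construction: significance filtering, LD clumping, confounder
# screening, weak-instrument filtering, proxy substitution and allele
# harmonization. Every stage carries forward a per-SNP audit trail so each
# input variant is accounted for exactly once as kept / proxied / dropped.

empty_audit <- function() {
  tibble(snp = character(), stage = character(), action = character(),
         reason = character())
}

get_audit <- function(x) attr(x, "mr_audit") %||% empty_audit()

append_audit <- function(x, snp, stage, action, reason) {
  aud <- dplyr::bind_rows(get_audit(x),
                          tibble(snp = snp, stage = stage, action = action,
                                 reason = reason))
  aud
}

set_audit <- function(x, audit) {
  attr(x, "mr_audit") <- audit
  x
}

#' Retrieve the per-SNP audit trail of an instrument-building stage
#'
#' Each instrument-selection function records the disposition of every SNP
#' it drops (stage, action, reason); [harmonize_data()] additionally records
#' kept and proxied SNPs. The trail accumulates across chained stages.
#'
#' @param x A tibble returned by an instrument-building function.
#' @return A tibble with columns `snp, stage, action, reason`.
#' @export
mr_audit <- function(x) get_audit(x)

#' Filter variant associations by p-value significance
#'
#' Keeps exactly the rows with `pval` strictly below the threshold
#' (genome-wide significance, p < 5e-8, by default), preserving input order.
#'
#' @param assocs Tibble of variant associations.
#' @param p_threshold Significance threshold in (0, 1).
#' @return Filtered tibble; dropped SNPs are logged in the audit trail.
#' @export
select_significant <- function(assocs, p_threshold = 5e-8) {
  assert_scalar_prob(p_threshold, "p_threshold")
  assert_columns(assocs, c("snp", "pval"))
  keep <- assocs$pval < p_threshold
  out <- assocs[keep, , drop = FALSE]
  set_audit(out, append_audit(assocs, assocs$snp[!keep], "significance",
                              "dropped",
                              glue::glue("p >= {format(p_threshold)}")))
}

# Normalize an LD lookup (matrix with dimnames, or long table snp_a/snp_b/r2)
# into a query function f(snp_i, snp_j) -> r2 (0 when unknown).
ld_lookup <- function(ld) {
  if (is.null(ld)) {
    return(function(a, b) 0)
  }
  if (is.matrix(ld)) {
    stopifnot(!is.null(rownames(ld)), !is.null(colnames(ld)))
    return(function(a, b) {
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
    })
  }
  assert_columns(ld, c("snp_a", "snp_b", "r2"), what = "ld table")
  key <- c(paste(ld$snp_a, ld$snp_b), paste(ld$snp_b, ld$snp_a))
  val <- c(ld$r2, ld$r2)
  env <- new.env(parent = emptyenv())
  for (i in seq_along(key)) assign(key[i], val[i], envir = env)
  function(a, b) {
    k <- paste(a, b)
    if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else 0
  }
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining variant with the smallest p-value and
#' discards all remaining variants correlated with it above `r2_max`
#' (within `window_kb` when positions are available). Ties at equal p are
#' broken by lexicographic SNP id so the result is deterministic. Pairs
#' absent from the LD lookup are treated as r2 = 0; when the input has no
#' `chr`/`pos` columns the distance window is ignored and the r2 rule alone
#' applies.
#'
#' @param assocs Tibble of variant associations (columns `snp`, `pval`,
#'   optionally `chr` and `pos` in base pairs).
#' @param ld Pairwise r2 lookup: a symmetric matrix with SNP dimnames or a
#'   long tibble with columns `snp_a, snp_b, r2`.
#' @param r2_max LD threshold above which a variant is clumped away
#'   (default 0.001).
#' @param window_kb Clumping distance in kilobases (default 10000).
#' @return Index variants sorted by ascending p-value.
#' @export
ld_clump <- function(assocs, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  assert_columns(assocs, c("snp", "pval"))
  lk <- ld_lookup(ld)
  has_pos <- all(c("chr", "pos") %in% names(assocs))
  ord <- order(assocs$pval, assocs$snp)
  pool <- assocs[ord, , drop = FALSE]
  kept <- pool[0, , drop = FALSE]
  audit <- get_audit(assocs)
  while (nrow(pool) > 0) {
    index <- pool[1, , drop = FALSE]
    kept <- dplyr::bind_rows(kept, index)
    pool <- pool[-1, , drop = FALSE]
    if (nrow(pool) > 0) {
      in_window <- rep(TRUE, nrow(pool))
      if (has_pos) {
        in_window <- pool$chr == index$chr &
          abs(pool$pos - index$pos) <= window_kb * 1000
      }
      r2 <- vapply(pool$snp, function(s) lk(index$snp, s), numeric(1))
      clumped <- in_window & r2 > r2_max
      if (any(clumped)) {
        audit <- dplyr::bind_rows(audit, tibble(
          snp = pool$snp[clumped], stage = "clump", action = "dropped",
          reason = glue::glue("r2 > {format(r2_max)} with index {index$snp}")
        ))
        pool <- pool[!clumped, , drop = FALSE]
      }
    }
  }
  set_audit(kept, audit)
}

#' Drop variants absent from the LD reference panel
#'
#' Variants whose LD with the rest of the instrument set cannot be resolved
#' (because they are missing from the reference panel) are removed and
#' logged, mirroring pre-clumping panel screening.
#'
#' @param assocs Tibble of variant associations.
#' @param ld_panel Character vector of variant ids present in the panel.
#' @return Filtered tibble.
#' @export
drop_ld_unresolved <- function(assocs, ld_panel) {
  assert_columns(assocs, "snp")
  keep <- assocs$snp %in% ld_panel
  out <- assocs[keep, , drop = FALSE]
  set_audit(out, append_audit(assocs, assocs$snp[!keep], "ld_panel", "dropped",
                              "absent from LD reference panel"))
}

#' Screen instruments against known confounder associations
#'
#' Drops any variant with a recorded confounder association stronger than
#' `p_conf` (genome-wide significance by default); the audit names the
#' confounding trait(s).
#'
#' @param assocs Tibble of variant associations.
#' @param hits Tibble of confounder hits (`snp, trait, pval`), e.g. from
#'   [read_confounder_table()].
#' @param p_conf Confounder significance threshold in (0, 1).
#' @return Filtered tibble.
#' @export
screen_confounders <- function(assocs, hits, p_conf = 5e-8) {
  assert_scalar_prob(p_conf, "p_conf")
  assert_columns(assocs, "snp")
  if (is.null(hits) || nrow(hits) == 0) {
    return(set_audit(assocs, get_audit(assocs)))
  }
  assert_columns(hits, c("snp", "trait", "pval"), what = "confounder hits")
  sig <- hits[hits$pval < p_conf, , drop = FALSE]
  flagged <- sig |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(traits = paste(sort(unique(.data$trait)), collapse = ", "),
                     .groups = "drop")
  drop <- assocs$snp %in% flagged$snp
  out <- assocs[!drop, , drop = FALSE]
  reasons <- flagged$traits[match(assocs$snp[drop], flagged$snp)]
  set_audit(out, append_audit(assocs, assocs$snp[drop], "confounder", "dropped",
                              glue::glue("associated with confounder(s): {reasons}")))
}

#' Filter weak instruments by F-statistic
#'
#' The per-SNP instrument strength is F = beta^2 / se^2 on the exposure
#' association; instruments with F strictly greater than `f_min`
#' (conventionally 10) are retained. Accepts either harmonized instruments
#' (columns `beta_exp`/`se_exp` or a precomputed `f_stat`) or raw exposure
#' associations (`beta`/`se`).
#'
#' @param data Tibble of instruments or exposure associations.
#' @param f_min Strength threshold (default 10); strictly-greater rule.
#' @return Filtered tibble with an `f_stat` column.
#' @export
filter_weak <- function(data, f_min = 10) {
  stopifnot(f_min > 0)
  assert_columns(data, "snp")
  if (!"f_stat" %in% names(data)) {
    if (all(c("beta_exp", "se_exp") %in% names(data))) {
      data$f_stat <- (data$beta_exp / data$se_exp)^2
    } else {
      assert_columns(data, c("beta", "se"))
      data$f_stat <- (data$beta / data$se)^2
    }
  }
  keep <- data$f_stat > f_min
  out <- data[keep, , drop = FALSE]
  set_audit(out, append_audit(data, data$snp[!keep], "f_filter", "dropped",
                              glue::glue("weak instrument: F <= {format(f_min)}")))
}

#' Choose proxy SNPs for variants missing from the outcome GWAS
#'
#' For each missing SNP, selects the highest-r2 proxy with `r2 >= r2_min`
#' that is present in the outcome GWAS; ties at equal r2 are broken by
#' lexicographic proxy id. Missing SNPs with no adequate proxy are marked
#' for exclusion.
#'
#' @param missing Character vector of SNP ids absent from the outcome GWAS.
#' @param proxies Proxy table (see [read_proxy_table()]).
#' @param available Character vector of SNP ids present in the outcome GWAS.
#' @param r2_min Minimum LD between proxy and missing SNP (default 0.8).
#' @return Tibble `snp, action (proxied/dropped), proxy_snp, r2`.
#' @export
substitute_proxies <- function(missing, proxies, available, r2_min = 0.8) {
  proxies <- validate_proxy_table(proxies)
  purrr::map_dfr(missing, function(s) {
    cand <- proxies[proxies$missing_snp == s &
                      proxies$r2 >= r2_min &
                      proxies$proxy_snp %in% available, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble(snp = s, action = "dropped",
                    proxy_snp = NA_character_, r2 = NA_real_))
    }
    cand <- cand[order(-cand$r2, cand$proxy_snp), , drop = FALSE]
    tibble(snp = s, action = "proxied",
           proxy_snp = cand$proxy_snp[1], r2 = cand$r2[1])
  })
}

# Harmonize one exposure/outcome pair of associations that share a variant.
# Returns list(status = "ok"/"dropped", reason, row) where row carries the
# harmonized fields.
harmonize_pair <- function(ea_x, oa_x, beta_x, se_x, eaf_x,
                           ea_y, oa_y, beta_y, se_y, eaf_y,
                           palindrome_policy = "infer",
                           ambiguity_window = c(0.42, 0.58)) {
  flip <- function(b, f) list(beta = -b, eaf = if (is.na(f)) NA_real_ else 1 - f)
  flipped <- FALSE
  palindromic <- unname(is_palindromic(ea_x, oa_x))

  if (!palindromic) {
    direct <- setequal(c(ea_y, oa_y), c(ea_x, oa_x))
    if (!direct) {
      # try the complementary strand
      ea_y2 <- unname(COMPLEMENT[ea_y]); oa_y2 <- unname(COMPLEMENT[oa_y])
      if (setequal(c(ea_y2, oa_y2), c(ea_x, oa_x))) {
        ea_y <- ea_y2; oa_y <- oa_y2
      } else {
        return(list(status = "dropped", reason = "allele mismatch"))
      }
    }
    if (ea_y != ea_x) {
      fl <- flip(beta_y, eaf_y); beta_y <- fl$beta; eaf_y <- fl$eaf
      flipped <- TRUE
    }
  } else {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(list(status = "dropped", reason = "allele mismatch"))
    }
    if (identical(palindrome_policy, "drop")) {
      return(list(status = "dropped", reason = "palindromic (policy: drop-all)"))
    }
    if (is.na(eaf_x) || is.na(eaf_y)) {
      return(list(status = "dropped",
                  reason = "palindromic and allele frequency unavailable"))
    }
    # nominal orientation by allele labels first
    if (ea_y != ea_x) {
      fl <- flip(beta_y, eaf_y); beta_y <- fl$beta; eaf_y <- fl$eaf
      flipped <- TRUE
    }
    in_window <- function(f) f >= ambiguity_window[1] & f <= ambiguity_window[2]
    if (in_window(eaf_x) || in_window(eaf_y)) {
      return(list(status = "dropped",
                  reason = "palindromic with ambiguous allele frequency"))
    }
    # strand flip implied when frequencies are incompatible as oriented
    if (abs(eaf_x - eaf_y) > abs(eaf_x - (1 - eaf_y))) {
      fl <- flip(beta_y, eaf_y); beta_y <- fl$beta; eaf_y <- fl$eaf
      flipped <- !flipped
    }
  }
  list(status = "ok", reason = NA_character_,
       row = tibble(effect_allele = ea_x, other_allele = oa_x,
                    beta_exp = beta_x, se_exp = se_x, eaf = eaf_x,
                    beta_out = beta_y, se_out = se_y, eaf_out = eaf_y,
                    flipped = flipped))
}

#' Harmonize exposure and outcome summary statistics into an MR dataset
#'
#' Pairs each exposure instrument with its outcome association (or a proxy
#' when the variant is absent from the outcome GWAS), orients the outcome
#' effect onto the exposure's effect allele (negating the effect and
#' complementing the frequency when alleles are swapped, resolving strand
#' flips via base complements), and handles palindromic A/T and C/G variants
#' according to `palindrome_policy`:
#'
#' * `"infer"` (default): orientation inferred from allele frequencies;
#'   variants whose exposure or outcome frequency falls inside the
#'   ambiguity window are dropped.
#' * `"drop"`: all palindromic variants are dropped.
#'
#' Every input instrument appears exactly once in the audit trail as kept,
#' proxied, or dropped with a reason.
#'
#' @param exposure Tibble of exposure instruments (canonical sumstats
#'   columns, post instrument selection).
#' @param outcome Tibble of outcome GWAS associations.
#' @param proxies Optional proxy table for outcome-missing variants.
#' @param palindrome_policy `"infer"` or `"drop"`.
#' @param ambiguity_window Frequency window treated as unresolvable for
#'   palindromic variants (default `c(0.42, 0.58)`).
#' @param r2_min Minimum proxy LD (default 0.8).
#' @param exposure_id,outcome_id,database_id Labels attached to the dataset.
#' @return An `mr_dataset`: a tibble with one row per harmonized instrument
#'   (`snp, effect_allele, other_allele, beta_exp, se_exp, eaf, beta_out,
#'   se_out, eaf_out, f_stat, proxy_of, flipped`) plus identifying
#'   attributes and the audit trail.
#' @export
harmonize_data <- function(exposure, outcome, proxies = NULL,
                           palindrome_policy = c("infer", "drop"),
                           ambiguity_window = c(0.42, 0.58),
                           r2_min = 0.8,
                           exposure_id = "exposure", outcome_id = "outcome",
                           database_id = "db") {
  palindrome_policy <- match.arg(palindrome_policy)
  audit <- get_audit(exposure)
  exposure <- validate_sumstats(exposure, source = "exposure")
  outcome <- validate_sumstats(outcome, source = "outcome")

  # Proxy substitution for instruments absent from the outcome GWAS.
  proxy_of <- setNames(rep(NA_character_, nrow(exposure)), exposure$snp)
  proxy_note <- proxy_of
  missing <- setdiff(exposure$snp, outcome$snp)
  out_lookup <- outcome
  if (length(missing) > 0 && !is.null(proxies)) {
    sub <- substitute_proxies(missing, proxies, available = outcome$snp,
                              r2_min = r2_min)
    for (i in seq_len(nrow(sub))) {
      if (sub$action[i] != "proxied") next
      s <- sub$snp[i]; p <- sub$proxy_snp[i]
      prow <- out_lookup[out_lookup$snp == p, , drop = FALSE][1, ]
      pmap <- proxies[proxies$missing_snp == s & proxies$proxy_snp == p, ][1, ]
      # translate proxy alleles into the missing SNP's alleles
      trans <- setNames(c(toupper(pmap$a1_missing), toupper(pmap$a2_missing)),
                        c(toupper(pmap$a1_proxy), toupper(pmap$a2_proxy)))
      if (!all(c(prow$effect_allele, prow$other_allele) %in% names(trans))) {
        audit <- dplyr::bind_rows(audit, tibble(
          snp = s, stage = "proxy", action = "dropped",
          reason = glue::glue("proxy {p} alleles do not match proxy table")))
        next
      }
      prow$snp <- s
      prow$effect_allele <- unname(trans[prow$effect_allele])
      prow$other_allele <- unname(trans[prow$other_allele])
      out_lookup <- dplyr::bind_rows(out_lookup, prow)
      proxy_of[s] <- p
      proxy_note[s] <- glue::glue("substituted by {p} (r2 = {format(sub$r2[i])})")
    }
  }

  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    s <- exposure$snp[i]
    orow <- out_lookup[out_lookup$snp == s, , drop = FALSE]
    if (nrow(orow) == 0) {
      audit <- dplyr::bind_rows(audit, tibble(
        snp = s, stage = "harmonize", action = "dropped",
        reason = "absent from outcome GWAS with no adequate proxy"))
      next
    }
    orow <- orow[1, ]
    h <- harmonize_pair(exposure$effect_allele[i], exposure$other_allele[i],
                        exposure$beta[i], exposure$se[i], exposure$eaf[i],
                        orow$effect_allele, orow$other_allele,
                        orow$beta, orow$se, orow$eaf,
                        palindrome_policy = palindrome_policy,
                        ambiguity_window = ambiguity_window)
    if (h$status != "ok") {
      audit <- dplyr::bind_rows(audit, tibble(
        snp = s, stage = "harmonize", action = "dropped", reason = h$reason))
      next
    }
    row <- h$row
    row$snp <- s
    row$f_stat <- (row$beta_exp / row$se_exp)^2
    row$proxy_of <- unname(proxy_of[s])
    rows[[length(rows) + 1L]] <- row
    audit <- dplyr::bind_rows(audit, tibble(
      snp = s, stage = "harmonize",
      action = if (is.na(proxy_of[s])) "kept" else "proxied",
      reason = unname(proxy_note[s])))
  }
  inst <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(effect_allele = character(), other_allele = character(),
           beta_exp = numeric(), se_exp = numeric(), eaf = numeric(),
           beta_out = numeric(), se_out = numeric(), eaf_out = numeric(),
           flipped = logical(), snp = character(), f_stat = numeric(),
           proxy_of = character())
  inst <- inst[, c("snp", "effect_allele", "other_allele", "beta_exp",
                   "se_exp", "eaf", "beta_out", "se_out", "eaf_out",
                   "f_stat", "proxy_of", "flipped")]
  new_mr_dataset(inst, exposure_id = exposure_id, outcome_id = outcome_id,
                 database_id = database_id, audit = audit)
}

#' Construct an MR dataset from harmonized instruments
#'
#' Lower-level constructor for a harmonized per-SNP exposure/outcome effect
#' table for one (exposure, outcome, database) triple. Most users get one
#' from [harmonize_data()] or [simulate_sumstats()].
#'
#' @param instruments Tibble with at least `snp, beta_exp, se_exp, beta_out,
#'   se_out`.
#' @param exposure_id,outcome_id,database_id Identifying labels.
#' @param audit Optional audit tibble.
#' @return A tibble of class `mr_dataset`.
#' @export
new_mr_dataset <- function(instruments, exposure_id = "exposure",
                           outcome_id = "outcome", database_id = "db",
                           audit = NULL) {
  assert_columns(instruments, c("snp", "beta_exp", "se_exp", "beta_out", "se_out"),
                 what = "instruments")
  if (anyDuplicated(instruments$snp)) {
    abort("instrument snp ids must be unique", class = "mrpipe_validation_error")
  }
  if (nrow(instruments) > 0 &&
      (any(instruments$se_exp <= 0) || any(instruments$se_out <= 0))) {
    abort("instrument standard errors must be positive",
          class = "mrpipe_validation_error")
  }
  out <- as_tibble(instruments)
  if (!"f_stat" %in% names(out)) out$f_stat <- (out$beta_exp / out$se_exp)^2
  attr(out, "exposure_id") <- exposure_id
  attr(out, "outcome_id") <- outcome_id
  attr(out, "database_id") <- database_id
  attr(out, "mr_audit") <- audit %||% empty_audit()
  class(out) <- unique(c("mr_dataset", class(out)))
  out
}
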