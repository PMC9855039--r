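#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-variant summary associations (one row
#' per SNP) and validates every row. The default column dialect is
#' `snp, effect_allele, other_allele, eaf, beta, se, pval, n`; files using
#' other column names are mapped via `column_map`. `eaf` and `n` are optional
#' columns; all others are required.
#'
#' Validation is total: every malformed row is reported with its file line
#' number, and nothing is silently dropped. Alleles are case-folded to
#' uppercase; indels and multi-allelic rows (any allele outside A/C/G/T) are
#' rejected, as are duplicated SNP identifiers.
#'
#' @param path Path to a TSV (default) or CSV (by `.csv` extension) file with
#'   a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(snp = "rsid", pval = "P")`.
#' @param trait_id Optional trait label attached to every row.
#' @return A tibble of validated variant associations with canonical columns
#'   `snp, effect_allele, other_allele, eaf, beta, se, pval, n, trait_id`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
#'              "rs1\tA\tG\t0.30\t0.12\t0.01\t1e-12\t50000"), tf)
#' read_sumstats(tf)
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL) {
  if (!file.exists(path)) {
    abort(glue::glue("summary-statistics file not found: {path}"),
          class = "mrpipe_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  canonical <- c("snp", "effect_allele", "other_allele", "eaf", "beta",
                 "se", "pval", "n")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad) > 0) {
      abort(glue::glue("unknown canonical column(s) in `column_map`: {paste(bad, collapse = ', ')}"),
            class = "mrpipe_config_error")
    }
    map[names(column_map)] <- unname(column_map)
  }
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  for (cn in required) {
    if (!map[[cn]] %in% names(raw)) {
      abort(glue::glue("missing required column `{map[[cn]]}` (canonical `{cn}`) in {path}"),
            class = "mrpipe_config_error")
    }
  }
  out <- tibble(
    snp = raw[[map[["snp"]]]],
    effect_allele = raw[[map[["effect_allele"]]]],
    other_allele = raw[[map[["other_allele"]]]],
    eaf = if (map[["eaf"]] %in% names(raw)) suppressWarnings(as.numeric(raw[[map[["eaf"]]]])) else NA_real_,
    beta = suppressWarnings(as.numeric(raw[[map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[map[["se"]]]])),
    pval = suppressWarnings(as.numeric(raw[[map[["pval"]]]])),
    n = if (map[["n"]] %in% names(raw)) suppressWarnings(as.numeric(raw[[map[["n"]]]])) else NA_real_
  )
  out$trait_id <- trait_id %||% NA_character_
  validate_sumstats(out, source = path)
}

#' Validate a table of variant associations
#'
#' Enforces the row invariants of a summary-statistics record: alleles are
#' single bases A/C/G/T and differ from each other, `se > 0`, `pval` in
#' (0, 1], `eaf` (when present) in (0, 1), `n` (when present) a positive
#' count, and SNP identifiers unique within a trait. Alleles are folded to
#' uppercase. All violations are collected and reported together with their
#' row numbers (file line numbers counting the header as line 1).
#'
#' @param df A data frame with canonical summary-statistics columns.
#' @param source Label used in error messages (e.g. the file path).
#' @return The validated tibble, alleles upper-cased.
#' @export
validate_sumstats <- function(df, source = "sumstats") {
  assert_columns(df, c("snp", "effect_allele", "other_allele", "beta", "se", "pval"),
                 what = source)
  df <- as_tibble(df)
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  if (!"trait_id" %in% names(df)) df$trait_id <- NA_character_
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  line <- seq_len(nrow(df)) + 1L  # header is line 1
  problems <- character(0)
  note <- function(bad, msg) {
    if (any(bad)) {
      problems <<- c(problems,
                     glue::glue("line {line[bad]}: {msg}"))
    }
  }
  note(!df$effect_allele %in% BASES | !df$other_allele %in% BASES,
       "alleles must be single bases A/C/G/T (indels and multi-allelic rows are not supported)")
  note(df$effect_allele %in% BASES & df$other_allele %in% BASES &
         df$effect_allele == df$other_allele,
       "effect and other allele are identical")
  note(is.na(df$beta), "beta is missing or non-numeric")
  note(is.na(df$se) | df$se <= 0, "se must be a positive number")
  note(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval must lie in (0, 1]")
  note(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf must lie in (0, 1)")
  note(!is.na(df$n) & (df$n <= 0 | df$n != round(df$n)), "n must be a positive integer")
  dup <- duplicated(paste(df$snp, df$trait_id))
  note(dup, "duplicate snp identifier for the same trait")
  if (length(problems) > 0) {
    abort(paste0("invalid rows in ", source, ":\n",
                 paste("  -", problems, collapse = "\n")),
          class = "mrpipe_validation_error")
  }
  df[c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pval",
       "n", "trait_id")]
}

#' Write a GWAS summary-statistics table
#'
#' Writes validated records in the canonical dialect so that
#' `read_sumstats()` reproduces them field-for-field (doubles survive to at
#' least 12 significant digits). An empty input yields a header-only file.
#'
#' @param df A tibble of variant associations (validated on the way out).
#' @param path Output path; `.csv` extension switches to comma delimiting.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(df, path) {
  if (nrow(df) > 0) df <- validate_sumstats(df, source = "records to write")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a local LD proxy table
#'
#' A proxy table supplies, for SNPs absent from an outcome GWAS, candidate
#' substitutes in high LD together with the allele pairing needed to orient
#' the proxy's effects onto the missing SNP's alleles. Columns:
#' `missing_snp, proxy_snp, r2, a1_missing, a1_proxy, a2_missing, a2_proxy`.
#'
#' @param path TSV file path.
#' @return A validated tibble.
#' @export
read_proxy_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    missing_snp = "c", proxy_snp = "c", r2 = "d",
    a1_missing = "c", a1_proxy = "c", a2_missing = "c", a2_proxy = "c"
  ), progress = FALSE, show_col_types = FALSE)
  validate_proxy_table(df, source = path)
}

validate_proxy_table <- function(df, source = "proxy table") {
  assert_columns(df, c("missing_snp", "proxy_snp", "r2", "a1_missing",
                       "a1_proxy", "a2_missing", "a2_proxy"), what = source)
  df <- as_tibble(df)
  for (cn in c("a1_missing", "a1_proxy", "a2_missing", "a2_proxy")) {
    df[[cn]] <- toupper(df[[cn]])
  }
  bad_r2 <- is.na(df$r2) | df$r2 < 0 | df$r2 > 1
  bad_map <- df$a1_missing == df$a2_missing | df$a1_proxy == df$a2_proxy
  if (any(bad_r2) || any(bad_map)) {
    abort(glue::glue(
      "invalid proxy rows in {source}: r2 must lie in [0, 1] and each allele map must pair two distinct alleles"
    ), class = "mrpipe_validation_error")
  }
  df
}

#' Read a confounder-association table
#'
#' Lists known associations of candidate instruments with confounding traits
#' (the local stand-in for a phenome-scan lookup). Columns: `snp, trait,
#' pval`.
#'
#' @param path TSV file path.
#' @return A validated tibble.
#' @export
read_confounder_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    snp = "c", trait = "c", pval = "d"
  ), progress = FALSE, show_col_types = FALSE)
  assert_columns(df, c("snp", "trait", "pval"), what = path)
  if (any(is.na(df$pval) | df$pval <= 0 | df$pval > 1)) {
    abort(glue::glue("invalid confounder rows in {path}: pval must lie in (0, 1]"),
          class = "mrpipe_validation_error")
  }
  as_tibble(df)
}
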