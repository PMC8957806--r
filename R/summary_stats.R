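#' Convert odds ratios to log-odds betas and back
#'
#' @param or,beta numeric vectors.
#' @return `or_to_beta` returns `log(or)`; `beta_to_or` returns `exp(beta)`.
#' @export
or_to_beta <- function(or) log(or)

#' @rdname or_to_beta
#' @export
beta_to_or <- function(beta) exp(beta)

.daner_map <- c(variant_id = "SNP", chrom = "CHR", pos = "BP",
                effect_allele = "A1", other_allele = "A2",
                or = "OR", beta = "BETA", se = "SE", p = "P", info = "INFO")

#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistic table (optionally
#' gzipped) into a standardized record layout. The default column mapping is
#' the daner convention (`SNP CHR BP A1 A2 OR SE P INFO`); any layout is
#' reachable by overriding `column_map` entries. When the source provides an
#' odds-ratio column, `beta = log(OR)` exactly; a `BETA` column, if mapped
#' and present, takes precedence.
#'
#' Rows with missing or invalid mandatory fields (unparseable beta/OR, `se
#' <= 0`, `p` outside `(0, 1]`, identical alleles) are skipped and counted.
#' Rows with `p == 0` are clamped to the smallest positive double and
#' counted separately, since thresholding needs `p` in `(0, 1]`.
#'
#' @param path file path.
#' @param column_map named character vector mapping internal field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `or`,
#'   `beta`, `se`, `p`, `info`) to source column names.
#' @return List: `stats` — data frame with columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `p`, `info`;
#'   `report` — list with `n_rows`, `n_parsed`, `n_skipped`, `n_p_clamped`.
#' @export
read_summary_stats <- function(path, column_map = .daner_map) {
  if (!file.exists(path)) stop2("no such file: ", path)
  map <- .daner_map
  map[names(column_map)] <- column_map
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ".", ""))
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele", "se", "p")
  for (f in mandatory)
    if (!map[[f]] %in% names(dt))
      stop2("mandatory column `", map[[f]], "` (", f, ") missing from ", path)
  has_beta <- map[["beta"]] %in% names(dt)
  has_or <- map[["or"]] %in% names(dt)
  if (!has_beta && !has_or)
    stop2("need an effect column: `", map[["beta"]], "` or `", map[["or"]], "`")

  out <- data.frame(
    variant_id = as.character(dt[[map[["variant_id"]]]]),
    chrom = as.character(dt[[map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(dt[[map[["pos"]]]])),
    effect_allele = toupper(as.character(dt[[map[["effect_allele"]]]])),
    other_allele = toupper(as.character(dt[[map[["other_allele"]]]])),
    beta = if (has_beta) suppressWarnings(as.numeric(dt[[map[["beta"]]]]))
           else or_to_beta(suppressWarnings(as.numeric(dt[[map[["or"]]]]))),
    se = suppressWarnings(as.numeric(dt[[map[["se"]]]])),
    p = suppressWarnings(as.numeric(dt[[map[["p"]]]])),
    info = if (map[["info"]] %in% names(dt))
      suppressWarnings(as.numeric(dt[[map[["info"]]]])) else NA_real_,
    stringsAsFactors = FALSE
  )

  clamped <- !is.na(out$p) & out$p == 0
  out$p[clamped] <- .Machine$double.xmin

  valid <- !is.na(out$variant_id) & !is.na(out$beta) & is.finite(out$beta) &
    !is.na(out$se) & out$se > 0 &
    !is.na(out$p) & out$p > 0 & out$p <= 1 &
    out$effect_allele != out$other_allele
  report <- list(n_rows = nrow(out), n_parsed = sum(valid),
                 n_skipped = sum(!valid), n_p_clamped = sum(clamped & valid))
  if (report$n_parsed == 0) stop2("no parseable summary-statistic rows in ", path)
  list(stats = out[valid, , drop = FALSE], report = report)
}

#' Write summary statistics in daner-style layout
#'
#' Columns `SNP CHR BP A1 A2 OR SE P INFO`, tab-delimited; the odds ratio is
#' `exp(beta)`.
#'
#' @param stats summary-statistic data frame (internal layout, see
#'   [read_summary_stats()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.table::data.table(
    SNP = stats$variant_id, CHR = stats$chrom, BP = stats$pos,
    A1 = stats$effect_allele, A2 = stats$other_allele,
    OR = beta_to_or(stats$beta), SE = stats$se, P = stats$p,
    INFO = stats$info
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter summary statistics on imputation quality
#'
#' Retains records with `info` strictly greater than `min_info` (records
#' with missing INFO are dropped when filtering is active).
#'
#' @param stats summary-statistic data frame.
#' @param min_info threshold; the conventional imputation-quality cut is a
#'   strict `INFO > 0.9`. `min_info = 0` keeps records with `info >= 0`
#'   and those with missing INFO (a no-op for well-formed input).
#' @return List: `stats` (filtered) and `report` with `n_before`, `n_after`.
#' @export
filter_info <- function(stats, min_info = 0.9) {
  if (min_info == 0) {
    keep <- rep(TRUE, nrow(stats))
  } else {
    keep <- !is.na(stats$info) & stats$info > min_info
  }
  out <- stats[keep, , drop = FALSE]
  if (!nrow(out)) warning("INFO filter removed every record")
  list(stats = out, report = list(n_before = nrow(stats), n_after = nrow(out)))
}
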