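#' Genotype matrix container
#'
#' Samples-by-variants dosage matrix with variant annotations. Dosages lie in
#' `[0, 2]` (number of copies of the counted allele `a1`) or are `NA` where
#' missing. Zero-filling of missing dosages is deliberately NOT done here —
#' it belongs to score computation, where absent GWAS variants and missing
#' entries contribute zero.
#'
#' @param dosages numeric matrix, samples x variants.
#' @param sample_ids character vector, one per row.
#' @param variants data frame with at least `variant_id`, `chrom`, `pos`,
#'   `a1` (the allele the dosage counts), `a2`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids))
    stop2("sample_ids length must match rows of dosages")
  if (ncol(dosages) != nrow(variants))
    stop2("variants rows must match columns of dosages")
  need <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(variants)))
    stop2("variants must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(variants$variant_id))
    stop2("duplicate variant ids: ",
          paste(unique(variants$variant_id[duplicated(variants$variant_id)]), collapse = ", "))
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop2("dosages must lie in [0, 2]")
  }
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 variants = as.data.frame(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variant ids
#'
#' @param gm a [genotype_matrix()].
#' @param variant_ids ids to retain, in the order given.
#' @return A [genotype_matrix()] restricted to those variants.
#' @export
subset_variants <- function(gm, variant_ids) {
  keep <- match(variant_ids, gm$variants$variant_id)
  if (anyNA(keep)) stop2("unknown variant ids: ",
                         paste(head(variant_ids[is.na(keep)], 5), collapse = ", "))
  genotype_matrix(gm$dosages[, keep, drop = FALSE], gm$sample_ids,
                  gm$variants[keep, , drop = FALSE])
}

#' Read target-cohort genotypes
#'
#' Supports VCF (v4.x; the `DS` FORMAT field when present, otherwise hard
#' calls counted from `GT`) and a plain dosage-matrix TSV with columns
#' `variant_id chrom pos a1 a2` followed by one column per sample. In both
#' formats the dosage counts the `a1` allele (the ALT allele for VCF input).
#' Missing entries (`./.`, `.`, empty, NA) are marked `NA`, never zero.
#'
#' @param path file path (VCF may be plain or gzipped).
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) as.data.frame(fix, stringsAsFactors = FALSE) else
    as.data.frame(t(fix), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids))
    stop2("duplicate variant ids in VCF: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fmt <- v@gt[, 1]
  has_ds <- all(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f, logical(1)))
  if (has_ds) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (any(grepl("^[0-9.](\\||/)[0-9.](\\||/)", gt), na.rm = TRUE))
      stop2("mixed or non-diploid ploidy in VCF genotypes")
    count_alt <- function(g) {
      al <- strsplit(g, "[/|]")
      vapply(al, function(a) {
        if (length(a) != 2L || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    }
    d <- apply(gt, 2, count_alt)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  variants <- data.frame(variant_id = ids, chrom = as.character(fix$CHROM),
                         pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(d), sample_ids = colnames(v@gt)[-1], variants = variants)
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c(".", "NA", ""))
  need <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(dt)))
    stop2("dosage TSV must start with columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$variant_id))
    stop2("duplicate variant ids in dosage TSV: ",
          paste(unique(dt$variant_id[duplicated(dt$variant_id)]), collapse = ", "))
  samples <- setdiff(names(dt), need)
  if (!length(samples)) stop2("dosage TSV has no sample columns")
  d <- t(as.matrix(dt[, samples, with = FALSE]))
  storage.mode(d) <- "double"
  variants <- as.data.frame(dt[, need, with = FALSE])
  variants$chrom <- as.character(variants$chrom)
  genotype_matrix(d, sample_ids = samples, variants = variants)
}

#' Write genotypes as a dosage-matrix TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; missing dosages are written as `.`.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  out <- data.table::data.table(gm$variants[c("variant_id", "chrom", "pos", "a1", "a2")])
  dos <- t(gm$dosages)
  for (i in seq_along(gm$sample_ids)) out[[gm$sample_ids[i]]] <- dos[, i]
  data.table::fwrite(out, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Write genotypes as a VCF with a DS (dosage) FORMAT field
#'
#' Minimal VCF 4.2 serialization of the dosage matrix: `a1` is written as
#' ALT (the counted allele), `a2` as REF; each genotype cell carries a
#' hard-call GT (nearest integer dosage) plus the DS dosage. Missing dosages
#' become `./.:.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            gm$sample_ids), collapse = "\t")
  ), con)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  for (j in seq_len(ncol(gm$dosages))) {
    d <- gm$dosages[, j]
    cell <- ifelse(is.na(d), "./.:.", paste0(gt_of(d), ":", format(d, trim = TRUE)))
    writeLines(paste(c(gm$variants$chrom[j], gm$variants$pos[j],
                       gm$variants$variant_id[j], gm$variants$a2[j],
                       gm$variants$a1[j], ".", "PASS", ".", "GT:DS", cell),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the 1-df goodness-of-fit chi-square of observed genotype counts
#' against Hardy-Weinberg expectations at the observed allele frequency. An
#' exact (mid-p by default) test enumerating heterozygote counts conditional
#' on the minor-allele count is available via `method = "exact"`.
#' Monomorphic variants return p = 1 with a `monomorphic` attribute, by
#' convention.
#'
#' @param counts integer vector `(hom_ref, het, hom_alt)`.
#' @param method `"chisq"` or `"exact"`.
#' @param midp use the mid-p correction for the exact test.
#' @return p-value (attributes: `chisq` for the default method,
#'   `monomorphic` flag when degenerate).
#' @export
hwe_test <- function(counts, method = c("chisq", "exact"), midp = TRUE) {
  method <- match.arg(method)
  if (length(counts) != 3L || any(counts < 0) || sum(counts) == 0)
    stop2("counts must be 3 nonnegative genotype counts with positive total")
  n <- sum(counts)
  p <- (2 * counts[3] + counts[2]) / (2 * n)  # counted-allele frequency
  if (p == 0 || p == 1)
    return(structure(1, monomorphic = TRUE))
  if (method == "chisq") {
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chisq <- sum((counts - expd)^2 / expd)
    structure(pchisq(chisq, df = 1, lower.tail = FALSE), chisq = chisq)
  } else {
    hwe_exact(counts, midp = midp)
  }
}

# Exact HWE test: enumerate heterozygote counts conditional on the
# minor-allele count (standard conditional distribution), two-sided by
# summing probabilities <= that of the observed table.
hwe_exact <- function(counts, midp = TRUE) {
  n <- sum(counts)
  n_minor <- min(2 * counts[3] + counts[2], 2 * counts[1] + counts[2])
  obs_het <- counts[2]
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # unnormalized log P(het = h | n, n_minor); constants in h drop out below
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(obs_het, hets)]
  pval <- sum(pr[pr <= p_obs + 1e-12])
  if (midp) pval <- pval - 0.5 * p_obs
  min(max(pval, 0), 1)
}

#' Default variant QC thresholds
#'
#' Standard imputation-grade thresholds: minor allele frequency strictly
#' above 0.01, call rate strictly above 0.95, Hardy-Weinberg p strictly above
#' 1e-6, and (when a reference frequency is supplied) absolute allele
#' frequency difference from the reference of at most 0.20.
#'
#' @param min_maf,min_call_rate,min_hwe_p,max_ref_af_diff thresholds in `[0,1]`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01, min_call_rate = 0.95,
                          min_hwe_p = 1e-6, max_ref_af_diff = 0.20) {
  vals <- c(min_maf, min_call_rate, min_hwe_p, max_ref_af_diff)
  if (any(vals < 0 | vals > 1)) stop2("all QC thresholds must lie in [0, 1]")
  structure(list(min_maf = min_maf, min_call_rate = min_call_rate,
                 min_hwe_p = min_hwe_p, max_ref_af_diff = max_ref_af_diff),
            class = "qc_thresholds")
}

#' Variant quality control
#'
#' Keeps a variant iff MAF > `min_maf` AND call rate > `min_call_rate` AND
#' HWE p > `min_hwe_p` AND (no reference frequency supplied OR
#' `|af - ref_af| <= max_ref_af_diff`). Removal counts are reported by the
#' first failing criterion in the order: call rate, MAF, HWE, reference
#' difference (survivorship itself is a conjunction, so order-independent).
#' HWE uses best-guess hard calls (dosages rounded to the nearest integer).
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param ref_freqs optional named numeric vector of reference counted-allele
#'   frequencies, keyed by variant id.
#' @return List: `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (list with `n_before`, `n_after` and per-criterion removal counts).
#' @export
qc_variants <- function(gm, thresholds = qc_thresholds(), ref_freqs = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  d <- gm$dosages
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  maf <- pmin(af, 1 - af)
  hard <- round(d)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    h <- hard[, j]
    cnt <- c(sum(h == 0, na.rm = TRUE), sum(h == 1, na.rm = TRUE), sum(h == 2, na.rm = TRUE))
    if (sum(cnt) == 0) return(NA_real_)
    as.numeric(hwe_test(cnt))
  }, numeric(1))

  ok_cr <- call_rate > thresholds$min_call_rate
  ok_maf <- !is.na(maf) & maf > thresholds$min_maf
  ok_hwe <- !is.na(hwe_p) & hwe_p > thresholds$min_hwe_p
  if (!is.null(ref_freqs)) {
    ref <- ref_freqs[gm$variants$variant_id]
    ok_ref <- is.na(ref) | abs(af - ref) <= thresholds$max_ref_af_diff
    ok_ref[is.na(af)] <- FALSE
  } else ok_ref <- rep(TRUE, ncol(d))

  keep <- ok_cr & ok_maf & ok_hwe & ok_ref
  first_fail <- rep(NA_character_, ncol(d))
  first_fail[!ok_ref] <- "ref_af_diff"
  first_fail[!ok_hwe] <- "hwe"
  first_fail[!ok_maf] <- "maf"
  first_fail[!ok_cr] <- "call_rate"   # listed-order priority: call rate first
  report <- list(
    n_before = ncol(d), n_after = sum(keep),
    removed = list(
      call_rate = sum(first_fail == "call_rate", na.rm = TRUE),
      maf = sum(first_fail == "maf", na.rm = TRUE),
      hwe = sum(first_fail == "hwe", na.rm = TRUE),
      ref_af_diff = sum(first_fail == "ref_af_diff", na.rm = TRUE)
    )
  )
  if (!any(keep)) warning("no variants survive QC")
  out <- genotype_matrix(d[, keep, drop = FALSE], gm$sample_ids,
                         gm$variants[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}
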