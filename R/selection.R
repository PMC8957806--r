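#' The canonical p-value threshold sweep
#'
#' The 14 thresholds conventionally swept when constructing
#' clumping-and-thresholding scores here: 0.5, 0.4, 0.3, 0.2, 0.1, 0.05,
#' 0.01, 0.005, 0.001, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8.
#'
#' @return Numeric vector of length 14, decreasing.
#' @export
prs_thresholds <- function() {
  c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05, 0.01, 0.005, 0.001,
    1e-4, 1e-5, 1e-6, 1e-7, 1e-8)
}

#' The APOE exclusion region
#'
#' +/- 300 kb around the APOE epsilon coding SNPs:
#' chr19:45,111,942-45,711,941 (GRCh37, 1-based, inclusive). Variants inside
#' are excluded from score construction so the score does not simply tag
#' APOE.
#'
#' @return A region list with `chrom`, `start`, `end`.
#' @export
apoe_region <- function() region_mask("19", 45111942L, 45711941L)

#' Construct a genomic region mask
#'
#' @param chrom chromosome name (compared as character, without `chr` prefix
#'   normalization — supply it as your data spells it).
#' @param start,end 1-based inclusive bounds, `start < end`.
#' @return A list of class `region_mask`.
#' @export
region_mask <- function(chrom, start, end) {
  if (start >= end) stop2("region start must be < end")
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)), class = "region_mask")
}

#' Remove variants inside a region
#'
#' Drops rows with matching chromosome and `start <= pos <= end` (both ends
#' inclusive).
#'
#' @param variants data frame with `chrom` and `pos` columns.
#' @param mask a [region_mask()], default the APOE region.
#' @return List: `variants` (survivors, order preserved) and `n_removed`.
#' @export
mask_region <- function(variants, mask = apoe_region()) {
  stopifnot(inherits(mask, "region_mask"))
  inside <- as.character(variants$chrom) == mask$chrom &
    variants$pos >= mask$start & variants$pos <= mask$end
  list(variants = variants[!inside, , drop = FALSE], n_removed = sum(inside))
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize GWAS summary statistics to target genotypes
#'
#' Intersects GWAS records with target variants (by variant id; unmatched
#' ids fall back to a `chrom:pos` key) and aligns the GWAS beta to the
#' allele the target dosage counts:
#' \itemize{
#'   \item exact allele match — beta kept as is;
#'   \item swapped alleles — beta negated, flip flagged;
#'   \item strand-complement (or complement+swap) match — alleles
#'     complemented, then the two rules above;
#'   \item strand-ambiguous pairs (A/T, C/G) — dropped when
#'     `drop_ambiguous` (their complement equals their swap, so orientation
#'     is undecidable);
#'   \item anything else — allele mismatch, dropped.
#' }
#'
#' @param stats summary-statistic data frame (see [read_summary_stats()]).
#' @param gm a [genotype_matrix()].
#' @param drop_ambiguous drop A/T and C/G pairs (default `TRUE`).
#' @return List: `variants` — data frame (`variant_id`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `flip`) with beta oriented to the target's counted
#'   allele; `report` — counts per category (`matched`, `flipped`,
#'   `strand_complemented`, `ambiguous_dropped`, `mismatch_dropped`,
#'   `unmatched`).
#' @export
harmonize <- function(stats, gm, drop_ambiguous = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!nrow(stats) || !ncol(gm$dosages)) stop2("both inputs must be nonempty")
  if (anyDuplicated(stats$variant_id))
    stop2("duplicate variant ids in summary statistics")
  tv <- gm$variants
  if (anyDuplicated(tv$variant_id)) stop2("duplicate variant ids in target")

  idx <- match(stats$variant_id, tv$variant_id)
  no_id <- is.na(idx)
  if (any(no_id)) {
    key_t <- paste(tv$chrom, tv$pos, sep = ":")
    if (!anyDuplicated(key_t)) {
      key_s <- paste(stats$chrom, stats$pos, sep = ":")
      idx[no_id] <- match(key_s[no_id], key_t)
    }
  }
  matched <- !is.na(idx)
  s <- stats[matched, , drop = FALSE]
  t <- tv[idx[matched], , drop = FALSE]

  amb <- is_ambiguous_pair(s$effect_allele, s$other_allele)
  ea <- s$effect_allele; oa <- s$other_allele
  direct <- ea == t$a1 & oa == t$a2
  swapped <- ea == t$a2 & oa == t$a1
  cea <- unname(.complement[ea]); coa <- unname(.complement[oa])
  comp_direct <- !direct & !swapped & cea == t$a1 & coa == t$a2
  comp_swapped <- !direct & !swapped & cea == t$a2 & coa == t$a1

  drop_amb <- drop_ambiguous & amb
  usable <- (direct | swapped | comp_direct | comp_swapped) & !drop_amb
  flip <- (swapped | comp_swapped)[usable]

  out <- data.frame(
    variant_id = t$variant_id[usable],
    chrom = as.character(t$chrom[usable]), pos = t$pos[usable],
    beta = ifelse(flip, -s$beta[usable], s$beta[usable]),
    se = s$se[usable], p = s$p[usable], flip = flip,
    stringsAsFactors = FALSE
  )
  report <- list(
    matched = sum(matched), retained = nrow(out),
    flipped = sum(flip),
    strand_complemented = sum((comp_direct | comp_swapped) & usable),
    ambiguous_dropped = sum(drop_amb),
    mismatch_dropped = sum(!(direct | swapped | comp_direct | comp_swapped) & !drop_amb),
    unmatched = sum(!matched)
  )
  list(variants = out, report = report)
}

#' Squared dosage correlation between two variants
#'
#' Sample correlation squared over pairwise-complete samples — the usual LD
#' r-squared proxy computed from the target cohort's own dosages. Zero
#' variance in either variant (or fewer than two complete pairs) is
#' undefined and returned as 0 with attribute `undefined = TRUE`.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j variant ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(gm, i, j) {
  col <- function(k) {
    if (is.character(k)) k <- match(k, gm$variants$variant_id)
    if (is.na(k) || k < 1 || k > ncol(gm$dosages)) stop2("unknown variant")
    gm$dosages[, k]
  }
  x <- col(i); y <- col(j)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0)
    return(structure(0, undefined = TRUE))
  min(stats::cor(x[ok], y[ok])^2, 1)
}

#' LD clumping parameters
#'
#' Defaults follow standard C+T practice here: prune partners with
#' r-squared > 0.1 within a +/- 250 kb window; index variants at any p
#' (`p_threshold = 1`) are retained, leaving p-value selection to the
#' threshold sweep.
#'
#' @param r2_threshold r-squared above which a partner is clumped away,
#'   in `(0, 1]`.
#' @param p_threshold retain index variants with `p <=` this value.
#' @param window_kb half-window around the index position, in kb.
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(r2_threshold = 0.1, p_threshold = 1.0, window_kb = 250) {
  if (r2_threshold <= 0 || r2_threshold > 1) stop2("r2_threshold must be in (0, 1]")
  if (window_kb <= 0) stop2("window_kb must be positive")
  assert_prob(p_threshold, "p_threshold")
  structure(list(r2_threshold = r2_threshold, p_threshold = p_threshold,
                 window_kb = window_kb), class = "clump_params")
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unassigned variant (ties broken by
#' smaller position, then lexicographic id) as an index, then removes every
#' unassigned variant on the same chromosome within +/- `window_kb` whose
#' r-squared with the index exceeds `r2_threshold`. Index variants with
#' `p <= p_threshold` are retained. Deterministic by construction.
#'
#' @param variants data frame with `variant_id`, `chrom`, `pos`, `p`.
#' @param gm a [genotype_matrix()] supplying dosages for r-squared.
#' @param params a [clump_params()].
#' @return The retained index variants (rows of `variants`, in
#'   clumping order).
#' @export
clump <- function(variants, gm, params = clump_params()) {
  stopifnot(inherits(params, "clump_params"))
  if (!nrow(variants)) return(variants[0, , drop = FALSE])
  cols <- match(variants$variant_id, gm$variants$variant_id)
  if (anyNA(cols)) stop2("variants absent from genotype matrix: ",
                         paste(head(variants$variant_id[is.na(cols)], 5), collapse = ", "))
  ord <- order(variants$p, variants$pos, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  cols <- cols[ord]
  window <- params$window_kb * 1000
  n <- nrow(v)
  unassigned <- rep(TRUE, n)
  retained <- logical(n)
  for (i in seq_len(n)) {
    if (!unassigned[i]) next
    unassigned[i] <- FALSE
    retained[i] <- v$p[i] <= params$p_threshold
    cand <- which(unassigned & v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= window)
    if (length(cand)) {
      x <- gm$dosages[, cols[i]]
      for (k in cand) {
        y <- gm$dosages[, cols[k]]
        ok <- !is.na(x) & !is.na(y)
        r2 <- if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) 0
              else stats::cor(x[ok], y[ok])^2
        if (r2 > params$r2_threshold) unassigned[k] <- FALSE
      }
    }
  }
  v[retained, , drop = FALSE]
}

#' Apply a p-value threshold
#'
#' Retains variants with `p <= p_threshold` (inclusive convention).
#'
#' @param variants data frame with a `p` column.
#' @param p_threshold value in `(0, 1]`.
#' @return The retained subset.
#' @export
apply_threshold <- function(variants, p_threshold) {
  assert_prob(p_threshold, "p_threshold")
  variants[variants$p <= p_threshold, , drop = FALSE]
}
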