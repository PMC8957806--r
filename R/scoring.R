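#' Score set container
#'
#' Per-sample polygenic scores for one formula and p-value threshold, with
#' the metadata needed to interpret them: `T` (number of scored variants)
#' and `sum_beta` (sum of betas after risk orientation, for the
#' risk-increasing formula).
#'
#' @param scores named numeric vector (names = sample ids).
#' @param formula `"standard"` or `"risk_increasing"`.
#' @param p_threshold the threshold the variant set was selected at (or NA).
#' @param n_variants number of scored variants (the `T` of the
#'   risk-increasing formula).
#' @param sum_beta sum of (risk-oriented) betas over scored variants.
#' @param standardized has the score been z-scaled within cohort?
#' @return An object of class `score_set`.
#' @export
score_set <- function(scores, formula, p_threshold = NA_real_,
                      n_variants, sum_beta, standardized = FALSE) {
  formula <- match.arg(formula, c("standard", "risk_increasing"))
  if (n_variants < 1) stop2("a score needs at least one variant")
  if (formula == "risk_increasing" && !standardized && sum_beta <= 0)
    stop2("risk-increasing scores require a positive beta sum")
  structure(list(scores = scores, formula = formula, p_threshold = p_threshold,
                 n_variants = as.integer(n_variants), sum_beta = sum_beta,
                 standardized = standardized), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %s formula, %d variants, %d samples%s%s\n",
              x$formula, x$n_variants, length(x$scores),
              if (is.na(x$p_threshold)) "" else sprintf(", p<=%g", x$p_threshold),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

# Dosage matrix for the selected variants, with the zero rule applied:
# GWAS variants entirely absent from the target contribute a zero column,
# and per-sample missing entries become zero. Rationale: most of the
# population carries at least one copy of the major allele, which a dosage
# of zero (no effect-allele copies) approximates.
.score_dosages <- function(variants, gm) {
  idx <- match(variants$variant_id, gm$variants$variant_id)
  X <- matrix(0, nrow = nrow(gm$dosages), ncol = nrow(variants),
              dimnames = list(gm$sample_ids, variants$variant_id))
  present <- which(!is.na(idx))
  miss <- matrix(TRUE, nrow(X), ncol(X))  # absent variants are all-missing
  if (length(present)) {
    Xp <- gm$dosages[, idx[present], drop = FALSE]
    miss[, present] <- is.na(Xp)
    Xp[is.na(Xp)] <- 0
    X[, present] <- Xp
  }
  attr(X, "missing_mask") <- miss
  X
}

#' Standard polygenic score (weighted sum of effect alleles)
#'
#' `score_s = sum_i beta_i * X_si` where `X_si` counts effect alleles.
#' Selected GWAS variants absent from the target, and missing per-sample
#' dosages, contribute zero.
#'
#' @param variants harmonized + selected variant data frame (`variant_id`,
#'   `beta`, optionally `p`).
#' @param gm a [genotype_matrix()].
#' @param p_threshold recorded in the result's metadata.
#' @return A [score_set()] with `formula = "standard"`.
#' @export
score_standard <- function(variants, gm, p_threshold = NA_real_) {
  if (!nrow(variants)) stop2("empty variant set")
  X <- .score_dosages(variants, gm)
  s <- as.numeric(X %*% variants$beta)
  score_set(setNames(s, gm$sample_ids), "standard", p_threshold,
            n_variants = nrow(variants), sum_beta = sum(variants$beta))
}

#' Risk-increasing polygenic score (average-of-risk-alleles scale)
#'
#' Each variant is reoriented so its beta is positive and the counted allele
#' is the risk allele: `G = X` when `beta > 0`, `G = 2 - X` when
#' `beta < 0`. Then
#' `score_s = (sum_i beta_i^+ * G_si) * T / sum_i beta_i^+`,
#' a beta-weighted mean risk-allele count scaled by the number of SNPs `T` —
#' so a unit increase corresponds to one additional (average) risk allele
#' and scores always lie in `[0, 2T]`. Variants with `beta == 0` carry no
#' risk orientation and are excluded from `T` and the beta sum (counted in
#' the `n_zero_beta` attribute). Missing dosages contribute zero risk
#' alleles, as in [score_standard()].
#'
#' @inheritParams score_standard
#' @return A [score_set()] with `formula = "risk_increasing"`.
#' @export
score_risk_increasing <- function(variants, gm, p_threshold = NA_real_) {
  if (!nrow(variants)) stop2("empty variant set")
  zero <- variants$beta == 0
  v <- variants[!zero, , drop = FALSE]
  if (!nrow(v)) stop2("no variants with nonzero beta")
  X <- .score_dosages(v, gm)
  miss <- attr(X, "missing_mask")
  G <- X
  neg <- v$beta < 0
  if (any(neg)) G[, neg] <- 2 - X[, neg, drop = FALSE]
  G[miss] <- 0  # missing means zero risk alleles, not two
  beta_pos <- abs(v$beta)
  tt <- nrow(v)
  s <- as.numeric(G %*% beta_pos) * tt / sum(beta_pos)
  out <- score_set(setNames(s, gm$sample_ids), "risk_increasing", p_threshold,
                   n_variants = tt, sum_beta = sum(beta_pos))
  attr(out, "n_zero_beta") <- sum(zero)
  out
}

#' Standardize a score set within cohort
#'
#' Z-scales to mean 0, SD 1 using the sample-SD (n - 1) convention.
#'
#' @param ss a [score_set()] or numeric vector.
#' @return The standardized [score_set()] (or vector).
#' @export
standardize_scores <- function(ss) {
  x <- if (inherits(ss, "score_set")) ss$scores else ss
  if (length(x) < 2) stop2("standardization needs at least 2 samples")
  s <- sd(x)
  if (s == 0) stop2("cannot standardize constant scores")
  z <- (x - mean(x)) / s
  if (inherits(ss, "score_set")) {
    ss$scores <- z
    ss$standardized <- TRUE
    ss
  } else z
}

#' Write a score set as TSV
#'
#' Columns: `sample_id`, `score`, `formula`, `p_threshold`, `n_variants`.
#'
#' @param ss a [score_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ss, path) {
  data.table::fwrite(data.table::data.table(
    sample_id = names(ss$scores), score = unname(ss$scores),
    formula = ss$formula, p_threshold = ss$p_threshold,
    n_variants = ss$n_variants
  ), path, sep = "\t", quote = FALSE)
  invisible(path)
}
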