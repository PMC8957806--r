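# Independent oracle implementations used to cross-check the package.
# Deliberately naive: loops and exhaustive enumeration, no shared code paths
# with the implementations under test.

# AUC by exhaustive concordant/tied pair enumeration (ties count one half).
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(psi) / (length(x) * length(y))
}

# Greedy clumping replay from an explicit r-squared matrix: smallest p first
# (ties: position, then id), prune same-chromosome partners within the
# window whose r2 exceeds the threshold.
oracle_clump <- function(variants, r2mat, r2_threshold, window_bp, p_threshold = 1) {
  ord <- order(variants$p, variants$pos, variants$variant_id)
  assigned <- rep(FALSE, nrow(variants))
  keep <- character(0)
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    if (variants$p[i] <= p_threshold) keep <- c(keep, variants$variant_id[i])
    for (j in ord) {
      if (assigned[j]) next
      if (variants$chrom[j] == variants$chrom[i] &&
          abs(variants$pos[j] - variants$pos[i]) <= window_bp &&
          r2mat[i, j] > r2_threshold)
        assigned[j] <- TRUE
    }
  }
  keep
}

# Product-limit estimator with delayed entry, one group, step by step.
oracle_km <- function(entry, exit, event) {
  times <- sort(unique(exit[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t <- times[k]
    n_t <- sum(entry < t & exit >= t)
    d_t <- sum(event == 1 & exit == t)
    s <- s * (1 - d_t / n_t)
    surv[k] <- s
  }
  data.frame(time = times, surv = surv)
}

# Small genotype matrix from a dosage matrix given column-wise, with a
# one-variant-per-position map on a single chromosome unless overridden.
make_gm <- function(dosages, chrom = NULL, pos = NULL, a1 = NULL, a2 = NULL,
                    ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  variants <- data.frame(
    variant_id = ids %||% sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% (seq_len(m) * 1000L),
    a1 = a1 %||% rep("A", m),
    a2 = a2 %||% rep("G", m),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, sprintf("s%03d", seq_len(nrow(dosages))), variants)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random genotype fixture with optional LD between consecutive pairs.
random_gm <- function(n, m, seed, chrom = NULL, pos = NULL) {
  set.seed(seed)
  maf <- runif(m, 0.1, 0.5)
  d <- sapply(seq_len(m), function(j) rbinom(n, 2, maf[j]))
  make_gm(d, chrom = chrom, pos = pos)
}
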