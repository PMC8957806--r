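#' Simulation configuration for synthetic PRS cohorts
#'
#' Bundles every parameter of the synthetic-cohort generator: LD-blocked
#' genotypes, GWAS summary statistics with a causal fraction, a
#' liability-threshold depression phenotype over an Alzheimer's-like cohort,
#' and left-truncated onset ages under a proportional-hazards model.
#'
#' Defaults emulate the structure of a single-cohort discovery analysis:
#' prevalence 0.36 (roughly one depression case per two controls among
#' Alzheimer's participants), baseline age around 81.5 (SD 6.7) years and
#' education around 16.2 (SD 3.7) years, and a GWAS of effective sample size
#' large enough that causal variants reach genome-wide-significant p-values.
#'
#' @param n_samples number of target-cohort samples.
#' @param n_variants number of biallelic variants.
#' @param block_size variants per LD block (last block may be smaller).
#' @param within_block_r target pairwise dosage correlation within a block,
#'   in `[0, 1)`; pairwise r-squared is `within_block_r^2`.
#' @param maf_range length-2 vector of minor-allele-frequency bounds in
#'   `(0, 0.5]`; one MAF per block is drawn uniformly in this range.
#' @param causal_fraction proportion of variants with nonzero GWAS effect.
#' @param effect_sd SD of causal effect sizes (per-allele log-odds scale).
#' @param n_gwas effective GWAS sample count; controls summary-statistic
#'   standard errors via `se = 1/sqrt(2 * n_gwas * maf * (1 - maf))`.
#' @param prevalence phenotype prevalence in `(0, 1)`.
#' @param genetic_var_share share of liability variance explained by the true
#'   genetic score, in `[0, 1)`.
#' @param covariate_effects named numeric vector of liability coefficients for
#'   standardized covariates: `baseline_age`, `sex`, `education`, `e4_count`,
#'   `financial_need`.
#' @param baseline_hazard depression onset hazard (events per person-year)
#'   at the mean PRS, from the age origin onward.
#' @param prs_log_hazard log hazard ratio per SD of the score driving onset.
#' @param fraction_ambiguous fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise harmonization filters.
#' @param seed integer seed; identical seed + config gives identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 2000L,
                       n_variants = 5000L,
                       block_size = 10L,
                       within_block_r = 0.6,
                       maf_range = c(0.05, 0.5),
                       causal_fraction = 0.02,
                       effect_sd = 0.05,
                       n_gwas = 156000L,
                       prevalence = 0.36,
                       genetic_var_share = 0.10,
                       covariate_effects = c(baseline_age = -0.10, sex = 0.10,
                                             education = -0.15, e4_count = 0.00,
                                             financial_need = 0.15),
                       baseline_hazard = 0.05,
                       prs_log_hazard = 0.12,
                       fraction_ambiguous = 0,
                       seed = 1L) {
  if (n_samples < 1 || n_variants < 1 || block_size < 1)
    stop2("n_samples, n_variants and block_size must be positive")
  if (!is.numeric(within_block_r) || within_block_r < 0 || within_block_r >= 1)
    stop2("within_block_r must lie in [0, 1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop2("maf_range must be an increasing pair in (0, 0.5]")
  assert_prob(causal_fraction, "causal_fraction", open_left = FALSE)
  assert_prob(prevalence, "prevalence", open_right = TRUE)
  if (genetic_var_share < 0 || genetic_var_share >= 1)
    stop2("genetic_var_share must lie in [0, 1)")
  assert_prob(fraction_ambiguous, "fraction_ambiguous", open_left = FALSE)
  if (effect_sd < 0 || n_gwas < 1) stop2("effect_sd must be >= 0 and n_gwas >= 1")
  if (baseline_hazard <= 0) stop2("baseline_hazard must be positive")
  known <- c("baseline_age", "sex", "education", "e4_count", "financial_need")
  if (!all(names(covariate_effects) %in% known))
    stop2("covariate_effects names must be among: ", paste(known, collapse = ", "))
  eff <- setNames(numeric(length(known)), known)
  eff[names(covariate_effects)] <- covariate_effects
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    block_size = as.integer(block_size), within_block_r = within_block_r,
    maf_range = maf_range, causal_fraction = causal_fraction,
    effect_sd = effect_sd, n_gwas = n_gwas, prevalence = prevalence,
    genetic_var_share = genetic_var_share, covariate_effects = eff,
    baseline_hazard = baseline_hazard, prs_log_hazard = prs_log_hazard,
    fraction_ambiguous = fraction_ambiguous, seed = as.integer(seed)
  ), class = "sim_config")
}

# Synthetic GRCh37-like variant map. Blocks are assigned to chromosomes 1..22
# round-robin; within a chromosome consecutive blocks start 1 Mb apart (so
# distinct blocks never share a 250 kb clumping window) and variants within a
# block sit 5 kb apart. The first block landing on chr19 is pinned inside the
# APOE exclusion region so the mask always has something to remove.
.apoe_start <- 45111942
.apoe_end <- 45711941

variant_map <- function(n_variants, block_size) {
  block <- rep(seq_len(ceiling(n_variants / block_size)), each = block_size)[seq_len(n_variants)]
  chrom <- ((block - 1L) %% 22L) + 1L
  chrom_block_idx <- stats::ave(block, chrom, FUN = function(b) match(b, unique(b)))
  within_idx <- stats::ave(seq_len(n_variants), block, FUN = seq_along)
  base <- 1e6 + (chrom_block_idx - 1) * 1e6
  on19 <- chrom == 19L
  base[on19] <- .apoe_start + 188058 + (chrom_block_idx[on19] - 1) * 1e6  # first chr19 block at 45.3 Mb
  data.frame(
    variant_id = sprintf("rs%07d", seq_len(n_variants)),
    chrom = as.character(chrom),
    pos = as.integer(base + (within_idx - 1) * 5000),
    block = block,
    stringsAsFactors = FALSE
  )
}

.non_ambiguous_pairs <- matrix(c("A","C", "A","G", "T","C", "T","G",
                                 "C","A", "G","A", "C","T", "G","T"),
                               ncol = 2, byrow = TRUE)
.ambiguous_pairs <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                           ncol = 2, byrow = TRUE)

#' Simulate LD-blocked genotype dosages
#'
#' Haplotypes are generated per LD block from a shared block "template"
#' haplotype: each variant copies the template allele with probability
#' `sqrt(within_block_r)` and otherwise draws a fresh Bernoulli(MAF) allele.
#' All variants in a block share one MAF, so marginal allele frequencies are
#' preserved and any two variants in a block have dosage correlation
#' `within_block_r` (hence r-squared `within_block_r^2`). Dosage is the sum
#' of two independent haplotype layers, giving Hardy-Weinberg genotypes.
#'
#' @param config a [sim_config()].
#' @param mode `"hard"` for genotypes in `{0,1,2}`; `"dosage"` adds small
#'   Gaussian imputation-like noise, truncated to `[0, 2]`.
#' @param template_variants variant annotations from a previous cohort's
#'   [genotype_matrix()]; reuses its map, alleles and MAFs so two cohorts
#'   share one variant universe (as discovery/validation cohorts genotyped
#'   on one panel do).
#' @return A [genotype_matrix()] whose variant annotations carry `chrom`,
#'   `pos` (synthetic GRCh37-like map including variants inside the APOE
#'   region chr19:45,111,942-45,711,941), allele pair, generating `maf`, and
#'   LD `block` index.
#' @export
simulate_genotypes <- function(config, mode = c("hard", "dosage"),
                               template_variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_samples
  m <- config$n_variants
  if (!is.null(template_variants)) {
    if (nrow(template_variants) != m)
      stop2("template_variants must match n_variants")
    map <- template_variants[c("variant_id", "chrom", "pos", "block")]
    maf_block <- tapply(template_variants$maf, template_variants$block, function(x) x[1])
    maf_block <- as.numeric(maf_block[as.character(seq_len(max(map$block)))])
  } else {
    map <- variant_map(m, config$block_size)
    maf_block <- runif(max(map$block), config$maf_range[1], config$maf_range[2])
  }
  copy_p <- sqrt(config$within_block_r)
  maf <- maf_block[map$block]

  dos <- matrix(0L, nrow = n, ncol = m)
  for (b in unique(map$block)) {
    idx <- which(map$block == b)
    p <- maf_block[b]
    for (layer in 1:2) {
      template <- rbinom(n, 1L, p)
      keep <- matrix(rbinom(n * length(idx), 1L, copy_p), n, length(idx))
      fresh <- matrix(rbinom(n * length(idx), 1L, p), n, length(idx))
      dos[, idx] <- dos[, idx] + keep * template + (1L - keep) * fresh
    }
  }
  if (mode == "dosage") {
    dos <- dos + rnorm(length(dos), sd = 0.05)
    dos <- pmin(pmax(dos, 0), 2)
  }

  if (!is.null(template_variants)) {
    alleles <- cbind(template_variants$a1, template_variants$a2)
  } else {
    # deterministic allele assignment by variant index, so cohorts simulated
    # over the same map agree on allele labels (like shared rsIDs)
    alleles <- .non_ambiguous_pairs[(seq_len(m) - 1L) %% nrow(.non_ambiguous_pairs) + 1L, ,
                                    drop = FALSE]
    n_amb <- round(config$fraction_ambiguous * m)
    if (n_amb > 0) {
      amb_idx <- seq(1L, m, length.out = n_amb)
      alleles[amb_idx, ] <- .ambiguous_pairs[(seq_len(n_amb) - 1L) %% 4L + 1L, , drop = FALSE]
    }
  }

  variants <- data.frame(
    variant_id = map$variant_id, chrom = map$chrom, pos = map$pos,
    a1 = alleles[, 1], a2 = alleles[, 2], maf = maf, block = map$block,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, sample_ids = sprintf("S%05d", seq_len(n)), variants = variants)
}

#' Draw the true per-variant effect vector
#'
#' A `causal_fraction` of variants receives a Normal(0, `effect_sd`^2)
#' per-allele effect; the rest are exactly zero.
#'
#' @param config a [sim_config()].
#' @return Numeric vector of length `n_variants`.
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "effects"))
  truth <- numeric(config$n_variants)
  k <- round(config$causal_fraction * config$n_variants)
  if (k > 0) truth[sample.int(config$n_variants, k)] <- rnorm(k, 0, config$effect_sd)
  truth
}

#' Simulate GWAS summary statistics around a true effect vector
#'
#' Each variant's estimated beta is `truth + Normal(0, se)` with
#' `se = 1 / sqrt(2 * n_gwas * maf * (1 - maf))`; the p-value is the
#' two-sided normal test of `beta / se`, the odds-ratio column is
#' `exp(beta)`, and INFO is drawn uniformly in `[0.5, 1]`.
#'
#' @param truth numeric effect vector, one entry per variant in `variants`.
#' @param variants variant annotation data frame (from a [genotype_matrix()]),
#'   with columns `variant_id`, `chrom`, `pos`, `a1`, `a2`, `maf`.
#' @param config a [sim_config()].
#' @return Data frame in daner-style layout: `SNP CHR BP A1 A2 OR SE P INFO`
#'   (plus a `BETA` convenience column). `A1` is the effect allele.
#' @export
simulate_summary_stats <- function(truth, variants, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(truth) != nrow(variants))
    stop2("length(truth) must equal nrow(variants)")
  set.seed(substream_seed(config$seed, "sumstats"))
  se <- 1 / sqrt(2 * config$n_gwas * variants$maf * (1 - variants$maf))
  beta <- truth + rnorm(length(truth), 0, se)
  p <- 2 * pnorm(-abs(beta / se))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(
    SNP = variants$variant_id, CHR = variants$chrom, BP = variants$pos,
    A1 = variants$a1, A2 = variants$a2,
    OR = exp(beta), SE = se, P = p,
    INFO = runif(length(truth), 0.5, 1.0), BETA = beta,
    stringsAsFactors = FALSE
  )
}

#' Simulate a liability-threshold depression phenotype with covariates
#'
#' The liability is `a * z_g + sum(c_k * z_k) + e` with `z_g` the
#' standardized true genetic score `dosages %*% truth`, `z_k` standardized
#' covariates with configured coefficients `c_k`, and `e` standard normal.
#' `a` is chosen so the genetic share of total liability variance equals
#' `genetic_var_share`; a subject is a case when liability exceeds the
#' normal quantile matching `prevalence`.
#'
#' Covariates are drawn with Alzheimer's-cohort-like marginals: baseline age
#' Normal(81.5, 6.7^2) years, education Normal(16.2, 3.7^2) years, sex
#' Bernoulli(0.68) (1 = female), APOE genotype from allele frequencies
#' e2/e3/e4 = 0.06/0.69/0.25 under Hardy-Weinberg (e4-enriched as in an
#' Alzheimer's sample), childhood financial need ordinal 1-5.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth per-variant effect vector (same length as variants).
#' @param config a [sim_config()].
#' @return A cohort data frame with columns `sample_id`, `case`,
#'   `baseline_age`, `sex`, `education`, `apoe_genotype`, `e4_count`,
#'   `financial_need`, and `genetic_value` (the true score, kept for
#'   oracle checks).
#' @export
simulate_phenotype <- function(genotypes, truth, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  if (length(truth) != ncol(genotypes$dosages))
    stop2("length(truth) must equal the number of variants")
  assert_prob(config$prevalence, "prevalence", open_right = TRUE)
  set.seed(substream_seed(config$seed, "phenotype"))
  n <- nrow(genotypes$dosages)

  g <- as.numeric(genotypes$dosages %*% truth)
  z_g <- if (sd(g) > 0) as.numeric(scale(g)) else numeric(n)

  baseline_age <- rnorm(n, 81.5, 6.7)
  sex <- rbinom(n, 1L, 0.68)
  education <- rnorm(n, 16.2, 3.7)
  apoe_alleles <- matrix(sample(c(2L, 3L, 4L), 2L * n, replace = TRUE,
                                prob = c(0.06, 0.69, 0.25)), ncol = 2)
  apoe_genotype <- paste0(pmin(apoe_alleles[, 1], apoe_alleles[, 2]),
                          pmax(apoe_alleles[, 1], apoe_alleles[, 2]))
  e4_count <- rowSums(apoe_alleles == 4L)
  financial_need <- sample(1:5, n, replace = TRUE, prob = c(0.25, 0.3, 0.25, 0.15, 0.05))

  zs <- function(x) if (sd(x) > 0) as.numeric(scale(x)) else numeric(n)
  covs <- cbind(baseline_age = zs(baseline_age), sex = zs(sex),
                education = zs(education), e4_count = zs(e4_count),
                financial_need = zs(financial_need))
  ce <- config$covariate_effects[colnames(covs)]
  cov_part <- as.numeric(covs %*% ce)
  c2 <- sum(ce^2)

  v <- config$genetic_var_share
  a <- if (v > 0 && sd(g) > 0) sqrt(v * (1 + c2) / (1 - v)) else 0
  liability <- a * z_g + cov_part + rnorm(n)
  total_sd <- sqrt(a^2 + c2 + 1)
  case <- as.integer(liability > qnorm(1 - config$prevalence, sd = total_sd))

  data.frame(
    sample_id = genotypes$sample_ids, case = case,
    baseline_age = baseline_age, sex = sex, education = education,
    apoe_genotype = apoe_genotype, e4_count = e4_count,
    financial_need = financial_need, genetic_value = g,
    stringsAsFactors = FALSE
  )
}

#' Simulate left-truncated depression onset ages
#'
#' Onset age is `origin + Exponential(rate)` with
#' `rate = baseline_hazard * exp(prs_log_hazard * z)` where `z` is the
#' standardized score; study entry age is Normal(81.5, 6.7^2) truncated
#' below at `origin + 1`. Subjects whose onset precedes entry are redrawn
#' (entry and onset jointly) — rejection sampling that mimics prevalent-cohort
#' recruitment, the generator's left-truncation contract. Follow-up is
#' uniform 2-12 years; onsets after last visit are right-censored there.
#'
#' @param cohort cohort data frame (rows = samples).
#' @param scores numeric score vector aligned to `cohort` rows, or a
#'   [score_set].
#' @param config a [sim_config()].
#' @param origin age at which subjects become at risk (years).
#' @return `cohort` with added columns `entry_age`, `exit_age`, `event`
#'   (1 = observed onset). Always satisfies `entry_age < exit_age`.
#' @export
simulate_onset <- function(cohort, scores, config, origin = 60) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(scores, "score_set")) scores <- scores$scores
  if (length(scores) != nrow(cohort)) stop2("scores must align with cohort rows")
  if (config$baseline_hazard <= 0) stop2("baseline_hazard must be positive")
  set.seed(substream_seed(config$seed, "onset"))
  n <- nrow(cohort)
  z <- if (sd(scores) > 0) as.numeric(scale(scores)) else numeric(n)
  rate <- config$baseline_hazard * exp(config$prs_log_hazard * z)

  draw_entry <- function(k) {
    e <- rnorm(k, 81.5, 6.7)
    while (any(bad <- e <= origin + 1)) e[bad] <- rnorm(sum(bad), 81.5, 6.7)
    e
  }
  entry <- draw_entry(n)
  onset <- origin + rexp(n, rate)
  for (iter in 1:1000) {
    bad <- which(onset <= entry)
    if (!length(bad)) break
    entry[bad] <- draw_entry(length(bad))
    onset[bad] <- origin + rexp(length(bad), rate[bad])
  }
  if (length(bad <- which(onset <= entry)))
    stop2("left-truncation rejection sampling failed to converge")

  last_visit <- entry + runif(n, 2, 12)
  event <- as.integer(onset <= last_visit)
  exit_age <- ifelse(event == 1L, onset, last_visit)
  cohort$entry_age <- entry
  cohort$exit_age <- exit_age
  cohort$event <- event
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_effects()],
#' [simulate_summary_stats()], [simulate_phenotype()] and [simulate_onset()]
#' (onset driven by the true genetic score). A second cohort drawn with a
#' different seed but the same `truth` serves as a validation cohort.
#'
#' @param config a [sim_config()].
#' @param truth optional effect vector; drawn via [simulate_effects()] when
#'   `NULL` (pass the discovery cohort's truth to build a validation cohort).
#' @param mode genotype mode, see [simulate_genotypes()].
#' @param template_variants see [simulate_genotypes()]; pass the discovery
#'   cohort's `genotypes$variants` when building a validation cohort.
#' @return List with `genotypes`, `truth`, `sumstats`, `cohort`, `config`.
#' @export
simulate_cohort <- function(config, truth = NULL, mode = "hard",
                            template_variants = NULL) {
  gm <- simulate_genotypes(config, mode = mode, template_variants = template_variants)
  if (is.null(truth)) truth <- simulate_effects(config)
  ss <- simulate_summary_stats(truth, gm$variants, config)
  cohort <- simulate_phenotype(gm, truth, config)
  cohort <- simulate_onset(cohort, cohort$genetic_value, config)
  list(genotypes = gm, truth = truth, sumstats = ss, cohort = cohort, config = config)
}
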