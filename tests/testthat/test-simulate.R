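test_that("identical seed and config reproduce the cohort exactly", {
  cfg <- sim_config(n_samples = 200, n_variants = 60, block_size = 6, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$cohort, b$cohort)
})

test_that("within-block dosage correlation tracks the configured target", {
  # independence case: mean off-diagonal r^2 at the 1/n noise floor
  cfg0 <- sim_config(n_samples = 5000, n_variants = 30, block_size = 6,
                     within_block_r = 0, seed = 21)
  gm0 <- simulate_genotypes(cfg0)
  r2 <- cor(gm0$dosages)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)

  # strong-LD case: r^2 should concentrate near within_block_r^2 = 0.81
  vals <- sapply(1:5, function(s) {
    cfg <- sim_config(n_samples = 5000, n_variants = 40, block_size = 10,
                      within_block_r = 0.9, seed = 100 + s)
    gm <- simulate_genotypes(cfg)
    mean(sapply(unique(gm$variants$block), function(b) {
      idx <- gm$variants$block == b
      r2b <- cor(gm$dosages[, idx])^2
      mean(r2b[upper.tri(r2b)])
    }))
  })
  expect_true(all(vals > 0.7 & vals < 0.95))
})

test_that("allele frequencies respect maf_range within binomial error", {
  cfg <- sim_config(n_samples = 5000, n_variants = 50, block_size = 5,
                    maf_range = c(0.3, 0.3), seed = 31)
  gm <- simulate_genotypes(cfg)
  af <- colMeans(gm$dosages) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 5000))
  expect_true(all(abs(af - 0.3) < 3 * se))
})

test_that("degenerate generator configs are rejected", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(within_block_r = 1), "within_block_r")
  expect_error(sim_config(prevalence = 1), "prevalence")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
})

test_that("null summary statistics give uniform p-values and the SE formula", {
  cfg <- sim_config(n_samples = 10, n_variants = 10000, seed = 41)
  variants <- data.frame(variant_id = sprintf("rs%05d", 1:10000),
                         chrom = "1", pos = 1:10000,
                         a1 = "A", a2 = "G", maf = runif(10000, 0.05, 0.5))
  frac <- sapply(1:10, function(s) {
    cfg_s <- sim_config(n_samples = 10, n_variants = 10000, seed = 41 + s)
    ss <- simulate_summary_stats(rep(0, 10000), variants, cfg_s)
    mean(ss$P < 0.05)
  })
  expect_gt(mean(frac), 0.04)
  expect_lt(mean(frac), 0.06)

  # doubling the GWAS sample shrinks SE by exactly 1/sqrt(2)
  ss1 <- simulate_summary_stats(rep(0, 10000), variants, cfg)
  cfg2 <- sim_config(n_samples = 10, n_variants = 10000,
                     n_gwas = 2 * cfg$n_gwas, seed = 41)
  ss2 <- simulate_summary_stats(rep(0, 10000), variants, cfg2)
  ratio <- median(ss2$SE) / median(ss1$SE)
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.05 / sqrt(2))

  # odds-ratio column is exp(beta)
  expect_equal(ss1$OR, exp(ss1$BETA))
  expect_error(simulate_summary_stats(rep(0, 3), variants, cfg), "length")
})

test_that("liability phenotype hits the configured prevalence", {
  cfg <- sim_config(n_samples = 10000, n_variants = 50, block_size = 5,
                    prevalence = 0.36, causal_fraction = 0.2, seed = 51)
  gm <- simulate_genotypes(cfg)
  truth <- simulate_effects(cfg)
  coh <- simulate_phenotype(gm, truth, cfg)
  se <- sqrt(0.36 * 0.64 / 10000)
  expect_lt(abs(mean(coh$case) - 0.36), 3 * se)
  expect_true(all(coh$e4_count %in% 0:2))
  expect_true(all(nchar(coh$apoe_genotype) == 2))
})

test_that("zero genetic variance share decouples score and case status", {
  cfg <- sim_config(n_samples = 10000, n_variants = 50, block_size = 5,
                    causal_fraction = 0.5, genetic_var_share = 0, seed = 61)
  gm <- simulate_genotypes(cfg)
  truth <- simulate_effects(cfg)
  coh <- simulate_phenotype(gm, truth, cfg)
  expect_gt(sd(coh$genetic_value), 0)
  expect_lt(abs(cor(coh$genetic_value, coh$case)), 0.03)
})

test_that("more heritable liabilities give higher true-score AUC", {
  auc_at <- function(v) {
    mean(sapply(1:3, function(s) {
      cfg <- sim_config(n_samples = 4000, n_variants = 40, block_size = 4,
                        causal_fraction = 0.5, genetic_var_share = v, seed = 70 + s)
      gm <- simulate_genotypes(cfg)
      truth <- simulate_effects(cfg)
      coh <- simulate_phenotype(gm, truth, cfg)
      roc_auc(coh$genetic_value, coh$case)$auc
    }))
  }
  a <- auc_at(0.05); b <- auc_at(0.2); c <- auc_at(0.5)
  expect_lt(a, b)
  expect_lt(b, c)
})

test_that("onset generator recovers the configured log hazard ratio", {
  fit_lhr <- function(lhr, seed) {
    cfg <- sim_config(n_samples = 5000, n_variants = 10, block_size = 5,
                      prs_log_hazard = lhr, seed = seed)
    coh <- data.frame(sample_id = sprintf("S%05d", 1:5000))
    scores <- rnorm(5000)
    coh <- simulate_onset(coh, scores, cfg)
    coh$z <- as.numeric(scale(scores))
    fit_ph_left_truncated(coh, "z")$terms$coef[1]
  }
  expect_lt(abs(fit_lhr(0, 81)), 0.05)
  expect_lt(abs(fit_lhr(0.3, 82) - 0.3), 0.05)
})

test_that("a vanishing baseline hazard censors everyone", {
  cfg <- sim_config(n_samples = 300, n_variants = 10, block_size = 5,
                    baseline_hazard = 1e-9, seed = 91)
  coh <- data.frame(sample_id = sprintf("S%05d", 1:300))
  coh <- simulate_onset(coh, rnorm(300), cfg)
  expect_identical(sum(coh$event), 0L)
  expect_true(all(coh$entry_age < coh$exit_age))
  # downstream log-rank is undefined and reported as such
  lr <- logrank_test(coh, rep(c("a", "b"), 150))
  expect_false(lr$defined)
  expect_true(is.na(lr$p))
})

test_that("onset times respect the left-truncation contract", {
  cfg <- sim_config(n_samples = 2000, n_variants = 10, block_size = 5, seed = 95)
  coh <- data.frame(sample_id = sprintf("S%04d", 1:2000))
  coh <- simulate_onset(coh, rnorm(2000), cfg)
  expect_true(all(coh$entry_age < coh$exit_age))
  expect_true(all(coh$entry_age > 60))
})
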