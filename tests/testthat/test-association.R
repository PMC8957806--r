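test_that("intercept-only logistic fit matches the closed-form MLE", {
  coh <- data.frame(case = rep(c(1, 0), c(30, 70)))
  rep <- fit_logistic(coh, character())
  expect_equal(rep$terms$estimate[1], log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("logistic regression recovers a known coefficient", {
  set.seed(12)
  n <- 8000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * x))
  rep <- fit_logistic(data.frame(case = y, x = x), "x")
  i <- match("x", rep$terms$term)
  expect_lt(abs(rep$terms$estimate[i] - 0.8), 0.1)
  expect_true(rep$converged)
})

test_that("logistic guards: rank deficiency errors, separation warns", {
  set.seed(13)
  d <- data.frame(case = rbinom(50, 1, 0.5), a = rnorm(50))
  d$b <- 2 * d$a
  expect_error(fit_logistic(d, c("a", "b")), "collinear")
  sep <- data.frame(case = rep(c(0, 1), each = 20), x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_warning(rs <- fit_logistic(sep, "x"), "separation")
  expect_true(rs$separation)
})

test_that("ROC AUC equals pair counting, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # brute-force enumeration with ties counting one half
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auc,
               oracle_auc(c(1, 2, 2, 3), c(0, 1, 0, 1)))
  set.seed(14)
  s <- rnorm(10000); l <- sample(rep(0:1, 5000))
  expect_gt(roc_auc(s, l)$auc, 0.48)
  expect_lt(roc_auc(s, l)$auc, 0.52)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("ROC curve endpoints and monotonicity are sane", {
  set.seed(15)
  r <- roc_auc(rnorm(50), rbinom(50, 1, 0.5))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("DeLong test: identity convention and agreement with pROC", {
  set.seed(16)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  sig <- rnorm(n) + y
  a <- sig + rnorm(n, 0, 0.5)
  b <- sig + rnorm(n, 0, 0.8)
  self <- delong_test(a, a, y)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)

  dl <- delong_test(a, b, y)
  roc_of <- function(p) pROC::roc(y, p, quiet = TRUE, direction = "<", levels = c(0, 1))
  ref <- pROC::roc.test(roc_of(a), roc_of(b), method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(dl$z), abs(unname(ref$statistic)), tolerance = 1e-8)
})

test_that("one-sided case/control mean comparison behaves at its poles", {
  set.seed(17)
  x <- rnorm(100)
  labels <- rep(c(1, 0), each = 100)
  # identical groups: symmetric null of the one-sided test
  same <- compare_score_means(c(x, x), labels)
  expect_equal(same$p, 0.5, tolerance = 1e-12)
  # cases shifted +1 SD
  up <- compare_score_means(c(x + 1, rnorm(100)), labels)
  expect_lt(up$p, 1e-6)
  # reversed direction: one-sided p above 0.5
  down <- compare_score_means(c(x - 1, x), labels)
  expect_gt(down$p, 0.5)
})

test_that("genotype PCA separates simulated subpopulations deterministically", {
  set.seed(18)
  n <- 200; m <- 120
  pop <- rep(0:1, each = n / 2)
  af1 <- runif(m, 0.1, 0.9); af2 <- pmin(pmax(af1 + runif(m, -0.35, 0.35), 0.05), 0.95)
  d <- t(sapply(pop, function(g) rbinom(m, 2, if (g == 0) af1 else af2)))
  gm <- make_gm(d)
  pc <- pca_genotypes(gm, k = 3)
  expect_gt(abs(cor(pc$scores[, 1], pop)), 0.9)
  pc2 <- pca_genotypes(gm, k = 3)
  expect_identical(pc$scores, pc2$scores)  # fixed sign convention

  # homogeneous population: no dominant axis
  dh <- t(sapply(1:200, function(i) rbinom(m, 2, af1)))
  ph <- pca_genotypes(make_gm(dh), k = 3)
  expect_lt(ph$variance_share[1], 5 / m)
  expect_error(pca_genotypes(make_gm(dh[1:3, 1:2]), k = 3), "rank")
})

test_that("threshold selection maximizes the PRS effect size", {
  sweep <- data.frame(threshold = c(0.5, 0.05, 0.005),
                      n_snps = c(100, 50, 10),
                      estimate = c(0.05, 0.153, 0.09),
                      se = 0.1, p = 0.5, auc = 0.5, converged = TRUE)
  expect_equal(select_threshold(sweep)$threshold, 0.05)
  expect_equal(select_threshold(sweep[3, ])$threshold, 0.005)
  # ties go to the smaller threshold
  sweep$estimate <- c(0.1, 0.1, 0.05)
  expect_equal(select_threshold(sweep)$threshold, 0.05)
  sweep$converged <- FALSE
  expect_error(select_threshold(sweep), "converged")
})

test_that("threshold selection tracks signal density in simulation", {
  hits <- sapply(1:6, function(s) {
    cfg <- sim_config(n_samples = 1200, n_variants = 300, block_size = 5,
                      causal_fraction = 0.1, effect_sd = 0.08,
                      genetic_var_share = 0.4, seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    v <- data.frame(variant_id = sim$sumstats$SNP, chrom = sim$sumstats$CHR,
                    pos = sim$sumstats$BP, beta = sim$sumstats$BETA,
                    p = sim$sumstats$P)
    cl <- clump(v, sim$genotypes, clump_params())
    sw <- sweep_thresholds(cl, sim$genotypes, sim$cohort)
    select_threshold(sw)$threshold <= 0.01
  })
  expect_gte(sum(hits), 4)
})

test_that("APOE e3-homozygote stratification keeps genotype 33 only", {
  coh <- data.frame(sample_id = 1:10,
                    apoe_genotype = c("33", "34", "44", "33", "23", "33", "24", "22", "33", "34"),
                    e4_count = c(0, 1, 2, 0, 0, 0, 1, 0, 0, 1))
  sub <- stratify_e3_homozygotes(coh)
  expect_equal(nrow(sub), 4L)
  expect_true(all(sub$apoe_genotype == "33"))
  expect_true(all(sub$e4_count == 0))
})

test_that("adding pure-noise covariates never decreases in-sample AUC", {
  set.seed(19)
  n <- 500
  d <- data.frame(case = rbinom(n, 1, 0.4), x = rnorm(n),
                  junk1 = rnorm(n), junk2 = rnorm(n))
  d$case <- rbinom(n, 1, plogis(-0.3 + 0.5 * d$x))
  a0 <- fit_logistic(d, "x")$auc
  a1 <- fit_logistic(d, c("x", "junk1"))$auc
  a2 <- fit_logistic(d, c("x", "junk1", "junk2"))$auc
  expect_gte(a1, a0 - 1e-12)
  expect_gte(a2, a1 - 1e-12)
})
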