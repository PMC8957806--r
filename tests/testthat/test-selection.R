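test_that("the canonical threshold sweep has exactly the 14 standard values", {
  th <- prs_thresholds()
  expect_length(th, 14L)
  expect_equal(th[1], 0.5)
  expect_equal(th[14], 1e-8)
  expect_true(all(diff(th) < 0))
})

test_that("harmonization aligns betas across all allele configurations", {
  d <- matrix(1, nrow = 4, ncol = 1)
  base_stats <- function(a1, a2) data.frame(
    variant_id = "v001", chrom = "1", pos = 1000L,
    effect_allele = a1, other_allele = a2, beta = 0.2, se = 0.1, p = 0.01,
    stringsAsFactors = FALSE)

  # identity match: target counts A
  gm <- make_gm(d, a1 = "A", a2 = "G")
  h <- harmonize(base_stats("A", "G"), gm)
  expect_equal(h$variants$beta, 0.2)
  expect_false(h$variants$flip)

  # swapped: target counts G -> beta negated, flip flagged
  gm2 <- make_gm(d, a1 = "G", a2 = "A")
  h2 <- harmonize(base_stats("A", "G"), gm2)
  expect_equal(h2$variants$beta, -0.2)
  expect_true(h2$variants$flip)

  # strand-complement: GWAS A/G vs target T/C
  gm3 <- make_gm(d, a1 = "T", a2 = "C")
  h3 <- harmonize(base_stats("A", "G"), gm3)
  expect_equal(h3$variants$beta, 0.2)
  expect_equal(h3$report$strand_complemented, 1L)

  # complement + swap: GWAS A/G vs target C/T
  gm4 <- make_gm(d, a1 = "C", a2 = "T")
  h4 <- harmonize(base_stats("A", "G"), gm4)
  expect_equal(h4$variants$beta, -0.2)
  expect_true(h4$variants$flip)

  # ambiguous A/T dropped by default, kept when allowed
  gm5 <- make_gm(d, a1 = "A", a2 = "T")
  h5 <- harmonize(base_stats("A", "T"), gm5)
  expect_equal(nrow(h5$variants), 0L)
  expect_equal(h5$report$ambiguous_dropped, 1L)
  h5b <- harmonize(base_stats("A", "T"), gm5, drop_ambiguous = FALSE)
  expect_equal(h5b$variants$beta, 0.2)

  # true mismatch dropped
  gm6 <- make_gm(d, a1 = "A", a2 = "C")
  h6 <- harmonize(base_stats("A", "G"), gm6)
  expect_equal(nrow(h6$variants), 0L)
  expect_equal(h6$report$mismatch_dropped, 1L)
})

test_that("harmonization enumerates the full 12-pair allele table correctly", {
  # hand enumeration: for target A/G, every GWAS ordered pair classified
  d <- matrix(1, nrow = 4, ncol = 1)
  gm <- make_gm(d, a1 = "A", a2 = "G")
  pairs <- list(
    list("A", "G", "direct"), list("G", "A", "swap"),
    list("T", "C", "comp"),   list("C", "T", "comp_swap"),
    list("A", "T", "ambiguous"), list("T", "A", "ambiguous"),
    list("C", "G", "ambiguous"), list("G", "C", "ambiguous"),
    list("A", "C", "mismatch"), list("C", "A", "mismatch"),
    list("T", "G", "mismatch"), list("G", "T", "mismatch")
  )
  for (pr in pairs) {
    st <- data.frame(variant_id = "v001", chrom = "1", pos = 1000L,
                     effect_allele = pr[[1]], other_allele = pr[[2]],
                     beta = 0.3, se = 0.1, p = 0.01, stringsAsFactors = FALSE)
    h <- harmonize(st, gm)
    lab <- paste(pr[[1]], pr[[2]])
    switch(pr[[3]],
      direct = { expect_equal(h$variants$beta, 0.3, label = lab) },
      swap = { expect_equal(h$variants$beta, -0.3, label = lab) },
      comp = { expect_equal(h$variants$beta, 0.3, label = lab) },
      comp_swap = { expect_equal(h$variants$beta, -0.3, label = lab) },
      ambiguous = { expect_equal(h$report$ambiguous_dropped, 1L, label = lab) },
      mismatch = { expect_equal(h$report$mismatch_dropped, 1L, label = lab) }
    )
  }
})

test_that("the APOE mask removes inclusively and only within bounds", {
  v <- data.frame(variant_id = c("in_mid", "below", "at_end", "at_start", "other_chrom"),
                  chrom = c("19", "19", "19", "19", "1"),
                  pos = c(45500000L, 45111941L, 45711941L, 45111942L, 45500000L),
                  p = 0.5)
  res <- mask_region(v, apoe_region())
  expect_identical(res$variants$variant_id, c("below", "other_chrom"))
  expect_equal(res$n_removed, 3L)
})

test_that("r-squared behaves at its boundary cases", {
  d <- cbind(a = c(0, 1, 2, 0, 1, 2), b = c(2, 1, 0, 2, 1, 0), c = c(1, 1, 1, 1, 1, 1))
  gm <- make_gm(d, ids = c("a", "b", "c"))
  expect_equal(as.numeric(compute_r2(gm, "a", "a")), 1)
  # perfect negative correlation squares to 1
  expect_equal(as.numeric(compute_r2(gm, "a", "b")), 1)
  # zero variance -> 0 with flag
  r <- compute_r2(gm, "a", "c")
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "undefined"))
  # independent variants at n = 10,000
  set.seed(5)
  big <- make_gm(cbind(rbinom(10000, 2, 0.3), rbinom(10000, 2, 0.3)))
  expect_lt(as.numeric(compute_r2(big, 1, 2)), 0.01)
})

test_that("greedy clumping retains and prunes per the r2/window rules", {
  # three SNPs: strong LD between 1-2 within the window, weak 1-3
  set.seed(13)
  n <- 2000
  x1 <- rbinom(n, 2, 0.4)
  flipmask <- rbinom(n, 1, 0.15) == 1
  x2 <- ifelse(flipmask, rbinom(n, 2, 0.4), x1)   # r2 well above 0.1
  x3 <- rbinom(n, 2, 0.4)                          # independent
  gm <- make_gm(cbind(x1, x2, x3), pos = c(1000L, 2000L, 3000L),
                ids = c("s1", "s2", "s3"))
  stopifnot(cor(x1, x2)^2 > 0.5, cor(x1, x3)^2 < 0.05)
  v <- data.frame(variant_id = c("s1", "s2", "s3"), chrom = "1",
                  pos = c(1000L, 2000L, 3000L), p = c(1e-8, 1e-4, 1e-3),
                  stringsAsFactors = FALSE)
  kept <- clump(v, gm, clump_params())
  expect_setequal(kept$variant_id, c("s1", "s3"))

  # no LD anywhere: everything is its own index
  gm0 <- random_gm(3000, 6, seed = 17)
  v0 <- gm0$variants[c("variant_id", "chrom", "pos")]
  v0$p <- seq(0.1, 0.6, by = 0.1)
  expect_equal(nrow(clump(v0, gm0, clump_params())), 6L)

  # total LD in one window: only the smallest-p SNP survives
  x <- rbinom(500, 2, 0.3)
  gmT <- make_gm(cbind(x, x, x), pos = c(1000L, 2000L, 3000L))
  vT <- data.frame(variant_id = sprintf("v%03d", 1:3), chrom = "1",
                   pos = c(1000L, 2000L, 3000L), p = c(0.2, 0.05, 0.9),
                   stringsAsFactors = FALSE)
  keptT <- clump(vT, gmT, clump_params())
  expect_identical(keptT$variant_id, "v002")
})

test_that("clumped output is an antichain under the r2/window relation", {
  for (s in 1:5) {
    gm <- random_gm(300, 30, seed = 200 + s,
                    pos = as.integer(cumsum(sample(c(1e3, 1e5, 3e5), 30, TRUE))))
    v <- gm$variants[c("variant_id", "chrom", "pos")]
    set.seed(300 + s)
    v$p <- runif(30)
    kept <- clump(v, gm, clump_params(r2_threshold = 0.05, window_kb = 250))
    if (nrow(kept) < 2) next
    for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
      if (abs(kept$pos[i] - kept$pos[j]) <= 250e3) {
        expect_lte(as.numeric(compute_r2(gm, kept$variant_id[i], kept$variant_id[j])),
                   0.05)
      }
    }
  }
})

test_that("p-value thresholding is inclusive and validates its argument", {
  v <- data.frame(variant_id = c("a", "b", "c"), p = c(0.005, 0.0049, 0.9))
  expect_identical(apply_threshold(v, 0.005)$variant_id, c("a", "b"))
  expect_equal(nrow(apply_threshold(v, 1.0)), 3L)
  expect_error(apply_threshold(v, 0), "p_threshold")
  expect_error(apply_threshold(v, 1.5), "p_threshold")
})

test_that("masking before or after clumping commutes away from the mask", {
  # all variants outside the APOE region; no clump index inside the mask
  gm <- random_gm(400, 12, seed = 31,
                  chrom = rep("2", 12), pos = as.integer(seq(1e6, 12e6, 1e6)))
  v <- gm$variants[c("variant_id", "chrom", "pos")]
  set.seed(32)
  v$p <- runif(12)
  a <- clump(mask_region(v)$variants, gm, clump_params())
  b <- mask_region(clump(v, gm, clump_params()))$variants
  expect_identical(a$variant_id, b$variant_id)
})
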