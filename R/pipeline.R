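#' Run the discovery C+T pipeline end to end
#'
#' Executes the full funnel on one cohort: INFO filter, variant QC,
#' harmonization, APOE masking, LD clumping, the standalone-PRS p-value
#' threshold sweep with effect-size-based threshold selection, score
#' construction under both formulas, logistic/ROC evaluation (standalone,
#' full, full + PCs, optionally + childhood financial need) with DeLong
#' nested-model comparisons, the APOE e3-homozygote stratum, and the
#' left-truncated time-to-event analysis with tertile survival curves and a
#' log-rank test.
#'
#' @param sumstats summary-statistic data frame (internal layout from
#'   [read_summary_stats()], or the generator's daner-style columns).
#' @param genotypes a [genotype_matrix()].
#' @param cohort cohort data frame (`sample_id`, `case`, covariates,
#'   `entry_age`, `exit_age`, `event`).
#' @param qc a [qc_thresholds()].
#' @param clump_pars a [clump_params()].
#' @param thresholds sweep list, default the canonical 14 values.
#' @param min_info INFO filter threshold (strict `>`).
#' @param mask a [region_mask()]; default the APOE region.
#' @param drop_ambiguous drop strand-ambiguous SNPs during harmonization.
#' @param n_pcs number of genotype principal components to adjust for.
#' @param include_financial_need add the childhood financial-need covariate
#'   model variants (skipped when the column is absent).
#' @param ref_freqs optional reference allele frequencies for QC.
#' @return A `prs_run` bundle: `selected_threshold`, `sweep`, `scores`
#'   (standard + risk-increasing [score_set()]s), `models`, `delong`,
#'   `score_means`, `stratum`, `survival`, `pca`, `funnel`, `manifest`.
#' @export
run_discovery <- function(sumstats, genotypes, cohort,
                          qc = qc_thresholds(), clump_pars = clump_params(),
                          thresholds = prs_thresholds(), min_info = 0.9,
                          mask = apoe_region(), drop_ambiguous = TRUE,
                          n_pcs = 3, include_financial_need = TRUE,
                          ref_freqs = NULL) {
  run_ct_pipeline(sumstats, genotypes, cohort, fixed_threshold = NULL,
                  qc = qc, clump_pars = clump_pars, thresholds = thresholds,
                  min_info = min_info, mask = mask,
                  drop_ambiguous = drop_ambiguous, n_pcs = n_pcs,
                  include_financial_need = include_financial_need,
                  ref_freqs = ref_freqs)
}

#' Run the validation pipeline at a fixed threshold
#'
#' Identical stages to [run_discovery()] except that threshold selection is
#' bypassed: the supplied `fixed_threshold` (chosen on the discovery
#' cohort) is applied verbatim and no sweep-based selection happens.
#'
#' @inheritParams run_discovery
#' @param fixed_threshold the discovery-selected p-value threshold
#'   (mandatory).
#' @return A `prs_run` bundle (see [run_discovery()]); `sweep` still tables
#'   all thresholds for reporting, but selection is not based on it.
#' @export
run_validation <- function(sumstats, genotypes, cohort, fixed_threshold,
                           qc = qc_thresholds(), clump_pars = clump_params(),
                           thresholds = prs_thresholds(), min_info = 0.9,
                           mask = apoe_region(), drop_ambiguous = TRUE,
                           n_pcs = 3, include_financial_need = TRUE,
                           ref_freqs = NULL) {
  if (missing(fixed_threshold) || is.null(fixed_threshold))
    stop2("validation requires `fixed_threshold` (no sweep-based selection)")
  assert_prob(fixed_threshold, "fixed_threshold")
  run_ct_pipeline(sumstats, genotypes, cohort, fixed_threshold = fixed_threshold,
                  qc = qc, clump_pars = clump_pars, thresholds = thresholds,
                  min_info = min_info, mask = mask,
                  drop_ambiguous = drop_ambiguous, n_pcs = n_pcs,
                  include_financial_need = include_financial_need,
                  ref_freqs = ref_freqs)
}

# Normalize generator daner-style columns to the internal sumstats layout.
as_internal_sumstats <- function(sumstats) {
  if ("variant_id" %in% names(sumstats)) return(sumstats)
  data.frame(
    variant_id = sumstats$SNP, chrom = as.character(sumstats$CHR),
    pos = sumstats$BP, effect_allele = sumstats$A1, other_allele = sumstats$A2,
    beta = if ("BETA" %in% names(sumstats)) sumstats$BETA else log(sumstats$OR),
    se = sumstats$SE, p = sumstats$P,
    info = if ("INFO" %in% names(sumstats)) sumstats$INFO else NA_real_,
    stringsAsFactors = FALSE
  )
}

run_ct_pipeline <- function(sumstats, genotypes, cohort, fixed_threshold,
                            qc, clump_pars, thresholds, min_info, mask,
                            drop_ambiguous, n_pcs, include_financial_need,
                            ref_freqs) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!length(thresholds) || any(thresholds <= 0 | thresholds > 1))
    stop2("thresholds must be a nonempty vector of values in (0, 1]")
  sumstats <- as_internal_sumstats(sumstats)
  cohort <- cohort[match(genotypes$sample_ids, cohort$sample_id), , drop = FALSE]
  if (anyNA(cohort$sample_id)) stop2("cohort is missing samples present in genotypes")
  funnel <- list(sumstats_in = nrow(sumstats))

  inf <- filter_info(sumstats, min_info = min_info)
  funnel$sumstats_info <- inf$report$n_after

  qcres <- qc_variants(genotypes, qc, ref_freqs = ref_freqs)
  gm <- qcres$genotypes
  funnel$variants_in <- qcres$report$n_before
  funnel$variants_qc <- qcres$report$n_after

  harm <- harmonize(inf$stats, gm, drop_ambiguous = drop_ambiguous)
  funnel$harmonized <- nrow(harm$variants)

  masked <- mask_region(harm$variants, mask)
  funnel$post_mask <- nrow(masked$variants)
  funnel$mask_removed <- masked$n_removed

  clumped <- clump(masked$variants, gm, clump_pars)
  funnel$post_clump <- nrow(clumped)
  if (!nrow(clumped)) stop2("clumping stage left no variants")

  sweep <- sweep_thresholds(clumped, gm, cohort, thresholds = thresholds)
  selected <- if (is.null(fixed_threshold)) select_threshold(sweep)$threshold
              else fixed_threshold

  sel_variants <- apply_threshold(clumped, selected)
  if (!nrow(sel_variants)) stop2("no variants pass the selected threshold")
  funnel$selected_snps <- nrow(sel_variants)

  std_raw <- score_standard(sel_variants, gm, p_threshold = selected)
  std <- standardize_scores(std_raw)
  risk <- score_risk_increasing(sel_variants, gm, p_threshold = selected)

  pca <- pca_genotypes(subset_variants(gm, clumped$variant_id), k = n_pcs)

  dat <- cohort
  dat$PRS <- std$scores[dat$sample_id]
  pcs <- pca$scores[dat$sample_id, , drop = FALSE]
  for (j in colnames(pcs)) dat[[j]] <- pcs[, j]

  full_terms <- c("PRS", "baseline_age", "sex", "education", "e4_count")
  pc_terms <- colnames(pcs)
  has_fn <- include_financial_need && "financial_need" %in% names(dat)

  models <- list(
    standalone = fit_logistic(dat, "PRS", label = "standalone"),
    full = fit_logistic(dat, full_terms, label = "full"),
    full_no_prs = fit_logistic(dat, setdiff(full_terms, "PRS"), label = "full_no_prs"),
    full_pcs = fit_logistic(dat, c(full_terms, pc_terms), label = "full_pcs")
  )
  if (has_fn) {
    models$full_fn <- fit_logistic(dat, c(full_terms, "financial_need"), label = "full_fn")
    models$full_fn_no_prs <- fit_logistic(dat, c(setdiff(full_terms, "PRS"), "financial_need"),
                                          label = "full_fn_no_prs")
  }
  delong <- list(
    full_vs_no_prs = delong_test(models$full$fitted, models$full_no_prs$fitted, dat$case)
  )
  if (has_fn)
    delong$full_fn_vs_no_prs <-
      delong_test(models$full_fn$fitted, models$full_fn_no_prs$fitted, dat$case)

  score_means <- compare_score_means(dat$PRS, dat$case)

  stratum <- NULL
  strat <- stratify_e3_homozygotes(dat)
  if (nrow(strat) >= 20 && length(unique(strat$case)) == 2) {
    strat_terms <- setdiff(full_terms, "e4_count")
    stratum <- list(
      n = nrow(strat),
      standalone = fit_logistic(strat, "PRS", label = "e3e3 standalone"),
      full = fit_logistic(strat, strat_terms, label = "e3e3 full")
    )
  }

  surv <- NULL
  if (all(c("entry_age", "exit_age", "event") %in% names(dat))) {
    if (sum(dat$event) == 0) {
      surv <- list(defined = FALSE, reason = "zero events: all subjects censored")
    } else {
      sdat <- dat
      sdat$risk_PRS <- risk$scores[sdat$sample_id]
      surv_full <- c("baseline_age", "sex", "education", "e4_count")
      tert <- tertile_groups(std$scores[sdat$sample_id])
      surv <- list(
        defined = TRUE,
        standard = list(
          standalone = fit_ph_left_truncated(sdat, "PRS"),
          full = fit_ph_left_truncated(sdat, c("PRS", surv_full)),
          full_no_age = fit_ph_left_truncated(sdat, c("PRS", setdiff(surv_full, "baseline_age")))
        ),
        risk_increasing = list(
          standalone = fit_ph_left_truncated(sdat, "risk_PRS"),
          full = fit_ph_left_truncated(sdat, c("risk_PRS", surv_full))
        ),
        tertiles = tert,
        km = km_curve(sdat, groups = tert),
        logrank = logrank_test(sdat, tert)
      )
    }
  }

  manifest <- list(
    params = list(
      min_info = min_info, qc = unclass(qc), clump = unclass(clump_pars),
      thresholds = thresholds, mask = unclass(mask),
      drop_ambiguous = drop_ambiguous, n_pcs = n_pcs,
      mode = if (is.null(fixed_threshold)) "discovery" else "validation",
      fixed_threshold = fixed_threshold
    ),
    n_samples = nrow(cohort),
    funnel = funnel,
    selected_threshold = selected,
    sweep = sweep
  )

  structure(list(
    selected_threshold = selected, sweep = sweep,
    scores = list(standard = std, standard_raw = std_raw, risk_increasing = risk),
    models = models, delong = delong, score_means = score_means,
    stratum = stratum, survival = surv, pca = pca,
    funnel = funnel, manifest = manifest, data = dat
  ), class = "prs_run")
}

#' @export
print.prs_run <- function(x, ...) {
  cat(sprintf("<prs_run> %s: threshold %g, %d SNPs scored, standalone AUC %.3f\n",
              x$manifest$params$mode, x$selected_threshold,
              x$funnel$selected_snps, x$models$standalone$auc))
  invisible(x)
}

#' Write a run manifest as canonical JSON
#'
#' Deterministic serialization (fixed precision, no pretty-printing
#' ambiguity) so reruns under the same seed produce byte-identical
#' manifests.
#'
#' @param run a `prs_run` bundle.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  json <- jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
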