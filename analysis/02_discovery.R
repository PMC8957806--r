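#!/usr/bin/env Rscript
# Discovery analysis: INFO filter -> variant QC -> harmonization -> APOE mask
# -> LD clumping -> 14-threshold sweep -> threshold selection -> scores ->
# logistic/ROC/DeLong models (incl. PCs and the APOE e3/e3 stratum).
#
# Reads the files written by 01_simulate.R through the package's own file
# readers, so the whole file-format surface is exercised.

suppressPackageStartupMessages(library(prsonset))

in_dir <- "scratch/analysis"
stopifnot(file.exists(file.path(in_dir, "sumstats.tsv")))

message("== 02: discovery pipeline ==")
ss <- read_summary_stats(file.path(in_dir, "sumstats.tsv"))
message(sprintf("summary stats: %d rows parsed, %d skipped",
                ss$report$n_parsed, ss$report$n_skipped))
gm <- read_genotypes(file.path(in_dir, "discovery_dosages.tsv"))
cohort <- as.data.frame(data.table::fread(file.path(in_dir, "discovery_cohort.tsv")))

run <- run_discovery(ss$stats, gm, cohort)

f <- run$funnel
message(sprintf(
  "funnel: %d sumstats -> %d INFO>0.9 -> %d harmonized -> %d post-mask (%d masked) -> %d post-clump -> %d scored",
  f$sumstats_in, f$sumstats_info, f$harmonized, f$post_mask, f$mask_removed,
  f$post_clump, f$selected_snps))
message(sprintf("selected p-threshold: %g", run$selected_threshold))
message(sprintf("standalone PRS AUC %.3f | full model AUC %.3f | full+PC1-3 AUC %.3f",
                run$models$standalone$auc, run$models$full$auc, run$models$full_pcs$auc))
message(sprintf("case vs control mean PRS: %.3f vs %.3f (one-sided t, p = %.3g)",
                run$score_means$mean_case, run$score_means$mean_control,
                run$score_means$p))
message(sprintf("DeLong full vs full-without-PRS: p = %.3g",
                run$delong$full_vs_no_prs$p))
if (!is.null(run$stratum))
  message(sprintf("APOE e3/e3 stratum (n=%d): standalone AUC %.3f, full AUC %.3f",
                  run$stratum$n, run$stratum$standalone$auc, run$stratum$full$auc))

dir.create("results", showWarnings = FALSE)
data.table::fwrite(run$sweep, "results/discovery_sweep.tsv", sep = "\t")
model_rows <- do.call(rbind, lapply(run$models, function(m)
  data.frame(model = m$label, auc = m$auc, n = m$n,
             prs_beta = if ("PRS" %in% m$terms$term)
               m$terms$estimate[match("PRS", m$terms$term)] else NA,
             prs_p = if ("PRS" %in% m$terms$term)
               m$terms$p[match("PRS", m$terms$term)] else NA)))
data.table::fwrite(model_rows, "results/discovery_models.tsv", sep = "\t")
data.table::fwrite(
  data.frame(stage = names(unlist(f)), count = unlist(f)),
  "results/discovery_funnel.tsv", sep = "\t")
write_manifest(run, "results/discovery_manifest.json")
write_scores(run$scores$standard, "results/discovery_scores_standard.tsv")
write_scores(run$scores$risk_increasing, "results/discovery_scores_risk.tsv")
saveRDS(run, file.path(in_dir, "discovery_run.rds"))  # scratch: reused by 03/04
message("wrote sweep, model, funnel tables and manifest under results/")
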