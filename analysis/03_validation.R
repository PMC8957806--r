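#!/usr/bin/env Rscript
# Validation analysis: rerun the pipeline on the independent cohort at the
# discovery-selected threshold (no sweep-based selection).

suppressPackageStartupMessages(library(prsonset))

in_dir <- "scratch/analysis"
run_d <- readRDS(file.path(in_dir, "discovery_run.rds"))

message("== 03: validation at fixed threshold ", run_d$selected_threshold, " ==")
ss <- read_summary_stats(file.path(in_dir, "sumstats.tsv"))
gm <- read_genotypes(file.path(in_dir, "validation_dosages.tsv"))
cohort <- as.data.frame(data.table::fread(file.path(in_dir, "validation_cohort.tsv")))

run_v <- run_validation(ss$stats, gm, cohort,
                        fixed_threshold = run_d$selected_threshold)

message(sprintf("validation standalone AUC %.3f (discovery %.3f)",
                run_v$models$standalone$auc, run_d$models$standalone$auc))
message(sprintf("validation full model AUC %.3f | +PC1-3 %.3f",
                run_v$models$full$auc, run_v$models$full_pcs$auc))
message(sprintf("case vs control PRS means: %.3f vs %.3f (p = %.3g)",
                run_v$score_means$mean_case, run_v$score_means$mean_control,
                run_v$score_means$p))

model_rows <- do.call(rbind, lapply(run_v$models, function(m)
  data.frame(model = m$label, auc = m$auc, n = m$n)))
data.table::fwrite(model_rows, "results/validation_models.tsv", sep = "\t")
write_manifest(run_v, "results/validation_manifest.json")
saveRDS(run_v, file.path(in_dir, "validation_run.rds"))
message("wrote validation tables under results/")
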