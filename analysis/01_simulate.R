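#!/usr/bin/env Rscript
# Build the synthetic discovery and validation cohorts.
#
# Emulates the structure of a two-cohort PRS study: a GWAS summary-statistic
# table (daner-style), LD-blocked target genotype dosages on a GRCh37-like
# map (including variants inside the APOE exclusion region), a
# liability-threshold depression phenotype among Alzheimer's-like
# participants (prevalence 0.36), and left-truncated onset ages. The
# validation cohort shares the variant universe and the genetic truth but is
# an independent sample.
#
# Bulky intermediates go to scratch/analysis/ (regenerable from the seed);
# small summary tables to results/.

suppressPackageStartupMessages(library(prsonset))

seed <- 101L
out_dir <- "scratch/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("== 01: simulating cohorts (seed ", seed, ") ==")
cfg_disc <- sim_config(seed = seed)            # 2,000 samples x 5,000 variants
disc <- simulate_cohort(cfg_disc)

cfg_val <- sim_config(seed = seed + 1L)
vali <- simulate_cohort(cfg_val, truth = disc$truth,
                        template_variants = disc$genotypes$variants)

message(sprintf("discovery: %d samples, %d variants, %.1f%% depression cases, %d onset events",
                nrow(disc$cohort), ncol(disc$genotypes$dosages),
                100 * mean(disc$cohort$case), sum(disc$cohort$event)))
message(sprintf("validation: %d samples, %.1f%% cases, %d events",
                nrow(vali$cohort), 100 * mean(vali$cohort$case),
                sum(vali$cohort$event)))

write_summary_stats(as.data.frame(prsonset:::as_internal_sumstats(disc$sumstats)),
                    file.path(out_dir, "sumstats.tsv"))
write_genotypes_tsv(disc$genotypes, file.path(out_dir, "discovery_dosages.tsv"))
write_genotypes_tsv(vali$genotypes, file.path(out_dir, "validation_dosages.tsv"))
data.table::fwrite(disc$cohort, file.path(out_dir, "discovery_cohort.tsv"), sep = "\t")
data.table::fwrite(vali$cohort, file.path(out_dir, "validation_cohort.tsv"), sep = "\t")

# a VCF excerpt exercises the other genotype input path
write_genotypes_vcf(subset_variants(disc$genotypes,
                                    disc$genotypes$variants$variant_id[1:100]),
                    file.path(out_dir, "discovery_excerpt.vcf"))

apoe_n <- sum(disc$genotypes$variants$chrom == "19" &
                disc$genotypes$variants$pos >= 45111942 &
                disc$genotypes$variants$pos <= 45711941)
message(sprintf("variants inside the APOE exclusion region: %d", apoe_n))
message("wrote cohort files under ", out_dir)
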