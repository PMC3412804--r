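#!/usr/bin/env Rscript
# End-to-end report over the simulated dataset, the published-ratio
# reproduction, and the planted-SNP parameter-recovery study.
suppressPackageStartupMessages(library(estmarker))

## one-call pipeline over the simulated dataset
report <- run_pipeline("results/dataset/contigs.fa",
                       "results/dataset/reads.sam",
                       out_dir = "results/report")
message("pipeline report written to results/report/report.json")
print(report$collection)

## the published SSR table ratios, recomputed from its printed counts
tab <- ssr_summary_from_counts(
  counts = c(3107L, 1428L, 339L, 61L, 17L),
  primer_ready_counts = c(2025L, 1068L, 224L, 41L, 14L),
  n_sequences = 100477L, total_length_bp = 47177000)
write_table(tab, "results/published_ssr_ratios.tsv")
message("per-class SSR ratios from published counts ",
        "(results/published_ssr_ratios.tsv):")
print(tab, row.names = FALSE)

## parameter recovery: 30x, 150-bp reads, 0.1% error, AF 0.3
study <- snp_recovery_study(seed = 101L)
message(sprintf(
  "planted-SNP recovery: %d/%d (%.1f%%), %d false positives over %d bp (%.2f per 10 kb)",
  study$n_recovered, study$n_planted, study$recovery_pct,
  study$n_false_positive, study$total_len, study$fp_per_10kb))
write_table(data.frame(
  n_planted = study$n_planted, n_recovered = study$n_recovered,
  recovery_pct = study$recovery_pct,
  n_false_positive = study$n_false_positive,
  fp_per_10kb = study$fp_per_10kb, total_len = study$total_len),
  "results/snp_recovery.tsv")
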