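#!/usr/bin/env Rscript
# Pileup-based variant calling on the simulated reads: declare putative
# SNPs/indels (depth >= 4, minor allele >= 2 reads), apply the MAF >15% /
# 15-bp cluster filters, and compare the passing calls with the planted
# truth.
suppressPackageStartupMessages(library(estmarker))

contigs <- read_fasta("results/dataset/contigs.fa")
reads <- read_alignments("results/dataset/reads.sam", "sam")
truth <- read_table("results/dataset/truth_variants.tsv")

pile <- build_pileup(reads, contigs)
putative <- call_variants(pile, contigs)
calls <- apply_filters(putative)
passed <- calls[calls$passed, , drop = FALSE]

vsum <- summarize_variants(calls, contigs)
print(vsum)

hit <- paste(truth$seq_id, truth$pos) %in%
  paste(passed$contig_id, passed$pos)
message(sum(hit), "/", nrow(truth), " planted variants pass the filters; ",
        sum(!paste(passed$contig_id, passed$pos) %in%
              paste(truth$seq_id, truth$pos)),
        " passing calls are not planted (false positives)")

write_vcf(calls, contigs, "results/putative.vcf")
write_vcf(passed, contigs, "results/filtered.vcf")
write_table(calls[, setdiff(names(calls), "multiallelic")],
            "results/variant_calls.tsv")
message("VCFs and call table written under results/")
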