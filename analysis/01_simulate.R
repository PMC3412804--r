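#!/usr/bin/env Rscript
# Build the simulated EST dataset the downstream analyses run on: 40
# contigs (length ~ N(730, 331), >= 400 bp so every contig can host a
# planted marker), with planted microsatellites of every period class and
# planted SNPs/indels at allele fraction 0.35, read at 10x coverage.
suppressPackageStartupMessages(library(estmarker))

outdir <- "results/dataset"
cfg <- simulation_config(n_contigs = 40L, contig_len_mean = 730,
                         contig_len_sd = 331, min_contig_len = 400L,
                         coverage = 10, read_len_mean = 200, read_len_sd = 40,
                         error_rate = 0.002, seed = 101L)
contigs <- simulate_contigs(cfg)

motifs <- rep(c("AC", "AG", "AAT", "AGAT", "AACCT", "AACGGT"), length.out = 12)
ssr_spec <- data.frame(seq_id = names(contigs)[1:12], motif = motifs,
                       repeat_count = ifelse(nchar(motifs) == 2, 7L, 5L),
                       min_flank = 60L, stringsAsFactors = FALSE)

# plant one variant per contig on contigs 21-40, well inside the sequence
vtypes <- rep(c("SNP", "SNP", "DEL", "INS"), length.out = 20)
variant_spec <- do.call(rbind, lapply(seq_len(20), function(i) {
  id <- names(contigs)[20 + i]
  pos <- as.integer(nchar(contigs[[id]]) %/% 2)
  ref <- substr(contigs[[id]], pos + 1, pos + 1)
  data.frame(seq_id = id, pos = pos, vtype = vtypes[i],
             alt_allele = if (vtypes[i] == "SNP")
               setdiff(c("A", "C", "G", "T"), ref)[1]
             else if (vtypes[i] == "INS") "TGA" else NA_character_,
             del_len = if (vtypes[i] == "DEL") 2L else NA_integer_,
             target_af = 0.35, stringsAsFactors = FALSE)
}))

paths <- generate_dataset(cfg, ssr_spec, variant_spec, outdir)
message("dataset written to ", outdir, ":")
for (p in paths) message("  ", p, "  (", file.size(p), " bytes)")
message(length(contigs), " contigs, ",
        nrow(read_alignments(paths[["reads"]], "sam")), " reads, ",
        nrow(ssr_spec), " planted SSRs, ", nrow(variant_spec),
        " planted variants")
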