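# estmarker

Molecular-marker discovery from assembled transcriptome (EST)
collections, for researchers developing markers in non-model species from
pooled-sample RNA sequencing. The package implements the classic 454-era
EST marker pipeline as tested R functions:

* **SSR (microsatellite) mining** — every maximal run of a *primitive*
  2–6 bp motif with ≥ 6 (di) or ≥ 5 (tri–hexa) perfect copies, with a
  primer-ready flag for loci having ≥ 50 bp of flank on both sides, and
  the per-class summary table (count, proportion, frequency = count /
  *n* sequences, mean distance = total collection length / count).
* **Pileup-based SNP/indel calling** — a putative variant needs depth
  ≥ 4 reads with the minor allele seen ≥ 2 times; quality variants
  additionally need minor allele frequency MAF = *m*/*d* **strictly**
  > 0.15, no other putative variant within 15 bp on the same contig
  (both members of a pair fail), optional mean flanking Phred ≥ 20, and
  a biallelic column. Filtered SNPs are classified as transitions
  (A↔G, C↔T) or transversions.
* **Six-frame ORF scan** — ATG to first in-frame stop (stop included),
  strict `length > 200 bp` by default, open-ended fragments flagged.
* **Collection statistics** — counts/percentages of sequences > 500 bp,
  > 1 kb, with an ORF; survey-style rounding (half away from zero).
* **A seeded simulator** — contigs with planted repeats and
  two-haplotype read sets with planted SNPs/indels at controlled allele
  fraction, emitting FASTA/SAM plus ground-truth tables, so every stage
  is testable against truth.

Inputs are plain FASTA, a SAM subset (CIGAR M/=/X/I/D/S) or an
equivalent TSV; outputs are TSV tables and minimal VCF v4.2. Internal
coordinates are 0-based half-open; all human-facing output is 1-based.

## Worked example

Simulate a small collection, plant one SSR and one SNP, and run the
mining and calling stages:

```r
library(estmarker)

cfg <- simulation_config(n_contigs = 8, coverage = 25, read_len_mean = 150,
                         read_len_sd = 0, min_read_len = 150,
                         min_contig_len = 500, error_rate = 0.001, seed = 42)
contigs <- simulate_contigs(cfg)
planted <- plant_ssrs(contigs, data.frame(seq_id = "contig_00001",
                                          motif = "AC", repeat_count = 8L,
                                          min_flank = 60L), seed = 43)
ref <- substr(planted$contigs[["contig_00002"]], 301, 301)
pv <- plant_variants(planted$contigs,
                     data.frame(seq_id = "contig_00002", pos = 300L,
                                vtype = "SNP",
                                alt_allele = setdiff(c("A","C","G","T"), ref)[1],
                                del_len = NA_integer_, target_af = 0.4))
reads <- simulate_reads(pv$haplotypes, cfg)

find_ssrs(planted$contigs)
#>         seq_id start end motif period repeat_count primer_ready
#> 1 contig_00001   355 371    AC      2            8         TRUE

calls <- apply_filters(call_variants(build_pileup(reads, planted$contigs),
                                     planted$contigs))
calls[, c("contig_id", "pos", "depth", "minor_count", "maf", "passed")]
#>      contig_id pos depth minor_count        maf passed
#> 1 contig_00002 300    29           8 0.27586207   TRUE
#> 2 contig_00004 159    35           2 0.05714286  FALSE
#> 3 contig_00005 493    26           2 0.07692308  FALSE
#> 4 contig_00005 533    25           2 0.08000000  FALSE
#> 5 contig_00008 403    32           2 0.06250000  FALSE
```

The planted SNP (allele fraction 0.4, 8 of 29 reads, MAF 0.276 > 0.15)
passes; four error-driven putative calls are declared (two identical
errors among ~30 reads) but fail the MAF filter. `write_vcf()` writes
either call set; `summarize_variants()` tabulates rates, Ts/Tv and the
MAF histogram.

The numbered scripts under `analysis/` run the same stages as a
workflow: `01_simulate.R` builds a dataset under `results/dataset/`,
`02`–`04` mine SSRs, call variants and scan ORFs against the planted
truth, and `05_report.R` produces the combined report, the published
ratio table and the parameter-recovery study.

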