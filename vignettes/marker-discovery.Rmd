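---
title: "Mining microsatellite and SNP markers from EST assemblies"
author: "estmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining microsatellite and SNP markers from EST assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estmarker)
```

## The problem

Transcriptome surveys of non-model species -- classically 454
pyrosequencing of a normalized cDNA pool from a few dozen individuals --
produce tens of thousands of assembled contigs and singletons. Two marker
types are routinely mined from such collections: simple sequence repeats
(SSRs, microsatellites), useful for linkage mapping once primers can be
designed against unique flanking sequence, and SNPs/indels, detected as
allele mixtures in the reads aligned back to the contigs from the pooled
sample. `estmarker` implements that discovery pipeline as composable,
tested functions: SSR mining with primer-design flanking checks,
pileup-based SNP/indel declaration and filtering, a six-frame ORF scan,
and the collection-level summary statistics such surveys report. A seeded
simulator generates contigs with planted repeats and two-haplotype read
sets with planted variants so every stage can be validated against ground
truth without touching a read archive.

## SSR mining

An SSR locus is a maximal run of full, consecutive copies of a primitive
motif of period 2--6; "primitive" means the motif is not itself a
repetition of a shorter motif, so a `(AT)x10` stretch is one dinucleotide
locus, never an `ATAT` tetranucleotide. Runs must reach the conventional
thresholds -- six copies for dinucleotides, five for tri- through
hexanucleotides (`ssr_thresholds()`); only perfect repeats count
(no mismatches or interruptions), matching the default behavior of the
Msatfinder family of tools. Further conventions, chosen where a convention
had to be picked:

* homopolymers (period 1) are excluded; the survey classes start at
  dinucleotides;
* partial trailing copies are excluded from the span, so
  `end - start = period x repeat_count` always holds with an integer
  count;
* runs of *different* primitive motifs may overlap and are each reported;
  adjacent/compound SSRs are reported as separate loci;
* `N` never matches any motif base, so a repeat cannot span an `N`;
* a locus is *primer-ready* when at least 50 bp of flank exists on both
  sides (inclusive boundary: exactly 50 bp suffices).

The detector scans, for each period `p`, the positions where
`s[i] == s[i+p]`; each maximal stretch of matches is one candidate run,
reported at its primitive period only. The test suite checks this
implementation exactly against an independent brute-force oracle that
enumerates every start and period and chases copies by substring
comparison, over hundreds of random sequences up to 2 kb.

`summarize_ssrs()` reproduces the survey-style class table: per class the
count, the proportion of all SSRs, the *frequency* (count per 100 input
sequences) and the *mean distance* (total length of **all** input
sequences divided by the class count, in kb). The all-sequence denominator
is deliberate: it is the only reading under which the published per-class
mean distances are mutually consistent (all back-compute to the same
~47.18 Mb collection length), whereas the restricted
"sequences-with-SSRs" length is not. `ssr_summary_from_counts()` exposes
the same arithmetic directly on integer counts.

## SNP/indel calling

Reads aligned to the contigs (a SAM subset or equivalent TSV; mapping
itself is out of scope) are piled up per position: aligned bases increment
per-base counts (`N` tallied separately, never as an allele; clipped bases
ignored), deletions increment a per-position deletion count, insertions
are recorded against the anchor base to their left.

**Declaration.** A putative SNP requires at least 4 reads at the column
with the second-ranked base seen at least twice (`variant_thresholds()`).
Indels follow the same counts-based rule: deletions compare
deletion-spanning reads against base-aligned reads using span depth
(aligned + deleted); insertions compare the most frequent inserted
sequence against non-inserting reads, with rarer inserted sequences at the
same anchor counting toward neither allele. Columns whose third-ranked
base also has two or more reads are declared but flagged `multiallelic`
and can never pass -- keeping the filtered set biallelic keeps the
transition/transversion classification well defined. When two bases tie in
count, the major/minor labels fall alphabetically; this affects labels
only, never counts. Consecutive qualifying deleted columns are merged into
a single multi-base deletion event anchored at the first deleted position;
without the merge, a 2-bp deletion would be reported as two putative calls
1 bp apart and disqualify itself under the cluster rule below.

**Filtering.** Four flags, each applied to the complete putative set:

* `maf15` -- the minor allele frequency (minor count / depth) must be
  *strictly* greater than 0.15; a site at exactly 15% fails. The strict
  reading follows the declared "more than 15%" criterion verbatim.
* `cluster` -- any other putative call (passing or not) on the same contig
  within 15 bp (start positions compared, boundary inclusive) fails
  *both* members. Nearby variant clusters typically indicate sequencing
  error or paralog collapse, and a symmetric exclusion is the conservative
  reading. Indel positions use the event start.
* `flankq` -- when per-base contig qualities are supplied, the mean Phred
  quality over the 15-bp windows either side must reach 20 (the same
  cutoff used for read trimming in such assemblies); with no qualities the
  check is skipped entirely rather than failing calls.
* `multiallelic` -- carried through from declaration.

A call passes iff it carries no flags. `summarize_variants()` reports
counts by type for putative and filtered sets, "one per N bp" rates over
the total contig length, Ts/Tv counts, per-contig means over contigs
containing calls, and the minor-allele-frequency histogram in 5% bins
above 15%. Variant rates quoted in the source survey imply denominators
that are not mutually consistent with any single printed collection
length; the package simply uses the total length of the supplied contigs
and leaves reconciliation to the reader.

## ORF scanning

`find_orfs()` scans all six frames; an ORF runs from an `ATG` to the first
in-frame stop, stop codon included in the length, with a strict
`length > min_len` cutoff (default 200 bp, per the usual "longer than
200 bp" screen; the threshold is configurable since published minimums
sometimes suggest an effective 300 bp cutoff). Within a frame each stop is
paired with the first `ATG` after the previous stop, i.e. the longest ORF
ending at that stop. Alternative start codons are not considered. ORFs
that run off the sequence end without a stop are reported with an
`open_ended` flag -- transcript fragments are expected -- and count toward
"has an ORF" statistics. Codons containing `N` match neither `ATG` nor a
stop, so a frame reads through them.

## The simulator and what it does (not) emulate

`simulation_config()` defaults encode the descriptive statistics of the
transcriptome collection this pipeline is modeled on: contig lengths
N(730, 331) truncated at 100 bp, read lengths N(411, 117) truncated at
40 bp (the assembly's minimum read length), mean coverage 7.6, GC 0.47
(typical teleost coding sequence), and a substitution-only error rate of
0.005. Reads are placed uniformly and emitted *pre-aligned* in reference
coordinates -- mapping is out of scope, so alignment error is deliberately
absent. Two haplotypes (reference and alternate) stand in for the pooled
sample: the declaration and filter rules see only allele counts, so the
per-read alternate-haplotype probability `target_af` controls exactly what
matters. Reads overlapping a planted variant at the extreme edge of their
span are drawn from the reference, a sub-1% dilution of the realized
allele fraction.

Consequences for interpreting green tests: passing recovery tests show the
counting, declaration and filtering logic is correct under the stated
error model. They do not exercise 454 flow-space homopolymer indel errors,
misassembly or paralog collapse, mapping ambiguity, or per-read base
qualities -- the main real-world sources of false markers that the filter
cascade exists to suppress.

The planted-SNP recovery study (`snp_recovery_study()`) uses 100 contigs
at 30x coverage with 150-bp reads, 0.1% error, and 200 isolated planted
SNPs at allele fraction 0.3. Contig lengths keep the published mean/SD but
are truncated at 500 bp so that both planted sites per contig sit at least
one read length from the contig ends, at full expected coverage; at 30x
the binomial sampling of a 0.3-fraction allele leaves roughly 3% of sites
at or below the 15% MAF boundary, which is the expected recovery loss.
These problem sizes run in seconds and were chosen as the smallest at
which the stochastic assertions are stable.

## Numerical and interface choices

* Internal coordinates are 0-based half-open everywhere; VCF POS and TSV
  start columns are 1-based (VCF indel records are left-anchored on the
  preceding reference base, so a deletion at contig position 0 cannot be
  represented and is an error).
* Summary percentages round half away from zero (`round_half_up()`), the
  convention the published tables follow; collection percentages use one
  decimal by default with an integer mode for mixed-precision reporting.
* Residues outside `{A,C,G,T,N}` are rejected at ingest, naming the
  offending records; downstream counting assumes the 5-letter alphabet.
* The CIGAR dialect is restricted to M/=/X/I/D/S; N/H/P raise errors
  rather than being silently mis-counted.
* FASTA I/O is backed by Biostrings; the SAM-subset/TSV readers and the
  minimal VCF writer are purpose-built for the restricted dialects above,
  and tests re-parse the VCF output with an independent reader (vcfR).
* The package's interface is its functions plus the numbered scripts under
  `analysis/`; `run_pipeline()` is the single-call entry point. No shell
  wrapper is shipped.

## Limitations

Beyond the simulator scope above: the pipeline consumes alignments rather
than producing them; base-quality recalibration and genotype likelihoods
are out of scope (calls are count-based, as in the original EST-era
pipelines); primer design itself, annotation, and downstream population
genetics are not covered.
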