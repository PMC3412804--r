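Package: estmarker
Title: Microsatellite and SNP Marker Discovery from EST Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining molecular markers from assembled transcriptome
    (EST) collections: perfect microsatellite (SSR) detection with
    primer-design flanking checks, pileup-based SNP and indel declaration
    with minor-allele-frequency and clustering filters, six-frame open
    reading frame scanning, and collection-level summary statistics of the
    kind reported in 454 transcriptome marker surveys. Includes a seeded
    simulator that emits contigs with planted repeats and reads drawn from
    two haplotypes carrying planted variants at controlled allele
    frequencies, so every pipeline stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
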