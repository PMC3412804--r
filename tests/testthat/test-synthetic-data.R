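# Simulator: determinism, planted truth fidelity, coverage and AF behavior.

test_that("contig simulation is deterministic and honors GC / length bounds", {
  cfg <- simulation_config(n_contigs = 5, seed = 1)
  a <- simulate_contigs(cfg)
  b <- simulate_contigs(cfg)
  expect_identical(a, b)
  expect_true(all(nchar(a) >= cfg$min_contig_len))

  pure_gc <- simulate_contigs(simulation_config(n_contigs = 3, gc = 1,
                                                seed = 2))
  expect_false(any(grepl("[AT]", pure_gc)))

  none <- simulate_contigs(simulation_config(n_contigs = 0, seed = 3))
  expect_length(none, 0)
  expect_error(simulation_config(n_contigs = 2),
               "seed")
  expect_error(simulation_config(n_contigs = 2, contig_len_sd = -1, seed = 1),
               "sd")
})

test_that("planted SSRs are recovered exactly from the emitted contigs", {
  cfg <- simulation_config(n_contigs = 6, contig_len_mean = 800,
                           contig_len_sd = 50, min_contig_len = 600, seed = 41)
  contigs <- simulate_contigs(cfg)
  spec <- data.frame(
    seq_id = names(contigs),
    motif = c("AC", "AAG", "AAAT", "AACTG", "AACGTT", "AT"),
    repeat_count = c(8L, 6L, 5L, 5L, 5L, 6L),
    min_flank = 60L, stringsAsFactors = FALSE)
  planted <- plant_ssrs(contigs, spec, seed = 99)
  loci <- find_ssrs(planted$contigs)
  key <- function(d, s, m, p, rc) paste(d, s, m, p, rc)
  found <- key(loci$seq_id, loci$start, loci$motif, loci$period,
               loci$repeat_count)
  want <- key(planted$truth$seq_id, planted$truth$start, planted$truth$motif,
              planted$truth$period, planted$truth$repeat_count)
  expect_true(all(want %in% found))
  expect_true(all(planted$truth$primer_ready_expected))
  # no reported locus falls below its threshold
  th <- ssr_thresholds()
  expect_true(all(loci$repeat_count >=
                    th$min_repeats[as.character(loci$period)]))
})

test_that("a repeat planted near the edge is flagged not primer-ready", {
  contigs <- c(c1 = random_dna(300, 0.5))
  spec <- data.frame(seq_id = "c1", motif = "AC", repeat_count = 8L,
                     start = 10L, stringsAsFactors = FALSE)
  planted <- plant_ssrs(contigs, spec, seed = 5)
  expect_false(planted$truth$primer_ready_expected)
  loci <- find_ssrs(planted$contigs)
  hit <- loci[loci$start == 10 & loci$motif == "AC", ]
  expect_false(hit$primer_ready)

  # empty spec leaves contigs unchanged
  empty <- plant_ssrs(contigs, NULL, seed = 5)
  expect_identical(empty$contigs, toupper(contigs))
  expect_identical(nrow(empty$truth), 0L)
})

test_that("haplotype construction matches the planted variant spec", {
  contigs <- c(c1 = strrep("ACGTTGCA", 40))
  ref_base <- substr(contigs[["c1"]], 101, 101)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  spec <- data.frame(
    seq_id = "c1", pos = c(100L, 160L, 220L),
    vtype = c("SNP", "DEL", "INS"),
    alt_allele = c(alt_base, NA, "TTG"),
    del_len = c(NA, 2L, NA), target_af = 0.4, stringsAsFactors = FALSE)
  pv <- plant_variants(contigs, spec)
  hp <- pv$haplotypes[["c1"]]
  # SNP: exactly one difference in the region before the indels
  pre <- substr(hp$ref, 1, 160) != substr(hp$alt, 1, 160)
  diffs <- which(strsplit(substr(hp$ref, 1, 160), "")[[1]] !=
                   strsplit(substr(hp$alt, 1, 160), "")[[1]])
  expect_identical(diffs, 101L)
  # 2-bp deletion and 3-bp insertion: net length +1
  expect_identical(nchar(hp$alt), nchar(hp$ref) + 1L)
  expect_identical(pv$truth$ref_allele[2], substr(contigs[["c1"]], 161, 162))

  # empty spec -> identical haplotypes
  pv0 <- plant_variants(contigs, NULL)
  expect_identical(pv0$haplotypes[["c1"]]$ref, pv0$haplotypes[["c1"]]$alt)

  # clustered planting must be requested explicitly
  close_spec <- data.frame(seq_id = "c1", pos = c(100L, 110L), vtype = "SNP",
                           alt_allele = "A", del_len = NA_integer_,
                           target_af = 0.4, stringsAsFactors = FALSE)
  close_spec$alt_allele <- vapply(close_spec$pos, function(p)
    setdiff(c("A", "C", "G", "T"),
            substr(contigs[["c1"]], p + 1, p + 1))[1], "")
  expect_error(plant_variants(contigs, close_spec), "15 bp")
  expect_silent(plant_variants(contigs, close_spec, allow_clustered = TRUE))
})

test_that("error-free reads with no variants produce a clean pileup", {
  cfg <- simulation_config(n_contigs = 3, coverage = 10, error_rate = 0,
                           seed = 8)
  contigs <- simulate_contigs(cfg)
  pv <- plant_variants(contigs, NULL)
  reads <- simulate_reads(pv$haplotypes, cfg)
  expect_identical(reads, simulate_reads(pv$haplotypes, cfg))  # determinism
  pile <- build_pileup(reads, contigs)
  for (id in names(contigs)) {
    p <- pile[[id]]
    ch <- strsplit(contigs[[id]], "")[[1]]
    covered <- rowSums(p$counts) > 0
    agreeing <- p$counts[cbind(seq_along(ch), match(ch, c("A","C","G","T")))]
    expect_equal(unname(as.numeric(agreeing[covered])),
                     unname(rowSums(p$counts)[covered]))
    expect_identical(sum(p$del_count), 0L)
    expect_identical(nrow(p$ins_events), 0L)
  }
})

test_that("coverage and allele-fraction targets are met empirically", {
  contigs <- c(c1 = random_dna(2000, 0.5))
  ref_base <- substr(contigs[["c1"]], 1001, 1001)
  spec <- data.frame(seq_id = "c1", pos = 1000L, vtype = "SNP",
                     alt_allele = setdiff(c("A","C","G","T"), ref_base)[1],
                     del_len = NA_integer_, target_af = 0.5,
                     stringsAsFactors = FALSE)
  pv <- plant_variants(contigs, spec)
  cfg <- simulation_config(n_contigs = 1, coverage = 200, read_len_mean = 150,
                           read_len_sd = 0, min_read_len = 150,
                           error_rate = 0, seed = 17)
  reads <- simulate_reads(pv$haplotypes, cfg)
  pile <- build_pileup(reads, contigs)[["c1"]]
  depth <- rowSums(pile$counts)
  expect_lt(abs(mean(depth) - 200) / 200, 0.10)
  site <- pile$counts[1001, ]
  af <- site[[spec$alt_allele]] / sum(site)
  # binomial(depth, 0.5) concentration: middle 99.9% well inside +-0.10
  expect_lt(abs(af - 0.5), 0.10)

  # coverage 0 -> no reads
  cfg0 <- simulation_config(n_contigs = 1, coverage = 0, seed = 1)
  expect_identical(nrow(simulate_reads(pv$haplotypes, cfg0)), 0L)
})

test_that("emitted alignments satisfy span/length consistency", {
  contigs <- c(c1 = random_dna(900, 0.5))
  spec <- data.frame(seq_id = "c1",
                     pos = c(200L, 400L, 600L),
                     vtype = c("SNP", "DEL", "INS"),
                     alt_allele = c("A", NA, "GATTA"),
                     del_len = c(NA, 3L, NA),
                     target_af = 0.5, stringsAsFactors = FALSE)
  b <- substr(contigs[["c1"]], 201, 201)
  if (b == "A") spec$alt_allele[1] <- "G"
  pv <- plant_variants(contigs, spec)
  cfg <- simulation_config(n_contigs = 1, coverage = 20, read_len_mean = 120,
                           read_len_sd = 20, min_read_len = 40,
                           error_rate = 0.005, seed = 23)
  reads <- simulate_reads(pv$haplotypes, cfg)
  for (i in seq_len(nrow(reads))) {
    ops <- parse_cigar(reads$cigar[i])
    qlen <- sum(ops$len[ops$op %in% c("ALN", "INS", "CLIP")])
    expect_identical(qlen, nchar(reads$residues[i]))
    span <- sum(ops$len[ops$op %in% c("ALN", "DEL")])
    expect_lte(reads$ref_start[i] + span, nchar(contigs[["c1"]]))
  }
  # pileup at the planted SNP contains both alleles
  pile <- build_pileup(reads, contigs)[["c1"]]
  site <- pile$counts[201, ]
  expect_gt(site[[spec$alt_allele[1]]], 0)
  expect_gt(site[[b]], 0)
})

test_that("generate_dataset writes a parseable, reproducible bundle", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- simulation_config(n_contigs = 4, coverage = 6, seed = 99,
                           contig_len_mean = 600, contig_len_sd = 100,
                           min_contig_len = 400)
  ssr_spec <- data.frame(seq_id = "contig_00001", motif = "AC",
                         repeat_count = 8L, min_flank = 60L,
                         stringsAsFactors = FALSE)
  contigs0 <- simulate_contigs(cfg)
  b1 <- substr(contigs0[["contig_00002"]], 301, 301)
  variant_spec <- data.frame(seq_id = "contig_00002", pos = 300L,
                             vtype = "SNP",
                             alt_allele = setdiff(c("A","C","G","T"), b1)[1],
                             del_len = NA_integer_, target_af = 0.5,
                             stringsAsFactors = FALSE)
  p1 <- generate_dataset(cfg, ssr_spec, variant_spec, dir1)
  p2 <- generate_dataset(cfg, ssr_spec, variant_spec, dir2)
  expect_true(all(file.exists(p1)))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = k)          # byte-identical rerun
  }
  contigs <- read_fasta(p1[["contigs"]])
  reads <- read_alignments(p1[["reads"]], "sam")
  truth_ssrs <- read_table(p1[["truth_ssrs"]])
  truth_vars <- read_table(p1[["truth_variants"]])
  expect_length(contigs, 4)
  expect_gt(nrow(reads), 0)
  expect_identical(nrow(truth_ssrs), 1L)
  expect_identical(nrow(truth_vars), 1L)
  loci <- find_ssrs(contigs)
  expect_true(truth_ssrs$start %in%
                loci$start[loci$seq_id == "contig_00001"])
})

test_that("a deliberately clustered planted pair is excluded downstream", {
  contigs <- c(c1 = random_dna(700, 0.5))
  pos <- c(300L, 310L)
  alts <- vapply(pos, function(p)
    setdiff(c("A","C","G","T"), substr(contigs[["c1"]], p + 1, p + 1))[1], "")
  spec <- data.frame(seq_id = "c1", pos = pos, vtype = "SNP",
                     alt_allele = alts, del_len = NA_integer_,
                     target_af = 0.45, stringsAsFactors = FALSE)
  pv <- plant_variants(contigs, spec, allow_clustered = TRUE)
  cfg <- simulation_config(n_contigs = 1, coverage = 60, read_len_mean = 100,
                           read_len_sd = 0, min_read_len = 100,
                           error_rate = 0, seed = 303)
  reads <- simulate_reads(pv$haplotypes, cfg)
  calls <- apply_filters(call_variants(build_pileup(reads, contigs), contigs))
  at_planted <- calls[calls$pos %in% pos & calls$vtype == "SNP", ]
  expect_identical(nrow(at_planted), 2L)
  expect_true(all(grepl("cluster", at_planted$filter_flags)))
  expect_false(any(at_planted$passed))
})
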