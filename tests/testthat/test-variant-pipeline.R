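# Pileup construction, putative declaration, filter cascade, summaries.

test_that("build_pileup tallies bases, deletions and anchored insertions", {
  contigs <- c(c1 = "ACGTACGT")
  aln <- data.frame(
    read_id = c("r1", "r2", "r3"), contig_id = "c1",
    ref_start = c(0L, 0L, 0L),
    cigar = c("4M", "4M", "2M1I2M"),
    residues = c("ACGT", "AGGT", "ACAGT"),
    qualities = NA_character_, stringsAsFactors = FALSE)
  pile <- build_pileup(aln, contigs)
  p <- pile[["c1"]]
  expect_identical(unname(p$counts[2, ]), c(0L, 2L, 1L, 0L))  # A/C/G/T at pos 1
  expect_identical(unname(rowSums(p$counts)[1:4]), rep(3, 4))
  expect_identical(p$ins_events$pos, 1L)        # anchored after 0-based pos 1
  expect_identical(p$ins_events$seq, "A")
  expect_identical(p$ins_events$count, 1L)

  # deletion columns
  aln2 <- data.frame(read_id = "d1", contig_id = "c1", ref_start = 1L,
                     cigar = "2M2D2M", residues = "CGGT",
                     qualities = NA_character_, stringsAsFactors = FALSE)
  p2 <- build_pileup(aln2, contigs)[["c1"]]
  expect_identical(p2$del_count, c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L))

  # read running past the contig end is an error naming the read
  bad <- data.frame(read_id = "rX", contig_id = "c1", ref_start = 6L,
                    cigar = "4M", residues = "ACGT",
                    qualities = NA_character_, stringsAsFactors = FALSE)
  expect_error(build_pileup(bad, contigs), "rX")
})

test_that("pileup base counts conserve the aligned bases of the reads", {
  set.seed(5)
  cfg <- simulation_config(n_contigs = 4, coverage = 8, seed = 31,
                           error_rate = 0.01)
  contigs <- simulate_contigs(cfg)
  pv <- plant_variants(contigs, NULL)
  reads <- simulate_reads(pv$haplotypes, cfg)
  pile <- build_pileup(reads, contigs)
  aligned <- sum(vapply(reads$cigar, function(cg) {
    ops <- parse_cigar(cg); sum(ops$len[ops$op == "ALN"])
  }, integer(1)))
  tallied <- sum(vapply(pile, function(p)
    sum(p$counts) + sum(p$n_count), numeric(1)))
  expect_identical(tallied, as.numeric(aligned))
})

test_that("putative declaration follows the depth-4 / minor-2 rule", {
  t <- variant_thresholds()
  snp <- declare_putative(column_fixture(c(A = 7, G = 3)), t)
  expect_identical(nrow(snp), 1L)
  expect_identical(snp$vtype, "SNP")
  expect_identical(snp$major_allele, "A")
  expect_identical(snp$minor_allele, "G")
  expect_identical(snp$depth, 10L)
  expect_identical(snp$minor_count, 3L)

  expect_identical(nrow(declare_putative(column_fixture(c(A = 3, G = 1)), t)),
                   0L)  # minor < 2
  expect_identical(nrow(declare_putative(column_fixture(c(A = 2, G = 1)), t)),
                   0L)  # depth < 4

  del <- declare_putative(column_fixture(c(A = 5), del_count = 2L), t)
  expect_identical(del$vtype, "DEL")
  expect_identical(del$depth, 7L)
  expect_identical(del$minor_count, 2L)

  ins <- declare_putative(column_fixture(
    c(A = 8), ins_events = data.frame(seq = "TT", count = 3L)), t)
  expect_identical(ins$vtype, "INS")
  expect_identical(ins$minor_count, 3L)
  expect_identical(ins$minor_allele, "TT")

  multi <- declare_putative(column_fixture(c(A = 5, C = 3, G = 2)), t)
  expect_true(multi$multiallelic)
})

test_that("substitution classes match the 12-entry lookup oracle", {
  pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  for (i in seq_len(nrow(pairs))) {
    expect_identical(classify_substitution(pairs$a[i], pairs$b[i]),
                     unname(TSTV_LOOKUP[paste0(pairs$a[i], ">", pairs$b[i])]))
  }
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A,C,G,T")
})

test_that("MAF boundary: exactly 15% fails, above passes", {
  t <- variant_thresholds()
  calls <- rbind(call_fixture(pos = 100, depth = 20, minor_count = 3),
                 call_fixture(pos = 200, depth = 1000, minor_count = 151),
                 call_fixture(pos = 300, depth = 20, minor_count = 4))
  out <- apply_filters(calls, t)
  expect_identical(out$filter_flags, c("maf15", "", ""))
  expect_identical(out$passed, c(FALSE, TRUE, TRUE))
})

test_that("cluster rule flags both members at 15 bp and neither at 16", {
  t <- variant_thresholds()
  near <- rbind(call_fixture(pos = 100, depth = 20, minor_count = 5),
                call_fixture(pos = 115, depth = 20, minor_count = 5))
  out <- apply_filters(near, t)
  expect_identical(out$filter_flags, c("cluster", "cluster"))

  far <- rbind(call_fixture(pos = 100, depth = 20, minor_count = 5),
               call_fixture(pos = 116, depth = 20, minor_count = 5))
  expect_true(all(apply_filters(far, t)$passed))

  # the cluster test runs against failing putative calls too
  mixed <- rbind(call_fixture(pos = 100, depth = 20, minor_count = 5),
                 call_fixture(pos = 110, depth = 20, minor_count = 3))
  out <- apply_filters(mixed, t)
  expect_identical(out$filter_flags[1], "cluster")
  expect_identical(out$filter_flags[2], "cluster;maf15")

  # different contigs never cluster
  twoctg <- rbind(call_fixture("c1", pos = 100, depth = 20, minor_count = 5),
                  call_fixture("c2", pos = 105, depth = 20, minor_count = 5))
  expect_true(all(apply_filters(twoctg, t)$passed))

  expect_error(apply_filters(rbind(call_fixture(pos = 200, depth = 20,
                                                minor_count = 5),
                                   call_fixture(pos = 100, depth = 20,
                                                minor_count = 5)), t),
               "sorted")
})

test_that("flanking-quality filter applies only when qualities are given", {
  t <- variant_thresholds()
  call <- call_fixture(pos = 100, depth = 20, minor_count = 5)
  expect_true(apply_filters(call, t)$passed)
  qual_low <- list(c1 = rep(10, 400))
  expect_identical(apply_filters(call, t, qual_low)$filter_flags, "flankq")
  qual_ok <- list(c1 = rep(30, 400))
  expect_true(apply_filters(call, t, qual_ok)$passed)
  # multiallelic columns never pass
  multi <- call_fixture(pos = 100, depth = 20, minor_count = 5,
                        multiallelic = TRUE)
  expect_identical(apply_filters(multi, t)$filter_flags, "multiallelic")
})

test_that("raising maf_cut or widening the window never grows the passed set", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 30
    pos <- cumsum(sample(3:40, n, replace = TRUE))
    depth <- sample(4:40, n, replace = TRUE)
    calls <- do.call(rbind, lapply(seq_len(n), function(i)
      call_fixture(pos = pos[i], depth = depth[i], minor_count = 2)))
    calls$minor_count <- as.integer(
      pmin(calls$depth %/% 2,
           pmax(2L, round(calls$depth * runif(n, 0.05, 0.5)))))
    calls$maf <- calls$minor_count / calls$depth
    base_pass <- apply_filters(calls, variant_thresholds())$passed
    strict_maf <- apply_filters(calls, variant_thresholds(maf_cut = 0.25))$passed
    wide_win <- apply_filters(calls,
                              variant_thresholds(cluster_window = 30L))$passed
    expect_true(all(!strict_maf | base_pass))
    expect_true(all(!wide_win | base_pass))
  }
})

test_that("every passed call has MAF in (0.15, 0.5]", {
  set.seed(123)
  study <- snp_recovery_study(n_contigs = 6, coverage = 25, seed = 606)
  passed <- study$calls[study$calls$passed, ]
  expect_true(all(passed$maf > 0.15 & passed$maf <= 0.5))
  # filtered set is a subset of the putative set, with explicit flags
  expect_true(all(study$calls$filter_flags[!study$calls$passed] != ""))
})

test_that("multi-base deletions are reported as one event", {
  contigs <- c(c1 = strrep("ACGTTGCA", 10))
  spec <- data.frame(seq_id = "c1", pos = 40L, vtype = "DEL",
                     alt_allele = NA_character_, del_len = 2L,
                     target_af = 0.5, stringsAsFactors = FALSE)
  pv <- plant_variants(contigs, spec)
  cfg <- simulation_config(n_contigs = 1, coverage = 40, read_len_mean = 30,
                           read_len_sd = 0, min_read_len = 30,
                           error_rate = 0, seed = 12)
  reads <- simulate_reads(pv$haplotypes, cfg)
  calls <- apply_filters(call_variants(build_pileup(reads, contigs), contigs))
  dels <- calls[calls$vtype == "DEL", ]
  expect_identical(nrow(dels), 1L)
  expect_identical(dels$pos, 40L)
  expect_identical(nchar(setdiff(c(dels$major_allele, dels$minor_allele),
                                 "-")), 2L)
  expect_true(dels$passed)
})

test_that("variant summaries report rates, Ts/Tv and MAF statistics", {
  contigs <- c(c1 = random_dna(1510, 0.5), c2 = random_dna(1510, 0.5))
  calls <- rbind(
    call_fixture("c1", pos = 100, depth = 20, minor_count = 4,
                 major = "A", minor = "G"),
    call_fixture("c1", pos = 300, depth = 20, minor_count = 8,
                 major = "C", minor = "T"),
    call_fixture("c2", pos = 200, depth = 20, minor_count = 5,
                 major = "A", minor = "C"))
  calls <- apply_filters(calls)
  s <- summarize_variants(calls, contigs)
  expect_identical(s$transitions, 2L)
  expect_identical(s$transversions, 1L)
  expect_equal(s$snp_rate_bp_filtered, 3020 / 3)   # "one per N bp"
  expect_equal(s$snp_contigs$n_contigs, 2L)
  expect_equal(s$snp_contigs$mean_per_contig, 1.5)
  expect_equal(s$mean_maf_pct,
               round(mean(c(4, 8, 5) / 20) * 100, 1))
  expect_identical(sum(s$maf_histogram), 3L)
})
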