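# Collection-level statistics and the end-to-end pipeline driver.

#' Summarize a sequence collection
#'
#' Counts and percentages of the kind quoted for EST assemblies: sequences
#' longer than 500 bp and longer than 1 kb (strict comparisons, percentages
#' of all sequences), mean/SD length, and -- when ORF hits are supplied --
#' the number and percentage of sequences carrying an ORF.
#'
#' @param sequences named character vector or DNAStringSet (non-empty).
#' @param orf_hits optional data.frame from [find_orfs()].
#' @param percent_digits decimals for percentages (default 1; use 0 for
#'   integer percents). Rounding is half away from zero.
#' @return list of class \code{collection_stats}.
#' @export
summarize_collection <- function(sequences, orf_hits = NULL,
                                 percent_digits = 1) {
  seqs <- as_seq_vector(sequences)
  if (length(seqs) == 0) stopf("cannot summarize an empty collection")
  lens <- nchar(seqs)
  pct <- function(k) round_half_up(100 * k / length(seqs), percent_digits)
  n500 <- sum(lens > 500)
  n1k <- sum(lens > 1000)
  res <- list(n_sequences = length(seqs),
              mean_length = round_half_up(mean(lens), 1),
              sd_length = round_half_up(stats::sd(lens), 1),
              n_over_500bp = n500, pct_over_500bp = pct(n500),
              n_over_1kb = n1k, pct_over_1kb = pct(n1k))
  if (!is.null(orf_hits)) {
    n_orf <- length(unique(orf_hits$seq_id))
    res$n_with_orf <- n_orf
    res$pct_with_orf <- pct(n_orf)
  }
  structure(res, class = "collection_stats")
}

#' Run the full marker-discovery pipeline
#'
#' Reads a FASTA collection (plus optional alignments), runs SSR mining,
#' variant calling and filtering (skipped when no alignments are given),
#' the ORF scan, and the collection summary, and returns one report. When
#' \code{out_dir} is set, per-stage TSV/VCF outputs and a
#' \code{report.json} are written as well.
#'
#' @param fasta path to the contig FASTA.
#' @param alignments optional path to read alignments.
#' @param aln_format \code{"sam"} or \code{"tsv"}.
#' @param out_dir optional output directory for per-stage files.
#' @param ssr [ssr_thresholds()].
#' @param variant [variant_thresholds()].
#' @param orf_min_len minimum ORF length (bp, strict).
#' @param qualities optional per-contig base qualities for the
#'   flanking-quality filter.
#' @return list of class \code{marker_report} with \code{collection},
#'   \code{ssr}, \code{variant} and \code{orf} sections.
#' @export
run_pipeline <- function(fasta, alignments = NULL,
                         aln_format = c("sam", "tsv"), out_dir = NULL,
                         ssr = ssr_thresholds(),
                         variant = variant_thresholds(),
                         orf_min_len = 200L, qualities = NULL) {
  aln_format <- match.arg(aln_format)
  contigs <- read_fasta(fasta)
  loci <- find_ssrs(contigs, ssr)
  ssr_summary <- summarize_ssrs(loci, contigs)
  orfs <- find_orfs(contigs, min_len = orf_min_len)
  collection <- summarize_collection(contigs, orfs)
  if (!is.null(alignments)) {
    reads <- read_alignments(alignments, aln_format)
    pile <- build_pileup(reads, contigs)
    calls <- apply_filters(call_variants(pile, contigs, variant), variant,
                           qualities)
    vsum <- summarize_variants(calls, contigs)
    variant_section <- list(summary = vsum, calls = calls)
  } else {
    calls <- NULL
    variant_section <- list(skipped = "no alignments")
  }
  report <- structure(list(
    collection = collection,
    ssr = list(summary = ssr_summary, n_loci = nrow(loci), loci = loci),
    variant = variant_section,
    orf = list(n_hits = nrow(orfs), n_sequences_with_orf =
                 length(unique(orfs$seq_id)), min_len = orf_min_len,
               hits = orfs)
  ), class = "marker_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ssr_out <- loci
    ssr_out$start <- ssr_out$start + 1L      # 1-based inclusive for tables
    write_table(ssr_out, file.path(out_dir, "ssrs.tsv"))
    write_table(orfs, file.path(out_dir, "orfs.tsv"))
    if (!is.null(calls)) {
      write_vcf(calls, contigs, file.path(out_dir, "putative.vcf"))
      write_vcf(calls[calls$passed, , drop = FALSE], contigs,
                file.path(out_dir, "filtered.vcf"))
    }
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# JSON-friendly view of a report (tables dropped, scalars kept)
report_json <- function(report) {
  list(
    collection = unclass(report$collection),
    ssr = list(n_loci = report$ssr$n_loci,
               summary = report$ssr$summary),
    variant = if (!is.null(report$variant$skipped)) {
      list(skipped = report$variant$skipped)
    } else {
      s <- report$variant$summary
      list(n_putative = s$n_putative, n_filtered = s$n_filtered,
           transitions = s$transitions, transversions = s$transversions,
           mean_maf_pct = s$mean_maf_pct,
           snp_contigs = s$snp_contigs, indel_contigs = s$indel_contigs)
    },
    orf = list(n_hits = report$orf$n_hits,
               n_sequences_with_orf = report$orf$n_sequences_with_orf,
               min_len = report$orf$min_len)
  )
}

#' @export
print.collection_stats <- function(x, ...) {
  cat(sprintf("Collection: %d sequences (mean %.1f bp, SD %.1f)\n",
              x$n_sequences, x$mean_length, x$sd_length))
  cat(sprintf("  >500 bp: %d (%.1f%%)   >1 kb: %d (%.1f%%)\n",
              x$n_over_500bp, x$pct_over_500bp, x$n_over_1kb, x$pct_over_1kb))
  if (!is.null(x$n_with_orf)) {
    cat(sprintf("  with ORF: %d (%s%%)\n", x$n_with_orf,
                format(x$pct_with_orf)))
  }
  invisible(x)
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("Putative: %d SNP / %d INS / %d DEL; filtered: %d / %d / %d\n",
              x$n_putative$SNP, x$n_putative$INS, x$n_putative$DEL,
              x$n_filtered$SNP, x$n_filtered$INS, x$n_filtered$DEL))
  if (!is.na(x$snp_rate_bp_filtered)) {
    cat(sprintf("  one filtered SNP per %.0f bp; Ts/Tv %d/%d; mean MAF %.1f%%\n",
                x$snp_rate_bp_filtered, x$transitions, x$transversions,
                x$mean_maf_pct))
  }
  invisible(x)
}
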