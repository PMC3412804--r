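# Perfect microsatellite (SSR) mining.
#
# An SSR locus is a maximal run of full copies of a primitive 2-6 bp motif.
# Detection thresholds follow the usual EST-survey settings: at least six
# dinucleotide copies, or five copies for tri- through hexanucleotide
# motifs. A repeat whose motif is itself periodic ((AT)x5 seen as ATAT
# copies) is reported once, at the primitive period, so the di- through
# hexa-nucleotide classes are disjoint.

PERIOD_CLASSES <- c(`2` = "di", `3` = "tri", `4` = "tetra",
                    `5` = "penta", `6` = "hexa")

#' SSR detection thresholds
#'
#' @param min_repeats named integer vector, minimum number of full motif
#'   copies per period (names \code{"2"} .. \code{"6"}). Defaults: six
#'   dinucleotide copies, five copies for periods 3-6.
#' @param flank_len bp of flanking sequence required on each side for a
#'   locus to be considered primer-ready (default 50).
#' @return list of class \code{ssr_thresholds}.
#' @export
ssr_thresholds <- function(min_repeats = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                           `5` = 5L, `6` = 5L),
                           flank_len = 50L) {
  min_repeats <- as.integer(min_repeats[as.character(2:6)])
  names(min_repeats) <- as.character(2:6)
  if (anyNA(min_repeats)) stopf("min_repeats must cover periods 2..6")
  if (any(min_repeats < 2L)) stopf("min_repeats must all be >= 2")
  if (flank_len < 0L) stopf("flank_len must be >= 0")
  structure(list(min_repeats = min_repeats, flank_len = as.integer(flank_len)),
            class = "ssr_thresholds")
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number repetition of any
#' shorter motif: \code{AT} is primitive, \code{ATAT} is not.
#'
#' @param motif character vector of motifs over \code{{A,C,G,T}}.
#' @return logical vector.
#' @export
is_primitive <- function(motif) {
  vapply(motif, function(m) {
    p <- nchar(m)
    if (p == 0) stopf("empty motif")
    if (grepl("[^ACGT]", m)) stopf("motif must be over {A,C,G,T}: '%s'", m)
    for (d in seq_len(p - 1)) {
      if (p %% d == 0 && strrep(substr(m, 1, d), p %/% d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# Core scan for one sequence. For each period p, positions where
# s[i] == s[i+p] (N never matches) form runs; a run of length L matched
# positions spans L+p residues and holds floor((L+p)/p) full motif copies
# starting at the run's first position.
find_ssrs_one <- function(id, seq, thresholds) {
  n <- nchar(seq)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      period = integer(0), repeat_count = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (p in 2:6) {
    minrep <- thresholds$min_repeats[[as.character(p)]]
    if (n < p * minrep) next
    i <- seq_len(n - p)
    m <- ch[i] == ch[i + p] & ch[i] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]                       # 1-based run start
      region_len <- r$lengths[k] + p
      count <- region_len %/% p
      if (count < minrep) next
      motif <- substr(seq, a, a + p - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive(motif)) next       # reported at the primitive period
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, start = a - 1L, end = a - 1L + count * p,
        motif = motif, period = p, repeat_count = count,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$period), , drop = FALSE]
}

#' Find perfect microsatellites in a sequence collection
#'
#' Reports every maximal run of at least \code{min_repeats[period]} full
#' consecutive copies of a primitive motif of period 2-6. Runs are maximal
#' (not extendable by a full motif unit on either side); partial trailing
#' copies are excluded from the span, so \code{end - start} is always
#' \code{period * repeat_count}. An N breaks a repeat. Overlapping runs of
#' different primitive motifs are all reported.
#'
#' @param sequences named character vector or DNAStringSet.
#' @param thresholds an [ssr_thresholds()] object.
#' @return data.frame with one row per locus: \code{seq_id}, \code{start},
#'   \code{end} (0-based half-open), \code{motif}, \code{period},
#'   \code{repeat_count}, \code{left_flank}, \code{right_flank},
#'   \code{primer_ready}.
#' @export
find_ssrs <- function(sequences, thresholds = ssr_thresholds()) {
  seqs <- as_seq_vector(sequences)
  check_alphabet(seqs)
  loci <- lapply(names(seqs), function(id)
    find_ssrs_one(id, seqs[[id]], thresholds))
  loci <- do.call(rbind, c(loci, list(find_ssrs_one("x", "", thresholds))))
  loci$left_flank <- loci$start
  loci$right_flank <- nchar(seqs)[match(loci$seq_id, names(seqs))] - loci$end
  flag_primer_ready(loci, thresholds)
}

#' Flag loci with enough flanking sequence for primer design
#'
#' A locus is primer-ready when at least \code{flank_len} bp (default 50)
#' of sequence is available on \emph{both} sides of the repeat; the
#' boundary is inclusive (exactly 50 bp suffices).
#'
#' @param loci SSR locus data.frame with \code{left_flank} and
#'   \code{right_flank} columns.
#' @param thresholds an [ssr_thresholds()] object.
#' @return `loci` with the \code{primer_ready} column set.
#' @export
flag_primer_ready <- function(loci, thresholds = ssr_thresholds()) {
  loci$primer_ready <- loci$left_flank >= thresholds$flank_len &
    loci$right_flank >= thresholds$flank_len
  loci
}

#' Summarize SSR loci per period class
#'
#' Computes, for each period class and in total: locus count, proportion of
#' all SSRs (percent), frequency (loci per 100 input sequences), mean
#' distance between loci (total length of \emph{all} input sequences divided
#' by the class count, in kb), and primer-ready counts with their share of
#' all primer-ready loci.
#'
#' @param loci data.frame from [find_ssrs()].
#' @param sequences the sequence collection the loci were mined from.
#' @return data.frame, one row per period class plus a \code{total} row.
#' @export
summarize_ssrs <- function(loci, sequences) {
  seqs <- as_seq_vector(sequences)
  if (length(seqs) == 0) stopf("cannot summarize SSRs over zero sequences")
  counts <- primer <- setNames(integer(5), PERIOD_CLASSES)
  if (nrow(loci) > 0) {
    tab <- table(factor(loci$period, levels = 2:6))
    counts[] <- as.integer(tab)
    ptab <- table(factor(loci$period[loci$primer_ready], levels = 2:6))
    primer[] <- as.integer(ptab)
  }
  ssr_summary_from_counts(counts, primer, length(seqs), sum(nchar(seqs)))
}

#' Build the SSR summary table from per-class integer counts
#'
#' The arithmetic core of [summarize_ssrs()], exposed so the class-level
#' ratios can also be computed directly from published integer counts:
#' proportion = count / total SSRs x 100; frequency = count / number of
#' sequences x 100; mean distance = total sequence length / count, in kb.
#' Percentages are rounded half away from zero to two decimals.
#'
#' @param counts integer vector of SSR counts, one per period class
#'   (di..hexa, in order).
#' @param primer_ready_counts integer vector of primer-ready counts per
#'   class.
#' @param n_sequences number of sequences mined.
#' @param total_length_bp summed length of all mined sequences.
#' @return data.frame with columns \code{class}, \code{count},
#'   \code{proportion_pct}, \code{frequency_pct}, \code{mean_distance_kb},
#'   \code{primer_ready}, \code{primer_ready_share_pct}.
#' @export
ssr_summary_from_counts <- function(counts, primer_ready_counts,
                                    n_sequences, total_length_bp) {
  if (n_sequences <= 0) stopf("n_sequences must be positive")
  counts <- as.integer(counts)
  primer <- as.integer(primer_ready_counts)
  if (length(counts) != 5 || length(primer) != 5) {
    stopf("counts and primer_ready_counts must have one entry per period class")
  }
  total <- sum(counts)
  ptotal <- sum(primer)
  all_counts <- c(counts, total)
  all_primer <- c(primer, ptotal)
  dist_kb <- ifelse(all_counts > 0,
                    round_half_up(total_length_bp / all_counts / 1000, 2), NA)
  data.frame(
    class = c(unname(PERIOD_CLASSES), "total"),
    count = all_counts,
    proportion_pct = if (total > 0)
      round_half_up(all_counts / total * 100, 2) else NA,
    frequency_pct = round_half_up(all_counts / n_sequences * 100, 2),
    mean_distance_kb = dist_kb,
    primer_ready = all_primer,
    primer_ready_share_pct = if (ptotal > 0)
      round_half_up(all_primer / ptotal * 100, 2) else NA,
    stringsAsFactors = FALSE)
}
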