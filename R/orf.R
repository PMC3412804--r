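# Six-frame open reading frame scan.
#
# An ORF runs from an ATG to the first in-frame stop (TAA/TAG/TGA), stop
# included in the span; within a frame, each stop is paired with the first
# ATG following the previous stop (the longest ORF ending at that stop).
# ORFs that run off the sequence end without a stop are reported with an
# open_ended flag, as expected for transcript fragments. Codons containing
# N match neither ATG nor a stop, so an ORF may read through an N.

STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# scan one strand-oriented sequence; returns codon-index hits per frame
scan_frames <- function(s, min_len) {
  n <- nchar(s)
  hits <- list()
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3
    if (n_codons < 2) next
    cstart <- f + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, cstart, cstart + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (length(atg) == 0) next
    # first stop at/after each ATG
    nxt_idx <- findInterval(atg - 1L, stp) + 1L
    nxt <- ifelse(nxt_idx <= length(stp), stp[nxt_idx], NA_integer_)
    # keep the first (longest) ATG per stop, plus the first open-ended ATG
    keep <- !duplicated(nxt, incomparables = NULL)
    for (j in which(keep)) {
      a <- atg[j]
      if (is.na(nxt[j])) {               # open-ended: runs to last full codon
        st <- f + 3L * (a - 1L)
        en <- f + 3L * n_codons
        open <- TRUE
      } else {
        st <- f + 3L * (a - 1L)
        en <- f + 3L * nxt[j]
        open <- FALSE
      }
      len <- en - st
      if (len > min_len) {
        hits[[length(hits) + 1L]] <- list(frame = f, start = st, end = en,
                                          length = len, open_ended = open)
      }
    }
  }
  hits
}

#' Find open reading frames in six frames
#'
#' @param sequences named character vector or DNAStringSet.
#' @param min_len minimum ORF length in bp; the comparison is strict
#'   (\code{length > min_len}), matching the "longer than 200 bp"
#'   convention. Default 200.
#' @param longest_only keep only the single longest hit per sequence.
#' @return data.frame with columns \code{seq_id}, \code{strand},
#'   \code{frame} (0-2 on the scanned strand), \code{start}, \code{end}
#'   (0-based half-open on the \emph{forward} strand), \code{length}
#'   (multiple of 3, stop codon included) and \code{open_ended}.
#' @export
find_orfs <- function(sequences, min_len = 200L, longest_only = FALSE) {
  if (min_len < 3L) stopf("min_len must be >= 3")
  seqs <- as_seq_vector(sequences)
  check_alphabet(seqs)
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- nchar(s)
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") s else revcomp(s)
      for (h in scan_frames(oriented, min_len)) {
        if (strand == "+") {
          st <- h$start; en <- h$end
        } else {                           # reflect to forward coordinates
          st <- n - h$end; en <- n - h$start
        }
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id, strand = strand, frame = as.integer(h$frame),
          start = as.integer(st), end = as.integer(en),
          length = as.integer(h$length),
          open_ended = h$open_ended, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      open_ended = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (longest_only) {
    res <- do.call(rbind, lapply(split(res, res$seq_id), function(d)
      d[which.max(d$length), , drop = FALSE]))
  }
  res <- res[order(match(res$seq_id, names(seqs)), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
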