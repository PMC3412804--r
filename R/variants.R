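# Pileup-based SNP/indel declaration and filtering.
#
# The declaration rule mirrors pooled-cDNA EST practice: a putative SNP or
# indel requires at least four reads aligned at the locus with the minor
# allele seen at least twice. Filters then require a minor allele frequency
# strictly above 15%, no other putative variant within 15 bp on the same
# contig, and (when per-base contig qualities are available) mean flanking
# quality of at least Phred 20.

#' Variant declaration and filter thresholds
#'
#' @param min_depth minimum reads aligned at a locus to declare a putative
#'   variant (default 4).
#' @param min_minor minimum minor-allele read count (default 2).
#' @param maf_cut minor allele frequency that must be strictly exceeded to
#'   pass filtering (default 0.15).
#' @param cluster_window bp; a putative call fails when any other putative
#'   call on the same contig lies within this distance (default 15,
#'   boundary inclusive).
#' @param flank_q minimum mean Phred quality over the flanking windows
#'   (default 20); checked only when contig qualities are supplied.
#' @param flank_q_span bp of flank examined on each side (default 15).
#' @return list of class \code{variant_thresholds}.
#' @export
variant_thresholds <- function(min_depth = 4L, min_minor = 2L,
                               maf_cut = 0.15, cluster_window = 15L,
                               flank_q = 20, flank_q_span = 15L) {
  if (min_minor < 1L || min_depth < min_minor) {
    stopf("need min_depth >= min_minor >= 1")
  }
  if (maf_cut <= 0 || maf_cut >= 0.5) stopf("maf_cut must be in (0, 0.5)")
  if (cluster_window < 0L) stopf("cluster_window must be >= 0")
  structure(list(min_depth = as.integer(min_depth),
                 min_minor = as.integer(min_minor),
                 maf_cut = maf_cut,
                 cluster_window = as.integer(cluster_window),
                 flank_q = flank_q,
                 flank_q_span = as.integer(flank_q_span)),
            class = "variant_thresholds")
}

BASES <- c("A", "C", "G", "T")

# --- pileup -----------------------------------------------------------------

#' Build per-position pileups from read alignments
#'
#' ALN bases increment the per-base counts (N bases are tallied separately
#' and never count as alleles), DEL ops increment the deletion count at each
#' deleted position, INS ops record the inserted sequence anchored at the
#' preceding reference position, and CLIP bases are ignored entirely.
#'
#' @param reads alignment data.frame (see [read_alignments()]).
#' @param contigs named character vector of contig sequences.
#' @return object of class \code{pileup}: a list with one entry per contig,
#'   each holding \code{counts} (length x 4 matrix, columns A/C/G/T),
#'   \code{n_count}, \code{del_count} and \code{ins_events} (data.frame
#'   \code{pos}, \code{seq}, \code{count}, anchors 0-based).
#' @export
build_pileup <- function(reads, contigs) {
  contigs <- as_seq_vector(contigs)
  check_alphabet(contigs)
  unknown <- setdiff(unique(reads$contig_id), names(contigs))
  if (length(unknown) > 0) {
    stopf("reads map to unknown contig(s): %s", paste(unknown, collapse = ", "))
  }
  spans <- vapply(reads$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  lens <- nchar(contigs)[match(reads$contig_id, names(contigs))]
  over <- reads$ref_start + spans > lens
  if (any(over)) {
    stopf("read '%s' extends past the end of contig '%s'",
          reads$read_id[over][1], reads$contig_id[over][1])
  }
  pile <- lapply(names(contigs), function(ctg) {
    len <- nchar(contigs[[ctg]])
    idx <- which(reads$contig_id == ctg)
    aln_pos <- vector("list", length(idx))
    aln_base <- character(length(idx))
    del_pos <- list()
    ins_pos <- integer(0); ins_seq <- character(0)
    for (j in seq_along(idx)) {
      r <- idx[j]
      ops <- parse_cigar(reads$cigar[r])
      rpos <- reads$ref_start[r]          # 0-based
      qpos <- 1L
      seg_pos <- list(); seg_base <- character(0)
      for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; L <- ops$len[k]
        if (op == "ALN") {
          seg_pos[[length(seg_pos) + 1L]] <- rpos:(rpos + L - 1L)
          seg_base[length(seg_base) + 1L] <-
            substr(reads$residues[r], qpos, qpos + L - 1L)
          rpos <- rpos + L; qpos <- qpos + L
        } else if (op == "DEL") {
          del_pos[[length(del_pos) + 1L]] <- rpos:(rpos + L - 1L)
          rpos <- rpos + L
        } else if (op == "INS") {
          ins_pos <- c(ins_pos, rpos - 1L)  # anchored after preceding ref base
          ins_seq <- c(ins_seq,
                       substr(reads$residues[r], qpos, qpos + L - 1L))
          qpos <- qpos + L
        } else {                            # CLIP: unaligned by definition
          qpos <- qpos + L
        }
      }
      aln_pos[[j]] <- unlist(seg_pos)
      aln_base[j] <- paste(seg_base, collapse = "")
    }
    pos <- unlist(aln_pos) %||% integer(0)
    base <- unlist(strsplit(paste(aln_base, collapse = ""), "", fixed = TRUE))
    counts <- matrix(0L, nrow = len, ncol = 4, dimnames = list(NULL, BASES))
    n_count <- integer(len)
    if (length(pos) > 0) {
      for (b in BASES) {
        counts[, b] <- tabulate(pos[base == b] + 1L, nbins = len)
      }
      n_count <- tabulate(pos[base == "N"] + 1L, nbins = len)
    }
    del_count <- if (length(del_pos) > 0) {
      tabulate(unlist(del_pos) + 1L, nbins = len)
    } else integer(len)
    ins_events <- if (length(ins_pos) > 0) {
      agg <- stats::aggregate(list(count = rep(1L, length(ins_pos))),
                              by = list(pos = ins_pos, seq = ins_seq), sum)
      agg[order(agg$pos, -agg$count, agg$seq), , drop = FALSE]
    } else {
      data.frame(pos = integer(0), seq = character(0), count = integer(0))
    }
    list(contig_id = ctg, length = len, counts = counts, n_count = n_count,
         del_count = del_count, ins_events = ins_events)
  })
  names(pile) <- names(contigs)
  structure(pile, class = "pileup")
}

#' Declare a putative variant at one pileup column
#'
#' Reference single-column form of the declaration rule used by
#' [call_variants()]. A SNP is declared when the base depth reaches
#' \code{min_depth} and the second-ranked base has at least
#' \code{min_minor} reads; deletions use span depth (base depth plus
#' deletion-spanning reads); insertions compare the most frequent inserted
#' sequence against non-inserting reads. A column whose third-ranked base
#' also reaches \code{min_minor} is flagged multiallelic.
#'
#' @param column list with \code{contig_id}, \code{pos}, \code{base_counts}
#'   (named numeric, A/C/G/T), and optionally \code{del_count},
#'   \code{del_seq}, \code{ins_events} (data.frame \code{seq},
#'   \code{count}).
#' @param thresholds a [variant_thresholds()] object.
#' @return variant call data.frame (zero rows when no rule fires).
#' @export
declare_putative <- function(column, thresholds = variant_thresholds()) {
  bc <- column$base_counts[BASES]
  bc[is.na(bc)] <- 0
  base_depth <- sum(bc)
  out <- list()
  ord <- order(-bc, BASES)             # ties broken alphabetically
  if (base_depth >= thresholds$min_depth &&
      bc[ord[2]] >= thresholds$min_minor) {
    out[[length(out) + 1L]] <- new_call(
      column$contig_id, column$pos, "SNP",
      major = BASES[ord[1]], minor = BASES[ord[2]],
      depth = base_depth, minor_count = unname(bc[ord[2]]),
      multiallelic = bc[ord[3]] >= thresholds$min_minor)
  }
  dc <- column$del_count %||% 0L
  if (dc > 0) {
    span_depth <- base_depth + dc
    if (span_depth >= thresholds$min_depth &&
        min(dc, base_depth) >= thresholds$min_minor) {
      delseq <- column$del_seq %||% "?"
      if (dc <= base_depth) {
        major <- delseq; minor <- "-"
      } else {
        major <- "-"; minor <- delseq
      }
      out[[length(out) + 1L]] <- new_call(
        column$contig_id, column$pos, "DEL", major, minor,
        depth = span_depth, minor_count = min(dc, base_depth),
        multiallelic = FALSE)
    }
  }
  ie <- column$ins_events
  if (!is.null(ie) && nrow(ie) > 0) {
    top <- which.max(ie$count)
    ci <- ie$count[top]
    non_ins <- base_depth - sum(ie$count)   # rarer insertions count to neither
    depth <- ci + max(non_ins, 0)
    if (depth >= thresholds$min_depth &&
        min(ci, non_ins) >= thresholds$min_minor) {
      if (ci <= non_ins) {
        major <- "-"; minor <- ie$seq[top]
      } else {
        major <- ie$seq[top]; minor <- "-"
      }
      out[[length(out) + 1L]] <- new_call(
        column$contig_id, column$pos, "INS", major, minor,
        depth = depth, minor_count = min(ci, non_ins),
        multiallelic = FALSE)
    }
  }
  if (length(out) == 0) return(empty_calls())
  do.call(rbind, out)
}

new_call <- function(contig_id, pos, vtype, major, minor, depth, minor_count,
                     multiallelic = FALSE) {
  maf <- minor_count / depth
  data.frame(contig_id = contig_id, pos = as.integer(pos), vtype = vtype,
             major_allele = major, minor_allele = minor,
             depth = as.integer(depth), minor_count = as.integer(minor_count),
             maf = maf,
             subst_class = if (vtype == "SNP")
               classify_substitution(major, minor) else NA_character_,
             multiallelic = multiallelic,
             filter_flags = "", passed = NA,
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(contig_id = character(0), pos = integer(0), vtype = character(0),
             major_allele = character(0), minor_allele = character(0),
             depth = integer(0), minor_count = integer(0), maf = numeric(0),
             subst_class = character(0), multiallelic = logical(0),
             filter_flags = character(0), passed = logical(0),
             stringsAsFactors = FALSE)
}

#' Declare putative variants across a whole pileup
#'
#' Applies the single-column declaration rule of [declare_putative()] to
#' every pileup column, merging runs of consecutive qualifying deleted
#' columns into one multi-base deletion event (anchored at the first
#' deleted position) so that a single deletion allele is not reported --
#' and cluster-filtered -- once per deleted base.
#'
#' @param pileup a [build_pileup()] object.
#' @param contigs the contig sequences (used for deletion allele sequence).
#' @param thresholds a [variant_thresholds()] object.
#' @return putative variant call data.frame sorted by (contig, position).
#' @export
call_variants <- function(pileup, contigs, thresholds = variant_thresholds()) {
  contigs <- as_seq_vector(contigs)
  res <- list()
  for (ctg in names(pileup)) {
    p <- pileup[[ctg]]
    M <- p$counts
    len <- p$length
    bd <- rowSums(M)
    # SNPs: top two (and third, for the multiallelic flag) base counts,
    # computed vectorized; max.col with ties.method = "first" breaks count
    # ties alphabetically, which fixes major/minor labels deterministically
    cand <- which(bd >= thresholds$min_depth)
    if (length(cand) > 0) {
      sub <- M[cand, , drop = FALSE]
      o1 <- max.col(sub, ties.method = "first")
      v1 <- sub[cbind(seq_along(cand), o1)]
      sub[cbind(seq_along(cand), o1)] <- -1L
      o2 <- max.col(sub, ties.method = "first")
      v2 <- sub[cbind(seq_along(cand), o2)]
      sub[cbind(seq_along(cand), o2)] <- -1L
      v3 <- sub[cbind(seq_along(cand), max.col(sub, ties.method = "first"))]
      hit <- which(v2 >= thresholds$min_minor)
      for (h in hit) {
        i <- cand[h]
        res[[length(res) + 1L]] <- new_call(
          ctg, i - 1L, "SNP", BASES[o1[h]], BASES[o2[h]],
          depth = bd[i], minor_count = v2[h],
          multiallelic = v3[h] >= thresholds$min_minor)
      }
    }
    # deletions: merge consecutive qualifying columns into one event
    dc <- p$del_count
    qual_del <- bd + dc >= thresholds$min_depth &
      pmin(dc, bd) >= thresholds$min_minor & dc > 0
    if (any(qual_del)) {
      r <- rle(qual_del)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]
        delseq <- substr(contigs[[ctg]], a, b)
        minor_count <- min(pmin(dc[a:b], bd[a:b]))
        if (dc[a] <= bd[a]) { major <- delseq; minor <- "-" }
        else { major <- "-"; minor <- delseq }
        res[[length(res) + 1L]] <- new_call(
          ctg, a - 1L, "DEL", major, minor,
          depth = bd[a] + dc[a], minor_count = minor_count,
          multiallelic = FALSE)
      }
    }
    # insertions
    ie <- p$ins_events
    if (nrow(ie) > 0) {
      for (anchor in unique(ie$pos)) {
        sub <- ie[ie$pos == anchor, , drop = FALSE]
        col <- list(contig_id = ctg, pos = anchor,
                    base_counts = M[anchor + 1L, ],
                    del_count = 0L, ins_events = sub)
        cl <- declare_putative(col, thresholds)
        cl <- cl[cl$vtype == "INS", , drop = FALSE]
        if (nrow(cl) > 0) res[[length(res) + 1L]] <- cl
      }
    }
  }
  if (length(res) == 0) return(empty_calls())
  calls <- do.call(rbind, res)
  calls <- calls[order(match(calls$contig_id, names(pileup)), calls$pos,
                       calls$vtype), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); every other base exchange is a transversion.
#'
#' @param a,b single bases in \code{{A,C,G,T}}, vectorized; \code{a != b}.
#' @return character vector, \code{"transition"} or \code{"transversion"}.
#' @export
classify_substitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(!a %in% BASES) || any(!b %in% BASES)) {
    stopf("bases must be in {A,C,G,T}")
  }
  if (any(a == b)) stopf("a and b must differ")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[a] == purine[b], "transition", "transversion"))
}

#' Apply the filter cascade to putative variant calls
#'
#' Flags assigned: \code{maf15} when the minor allele frequency is not
#' strictly above \code{maf_cut} (exactly 15% fails); \code{cluster} on
#' \emph{both} members when any other putative call on the same contig lies
#' within \code{cluster_window} bp (start positions compared, boundary
#' inclusive); \code{flankq} when per-base contig qualities are supplied
#' and the mean Phred quality over the flanking windows falls below
#' \code{flank_q} (skipped entirely when qualities are absent);
#' \code{multiallelic} carried through from declaration. A call passes iff
#' it has no flags. The cluster test runs against the complete putative
#' set, not merely against surviving calls.
#'
#' @param calls putative calls sorted by (contig, position); unsorted input
#'   is an error.
#' @param thresholds a [variant_thresholds()] object.
#' @param qualities optional named list (by contig) of per-base numeric
#'   Phred qualities.
#' @return `calls` with \code{filter_flags} (semicolon-joined) and
#'   \code{passed} filled in.
#' @export
apply_filters <- function(calls, thresholds = variant_thresholds(),
                          qualities = NULL) {
  if (nrow(calls) == 0) {
    calls$filter_flags <- character(0); calls$passed <- logical(0)
    return(calls)
  }
  unsorted <- unlist(tapply(calls$pos, factor(calls$contig_id,
                                              levels = unique(calls$contig_id)),
                            function(p) is.unsorted(p)))
  if (any(unsorted)) stopf("calls must be sorted by position within contig")
  flags <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    fl <- character(0)
    if (calls$maf[i] <= thresholds$maf_cut) fl <- c(fl, "maf15")
    near <- calls$contig_id == calls$contig_id[i] &
      abs(calls$pos - calls$pos[i]) <= thresholds$cluster_window
    if (sum(near) > 1L) fl <- c(fl, "cluster")
    if (!is.null(qualities)) {
      q <- qualities[[calls$contig_id[i]]]
      if (!is.null(q)) {
        s <- thresholds$flank_q_span
        p <- calls$pos[i] + 1L            # 1-based
        win <- c(max(1L, p - s):(p - 1L), (p + 1L):min(length(q), p + s))
        win <- win[win >= 1L & win <= length(q) & win != p]
        if (length(win) > 0 && mean(q[win]) < thresholds$flank_q) {
          fl <- c(fl, "flankq")
        }
      }
    }
    if (isTRUE(calls$multiallelic[i])) fl <- c(fl, "multiallelic")
    flags[[i]] <- fl
  }
  calls$filter_flags <- vapply(flags, function(f)
    paste(sort(f), collapse = ";"), character(1))
  calls$passed <- calls$filter_flags == ""
  calls
}

#' Summarize putative and filtered variant calls
#'
#' @param calls filtered call set from [apply_filters()] (putative calls
#'   with pass/fail state).
#' @param contigs the contig collection the calls derive from.
#' @return list of class \code{variant_summary}: counts by type for the
#'   putative and filtered sets, per-type variant rates ("one per N bp" of
#'   total contig length), transition/transversion counts over filtered
#'   SNPs, per-contig means over contigs containing calls, the minor allele
#'   frequency histogram of filtered calls in 5% bins above 15%, and the
#'   mean minor allele frequency (percent).
#' @export
summarize_variants <- function(calls, contigs) {
  contigs <- as_seq_vector(contigs)
  total_len <- sum(nchar(contigs))
  types <- c("SNP", "INS", "DEL")
  n_put <- table(factor(calls$vtype, levels = types))
  filt <- calls[isTRUE_vec(calls$passed), , drop = FALSE]
  n_filt <- table(factor(filt$vtype, levels = types))
  rate <- function(n) if (n > 0) total_len / n else NA_real_
  fsnp <- filt[filt$vtype == "SNP", , drop = FALSE]
  findel <- filt[filt$vtype != "SNP", , drop = FALSE]
  psnp <- calls[calls$vtype == "SNP", , drop = FALSE]
  pindel <- calls[calls$vtype != "SNP", , drop = FALSE]
  per_contig <- function(df) {
    if (nrow(df) == 0) return(list(n_contigs = 0L, mean_per_contig = NA_real_))
    tab <- table(df$contig_id)
    list(n_contigs = length(tab),
         mean_per_contig = round_half_up(nrow(df) / length(tab), 2))
  }
  breaks <- seq(0.15, 0.50, by = 0.05)
  hist <- table(cut(filt$maf, breaks = breaks, include.lowest = FALSE,
                    right = TRUE))
  structure(list(
    n_putative = as.list(n_put),
    n_filtered = as.list(n_filt),
    snp_rate_bp_putative = rate(sum(psnp$vtype == "SNP")),
    snp_rate_bp_filtered = rate(nrow(fsnp)),
    indel_rate_bp_putative = rate(nrow(pindel)),
    indel_rate_bp_filtered = rate(nrow(findel)),
    transitions = sum(fsnp$subst_class == "transition"),
    transversions = sum(fsnp$subst_class == "transversion"),
    snp_contigs = per_contig(fsnp),
    indel_contigs = per_contig(findel),
    maf_histogram = as.integer(hist),
    maf_bins = levels(cut(numeric(0), breaks)),
    mean_maf_pct = if (nrow(filt) > 0)
      round_half_up(mean(filt$maf) * 100, 1) else NA_real_,
    total_contig_length = total_len
  ), class = "variant_summary")
}

isTRUE_vec <- function(x) !is.na(x) & x
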