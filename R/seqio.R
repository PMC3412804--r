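# Sequence and alignment I/O: FASTA, a SAM subset, minimal VCF, TSV tables.
#
# Conventions used throughout the package:
#   * internal coordinates are 0-based half-open;
#   * everything human-facing (VCF POS, TSV start/end columns) is 1-based
#     inclusive;
#   * residues are uppercased on ingest and restricted to {A,C,G,T,N}.

#' Read a FASTA file into a named sequence vector
#'
#' Sequences are returned as a named uppercase character vector, one element
#' per record, with wrapped lines concatenated. Header text after the first
#' whitespace is kept in the \code{"description"} attribute. Duplicate ids and
#' residues outside \code{{A,C,G,T,N}} are errors.
#'
#' @param path path to a FASTA text file (wrapped or unwrapped).
#' @return named character vector of sequences; attribute
#'   \code{description} holds any header free text.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) {
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stopf("malformed FASTA %s: sequence before first '>' header at line 1",
          path)
  }
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  check_alphabet(out)
  if (any(nchar(out) == 0)) {
    stopf("empty sequence record(s) in %s: %s", path,
          paste(ids[nchar(out) == 0], collapse = ", "))
  }
  names(desc) <- ids
  attr(out, "description") <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector or DNAStringSet.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  seqs <- as_seq_vector(sequences)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# --- CIGAR handling (restricted dialect: M/=/X -> ALN, I, D, S) -------------

.cigar_cache <- new.env(parent = emptyenv())

#' Parse a CIGAR string of the supported dialect
#'
#' Supported operations are M/=/X (mapped to \code{ALN}), I (\code{INS}),
#' D (\code{DEL}) and S (\code{CLIP}). N, H and P raise an unsupported-op
#' error: spliced or hard-clipped alignments are outside the EST use case.
#'
#' @param cigar a single CIGAR string, e.g. \code{"2M1I2M"}.
#' @return data.frame with columns \code{op} (ALN/INS/DEL/CLIP) and
#'   \code{len}.
#' @export
parse_cigar <- function(cigar) {
  cached <- .cigar_cache[[cigar]]
  if (!is.null(cached)) return(cached)
  if (!grepl("^([0-9]+[MIDSNHP=X])+$", cigar)) {
    stopf("malformed CIGAR string: '%s'", cigar)
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  raw_ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (any(raw_ops %in% c("N", "H", "P"))) {
    stopf("unsupported CIGAR op '%s' in '%s' (only M/=/X/I/D/S are handled)",
          intersect(raw_ops, c("N", "H", "P"))[1], cigar)
  }
  if (any(lens < 1L)) stopf("zero-length CIGAR op in '%s'", cigar)
  op <- c(M = "ALN", `=` = "ALN", X = "ALN",
          I = "INS", D = "DEL", S = "CLIP")[raw_ops]
  res <- data.frame(op = unname(op), len = lens, stringsAsFactors = FALSE)
  .cigar_cache[[cigar]] <- res
  res
}

#' Reference span consumed by a CIGAR string (ALN + DEL lengths)
#' @param cigar CIGAR string.
#' @return integer span on the reference.
#' @export
cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("ALN", "DEL")])
}

cigar_query_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("ALN", "INS", "CLIP")])
}

# --- alignments -------------------------------------------------------------

#' Read read-to-contig alignments
#'
#' Two formats are accepted: a header-optional SAM subset (CIGAR limited to
#' M/=/X/I/D/S) and an equivalent TSV with columns \code{read_id},
#' \code{contig_id}, \code{ref_start} (0-based), \code{cigar},
#' \code{residues} and optionally \code{qualities}. Unmapped SAM records
#' (flag 0x4 or RNAME \code{*}) are skipped with a message reporting the
#' count. Residue length inconsistent with the CIGAR is an error.
#'
#' @param path input path.
#' @param format \code{"sam"} or \code{"tsv"}.
#' @return data.frame with columns \code{read_id}, \code{contig_id},
#'   \code{ref_start} (0-based), \code{cigar}, \code{residues},
#'   \code{qualities} (comma-separated Phred integers or \code{NA}).
#' @export
read_alignments <- function(path, format = c("sam", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  if (format == "sam") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(lines) == 0) return(empty_alignments())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      stopf("SAM line %d has %d fields (>= 11 required)",
            which(nf < 11L)[1], min(nf))
    }
    m <- vapply(fields, function(f) f[1:10], character(10))
    flag <- as.integer(m[2, ])
    unmapped <- bitwAnd(flag, 4L) != 0L | m[3, ] == "*"
    if (any(unmapped)) {
      message(sum(unmapped), " unmapped record(s) skipped")
      m <- m[, !unmapped, drop = FALSE]
      if (ncol(m) == 0) return(empty_alignments())
    }
    aln <- data.frame(
      read_id = m[1, ], contig_id = m[3, ],
      ref_start = as.integer(m[4, ]) - 1L,
      cigar = m[6, ], residues = toupper(m[10, ]),
      qualities = NA_character_, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("read_id", "contig_id", "ref_start", "cigar", "residues")
    if (!all(need %in% names(tab))) {
      stopf("alignment TSV must have columns: %s", paste(need, collapse = ", "))
    }
    aln <- data.frame(
      read_id = tab$read_id, contig_id = tab$contig_id,
      ref_start = as.integer(tab$ref_start),
      cigar = tab$cigar, residues = toupper(tab$residues),
      qualities = if ("qualities" %in% names(tab)) {
        ifelse(nzchar(tab$qualities), tab$qualities, NA_character_)
      } else NA_character_,
      stringsAsFactors = FALSE)
  }
  validate_alignments(aln)
  aln
}

empty_alignments <- function() {
  data.frame(read_id = character(0), contig_id = character(0),
             ref_start = integer(0), cigar = character(0),
             residues = character(0), qualities = character(0),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(aln) {
  if (nrow(aln) == 0) return(invisible(aln))
  if (any(aln$residues == "*" | !nzchar(aln$residues))) {
    stopf("alignment record without residues: %s",
          aln$read_id[aln$residues == "*" | !nzchar(aln$residues)][1])
  }
  bad <- grepl("[^ACGTN]", aln$residues)
  if (any(bad)) {
    stopf("read residues outside {A,C,G,T,N}: %s",
          paste(aln$read_id[bad], collapse = ", "))
  }
  qlen <- vapply(aln$cigar, cigar_query_len, integer(1), USE.NAMES = FALSE)
  mism <- qlen != nchar(aln$residues)
  if (any(mism)) {
    stopf("residue length inconsistent with CIGAR for read '%s' (%d vs %d)",
          aln$read_id[mism][1], nchar(aln$residues)[mism][1], qlen[mism][1])
  }
  if (any(aln$ref_start < 0L)) {
    stopf("negative ref_start for read '%s'", aln$read_id[aln$ref_start < 0][1])
  }
  invisible(aln)
}

#' Write alignments as a minimal SAM file
#'
#' @param aln alignment data.frame as returned by [read_alignments()].
#' @param contigs named character vector of reference sequences (for the
#'   \code{@SQ} header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, contigs, path) {
  contigs <- as_seq_vector(contigs)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  body <- if (nrow(aln) > 0) {
    sam_cigar <- aln$cigar
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            aln$read_id, aln$contig_id, aln$ref_start + 1L, sam_cigar,
            aln$residues)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- VCF --------------------------------------------------------------------

#' Write variant calls as minimal VCF v4.2
#'
#' SNP records use the major allele as REF and the minor as ALT; insertion
#' and deletion records are left-anchored on the reference base preceding the
#' event, following VCF convention. FILTER is \code{PASS} for calls passing
#' the filter cascade and the semicolon-joined flag names otherwise. INFO
#' carries \code{DP} (depth), \code{MC} (minor-allele read count) and
#' \code{MAF}.
#'
#' @param calls variant call data.frame (see [call_variants()]), sorted by
#'   (contig, position).
#' @param contigs named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, contigs, path) {
  contigs <- as_seq_vector(contigs)
  if (nrow(calls) > 0) {
    if (!all(calls$contig_id %in% names(contigs))) {
      stopf("call contig(s) absent from contig collection: %s",
            paste(setdiff(calls$contig_id, names(contigs)), collapse = ", "))
    }
    ord <- order(match(calls$contig_id, names(contigs)), calls$pos)
    if (!identical(ord, seq_len(nrow(calls)))) {
      stopf("calls must be sorted by (contig, position) before writing VCF")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), nchar(contigs)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the locus\">",
    "##INFO=<ID=MC,Number=1,Type=Integer,Description=\"Minor allele read count\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##FILTER=<ID=maf15,Description=\"Minor allele frequency not above 0.15\">",
    "##FILTER=<ID=cluster,Description=\"Another putative variant within 15 bp\">",
    "##FILTER=<ID=flankq,Description=\"Mean flanking base quality below threshold\">",
    "##FILTER=<ID=multiallelic,Description=\"Third allele with two or more supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(calls))
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      cl <- calls[i, ]
      ctg <- contigs[[cl$contig_id]]
      if (cl$vtype == "SNP") {
        pos1 <- cl$pos + 1L
        ref <- cl$major_allele
        alt <- cl$minor_allele
      } else if (cl$vtype == "DEL") {
        if (cl$pos == 0L) {
          stopf("deletion at position 0 of contig '%s' has no left anchor base",
                cl$contig_id)
        }
        anchor <- substr(ctg, cl$pos, cl$pos)   # base at 0-based pos-1
        delseq <- if (cl$major_allele == "-") cl$minor_allele else cl$major_allele
        pos1 <- cl$pos            # 1-based position of the anchor base
        ref <- paste0(anchor, delseq)
        alt <- anchor
      } else {                    # INS anchored after 0-based pos
        anchor <- substr(ctg, cl$pos + 1L, cl$pos + 1L)
        insseq <- if (cl$major_allele == "-") cl$minor_allele else cl$major_allele
        pos1 <- cl$pos + 1L
        ref <- anchor
        alt <- paste0(anchor, insseq)
      }
      filt <- if (isTRUE(cl$passed) || identical(cl$filter_flags, "")) "PASS"
              else cl$filter_flags
      rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;MC=%d;MAF=%s",
                         cl$contig_id, pos1, ref, alt, filt,
                         cl$depth, cl$minor_count,
                         format(cl$maf, digits = 6))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# --- TSV tables -------------------------------------------------------------

#' Write a data.frame as a TSV table
#'
#' Tab-separated, header line, no quoting; \code{write_table()} and
#' [read_table()] are inverses on tables whose character cells contain no
#' tabs or newlines.
#'
#' @param rows data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stopf("rows must be a data.frame")
  bad <- vapply(rows, function(col)
    is.character(col) && any(grepl("[\t\n]", col)), logical(1))
  if (any(bad)) {
    stopf("character column(s) contain tab/newline: %s",
          paste(names(rows)[bad], collapse = ", "))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#' @param path input path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
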