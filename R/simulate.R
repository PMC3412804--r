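# Seeded simulator: contigs with planted repeats, two-haplotype read sets
# with planted variants, and ground-truth tables.
#
# The generator emulates an assembled 454 EST collection: contig lengths
# are drawn from a truncated normal with mean 730 bp and SD 331 bp, read
# lengths from mean 411 / SD 117 bp, matching the descriptive statistics of
# the collection the pipeline was designed around. Sequencing errors are
# substitution-only; two haplotypes (reference and alternate) stand in for
# a pooled sample, since the declaration and filter rules operate purely on
# allele counts and the per-read haplotype probability target_af directly
# controls what they see.

#' Simulation configuration
#'
#' @param n_contigs number of contigs to simulate.
#' @param contig_len_mean,contig_len_sd contig length distribution (bp);
#'   normal truncated at \code{min_contig_len}.
#' @param min_contig_len minimum contig length (bp).
#' @param gc GC fraction of simulated contigs.
#' @param coverage mean per-base read coverage.
#' @param read_len_mean,read_len_sd read length distribution (bp).
#' @param min_read_len minimum read length (bp).
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed; mandatory so that the same configuration
#'   always yields byte-identical output.
#' @return list of class \code{sim_config}.
#' @export
simulation_config <- function(n_contigs = 50L,
                              contig_len_mean = 730, contig_len_sd = 331,
                              min_contig_len = 100L,
                              gc = 0.47,
                              coverage = 7.6,
                              read_len_mean = 411, read_len_sd = 117,
                              min_read_len = 40L,
                              error_rate = 0.005,
                              seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (contig_len_sd < 0 || read_len_sd < 0) stopf("sd must be >= 0")
  if (contig_len_mean < min_contig_len) {
    stopf("contig_len_mean must be >= min_contig_len")
  }
  if (gc < 0 || gc > 1 || error_rate < 0 || error_rate > 1) {
    stopf("gc and error_rate must be in [0, 1]")
  }
  if (coverage < 0) stopf("coverage must be >= 0")
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_len_mean = contig_len_mean,
                 contig_len_sd = contig_len_sd,
                 min_contig_len = as.integer(min_contig_len),
                 gc = gc, coverage = coverage,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 min_read_len = as.integer(min_read_len),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate contig sequences
#'
#' @param config a [simulation_config()] object.
#' @return named character vector of \code{n_contigs} sequences with
#'   i.i.d. bases at the configured GC and truncated-normal lengths;
#'   deterministic under the configured seed.
#' @export
simulate_contigs <- function(config) {
  set.seed(config$seed)
  n <- config$n_contigs
  if (n == 0) return(setNames(character(0), character(0)))
  lens <- integer(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {             # rejection sampling below min length
    draw <- round(stats::rnorm(length(todo), config$contig_len_mean,
                               config$contig_len_sd))
    ok <- draw >= config$min_contig_len
    lens[todo[ok]] <- as.integer(draw[ok])
    todo <- todo[!ok]
  }
  seqs <- vapply(lens, function(L)
    paste(random_bases(L, config$gc), collapse = ""), character(1))
  names(seqs) <- sprintf("contig_%05d", seq_len(n))
  seqs
}

#' Plant perfect microsatellites into contigs
#'
#' Each specification row substitutes \code{repeat_count} copies of
#' \code{motif} into one contig at a position honoring the flank policy.
#' The bases immediately flanking the planted run are adjusted, when
#' needed, so the run cannot be extended in either direction -- the truth
#' rows then describe the emitted sequence exactly.
#'
#' @param contigs named character vector.
#' @param spec data.frame with columns \code{seq_id}, \code{motif},
#'   \code{repeat_count} and either \code{start} (0-based) or
#'   \code{min_flank} (bp of flank on each side; placement is then drawn
#'   uniformly).
#' @param seed RNG seed for placement draws.
#' @return list with \code{contigs} (modified collection) and \code{truth}
#'   (data.frame \code{seq_id}, \code{start}, \code{motif}, \code{period},
#'   \code{repeat_count}, \code{primer_ready_expected}).
#' @export
plant_ssrs <- function(contigs, spec, seed) {
  contigs <- as_seq_vector(contigs)
  if (is.null(spec) || nrow(spec) == 0) {
    return(list(contigs = contigs,
                truth = data.frame(seq_id = character(0), start = integer(0),
                                   motif = character(0), period = integer(0),
                                   repeat_count = integer(0),
                                   primer_ready_expected = logical(0))))
  }
  set.seed(seed)
  if (!all(is_primitive(spec$motif))) {
    stopf("planted motifs must be primitive")
  }
  placed <- lapply(names(contigs), function(x) cbind(integer(0), integer(0)))
  names(placed) <- names(contigs)
  truth <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    id <- spec$seq_id[i]
    if (!id %in% names(contigs)) stopf("unknown contig '%s' in SSR spec", id)
    s <- contigs[[id]]
    len <- nchar(s)
    p <- nchar(spec$motif[i])
    rep_len <- p * spec$repeat_count[i]
    if (!is.null(spec$start) && !is.na(spec$start[i])) {
      start <- as.integer(spec$start[i])
    } else {
      mf <- spec$min_flank[i]
      lo <- mf; hi <- len - rep_len - mf
      if (hi < lo) stopf("contig '%s' too short for planted repeat", id)
      start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    if (start < 0 || start + rep_len > len) {
      stopf("contig '%s' too short for planted repeat at %d", id, start)
    }
    prior <- placed[[id]]
    if (any(start < prior[, 2] + p & start + rep_len + p > prior[, 1])) {
      stopf("planted repeats on '%s' overlap or abut", id)
    }
    placed[[id]] <- rbind(prior, c(start, start + rep_len))
    run <- strrep(spec$motif[i], spec$repeat_count[i])
    s <- paste0(substr(s, 1, start), run,
                substr(s, start + rep_len + 1L, len))
    # break any accidental extension: base left of the run must differ from
    # the motif base one period in; base right of the run from the base one
    # period back
    if (start > 0) {
      guard <- substr(s, start + p, start + p)
      if (substr(s, start, start) == guard) {
        substr(s, start, start) <- sample(setdiff(BASES, guard), 1L)
      }
    }
    endp <- start + rep_len
    if (endp < len) {
      guard <- substr(s, endp - p + 1L, endp - p + 1L)
      if (substr(s, endp + 1L, endp + 1L) == guard) {
        substr(s, endp + 1L, endp + 1L) <- sample(setdiff(BASES, guard), 1L)
      }
    }
    contigs[[id]] <- s
    truth[[i]] <- data.frame(
      seq_id = id, start = start, motif = spec$motif[i], period = p,
      repeat_count = as.integer(spec$repeat_count[i]),
      primer_ready_expected = start >= 50L && len - (start + rep_len) >= 50L,
      stringsAsFactors = FALSE)
  }
  list(contigs = contigs, truth = do.call(rbind, truth))
}

#' Plant variants and build reference/alternate haplotype pairs
#'
#' @param contigs named character vector.
#' @param spec data.frame with columns \code{seq_id}, \code{pos} (0-based
#'   reference position; for insertions the anchor base after which the
#'   sequence is inserted), \code{vtype} (SNP/INS/DEL), \code{alt_allele}
#'   (SNP alternate base or inserted sequence; ignored for DEL),
#'   \code{del_len} (DEL only, 1-10), \code{target_af} fraction of reads to
#'   draw from the alternate haplotype.
#' @param allow_clustered permit planted variants within 15 bp of each
#'   other (off by default; a deliberately clustered pair must be asked
#'   for explicitly).
#' @return list with \code{haplotypes} (per contig: \code{ref},
#'   \code{alt}, \code{variants}) and \code{truth} (data.frame with
#'   \code{ref_allele}/\code{alt_allele} as emitted).
#' @export
plant_variants <- function(contigs, spec, allow_clustered = FALSE) {
  contigs <- as_seq_vector(contigs)
  if (is.null(spec)) spec <- data.frame()
  haplotypes <- lapply(names(contigs), function(id) {
    list(contig_id = id, ref = contigs[[id]], alt = contigs[[id]],
         variants = NULL)
  })
  names(haplotypes) <- names(contigs)
  truth <- list()
  if (nrow(spec) > 0) {
    if (any(!spec$seq_id %in% names(contigs))) {
      stopf("variant spec names unknown contig(s)")
    }
    if (any(spec$target_af <= 0 | spec$target_af >= 1)) {
      stopf("target_af must be in (0, 1)")
    }
    for (id in unique(spec$seq_id)) {
      sub <- spec[spec$seq_id == id, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      ref <- contigs[[id]]
      len <- nchar(ref)
      vl <- vector("list", nrow(sub))
      for (i in seq_len(nrow(sub))) {
        v <- sub[i, ]
        if (v$pos < 0 || v$pos >= len) stopf("variant position out of range")
        if (v$vtype == "SNP") {
          ref_allele <- substr(ref, v$pos + 1L, v$pos + 1L)
          alt_allele <- toupper(v$alt_allele)
          if (identical(ref_allele, alt_allele)) {
            stopf("planted SNP allele equals the reference base at %s:%d",
                  id, v$pos)
          }
          span <- c(v$pos, v$pos + 1L)
        } else if (v$vtype == "DEL") {
          k <- as.integer(v$del_len)
          if (is.na(k) || k < 1L || k > 10L) stopf("del_len must be 1-10")
          if (v$pos + k > len) stopf("deletion runs past contig end")
          ref_allele <- substr(ref, v$pos + 1L, v$pos + k)
          alt_allele <- "-"
          span <- c(v$pos, v$pos + k)
        } else if (v$vtype == "INS") {
          alt_allele <- toupper(v$alt_allele)
          if (nchar(alt_allele) < 1L || nchar(alt_allele) > 10L) {
            stopf("inserted sequence must be 1-10 bp")
          }
          ref_allele <- "-"
          span <- c(v$pos, v$pos + 1L)
        } else stopf("unknown vtype '%s'", v$vtype)
        vl[[i]] <- data.frame(seq_id = id, pos = as.integer(v$pos),
                              vtype = v$vtype, ref_allele = ref_allele,
                              alt_allele = alt_allele,
                              target_af = v$target_af,
                              span_end = span[2],
                              stringsAsFactors = FALSE)
      }
      vars <- do.call(rbind, vl)
      if (nrow(vars) > 1) {
        gaps <- diff(vars$pos)
        overlap <- vars$pos[-1] < vars$span_end[-nrow(vars)]
        if (any(overlap & vars$vtype[-1] != "SNP" |
                overlap & vars$vtype[-nrow(vars)] != "SNP")) {
          stopf("planted indels on '%s' overlap", id)
        }
        if (!allow_clustered && any(gaps <= 15)) {
          stopf(paste0("planted variants on '%s' are within 15 bp; ",
                       "set allow_clustered = TRUE if intended"), id)
        }
      }
      # build the alternate haplotype right-to-left so positions stay valid
      alt <- ref
      for (i in rev(seq_len(nrow(vars)))) {
        v <- vars[i, ]
        if (v$vtype == "SNP") {
          substr(alt, v$pos + 1L, v$pos + 1L) <- v$alt_allele
        } else if (v$vtype == "DEL") {
          alt <- paste0(substr(alt, 1, v$pos),
                        substr(alt, v$span_end + 1L, nchar(alt)))
        } else {
          alt <- paste0(substr(alt, 1, v$pos + 1L), v$alt_allele,
                        substr(alt, v$pos + 2L, nchar(alt)))
        }
      }
      haplotypes[[id]]$alt <- alt
      haplotypes[[id]]$variants <- vars
      truth[[length(truth) + 1L]] <- vars[, c("seq_id", "pos", "vtype",
                                              "ref_allele", "alt_allele",
                                              "target_af")]
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(seq_id = character(0), pos = integer(0), vtype = character(0),
               ref_allele = character(0), alt_allele = character(0),
               target_af = numeric(0), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(haplotypes = haplotypes, truth = truth)
}

# assemble residues + cigar for a read on the alternate haplotype whose
# reference span is [s, e); vars are the planted variants interior to it
alt_read <- function(ref, vars, s, e) {
  span <- substr(ref, s + 1L, e)
  snps <- vars[vars$vtype == "SNP", , drop = FALSE]
  for (i in seq_len(nrow(snps))) {
    off <- snps$pos[i] - s + 1L
    substr(span, off, off) <- snps$alt_allele[i]
  }
  indels <- vars[vars$vtype != "SNP", , drop = FALSE]
  if (nrow(indels) == 0) {
    return(list(residues = span, cigar = paste0(e - s, "M")))
  }
  indels <- indels[order(indels$pos), , drop = FALSE]
  res <- character(0); cig_op <- character(0); cig_len <- integer(0)
  cur <- s
  emit <- function(op, len) {
    if (len <= 0) return()
    cig_op <<- c(cig_op, op); cig_len <<- c(cig_len, len)
  }
  for (i in seq_len(nrow(indels))) {
    v <- indels[i, ]
    if (v$vtype == "DEL") {
      k <- nchar(v$ref_allele)
      res <- c(res, substr(span, cur - s + 1L, v$pos - s))
      emit("M", v$pos - cur); emit("D", k)
      cur <- v$pos + k
    } else {                              # INS after anchor pos
      res <- c(res, substr(span, cur - s + 1L, v$pos - s + 1L), v$alt_allele)
      emit("M", v$pos + 1L - cur); emit("I", nchar(v$alt_allele))
      cur <- v$pos + 1L
    }
  }
  res <- c(res, substr(span, cur - s + 1L, e - s))
  emit("M", e - cur)
  list(residues = paste(res, collapse = ""),
       cigar = paste0(cig_len, cig_op, collapse = ""))
}

#' Simulate reads from haplotype pairs
#'
#' Reads are placed uniformly along each contig (count per contig is
#' \code{round(coverage x length / read_len_mean)}); a read overlapping a
#' planted variant in its interior is drawn from the alternate haplotype
#' with probability \code{target_af}, otherwise from the reference.
#' Substitution errors are injected at \code{error_rate}. Alignments are
#' emitted directly in reference coordinates with the correct I/D
#' operations (ground-truth placement; no mapping step).
#'
#' @param haplotypes output of [plant_variants()] (\code{$haplotypes}).
#' @param config a [simulation_config()] object; reads use
#'   \code{config$seed + 1} so contig and read draws are decoupled.
#' @return alignment data.frame as from [read_alignments()].
#' @export
simulate_reads <- function(haplotypes, config) {
  set.seed(config$seed + 1L)
  out <- list()
  for (hp in haplotypes) {
    len <- nchar(hp$ref)
    n_reads <- max(0L, as.integer(round(config$coverage * len /
                                          config$read_len_mean)))
    if (n_reads == 0) next
    rl <- as.integer(round(stats::rnorm(n_reads, config$read_len_mean,
                                        config$read_len_sd)))
    rl <- pmin(pmax(rl, config$min_read_len), len)
    starts <- as.integer(floor(stats::runif(n_reads, 0, len - rl + 1)))
    starts <- pmin(starts, len - rl)      # guard the open upper bound
    vars <- hp$variants
    use_alt <- rep(FALSE, n_reads)
    if (!is.null(vars) && nrow(vars) > 0) {
      for (j in seq_len(n_reads)) {
        s <- starts[j]; e <- s + rl[j]
        interior <- interior_variants(vars, s, e)
        if (nrow(interior) > 0) {
          use_alt[j] <- stats::runif(1) < interior$target_af[1]
        }
      }
    }
    for (j in seq_len(n_reads)) {
      s <- starts[j]; e <- s + rl[j]
      if (use_alt[j]) {
        interior <- interior_variants(vars, s, e)
        ar <- alt_read(hp$ref, interior, s, e)
        residues <- ar$residues; cigar <- ar$cigar
      } else {
        residues <- substr(hp$ref, s + 1L, e)
        cigar <- paste0(e - s, "M")
      }
      nres <- nchar(residues)
      nerr <- stats::rbinom(1, nres, config$error_rate)
      if (nerr > 0) {
        at <- sample.int(nres, nerr)
        for (pp in at) {
          old <- substr(residues, pp, pp)
          substr(residues, pp, pp) <- sample(setdiff(BASES, old), 1L)
        }
      }
      out[[length(out) + 1L]] <- c(sprintf("%s_r%05d", hp$contig_id, j),
                                   hp$contig_id, s, cigar, residues)
    }
  }
  if (length(out) == 0) return(empty_alignments())
  m <- do.call(rbind, out)
  data.frame(read_id = m[, 1], contig_id = m[, 2],
             ref_start = as.integer(m[, 3]), cigar = m[, 4],
             residues = m[, 5], qualities = NA_character_,
             stringsAsFactors = FALSE)
}

# variants whose event lies strictly inside [s, e) with at least one
# aligned base on each side, so every emitted alignment stays well-formed
interior_variants <- function(vars, s, e) {
  if (is.null(vars) || nrow(vars) == 0) return(vars[0, , drop = FALSE])
  keep <- (vars$vtype == "SNP" & vars$pos > s & vars$pos < e - 1L) |
    (vars$vtype == "DEL" & vars$pos > s & vars$span_end < e) |
    (vars$vtype == "INS" & vars$pos >= s & vars$pos + 1L < e - 1L)
  vars[keep, , drop = FALSE]
}

#' Generate a complete simulated dataset on disk
#'
#' Writes \code{contigs.fa}, \code{reads.sam}, \code{truth_ssrs.tsv},
#' \code{truth_variants.tsv} and \code{config.json} into \code{outdir}.
#' Re-running with the same configuration and seed reproduces the files
#' byte for byte.
#'
#' @param config a [simulation_config()] object.
#' @param ssr_spec optional SSR plant specification (see [plant_ssrs()]).
#' @param variant_spec optional variant specification (see
#'   [plant_variants()]).
#' @param outdir output directory (created if absent).
#' @param allow_clustered passed to [plant_variants()].
#' @return named character vector of the five file paths, invisibly.
#' @export
generate_dataset <- function(config, ssr_spec = NULL, variant_spec = NULL,
                             outdir, allow_clustered = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stopf("cannot create output directory %s", outdir)
  contigs <- simulate_contigs(config)
  ssr <- plant_ssrs(contigs, ssr_spec, seed = config$seed + 2L)
  pv <- plant_variants(ssr$contigs, variant_spec,
                       allow_clustered = allow_clustered)
  reads <- simulate_reads(pv$haplotypes, config)
  paths <- c(contigs = file.path(outdir, "contigs.fa"),
             reads = file.path(outdir, "reads.sam"),
             truth_ssrs = file.path(outdir, "truth_ssrs.tsv"),
             truth_variants = file.path(outdir, "truth_variants.tsv"),
             config = file.path(outdir, "config.json"))
  write_fasta(ssr$contigs, paths[["contigs"]])
  write_sam(reads, ssr$contigs, paths[["reads"]])
  write_table(ssr$truth, paths[["truth_ssrs"]])
  write_table(pv$truth, paths[["truth_variants"]])
  jsonlite::write_json(unclass(config), paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Planted-SNP recovery study
#'
#' End-to-end parameter-recovery experiment: simulates contigs (two
#' isolated SNPs planted per contig, each at least one read length from
#' the contig ends so planted sites sit at full expected coverage),
#' simulates reads, builds pileups, declares and filters variants, and
#' scores recovery of the planted SNPs and the false-positive rate among
#' passing calls.
#'
#' @param n_contigs number of contigs (default 100).
#' @param coverage mean coverage (default 30).
#' @param read_len fixed read length (default 150).
#' @param error_rate per-base substitution error rate (default 0.001).
#' @param target_af planted allele fraction (default 0.3).
#' @param seed RNG seed.
#' @return list with \code{n_planted}, \code{n_recovered},
#'   \code{recovery_pct}, \code{n_false_positive}, \code{fp_per_10kb},
#'   \code{total_len}, and the underlying \code{calls} and \code{truth}.
#' @export
snp_recovery_study <- function(n_contigs = 100L, coverage = 30,
                               read_len = 150, error_rate = 0.001,
                               target_af = 0.3, seed) {
  config <- simulation_config(
    n_contigs = n_contigs, contig_len_mean = 730, contig_len_sd = 331,
    min_contig_len = 500L, coverage = coverage,
    read_len_mean = read_len, read_len_sd = 0, min_read_len = read_len,
    error_rate = error_rate, seed = seed)
  contigs <- simulate_contigs(config)
  lens <- nchar(contigs)
  set.seed(config$seed + 3L)
  spec <- do.call(rbind, lapply(names(contigs), function(id) {
    len <- lens[[id]]
    lo <- as.integer(read_len); hi <- len - as.integer(read_len) - 1L
    mid <- (lo + hi) %/% 2L
    p1 <- lo + sample.int(max(mid - 25L - lo, 1L), 1L) - 1L
    p2 <- (mid + 25L) + sample.int(max(hi - mid - 25L, 1L), 1L) - 1L
    ref <- substring(contigs[[id]], c(p1, p2) + 1L, c(p1, p2) + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
    data.frame(seq_id = id, pos = c(p1, p2), vtype = "SNP",
               alt_allele = unname(alt), del_len = NA_integer_,
               target_af = target_af, stringsAsFactors = FALSE)
  }))
  pv <- plant_variants(contigs, spec)
  reads <- simulate_reads(pv$haplotypes, config)
  pile <- build_pileup(reads, contigs)
  calls <- call_variants(pile, contigs)
  calls <- apply_filters(calls)
  passed <- calls[calls$passed, , drop = FALSE]
  truth <- pv$truth
  key <- function(d, p) paste(d, p)
  hit <- logical(nrow(truth))
  pk <- key(passed$contig_id, passed$pos)
  for (i in seq_len(nrow(truth))) {
    j <- match(key(truth$seq_id[i], truth$pos[i]), pk)
    if (!is.na(j) && passed$vtype[j] == "SNP" &&
        setequal(c(passed$major_allele[j], passed$minor_allele[j]),
                 c(truth$ref_allele[i], truth$alt_allele[i]))) {
      hit[i] <- TRUE
    }
  }
  tk <- key(truth$seq_id, truth$pos)
  fp <- sum(!key(passed$contig_id, passed$pos) %in% tk)
  total_len <- sum(lens)
  list(n_planted = nrow(truth), n_recovered = sum(hit),
       recovery_pct = round_half_up(100 * sum(hit) / nrow(truth), 1),
       n_false_positive = fp,
       fp_per_10kb = fp / total_len * 1e4,
       total_len = total_len, calls = calls, truth = truth)
}
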