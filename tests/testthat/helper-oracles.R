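# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n, gc = 0.5, n_rate = 0) {
  probs <- c((1 - gc) / 2 * (1 - n_rate), gc / 2 * (1 - n_rate),
             gc / 2 * (1 - n_rate), (1 - gc) / 2 * (1 - n_rate), n_rate)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = probs / sum(probs)), collapse = "")
}

# Brute-force SSR oracle: enumerate every start x period, chase consecutive
# full motif copies by substring equality, keep runs meeting the threshold
# whose motif is primitive and whose start cannot be shifted one base left
# (left-shiftable starts describe the same run in a later phase).
oracle_primitive <- function(m) {
  p <- nchar(m)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 &&
        paste(rep(substr(m, 1, d), p / d), collapse = "") == m) return(FALSE)
  }
  TRUE
}

oracle_find_ssrs <- function(seq,
                             min_repeats = c(`2` = 6, `3` = 5, `4` = 5,
                                             `5` = 5, `6` = 5)) {
  n <- nchar(seq)
  rows <- list()
  for (p in 2:6) {
    minrep <- min_repeats[[as.character(p)]]
    if (n < p * minrep) next
    starts <- seq_len(n - p * minrep + 1)
    motif <- substring(seq, starts, starts + p - 1)
    counts <- rep(1L, length(starts))
    alive <- !grepl("N", motif, fixed = TRUE)
    k <- 1L
    while (any(alive)) {
      nxt <- substring(seq, starts + k * p, starts + (k + 1L) * p - 1L)
      alive <- alive & nchar(nxt) == p & nxt == motif
      counts[alive] <- counts[alive] + 1L
      k <- k + 1L
    }
    for (j in seq_along(starts)) {
      if (counts[j] < minrep) next
      if (!oracle_primitive(motif[j])) next
      a <- starts[j]
      if (a > 1) {
        prev <- substr(seq, a - 1L, a - 1L)
        inpd <- substr(seq, a + p - 1L, a + p - 1L)
        if (prev == inpd && prev != "N") next   # same run, later phase
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = a - 1L, end = a - 1L + counts[j] * p,
        motif = motif[j], period = p, repeat_count = counts[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), period = integer(0),
                      repeat_count = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$period), , drop = FALSE]
}

# 12-entry transition/transversion lookup, written out by hand
TSTV_LOOKUP <- c("A>G" = "transition",   "G>A" = "transition",
                 "C>T" = "transition",   "T>C" = "transition",
                 "A>C" = "transversion", "C>A" = "transversion",
                 "A>T" = "transversion", "T>A" = "transversion",
                 "C>G" = "transversion", "G>C" = "transversion",
                 "G>T" = "transversion", "T>G" = "transversion")

# Minimal pileup column constructor for declaration tests
column_fixture <- function(base_counts = c(A = 0, C = 0, G = 0, T = 0),
                           del_count = 0L, ins_events = NULL,
                           contig_id = "c1", pos = 100L) {
  bc <- c(A = 0, C = 0, G = 0, T = 0)
  bc[names(base_counts)] <- base_counts
  list(contig_id = contig_id, pos = pos, base_counts = bc,
       del_count = del_count, del_seq = "A", ins_events = ins_events)
}

# A putative-call row for filter-semantics tests
call_fixture <- function(contig_id = "c1", pos, depth, minor_count,
                         vtype = "SNP", major = "A", minor = "G",
                         multiallelic = FALSE) {
  data.frame(contig_id = contig_id, pos = as.integer(pos), vtype = vtype,
             major_allele = major, minor_allele = minor,
             depth = as.integer(depth), minor_count = as.integer(minor_count),
             maf = minor_count / depth,
             subst_class = if (vtype == "SNP")
               classify_substitution(major, minor) else NA_character_,
             multiallelic = multiallelic, filter_flags = "", passed = NA,
             stringsAsFactors = FALSE)
}
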