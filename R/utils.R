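# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base \code{round()} uses banker's rounding; marker tables in the EST
#' literature round halves away from zero (2.085 -> 2.09), so summaries use
#' this variant throughout.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a sequence collection to a named uppercase character vector.
# Accepts a named character vector or a Biostrings::DNAStringSet.
as_seq_vector <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    out <- toupper(as.character(sequences))
    names(out) <- names(sequences)
    sequences <- out
  }
  if (!is.character(sequences)) {
    stop("sequences must be a named character vector or DNAStringSet")
  }
  if (length(sequences) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("all sequences must be named")
  }
  toupper(sequences)
}

# Validate the 5-letter alphabet; errors listing offending ids.
check_alphabet <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequences contain residues outside {A,C,G,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(seqs)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
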