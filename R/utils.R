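# Internal helpers shared across modules.

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param len integer vector of lengths (recycled to `n`).
#' @param alphabet bases to draw from, uniform.
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  # draw one long stream and split; fast for 1e5+ reads
  chars <- sample(alphabet, sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  big <- paste(chars, collapse = "")
  substring(big, starts, ends)
}

# accumulate weights at 0-based positions into a vector of length L
add_at0 <- function(L, pos0, w) {
  v <- numeric(L)
  if (length(pos0)) {
    keep <- pos0 >= 0L & pos0 < L
    if (any(keep)) {
      t <- rowsum(w[keep], pos0[keep])
      v[as.integer(rownames(t)) + 1L] <- t[, 1L]
    }
  }
  v
}

# population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stopifnot_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (first offender: '%s')",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

# new read table (collapsed reads)
read_table <- function(seq, count) {
  data.frame(seq = as.character(seq), count = as.numeric(count),
             stringsAsFactors = FALSE)
}
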