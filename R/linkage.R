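#' Ping-pong and phasing linkage spectra
#'
#' Linkage spectra measure the abundance-weighted co-occurrence of piRNA
#' ends at fixed nucleotide offsets. Frequencies are evaluated over a
#' window of 20 consecutive offsets containing the designated linkage
#' position, and the z-score of the linkage position is the deviation of
#' its frequency from the window mean divided by the (population) standard
#' deviation of the window frequencies.
#'
#' @name linkage
NULL

#' Window z-score of a linkage frequency
#'
#' The deviation of the linkage-position frequency from the mean window
#' frequency, divided by the (population, n-denominator) standard
#' deviation. With `exclude_link = TRUE` (the default, and what the
#' spectrum functions use) the background mean and standard deviation are
#' taken over the other window positions only; including the linkage
#' value itself caps the attainable z at `sqrt(n - 1)` (about 4.36 for a
#' window of 20), which cannot express a strong linkage signal. A
#' zero-variance background yields `z = 0`.
#'
#' @param frequencies window frequency values.
#' @param link_index position of the linkage frequency within the window.
#' @param exclude_link whether the background excludes the linkage value.
#' @return numeric z-score.
#' @export
linkage_zscore <- function(frequencies, link_index, exclude_link = TRUE) {
  bg <- if (exclude_link) frequencies[-link_index] else frequencies
  s <- pop_sd(bg)
  if (s == 0) return(0)
  (frequencies[link_index] - mean(bg)) / s
}

linkage_spectrum <- function(kind, offsets, freq, link_at) {
  i <- which(offsets == link_at)
  zero_var <- pop_sd(freq[-i]) == 0
  z <- linkage_zscore(freq, i)
  structure(list(kind = kind,
                 spectrum = data.frame(offset = offsets, frequency = freq),
                 link_at = link_at, z = as.numeric(z),
                 zero_variance = zero_var),
            class = "linkage_spectrum")
}

#' @export
print.linkage_spectrum <- function(x, ...) {
  cat(sprintf("%s linkage spectrum: z = %.2f at offset %+d%s\n", x$kind,
              x$z, x$link_at,
              if (x$zero_variance) " (zero-variance window)" else ""))
  invisible(x)
}

# f(k) = sum_p a(p) * b(p + shift), shift may be negative
shifted_product <- function(a, b, shift) {
  L <- length(a)
  if (shift >= 0) {
    if (shift >= L) return(0)
    sum(a[seq_len(L - shift)] * b[seq_len(L - shift) + shift])
  } else {
    shifted_product(b, a, -shift)
  }
}

#' Ping-pong (5'-5' overlap) linkage spectrum
#'
#' For each overlap `k` in the window, the frequency is the sum over
#' reference positions `p` of `senseFive(p) * antisenseFive(p + k - 1)`,
#' so `k = 10` corresponds to the characteristic 10-nt 5' overlap of
#' ping-pong pairs. The z-score is evaluated at `k = 10`.
#'
#' @param profile an [end_profile()] carrying both strands (single-strand
#'   profiles are an error).
#' @param offsets overlap window (20 consecutive values including
#'   `link_at`).
#' @param link_at the designated linkage overlap.
#' @return a `linkage_spectrum` object.
#' @export
pingpong_spectrum <- function(profile, offsets = 1:20, link_at = 10L) {
  if (profile$sense_cpm <= 0 || profile$antisense_cpm <= 0) {
    stop("ping-pong linkage requires reads on both strands")
  }
  f <- vapply(offsets, function(k)
    shifted_product(profile$five_sense, profile$five_antisense, k - 1L),
    numeric(1))
  linkage_spectrum("pingpong", offsets, f, link_at)
}

#' Phasing (3'-5') linkage spectrum
#'
#' For each offset `k`, the frequency is the sum over positions `p` of
#' `three(p) * five(p + k)` on the same strand, evaluated in the strand's
#' own 5'-to-3' (transcript) orientation; head-to-tail phased trails place
#' the next piRNA's 5' end one nucleotide downstream of the previous 3'
#' end, i.e. at offset `+1`.
#'
#' @param profile an [end_profile()].
#' @param strand which strand's reads to analyse (antisense by default, as
#'   phased transposon piRNAs are predominantly antisense).
#' @param offsets offset window (20 consecutive values including
#'   `link_at`).
#' @param link_at designated linkage offset.
#' @return a `linkage_spectrum` object.
#' @export
phasing_spectrum <- function(profile, strand = c("antisense", "sense"),
                             offsets = -9:10, link_at = 1L) {
  strand <- match.arg(strand)
  if (strand == "antisense") {
    if (profile$antisense_cpm <= 0) stop("no antisense reads in profile")
    three <- rev(profile$three_antisense)
    five <- rev(profile$five_antisense)
  } else {
    if (profile$sense_cpm <= 0) stop("no sense reads in profile")
    three <- profile$three_sense
    five <- profile$five_sense
  }
  f <- vapply(offsets, function(k) shifted_product(three, five, k),
              numeric(1))
  linkage_spectrum("phasing", offsets, f, link_at)
}

#' Uridine frequency around piRNA 3' ends
#'
#' Abundance-weighted fraction of reads whose reference base at each
#' position relative to the 3' end is a U (T on the read strand). Position
#' `+1` is the immediate downstream nucleotide in the read's own 3'
#' direction; Zucchini-cleaved phased piRNAs show a U preference there.
#' Reads falling outside the reference at a given offset are excluded at
#' that offset.
#'
#' @param alignments alignment data frame on one reference.
#' @param ref_seq the reference sequence (character scalar).
#' @param positions integer offsets relative to the 3' end (0 is the last
#'   read base).
#' @param min_len minimum read length (piRNA definition).
#' @return data frame with columns `position` and `u_frequency`.
#' @export
downstream_u_frequency <- function(alignments, ref_seq, positions = -4:10,
                                   min_len = 23L) {
  keep <- (alignments$end - alignments$start) >= min_len
  a <- alignments[keep, , drop = FALSE]
  L <- nchar(ref_seq)
  bases <- strsplit(ref_seq, "")[[1]]
  w <- a$weight * a$count
  plus <- a$strand == "+"
  three0 <- ifelse(plus, a$end - 1L, a$start)
  res <- vapply(positions, function(r) {
    pos0 <- ifelse(plus, three0 + r, three0 - r)
    ok <- pos0 >= 0L & pos0 < L
    if (!any(ok)) return(NA_real_)
    b <- bases[pos0[ok] + 1L]
    is_u <- ifelse(plus[ok], b == "T", b == "A")
    sum(w[ok] * is_u) / sum(w[ok])
  }, numeric(1))
  data.frame(position = positions, u_frequency = res)
}
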