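# Independent oracles used by the test suite.

# Brute-force all-pairs sum-product linkage between two 9mer sets:
# aggregates frequencies per distinct 9mer by string comparison and sums
# products over every pair of entries with equal strings.
brute_force_linkage <- function(kmers_a, counts_a, kmers_b, counts_b) {
  fa <- 1000 * counts_a / sum(counts_a)
  fb <- 1000 * counts_b / sum(counts_b)
  total <- 0
  for (ka in unique(kmers_a)) {
    va <- sum(fa[kmers_a == ka])
    vb <- sum(fb[kmers_b == ka])
    total <- total + va * vb
  }
  total
}

# Position-by-position 25mer uniqueness oracle: counts occurrences of each
# k-mer across all contigs and their reverse complements by sliding-window
# string comparison, then marks covered positions by looping over unique
# k-mer footprints.
oracle_mappability <- function(genome, k) {
  all_kmers <- character(0)
  for (s in c(genome, vapply(genome, pirnasig::revcomp, character(1)))) {
    L <- nchar(s)
    if (L >= k) {
      for (i in 1:(L - k + 1L)) {
        all_kmers <- c(all_kmers, substr(s, i, i + k - 1L))
      }
    }
  }
  lapply(genome, function(s) {
    L <- nchar(s)
    cov <- logical(L)
    if (L >= k) {
      for (i in 1:(L - k + 1L)) {
        km <- substr(s, i, i + k - 1L)
        if (sum(all_kmers == km) == 1L) cov[i:(i + k - 1L)] <- TRUE
      }
    }
    cov
  })
}

# introduce n mismatches into a sequence at fixed positions
mutate_seq <- function(s, at) {
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  for (i in at) substr(s, i, i) <- swap[[substr(s, i, i)]]
  s
}

make_reads <- function(seqs, counts = rep(1, length(seqs))) {
  data.frame(seq = seqs, count = counts, stringsAsFactors = FALSE)
}
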