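#' Read raw reads from FASTQ with a mean-quality pass filter
#'
#' Loads a FASTQ file and drops reads whose mean Phred quality is below
#' `min_mean_phred` (a simple pass-through threshold; no per-base
#' trimming). Returns raw sequences ready for [trim_small_rna()].
#'
#' @param path FASTQ file (uncompressed).
#' @param min_mean_phred minimum mean base quality; `0` keeps everything.
#' @return character vector of read sequences.
#' @export
read_fastq_reads <- function(path, min_mean_phred = 20) {
  # the reader warns about dropping FASTQ metadata columns; irrelevant here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- unname(as.character(x))
  if (min_mean_phred > 0) {
    q <- methods::as(Biostrings::quality(x), "IntegerList")
    seqs <- seqs[vapply(q, mean, numeric(1)) >= min_mean_phred]
  }
  seqs
}
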