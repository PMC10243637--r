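#' Small RNA library preprocessing
#'
#' Functions to turn raw small-RNA sequencing reads into filtered, collapsed
#' piRNA read sets with mapping weights and normalisation denominators.
#' Reads are represented throughout as a data frame with columns `seq`
#' (DNA string, A/C/G/T/N; U on input is converted to T) and `count`
#' (collapsed multiplicity). Alignments are data frames with 0-based
#' half-open coordinates and a fractional weight `1/n_hits` per mapping
#' instance, so that the weights of one read always sum to 1.
#'
#' @name preprocess
NULL

#' Default 3' cloning adapter (genomic-strand prefix)
#'
#' The cloning adapter carries 4 random nucleotides (a UMI) between the
#' insert and this constant sequence; [trim_small_rna()] locates this prefix.
#'
#' @export
default_adapter3 <- function() "AGATCGGAAGAGCACACGTCT"

#' Size-selection spike sequences
#'
#' DNA forms of the 19mer and 35mer RNA spikes co-loaded during PAGE size
#' selection; reads identical to either spike are removed by
#' [filter_by_size()].
#'
#' @return named character vector with elements `spike19` and `spike35`.
#' @export
spike_sequences <- function() {
  c(spike19 = "CGTACGCGGGTTTAAACGA",
    spike35 = "CTCATCTTGGTCGTACGCGGAATAGTTTAAACTGT")
}

#' Trim the 3' adapter and terminal UMIs from raw reads
#'
#' Locates the adapter by exact match of its first `anchor_len` bases
#' (leftmost hit wins), removes the adapter and everything downstream, then
#' strips `umi_len` random nucleotides from each end of the remainder.
#'
#' @param raw character vector of raw read sequences (U is converted to T;
#'   case-insensitive). Reads containing non-nucleotide characters are
#'   rejected with a warning and returned as `NA`.
#' @param adapter3 the 3' adapter given as its genomic-strand prefix.
#' @param umi_len number of random nucleotides at each end of the insert.
#' @param anchor_len number of adapter bases used for the exact match.
#' @return character vector of inserts; `NA` where no adapter was found or
#'   the remainder was shorter than `2 * umi_len`.
#' @examples
#' trim_small_rna(paste0("TTTT", strrep("ACGT", 6), "TTTT",
#'                       default_adapter3()))
#' @export
trim_small_rna <- function(raw, adapter3 = default_adapter3(), umi_len = 4L,
                           anchor_len = 10L) {
  stopifnot(umi_len >= 0L)
  raw <- chartr("u", "U", toupper(raw))
  raw <- chartr("U", "T", raw)
  bad <- !grepl("^[ACGTN]*$", raw)
  if (any(bad)) {
    warning(sprintf("%d read(s) with non-nucleotide characters rejected",
                    sum(bad)))
  }
  key <- substr(adapter3, 1L, min(anchor_len, nchar(adapter3)))
  pos <- regexpr(key, raw, fixed = TRUE)
  out <- rep(NA_character_, length(raw))
  hit <- !bad & pos > 0L
  rem <- substr(raw[hit], 1L, pos[hit] - 1L)
  ok <- nchar(rem) >= 2L * umi_len
  insert <- substr(rem[ok], umi_len + 1L, nchar(rem[ok]) - umi_len)
  idx <- which(hit)[ok]
  out[idx] <- insert
  out
}

#' Collapse reads to unique sequences with multiplicities
#'
#' @param seqs character vector of read sequences (`NA` entries dropped).
#' @param counts optional multiplicities (default 1 each).
#' @return read table (`seq`, `count`), one row per distinct sequence.
#' @export
collapse_reads <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(seqs))
  keep <- !is.na(seqs)
  seqs <- seqs[keep]; counts <- counts[keep]
  if (!length(seqs)) return(read_table(character(0), numeric(0)))
  agg <- rowsum(counts, seqs)
  read_table(rownames(agg), agg[, 1L])
}

#' Size-select reads and drop spike sequences
#'
#' Keeps reads whose length is within `[min_len, max_len]` and removes reads
#' identical to the size-selection spikes.
#'
#' @param reads read table (`seq`, `count`).
#' @param min_len,max_len inclusive length window.
#' @param spikes character vector of spike sequences to remove exactly.
#' @return filtered read table.
#' @export
filter_by_size <- function(reads, min_len = 18L, max_len = 40L,
                           spikes = spike_sequences()) {
  n <- nchar(reads$seq)
  keep <- n >= min_len & n <= max_len & !(reads$seq %in% spikes)
  reads[keep, , drop = FALSE]
}

#' Remove reads matching infrastructural RNAs
#'
#' Reads matching (as a substring, either orientation, within `max_mismatch`
#' Hamming distance) any supplied rRNA/snoRNA/snRNA/miRNA/tRNA sequence are
#' removed. Counts of reads matching the class named `"miRNA"` are recorded
#' for normalisation.
#'
#' @param reads read table.
#' @param annotations named list of character vectors of annotation
#'   sequences, one element per class (e.g. `rRNA`, `miRNA`, `tRNA`).
#' @param max_mismatch maximum Hamming distance for a match.
#' @return list with elements `reads` (surviving read table), `mirna_count`
#'   (summed multiplicity of miRNA-matching reads) and `removed` (named
#'   numeric of removed multiplicity per class).
#' @export
filter_infrastructural <- function(reads, annotations, max_mismatch = 1L) {
  classes <- names(annotations)
  if (length(annotations) == 0L || sum(lengths(annotations)) == 0L) {
    warning("empty annotation set: reads passed through, zero miRNA count")
    return(list(reads = reads, mirna_count = 0,
                removed = stats::setNames(numeric(0), character(0))))
  }
  subjects <- lapply(annotations, function(s) Biostrings::DNAStringSet(s))
  hit_class <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rs <- reads$seq[i]
    if (grepl("N", rs, fixed = TRUE)) next
    pats <- c(rs, revcomp(rs))
    for (cl in classes) {
      found <- FALSE
      for (j in seq_along(subjects[[cl]])) {
        subj <- subjects[[cl]][[j]]
        for (p in pats) {
          if (Biostrings::countPattern(p, subj,
                                       max.mismatch = max_mismatch) > 0L) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (found) { hit_class[i] <- cl; break }
    }
  }
  removed <- tapply(reads$count[!is.na(hit_class)],
                    hit_class[!is.na(hit_class)], sum)
  removed <- stats::setNames(as.numeric(removed), names(removed))
  mirna <- if ("miRNA" %in% names(removed)) removed[["miRNA"]] else 0
  list(reads = reads[is.na(hit_class), , drop = FALSE],
       mirna_count = mirna, removed = removed)
}

#' Brute-force read mapper for toy references
#'
#' Exhaustive Hamming-distance search of each read against both strands of a
#' small reference set (intended for toy genomes and transposon consensus
#' sequences; pre-aligned SAM/BED should be ingested for real genomes).
#'
#' @param reads read table.
#' @param references named character vector (or `DNAStringSet`) of reference
#'   sequences; non-ACGTN characters are an error.
#' @param max_mismatch maximum Hamming distance.
#' @param mode `"all"` reports every hit within `max_mismatch`; `"best_strata"`
#'   keeps only hits in the lowest observed mismatch stratum per read.
#' @return alignment data frame with columns `read_id`, `seq`, `count`,
#'   `ref`, `start` (0-based), `end` (exclusive), `strand`, `mismatches`,
#'   `n_hits`, `weight`. Reads containing N are not mapped.
#' @export
map_reads <- function(reads, references, max_mismatch = 0L,
                      mode = c("all", "best_strata")) {
  mode <- match.arg(mode)
  if (is.character(references)) {
    stopifnot_dna(references, "reference")
    references <- Biostrings::DNAStringSet(references)
  }
  if (is.null(names(references)) || anyNA(names(references))) {
    stop("references must be named")
  }
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rs <- reads$seq[i]
    if (grepl("N", rs, fixed = TRUE)) next
    hits <- list(); h <- 0L
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") rs else revcomp(rs)
      pd <- Biostrings::DNAString(pat)
      for (r in seq_along(references)) {
        m <- Biostrings::matchPattern(pd, references[[r]],
                                      max.mismatch = max_mismatch)
        if (length(m) == 0L) next
        mm <- lengths(Biostrings::mismatch(pd, m))
        for (j in seq_along(m)) {
          h <- h + 1L
          hits[[h]] <- data.frame(
            read_id = i, seq = rs, count = reads$count[i],
            ref = names(references)[r],
            start = BiocGenerics::start(m)[j] - 1L,
            end = BiocGenerics::end(m)[j],
            strand = strand, mismatches = mm[j],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (h == 0L) next
    df <- do.call(rbind, hits)
    if (mode == "best_strata") {
      df <- df[df$mismatches == min(df$mismatches), , drop = FALSE]
    }
    df$n_hits <- nrow(df)
    df$weight <- 1 / nrow(df)
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = integer(0), seq = character(0),
                      count = numeric(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      n_hits = integer(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Remove reads mapping near tRNA loci
#'
#' Drops every read that has at least one mapping instance overlapping a
#' tRNA interval extended by `flank` on both sides; all mapping instances of
#' such reads are removed.
#'
#' @param alignments alignment data frame (see [map_reads()]).
#' @param trna_intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, genome coordinates).
#' @param flank extension in nt on each side.
#' @return filtered alignment data frame.
#' @export
remove_trna_flanks <- function(alignments, trna_intervals, flank = 100L) {
  if (nrow(alignments) == 0L || nrow(trna_intervals) == 0L) return(alignments)
  aln <- GenomicRanges::GRanges(
    alignments$ref,
    IRanges::IRanges(alignments$start + 1L, alignments$end))
  trna <- GenomicRanges::GRanges(
    trna_intervals$chrom,
    IRanges::IRanges(pmax(1L, trna_intervals$start + 1L - flank),
                     trna_intervals$end + flank))
  ov <- GenomicRanges::findOverlaps(aln, trna)
  bad_reads <- unique(alignments$read_id[S4Vectors::queryHits(ov)])
  alignments[!(alignments$read_id %in% bad_reads), , drop = FALSE]
}

#' Library-level normalisation statistics
#'
#' @param alignments genome alignment data frame.
#' @param mirna_count miRNA-matching read multiplicity (from
#'   [filter_infrastructural()]).
#' @param spike_count multiplicity of removed spike reads.
#' @return one-row data frame: `total_mappers`, `unique_mappers`,
#'   `mirna_reads`, `spike_reads`.
#' @export
library_stats <- function(alignments, mirna_count = 0, spike_count = 0) {
  per_read <- unique(alignments[, c("read_id", "count", "n_hits")])
  data.frame(
    total_mappers = sum(per_read$count),
    unique_mappers = sum(per_read$count[per_read$n_hits == 1L]),
    mirna_reads = mirna_count,
    spike_reads = spike_count)
}

#' Read a collapsed FASTA file
#'
#' Headers are expected in `>id_count` form; the integer after the final
#' underscore is the collapsed multiplicity.
#'
#' @param path FASTA file.
#' @return read table (`seq`, `count`).
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- suppressWarnings(as.numeric(sub("^.*_", "", names(x))))
  if (anyNA(counts)) {
    stop("collapsed FASTA headers must end in '_<count>'")
  }
  read_table(as.character(x), counts)
}

#' Write a collapsed FASTA file
#'
#' @param reads read table.
#' @param path output file.
#' @param prefix header prefix (`>prefix<i>_<count>`).
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- sprintf("%s%d_%d", prefix, seq_len(nrow(reads)),
                      as.integer(round(reads$count)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read pre-computed alignments from 6-column BED
#'
#' Columns: chrom, start, end, name, n_hits (score), strand. The `name`
#' column must be `id_count` as in collapsed FASTA headers so multiplicities
#' can be recovered; all rows sharing a name are mapping instances of the
#' same read.
#'
#' @param path BED file.
#' @return alignment data frame as produced by [map_reads()] (without `seq`
#'   and `mismatches`).
#' @export
read_bed_alignments <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("expected 6-column BED")
  names(bed)[1:6] <- c("ref", "start", "end", "name", "n_hits", "strand")
  count <- suppressWarnings(as.numeric(sub("^.*_", "", bed$name)))
  if (anyNA(count)) stop("BED name column must be 'id_<count>'")
  data.frame(read_id = match(bed$name, unique(bed$name)),
             count = count, ref = bed$ref,
             start = bed$start, end = bed$end, strand = bed$strand,
             n_hits = as.integer(bed$n_hits),
             weight = 1 / as.integer(bed$n_hits),
             stringsAsFactors = FALSE)
}
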