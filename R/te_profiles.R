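#' Per-transposon end-coverage profiles
#'
#' An `end_profile` stores, for a single reference sequence (typically a
#' transposon consensus), per-position counts of piRNA 5' and 3' ends on
#' the sense and antisense strands, in CPM (counts per million genome
#' mappers). Only reads of at least `min_len` nt contribute.
#'
#' @param alignments alignment data frame against a single reference.
#' @param ref_name reference name; alignments to other references are an
#'   error.
#' @param ref_length reference length in nt.
#' @param genome_mappers normalisation denominator (total genome-mapping
#'   read count of the library).
#' @param min_len minimum read length in nt (piRNA definition).
#' @return object of class `end_profile`: list with per-position numeric
#'   vectors `five_sense`, `three_sense`, `five_antisense`,
#'   `three_antisense` (CPM), plus totals `sense_cpm` and `antisense_cpm`.
#' @export
end_profile <- function(alignments, ref_name, ref_length, genome_mappers,
                        min_len = 23L) {
  if (nrow(alignments) && any(alignments$ref != ref_name)) {
    stop("alignments reference other sequences than '", ref_name, "'")
  }
  keep <- (alignments$end - alignments$start) >= min_len
  a <- alignments[keep, , drop = FALSE]
  scale <- 1e6 / genome_mappers
  w <- a$weight * a$count * scale
  plus <- a$strand == "+"
  five0 <- ifelse(plus, a$start, a$end - 1L)
  three0 <- ifelse(plus, a$end - 1L, a$start)
  out <- list(
    reference = ref_name, length = ref_length,
    five_sense = add_at0(ref_length, five0[plus], w[plus]),
    three_sense = add_at0(ref_length, three0[plus], w[plus]),
    five_antisense = add_at0(ref_length, five0[!plus], w[!plus]),
    three_antisense = add_at0(ref_length, three0[!plus], w[!plus]),
    genome_mappers = genome_mappers, min_len = min_len)
  out$sense_cpm <- sum(out$five_sense)
  out$antisense_cpm <- sum(out$five_antisense)
  class(out) <- "end_profile"
  out
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("end_profile of %s (%d nt): sense %.2f CPM, antisense %.2f CPM\n",
              x$reference, x$length, x$sense_cpm, x$antisense_cpm))
  invisible(x)
}

#' Antisense strand bias of a profile
#'
#' Fraction of antisense reads out of all reads mapping to the reference.
#'
#' @param profile an `end_profile`.
#' @return value in `[0, 1]`, or `NA` if the profile is empty.
#' @export
strand_bias <- function(profile) {
  tot <- profile$sense_cpm + profile$antisense_cpm
  if (tot <= 0) return(NA_real_)
  profile$antisense_cpm / tot
}

#' Mirror a profile to the opposite reference strand
#'
#' Equivalent to reverse-complementing the reference: coordinates are
#' mirrored and sense/antisense roles exchanged. Used to express the strand
#' symmetry of the linkage statistics.
#'
#' @param profile an `end_profile`.
#' @return the mirrored `end_profile`.
#' @export
flip_profile <- function(profile) {
  out <- profile
  out$five_sense <- rev(profile$five_antisense)
  out$three_sense <- rev(profile$three_antisense)
  out$five_antisense <- rev(profile$five_sense)
  out$three_antisense <- rev(profile$three_sense)
  out$sense_cpm <- profile$antisense_cpm
  out$antisense_cpm <- profile$sense_cpm
  out
}

#' Per-length 5' nucleotide composition
#'
#' Fraction of read multiplicity starting with each base, per read length;
#' the U (T) column measures the 1U bias.
#'
#' @param reads read table.
#' @return data frame with columns `length`, `A`, `C`, `G`, `T` (fractions
#'   summing to 1 per length; reads starting with N are ignored).
#' @export
first_nt_fractions <- function(reads) {
  first <- substr(reads$seq, 1L, 1L)
  keep <- first %in% c("A", "C", "G", "T")
  len <- nchar(reads$seq)[keep]
  first <- factor(first[keep], levels = c("A", "C", "G", "T"))
  cnt <- reads$count[keep]
  tab <- tapply(cnt, list(len, first), sum, default = 0)
  frac <- tab / rowSums(tab)
  out <- data.frame(length = as.integer(rownames(frac)))
  out <- cbind(out, as.data.frame(frac))
  rownames(out) <- NULL
  out
}

#' Select a nonredundant transposon set
#'
#' Ranks entries by piRNA abundance, takes the `top_n`, then greedily drops
#' any lower-ranked entry whose shared-read fraction with a retained
#' higher-ranked entry exceeds `share_threshold`. The shared fraction of a
#' lower-ranked entry `j` against a retained entry `i` is
#' `shared[i, j] / te_counts[j]` (share of `j`'s weighted reads also
#' mapping to `i`).
#'
#' @param te_counts named numeric of weighted piRNA counts per entry.
#' @param share_matrix square matrix (dimnames = entry names) of weighted
#'   reads mapping to both entries.
#' @param top_n number of most-abundant entries considered.
#' @param share_threshold redundancy cutoff on the shared fraction.
#' @return list with `selected` (ordered names) and `audit` (data frame of
#'   removed entries: `removed`, `absorbed_by`, `share`).
#' @export
select_nonredundant_te <- function(te_counts, share_matrix, top_n = 150L,
                                   share_threshold = 0.5) {
  ranked <- names(sort(te_counts, decreasing = TRUE))
  ranked <- utils::head(ranked, top_n)
  kept <- character(0)
  audit <- list()
  for (e in ranked) {
    shares <- if (length(kept))
      vapply(kept, function(k) share_matrix[k, e] / te_counts[[e]],
             numeric(1))
    else numeric(0)
    if (length(shares) && max(shares) > share_threshold) {
      by <- kept[which.max(shares)]
      audit[[length(audit) + 1L]] <- data.frame(
        removed = e, absorbed_by = by, share = max(shares),
        stringsAsFactors = FALSE)
    } else {
      kept <- c(kept, e)
    }
  }
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(removed = character(0), absorbed_by = character(0),
               share = numeric(0), stringsAsFactors = FALSE)
  list(selected = kept, audit = audit)
}

#' Classify transposons as germline or soma-enriched
#'
#' A transposon is soma-enriched when its ovarian piRNA level exceeds
#' `fold` times its embryonic level (the embryonic pool is devoid of
#' somatic material). A pseudocount guards zero denominators.
#'
#' @param ovary_cpm,embryo_cpm CPM vectors from matched libraries.
#' @param fold enrichment fold.
#' @param pseudocount added to the embryonic CPM.
#' @return character vector, `"germline"` or `"soma_enriched"`.
#' @export
classify_te_compartment <- function(ovary_cpm, embryo_cpm, fold = 3,
                                    pseudocount = 0.1) {
  ifelse(ovary_cpm > fold * (embryo_cpm + pseudocount),
         "soma_enriched", "germline")
}

#' Both-strand eligibility for ping-pong analysis
#'
#' True when at least `min_frac` of the reads come from each strand
#' (boundary inclusive).
#'
#' @param profile an `end_profile`.
#' @param min_frac minimum minority-strand fraction.
#' @return logical.
#' @export
both_strand_eligible <- function(profile, min_frac = 0.10) {
  tot <- profile$sense_cpm + profile$antisense_cpm
  if (tot <= 0) return(FALSE)
  min(profile$sense_cpm, profile$antisense_cpm) / tot >= min_frac
}
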