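#' Genomic tile quantification of piRNA sources
#'
#' Fixed-width genomic windows (0.5 kb for genome-unique scatter analyses,
#' 0.2 kb for multimapper-weighted somatic quantification) with unique
#' mappability, annotation class and per-library normalised piRNA counts.
#' Comparing whole-ovary to embryonic (germline-only) libraries attributes
#' tiles with a strong ovary excess to the ovarian somatic cells.
#'
#' @name tiles
NULL

#' Partition contigs into fixed-width tiles
#'
#' The last partial tile of each contig is kept when it is at least half
#' the tile width, otherwise dropped.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param width tile width in nt.
#' @return data frame `chrom`, `start`, `end` (0-based half-open) with
#'   attribute `width`.
#' @export
tile_partition <- function(contig_lengths, width = 500L) {
  out <- do.call(rbind, lapply(names(contig_lengths), function(ch) {
    L <- contig_lengths[[ch]]
    starts <- seq(0L, max(0L, L - 1L), by = width)
    ends <- pmin(starts + width, L)
    keep <- (ends - starts) >= width / 2
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "width") <- as.integer(width)
  out
}

#' Unique-mappability of genomic tiles
#'
#' A genomic position is unique when the k-mer starting there occurs
#' exactly once in the genome (an occurrence on either strand counts); a
#' position is covered by unique regions when it is overlapped by at least
#' one unique k-mer. The mappability of a tile is its covered fraction,
#' and (for the 0.5 kb analysis) tiles pass at `min_frac` of 0.85.
#' Contigs shorter than `kmer` have zero mappability.
#'
#' @param genome named character vector of contig sequences.
#' @param tile_width tile width.
#' @param kmer k-mer length used to assess uniqueness.
#' @param min_frac minimum covered fraction for the `mappable` flag.
#' @return tile data frame with `mappability` and logical `mappable`
#'   columns.
#' @export
mappable_tiles <- function(genome, tile_width = 500L, kmer = 25L,
                           min_frac = 0.85) {
  lens <- stats::setNames(nchar(genome), names(genome))
  tiles <- tile_partition(lens, tile_width)
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < kmer) return(character(0))
    substring(s, 1:(L - kmer + 1L), kmer:L)
  }
  fwd <- lapply(genome, kmers_of)
  rvs <- lapply(genome, function(s) kmers_of(revcomp(s)))
  counts <- table(unlist(c(fwd, rvs), use.names = FALSE))
  covered <- lapply(names(genome), function(ch) {
    L <- lens[[ch]]
    cov <- logical(L)
    ks <- fwd[[ch]]
    if (length(ks)) {
      uniq <- as.integer(counts[ks]) == 1L
      # position covered iff a unique k-mer starts within the k last positions
      ind <- c(as.numeric(uniq), numeric(kmer - 1L))
      run <- stats::filter(ind, rep(1, kmer), sides = 1)
      run[is.na(run)] <- cumsum(ind)[is.na(run)]
      cov <- run[seq_len(L)] > 0
    }
    cov
  })
  names(covered) <- names(genome)
  tiles$mappability <- vapply(seq_len(nrow(tiles)), function(i) {
    cv <- covered[[tiles$chrom[i]]]
    mean(cv[(tiles$start[i] + 1L):tiles$end[i]])
  }, numeric(1))
  tiles$mappable <- tiles$mappability >= min_frac
  tiles
}

# 5' end (0-based) of each alignment instance
five_prime0 <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
}

#' Count piRNA reads per tile
#'
#' Each read (or mapping instance) is assigned to the single tile
#' containing its 5' end. In unique mode only genome-unique reads
#' (`n_hits == 1`) count, each with its full multiplicity; in all-mapper
#' mode every instance contributes `count / n_hits`, distributing
#' multimappers evenly across their mapping positions. Counts are
#' normalised to reads per million of `denom`.
#'
#' @param alignments alignment data frame (genome coordinates).
#' @param tiles tile data frame from [tile_partition()] or
#'   [mappable_tiles()].
#' @param denom normalisation denominator (e.g. genome-unique piRNA
#'   mappers for the unique analysis, all genome piRNA mappers otherwise);
#'   `NA` leaves raw counts.
#' @param unique_only count only `n_hits == 1` reads.
#' @param min_len minimum read length (piRNA definition).
#' @return `tiles` with an added `count` column.
#' @export
count_tile_reads <- function(alignments, tiles, denom = NA,
                             unique_only = TRUE, min_len = 23L) {
  width <- attr(tiles, "width")
  if (is.null(width)) stop("tiles must carry a 'width' attribute")
  a <- alignments[(alignments$end - alignments$start) >= min_len, ,
                  drop = FALSE]
  if (unique_only) {
    a <- a[a$n_hits == 1L, , drop = FALSE]
    w <- a$count
  } else {
    w <- a$count * a$weight
  }
  key <- paste(tiles$chrom, tiles$start, sep = ":")
  pos0 <- five_prime0(a)
  akey <- paste(a$ref, (pos0 %/% width) * width, sep = ":")
  idx <- match(akey, key)
  ok <- !is.na(idx)
  agg <- rowsum(w[ok], idx[ok])
  cnt <- numeric(nrow(tiles))
  cnt[as.integer(rownames(agg))] <- agg[, 1L]
  if (!is.na(denom)) cnt <- 1e6 * cnt / denom
  tiles$count <- cnt
  tiles
}

#' Flag somatic tiles from an ovary/embryo library pair
#'
#' A tile is somatic when its whole-ovary piRNA level exceeds `fold` times
#' its embryonic level (pseudocount-guarded), attributing its piRNAs to
#' the ovarian somatic cells absent from embryos.
#'
#' @param ovary_counts,embryo_counts normalised per-tile counts.
#' @param fold enrichment fold.
#' @param pseudocount added to the embryonic count.
#' @return logical vector.
#' @export
classify_somatic_tiles <- function(ovary_counts, embryo_counts, fold = 10,
                                   pseudocount = 0.1) {
  ovary_counts > fold * (embryo_counts + pseudocount)
}

coverage_fraction <- function(tiles, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(numeric(nrow(tiles)))
  tg <- GenomicRanges::GRanges(tiles$chrom,
                               IRanges::IRanges(tiles$start + 1L, tiles$end))
  ig <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end)))
  ov <- GenomicRanges::findOverlaps(tg, ig)
  inter <- IRanges::pintersect(tg[S4Vectors::queryHits(ov)],
                               ig[S4Vectors::subjectHits(ov)])
  covered <- tapply(BiocGenerics::width(inter), S4Vectors::queryHits(ov), sum)
  frac <- numeric(nrow(tiles))
  frac[as.integer(names(covered))] <- covered
  frac / (tiles$end - tiles$start)
}

#' Annotate tiles by overlapping features
#'
#' A class is eligible when its intervals cover at least `min_cover` of the
#' tile (boundary inclusive); conflicts are resolved in the priority order
#' piRNA cluster, then gypsy antisense, gypsy sense, then mRNA exon;
#' everything else is `other`.
#'
#' @param tiles tile data frame.
#' @param cluster_bed piRNA-cluster intervals (`chrom`, `start`, `end`).
#' @param gypsy_bed gypsy-insertion intervals with a `strand` column; `-`
#'   rows mark insertions whose piRNAs are antisense to the element.
#' @param exon_bed mRNA exon intervals.
#' @param min_cover minimum covered fraction.
#' @return `tiles` with an added `class` column (factor with levels
#'   `piRNA_cluster`, `gypsy_antisense`, `gypsy_sense`, `mRNA_exon`,
#'   `other`).
#' @export
annotate_tiles <- function(tiles, cluster_bed = NULL, gypsy_bed = NULL,
                           exon_bed = NULL, min_cover = 0.5) {
  gy_as <- gy_s <- NULL
  if (!is.null(gypsy_bed) && nrow(gypsy_bed)) {
    gy_as <- gypsy_bed[gypsy_bed$strand == "-", , drop = FALSE]
    gy_s <- gypsy_bed[gypsy_bed$strand == "+", , drop = FALSE]
  }
  fr <- cbind(
    piRNA_cluster = coverage_fraction(tiles, cluster_bed),
    gypsy_antisense = coverage_fraction(tiles, gy_as),
    gypsy_sense = coverage_fraction(tiles, gy_s),
    mRNA_exon = coverage_fraction(tiles, exon_bed))
  classes <- c(colnames(fr), "other")
  eligible <- fr >= min_cover
  pick <- apply(eligible, 1L, function(e)
    if (any(e)) which(e)[1L] else length(classes))
  tiles$class <- factor(classes[pick], levels = classes)
  tiles
}

#' Composition of the somatic piRNA pool
#'
#' Sums normalised counts of somatic tiles per annotation class and
#' reports the cluster plus gypsy-antisense share of somatic piRNAs and
#' the somatic share of all ovarian piRNAs.
#'
#' @param tiles annotated tile data frame with a `count` column (ovary
#'   library).
#' @param somatic logical somatic flags (from
#'   [classify_somatic_tiles()]).
#' @return list with `class_mass` (named numeric), `class_share`,
#'   `cluster_gypsy_as_share` and `soma_share`.
#' @export
soma_composition <- function(tiles, somatic) {
  stopifnot(!is.null(tiles$count), !is.null(tiles$class))
  soma <- tiles[somatic, , drop = FALSE]
  mass <- tapply(soma$count, soma$class, sum, default = 0)
  mass <- stats::setNames(as.numeric(mass), names(mass))
  total_soma <- sum(mass)
  share <- if (total_soma > 0) mass / total_soma else mass * NA_real_
  list(class_mass = mass,
       class_share = share,
       cluster_gypsy_as_share =
         unname(share["piRNA_cluster"] + share["gypsy_antisense"]),
       soma_share = total_soma / sum(tiles$count))
}
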