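#' Synthetic piRNA data generator
#'
#' Generates toy genomes, annotations and piRNA pools carrying the
#' statistical structure the analyses assume: a 23-29 nt length mode, 5'
#' 1U bias, ping-pong pairs with exact 10-nt 5' overlaps at a controlled
#' fraction, head-to-tail phased trails with a downstream-U preference,
#' per-transposon strand bias, power-law abundance heterogeneity, and
#' paired ovary/embryo libraries differing by a somatic compartment. All
#' generators are deterministic given the RNG state (call `set.seed()` or
#' pass `seed` in the config).
#'
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Collects the generator parameters with validated defaults.
#'
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @param contig_lengths named contig lengths of the toy genome.
#' @param te_length length of each transposon consensus.
#' @param n_te number of transposon consensus sequences.
#' @param uni_cluster,dual_cluster named lists `list(chrom=, start=, end=)`
#'   placing the uni-strand (flamenco-like, somatic) and dual-strand
#'   (germline) clusters.
#' @param n_insertions TE fragments inserted per cluster.
#' @param read_lengths piRNA length support.
#' @param p_1u probability of a 5' U.
#' @param p_u_downstream probability of a U immediately downstream of a
#'   phased 3' end.
#' @param antisense_frac per-TE antisense read fraction.
#' @param pingpong_frac fraction of reads engaged in ping-pong pairs.
#' @param alpha Pareto tail index of the species abundance distribution.
#' @param n_germ,n_soma germline/somatic read counts of the ovary library.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       contig_lengths = c(chr1 = 200000L, chr2 = 100000L),
                       te_length = 5000L, n_te = 3L,
                       uni_cluster = list(chrom = "chr1", start = 10000L,
                                          end = 30000L),
                       dual_cluster = list(chrom = "chr1", start = 100000L,
                                           end = 140000L),
                       n_insertions = 8L,
                       read_lengths = 23:29,
                       p_1u = 0.75, p_u_downstream = 0.7,
                       antisense_frac = 0.9, pingpong_frac = 0,
                       alpha = 1.5,
                       n_germ = 40000L, n_soma = 20000L) {
  probs <- c(p_1u = p_1u, p_u_downstream = p_u_downstream,
             antisense_frac = antisense_frac, pingpong_frac = pingpong_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (alpha <= 1) stop("alpha must exceed 1 for a finite-mean abundance law")
  cfg <- list(seed = seed, contig_lengths = contig_lengths,
              te_length = te_length, n_te = n_te,
              uni_cluster = uni_cluster, dual_cluster = dual_cluster,
              n_insertions = n_insertions, read_lengths = read_lengths,
              p_1u = p_1u, p_u_downstream = p_u_downstream,
              antisense_frac = antisense_frac,
              pingpong_frac = pingpong_frac, alpha = alpha,
              n_germ = n_germ, n_soma = n_soma)
  class(cfg) <- "sim_config"
  cfg
}

insert_fragment <- function(contig, at0, frag) {
  paste0(substr(contig, 1L, at0),
         frag,
         substr(contig, at0 + nchar(frag) + 1L, nchar(contig)))
}

#' Generate a toy genome with clusters and annotations
#'
#' Random-sequence contigs with embedded transposon fragments: the
#' uni-strand cluster carries all insertions antisense (flamenco-like),
#' the dual-strand cluster carries mixed orientations. Also emits
#' cluster/gypsy/exon/tRNA interval tables consistent with the
#' coordinates.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character), `te_consensus` (named
#'   character) and interval data frames `clusters`, `gypsy`, `exons`,
#'   `trna` (0-based half-open; `gypsy` and `clusters` carry `strand`).
#' @export
make_genome <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- vapply(config$contig_lengths,
                   function(L) random_dna(1L, L), character(1))
  te <- stats::setNames(
    as.character(vapply(seq_len(config$n_te),
                        function(i) random_dna(1L, config$te_length),
                        character(1))),
    paste0("TE", seq_len(config$n_te)))
  place_insertions <- function(cl, strands) {
    width <- cl$end - cl$start
    frag_len <- min(1000L, width %/% (2L * config$n_insertions) * 2L)
    if (cl$end > nchar(genome[[cl$chrom]])) {
      stop("cluster exceeds contig length")
    }
    starts <- cl$start +
      sort(sample.int(width - frag_len, config$n_insertions))
    rows <- lapply(seq_along(starts), function(i) {
      te_i <- sample(names(te), 1L)
      off <- sample.int(config$te_length - frag_len, 1L)
      frag <- substr(te[[te_i]], off, off + frag_len - 1L)
      strand <- strands[(i - 1L) %% length(strands) + 1L]
      if (strand == "-") frag <- revcomp(frag)
      genome[[cl$chrom]] <<- insert_fragment(genome[[cl$chrom]],
                                             starts[i], frag)
      data.frame(chrom = cl$chrom, start = starts[i],
                 end = starts[i] + frag_len, name = te_i,
                 strand = strand, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  gypsy <- rbind(
    if (config$n_insertions > 0L)
      place_insertions(config$uni_cluster, "-"),
    if (config$n_insertions > 0L)
      place_insertions(config$dual_cluster, c("+", "-")))
  if (is.null(gypsy)) {
    gypsy <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        strand = character(0), stringsAsFactors = FALSE)
  }
  clusters <- data.frame(
    chrom = c(config$uni_cluster$chrom, config$dual_cluster$chrom),
    start = c(config$uni_cluster$start, config$dual_cluster$start),
    end = c(config$uni_cluster$end, config$dual_cluster$end),
    name = c("uni_cluster", "dual_cluster"),
    strand = c("-", "."), stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "chr2",
                      start = c(10000L, 40000L),
                      end = c(12000L, 43000L),
                      name = c("gene1", "gene2"),
                      strand = "+", stringsAsFactors = FALSE)
  trna <- data.frame(chrom = "chr2", start = 80000L, end = 80072L,
                     name = "tRNA1", strand = "+",
                     stringsAsFactors = FALSE)
  list(genome = genome, te_consensus = te, clusters = clusters,
       gypsy = gypsy, exons = exons, trna = trna)
}

# Pareto-tail species abundances scaled to a fixed total
power_law_counts <- function(n_species, total, alpha = 1.5) {
  raw <- stats::runif(n_species)^(-1 / alpha)
  counts <- pmax(1, round(raw * total / sum(raw)))
  counts * (total / sum(counts))
}

#' Random piRNA-like read pool
#'
#' Distinct random reads with power-law abundances and a 5' 1U bias; the
#' base material for the in-trans null and calibration simulations.
#'
#' @param n_species number of distinct read species.
#' @param total total read count (multiplicities sum to this).
#' @param lengths read length support (uniform).
#' @param alpha Pareto tail index of the abundance law; `NULL` gives every
#'   species the same multiplicity (`total / n_species`), the "pool of
#'   distinct reads" used for null simulations.
#' @param p_1u probability that a read starts with U (T).
#' @return read table (`seq`, `count`).
#' @export
sim_pirna_pool <- function(n_species, total = 1e6, lengths = 23:29,
                           alpha = 1.5, p_1u = 0.75) {
  lens <- sample(lengths, n_species, replace = TRUE)
  seqs <- random_dna(n_species, lens)
  # P(first base is U) is exactly p_1u: non-U reads start with A/C/G
  first <- ifelse(stats::runif(n_species) < p_1u, "T",
                  sample(c("A", "C", "G"), n_species, replace = TRUE))
  seqs <- paste0(first, substr(seqs, 2L, max(lengths)))
  counts <- if (is.null(alpha)) rep(total / n_species, n_species)
            else power_law_counts(n_species, total, alpha)
  collapse_reads(seqs, counts)
}

#' Simulate a transposon read pool with controlled strand bias
#'
#' Reads at uniform random positions on a single reference with strands
#' drawn independently at the configured antisense fraction.
#'
#' @param te_length reference length.
#' @param n_reads number of reads (count 1 each).
#' @param antisense_frac probability of the antisense strand.
#' @param lengths read length support.
#' @param ref reference name.
#' @return alignment data frame.
#' @export
sim_strand_pool <- function(te_length, n_reads, antisense_frac = 0.99,
                            lengths = 23:29, ref = "TE") {
  len <- sample(lengths, n_reads, replace = TRUE)
  start <- floor(stats::runif(n_reads) * (te_length - len + 1L))
  strand <- ifelse(stats::runif(n_reads) < antisense_frac, "-", "+")
  data.frame(read_id = seq_len(n_reads), count = 1, ref = ref,
             start = start, end = start + len, strand = strand,
             n_hits = 1L, weight = 1, stringsAsFactors = FALSE)
}

#' Simulate ping-pong pairs on a transposon
#'
#' Each pair is a sense read and an antisense read whose 5' ends overlap
#' by exactly 10 nt (antisense 5' end 9 nt downstream of the sense 5'
#' end). Optional background reads are placed uniformly on both strands.
#'
#' @param te_length reference length.
#' @param n_pairs number of engineered pairs.
#' @param n_background uniform random background reads.
#' @param lengths read length support.
#' @param ref reference name.
#' @return alignment data frame.
#' @export
sim_pingpong_te <- function(te_length, n_pairs, n_background = 0,
                            lengths = 23:29, ref = "TE") {
  lmax <- max(lengths)
  p <- sample.int(te_length - 2L * lmax, n_pairs, replace = TRUE) + lmax
  sl <- sample(lengths, n_pairs, replace = TRUE)
  al <- sample(lengths, n_pairs, replace = TRUE)
  sense <- data.frame(read_id = seq_len(n_pairs), count = 1, ref = ref,
                      start = p, end = p + sl, strand = "+",
                      n_hits = 1L, weight = 1, stringsAsFactors = FALSE)
  # antisense 5' end at p + 9 (0-based): alignment [p + 10 - al, p + 10)
  anti <- data.frame(read_id = n_pairs + seq_len(n_pairs), count = 1,
                     ref = ref, start = p + 10L - al, end = p + 10L,
                     strand = "-", n_hits = 1L, weight = 1,
                     stringsAsFactors = FALSE)
  out <- rbind(sense, anti)
  if (n_background > 0) {
    bg <- sim_strand_pool(te_length, n_background, antisense_frac = 0.5,
                          lengths = lengths, ref = ref)
    bg$read_id <- bg$read_id + 2L * n_pairs
    out <- rbind(out, bg)
  }
  out
}

#' Simulate phased (head-to-tail) antisense piRNA trails
#'
#' Builds a random reference and walks trails of adjacent antisense reads
#' (each read's 3' end one nucleotide before the next read's 5' end in
#' transcript orientation). The reference base immediately downstream of
#' every 3' end is set to give a U in the precursor with probability
#' `p_u_downstream`; trail-initial 5' bases are set to U with probability
#' `p_1u`.
#'
#' @param n_reads total reads to emit.
#' @param trail_len reads per trail.
#' @param lengths read length support.
#' @param p_u_downstream probability of U at the +1 downstream position.
#' @param p_1u probability of a 5' U on trail-initial reads.
#' @param n_background uniform random background reads (both strands) to
#'   add on top of the trails.
#' @param ref reference name.
#' @return list with `ref_seq` (character) and `alignments`.
#' @export
sim_phased_te <- function(n_reads, trail_len = 10L, lengths = 23:29,
                          p_u_downstream = 0.7, p_1u = 0.75,
                          n_background = 0, ref = "TE") {
  n_trails <- as.integer(ceiling(n_reads / trail_len))
  span <- trail_len * max(lengths) + 10L
  ref_len <- n_trails * span + 20L
  bases <- sample(c("A", "C", "G", "T"), ref_len, replace = TRUE)
  len <- matrix(sample(lengths, n_trails * trail_len, replace = TRUE),
                nrow = trail_len)
  csum <- apply(len, 2L, cumsum)
  trail_end <- span * seq_len(n_trails)   # 0-based exclusive end per trail
  ends <- sweep(rbind(0L, csum[-trail_len, , drop = FALSE]), 2L,
                trail_end, function(o, e) e - o)
  starts <- sweep(csum, 2L, trail_end, function(o, e) e - o)
  keep <- seq_len(n_reads)   # column-major: trail by trail
  starts <- as.integer(starts)[keep]
  ends <- as.integer(ends)[keep]
  # antisense precursor: a U at reference position p reads as base 'A';
  # the base just downstream of each 3' end (0-based start - 1) is the
  # cleavage position, the trail-initial base is the first 5' nucleotide
  cleave_u <- stats::runif(n_reads) < p_u_downstream
  bases[starts[cleave_u]] <- "A"
  bases[starts[!cleave_u]] <- sample(c("C", "G", "T"), sum(!cleave_u),
                                     replace = TRUE)
  first_ends <- ends[seq(1L, n_reads, by = trail_len)]
  init_u <- stats::runif(length(first_ends)) < p_1u
  bases[first_ends[init_u]] <- "A"
  bases[first_ends[!init_u]] <- sample(c("C", "G", "T"), sum(!init_u),
                                       replace = TRUE)
  aln <- data.frame(read_id = keep, count = 1, ref = ref,
                    start = starts, end = ends, strand = "-",
                    n_hits = 1L, weight = 1, stringsAsFactors = FALSE)
  if (n_background > 0) {
    bg <- sim_strand_pool(ref_len, n_background, antisense_frac = 0.5,
                          lengths = lengths, ref = ref)
    bg$read_id <- bg$read_id + n_reads
    aln <- rbind(aln, bg)
  }
  list(ref_seq = paste(bases, collapse = ""), alignments = aln)
}

#' Simulate a matched ovary/embryo library pair
#'
#' Draws germline reads from the dual-strand cluster (both strands) and
#' background genic regions, and somatic reads from the uni-strand cluster
#' (antisense only). The ovary library is the union of both compartments;
#' the embryo library is an independent draw from the germline compartment
#' alone. Truth labels record each read's compartment.
#'
#' @param config a [sim_config()].
#' @param genome output of [make_genome()].
#' @return list with alignment data frames `ovary` and `embryo`, each with
#'   a `compartment` column, and `somatic_region` (the uni-strand cluster
#'   interval).
#' @export
sim_library_pair <- function(config, genome) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  draw <- function(n, region, strands, compartment) {
    if (n == 0L) {
      return(data.frame(read_id = integer(0), count = numeric(0),
                        ref = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        n_hits = integer(0), weight = numeric(0),
                        compartment = character(0),
                        stringsAsFactors = FALSE))
    }
    len <- sample(config$read_lengths, n, replace = TRUE)
    start <- region$start +
      sample.int(region$end - region$start - max(len), n, replace = TRUE)
    strand <- sample(strands, n, replace = TRUE)
    data.frame(read_id = seq_len(n), count = 1, ref = region$chrom,
               start = start, end = start + len, strand = strand,
               n_hits = 1L, weight = 1, compartment = compartment,
               stringsAsFactors = FALSE)
  }
  germ <- function(n) {
    n_exon <- round(0.1 * n)
    rbind(draw(n - n_exon, config$dual_cluster, c("+", "-"), "germline"),
          draw(n_exon, list(chrom = "chr2", start = 10000L, end = 43000L),
               "+", "germline"))
  }
  soma <- draw(config$n_soma, config$uni_cluster, "-", "somatic")
  ovary <- rbind(germ(config$n_germ), soma)
  ovary$read_id <- seq_len(nrow(ovary))
  embryo <- germ(config$n_germ)
  embryo$read_id <- seq_len(nrow(embryo))
  list(ovary = ovary, embryo = embryo,
       somatic_region = config$uni_cluster)
}
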