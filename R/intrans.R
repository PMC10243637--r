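#' In-trans ping-pong 9mer statistic
#'
#' Slicing by a piRNA-guided RISC requires complementarity between the
#' guide's g2-g10 positions and the target; a slicing event places the 5'
#' end of the responder piRNA so that its first nine bases (g1-g9) are the
#' reverse complement of the guide's g2-g10. Genome-wide, slicing-triggered
#' biogenesis therefore shows up as an excess of piRNAs whose g1g9 9mer
#' equals the reverse-complemented g2-g10 (g2g10_revComp) of other piRNAs.
#' The statistic is the sum over all 9mers of the product of the scaled
#' g1g9 and g2g10_revComp frequencies; the same sum against the last nine
#' read bases (last9), which carry no slicing information, serves as the
#' genomic-composition background.
#'
#' @name intrans
NULL

#' Extract the three category 9mers from piRNA reads
#'
#' @param seqs character vector of piRNA sequences (>= 23 nt, A/C/G/T;
#'   reads containing N are skipped and counted).
#' @param counts optional multiplicities carried through.
#' @return data frame with columns `seq`, `count`, `g1g9`, `last9`,
#'   `g2g10_revComp`; attribute `n_skipped` counts dropped reads.
#' @export
extract_ninemers <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(seqs))
  has_n <- grepl("N", seqs, fixed = TRUE)
  short <- nchar(seqs) < 23L
  keep <- !has_n & !short
  s <- seqs[keep]
  n <- nchar(s)
  out <- data.frame(
    seq = s, count = counts[keep],
    g1g9 = substr(s, 1L, 9L),
    last9 = substr(s, n - 8L, n),
    g2g10_revComp = revcomp(substr(s, 2L, 10L)),
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Scaled 9mer frequency profile
#'
#' Counts each read's category 9mer weighted by multiplicity, normalises to
#' one million genome mappers, and rescales the profile to sum to 1000
#' (so the frequency of a 9mer is 1000 times its share of reads; the
#' intermediate CPM is kept as an attribute for inspection).
#'
#' @param ninemers character vector of 9mers (one per read).
#' @param counts read multiplicities.
#' @param category label (`"g1g9"`, `"last9"` or `"g2g10_revComp"`).
#' @param genome_mappers denominator for the intermediate CPM (defaults to
#'   the summed counts, i.e. the pool itself is the genome-mapper set).
#' @return object of class `ninemer_profile`: named numeric vector of
#'   scaled frequencies summing to 1000.
#' @export
ninemer_profile <- function(ninemers, counts, category = "g1g9",
                            genome_mappers = sum(counts)) {
  if (length(ninemers) == 0L || sum(counts) <= 0) {
    stop("cannot build a 9mer profile from an empty pool")
  }
  stopifnot(all(nchar(ninemers) == 9L))
  agg <- rowsum(counts, ninemers)
  freq <- 1000 * agg[, 1L] / sum(agg)
  structure(stats::setNames(freq, rownames(agg)),
            category = category,
            cpm = stats::setNames(1e6 * agg[, 1L] / genome_mappers,
                                  rownames(agg)),
            n_reads = sum(counts),
            class = "ninemer_profile")
}

#' Sum-product linkage between two 9mer profiles
#'
#' Sum over 9mers of the product of the two scaled frequencies; non-shared
#' 9mers contribute zero.
#'
#' @param a,b `ninemer_profile` objects (each scaled to sum 1000).
#' @return non-negative numeric.
#' @export
intrans_linkage <- function(a, b) {
  idx <- match(names(a), names(b))
  hit <- !is.na(idx)
  if (!any(hit)) return(0)
  sum(as.numeric(a)[hit] * as.numeric(b)[idx[hit]])
}

#' Estimate the percentage of in-trans ping-pong pairs
#'
#' Foreground is the linkage between the g1g9 and g2g10_revComp profiles;
#' background is the linkage between last9 and g2g10_revComp. By the
#' spike-in calibration, one linkage unit of the background-subtracted
#' value corresponds to about 1% of reads engaged in pairs. In
#' cross-library mode (`query` given), the g2g10_revComp profile is taken
#' from the query pool (e.g. an IP library) and the g1g9/last9 profiles
#' from `reads` (e.g. the total ovarian pool).
#'
#' @param reads read table of genome-mapping piRNAs (>= 23 nt).
#' @param query optional second read table supplying the g2g10_revComp
#'   profile.
#' @param genome_mappers denominator for the intermediate CPM.
#' @return object of class `intrans_result`: list with `foreground`,
#'   `background`, `estimate` (percent; may be slightly negative on null
#'   pools, reported as-is), `n_reads`.
#' @export
intrans_estimate <- function(reads, query = NULL,
                             genome_mappers = sum(reads$count)) {
  nm <- extract_ninemers(reads$seq, reads$count)
  qq <- if (is.null(query)) nm else extract_ninemers(query$seq, query$count)
  g1g9 <- ninemer_profile(nm$g1g9, nm$count, "g1g9", genome_mappers)
  last9 <- ninemer_profile(nm$last9, nm$count, "last9", genome_mappers)
  g2 <- ninemer_profile(qq$g2g10_revComp, qq$count, "g2g10_revComp",
                        if (is.null(query)) genome_mappers
                        else sum(qq$count))
  fg <- intrans_linkage(g1g9, g2)
  bg <- intrans_linkage(last9, g2)
  structure(list(foreground = fg, background = bg, estimate = fg - bg,
                 n_reads = sum(nm$count)),
            class = "intrans_result")
}

#' @export
print.intrans_result <- function(x, ...) {
  cat(sprintf(
    "in-trans ping-pong: foreground %.3f, background %.3f, estimate %.2f%%\n",
    x$foreground, x$background, x$estimate))
  invisible(x)
}

#' Inject artificial ping-pong pairs into a read pool
#'
#' Adds pair species (two reads whose 5' ends overlap by exactly 10
#' complementary nucleotides, so each read's g1g9 equals the reverse
#' complement of the other's g2-g10) until pair reads make up the target
#' percentage of the final pool, with each pair member at `pair_cpm`
#' counts per million of the final pool. With the defaults this adds
#' `50 * percent` species regardless of the base pool size. Injected
#' 9mers are drawn so that they collide with no 9mer already in the pool
#' and with none of the other injected species.
#'
#' @param pool base read table.
#' @param percent target percentage of pair reads in the final pool.
#' @param pair_cpm per-member abundance in CPM of the final pool.
#' @param lengths read lengths to draw from.
#' @return read table with attribute `achieved_percent`.
#' @export
inject_pairs <- function(pool, percent, pair_cpm = 100, lengths = 23:29) {
  if (percent <= 0) {
    attr(pool, "achieved_percent") <- 0
    return(pool)
  }
  if (percent >= 100) stop("percent must be below 100")
  base_total <- sum(pool$count)
  final_total <- base_total / (1 - percent / 100)
  per_read <- pair_cpm * 1e-6 * final_total
  n_species <- round(percent / 100 * final_total / (2 * per_read))
  n <- nchar(pool$seq)
  used <- unique(c(substr(pool$seq, 1L, 9L),
                   revcomp(substr(pool$seq, 2L, 10L)),
                   substr(pool$seq, n - 8L, n)))
  seqs_a <- character(0)
  seqs_b <- character(0)
  while (length(seqs_a) < n_species) {
    m <- max(16L, 2L * (n_species - length(seqs_a)))
    a <- random_dna(m, sample(lengths, m, replace = TRUE))
    b <- paste0(revcomp(substr(a, 1L, 10L)),
                random_dna(m, sample(lengths, m, replace = TRUE) - 10L))
    # a's g1g9 equals revcomp of b's g2-g10 and vice versa (the pairing
    # property), so the novelty check runs on the two matching keys plus
    # the last9s, none of which may collide with anything already present
    na_ <- nchar(a); nb_ <- nchar(b)
    keys <- c(substr(a, 1L, 9L), substr(b, 1L, 9L),
              substr(a, na_ - 8L, na_), substr(b, nb_ - 8L, nb_))
    bad_key <- keys %in% used |
      duplicated(keys) | duplicated(keys, fromLast = TRUE)
    ok <- !apply(matrix(bad_key, nrow = m), 1L, any)
    take <- utils::head(which(ok), n_species - length(seqs_a))
    seqs_a <- c(seqs_a, a[take])
    seqs_b <- c(seqs_b, b[take])
    used <- c(used, matrix(keys, nrow = m)[take, , drop = FALSE])
  }
  out <- rbind(pool, read_table(c(seqs_a, seqs_b),
                                rep(per_read, 2L * n_species)))
  attr(out, "achieved_percent") <-
    100 * 2 * n_species * per_read / sum(out$count)
  out
}

#' Spike-in calibration of the in-trans statistic
#'
#' Repeats the estimator on random piRNA-like pools into which a known
#' percentage of artificial ping-pong pairs (members at `pair_cpm`) has
#' been injected, and fits the least-squares slope of the
#' background-subtracted linkage versus the injected percentage. The
#' closed form expects one injected pair species to contribute
#' `2 * (pair_cpm / 1000)^2` linkage units, hence a slope of 1 at the
#' default 100 CPM.
#'
#' @param percents injected pair percentages.
#' @param pair_cpm per-member abundance of injected pairs.
#' @param replicates independent base pools per level.
#' @param n_species distinct species in each base pool.
#' @param total total read count of each base pool.
#' @param lengths read lengths.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `slope`, `intercept` and `table` (data frame of
#'   `percent`, `achieved_percent`, `replicate`, `linkage`).
#' @export
calibrate_intrans <- function(percents = c(0, 1, 3, 5, 10), pair_cpm = 100,
                              replicates = 5, n_species = 1e5, total = 1e6,
                              lengths = 23:29, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in seq_len(replicates)) {
    base <- sim_pirna_pool(n_species, total = total, lengths = lengths)
    for (p in percents) {
      pool <- inject_pairs(base, p, pair_cpm = pair_cpm, lengths = lengths)
      est <- intrans_estimate(pool)
      rows[[length(rows) + 1L]] <- data.frame(
        percent = p, achieved_percent = attr(pool, "achieved_percent"),
        replicate = r, linkage = est$estimate)
    }
  }
  tab <- do.call(rbind, rows)
  fit <- stats::lm(linkage ~ percent, data = tab)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       table = tab)
}
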