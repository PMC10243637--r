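test_that("adapter and UMI trimming recovers the cloned insert", {
  insert <- "ACGTACGTACGTACGTACGTACG"
  raw <- paste0("TTTT", insert, "TTTT", default_adapter3())
  expect_identical(trim_small_rna(raw), insert)

  # no adapter match
  expect_true(is.na(trim_small_rna(strrep("ACGT", 10))))

  # remainder shorter than both UMIs
  short <- paste0("ACGTAC", default_adapter3())
  expect_true(is.na(trim_small_rna(short)))

  # U converted to T, lowercase accepted
  raw_u <- chartr("T", "U", tolower(raw))
  expect_identical(trim_small_rna(raw_u), insert)

  # non-nucleotide characters rejected with a warning
  expect_warning(out <- trim_small_rna(c(raw, "ACXT")), "non-nucleotide")
  expect_identical(out, c(insert, NA))
})

test_that("size selection window is inclusive and spikes are removed", {
  reads <- make_reads(c(random_dna(1, 17), random_dna(1, 18),
                        random_dna(1, 40), random_dna(1, 41),
                        spike_sequences()[["spike19"]]),
                      counts = c(1, 2, 3, 4, 5))
  kept <- filter_by_size(reads)
  expect_identical(kept$count, c(2, 3))
  # idempotence: filtering a filtered set changes nothing
  expect_identical(filter_by_size(kept), kept)
})

test_that("infrastructural filtering removes matches and counts miRNAs", {
  mirna <- "TGAGGTAGTAGGTTGTATAGTT"
  rrna <- "GCGGGTGCTAACGGACTAGCCCTGAAAATGGATGGCGCT"
  reads <- make_reads(
    c(mirna,                              # exact miRNA hit
      mutate_seq(rrna, c(3, 7)),          # 2 mismatches from rRNA: kept
      random_dna(1, 25)),
    counts = c(5, 2, 1))
  res <- filter_infrastructural(reads,
                                list(miRNA = mirna, rRNA = rrna),
                                max_mismatch = 1)
  expect_equal(res$mirna_count, 5)
  expect_equal(nrow(res$reads), 2)
  expect_equal(sum(res$reads$count), 3)

  # reverse-orientation hit is also removed
  res2 <- filter_infrastructural(make_reads(revcomp(mirna)),
                                 list(miRNA = mirna))
  expect_equal(nrow(res2$reads), 0)

  # empty annotation set passes through with a warning
  expect_warning(res3 <- filter_infrastructural(reads, list()), "empty")
  expect_equal(nrow(res3$reads), 3)
})

test_that("brute-force mapper reports hits, strata and weights", {
  set.seed(11)
  r <- random_dna(1, 24)
  filler <- function(n) random_dna(1, n)
  # one perfect copy and three 2-mismatch copies
  ref1 <- paste0(filler(50), r, filler(50), mutate_seq(r, c(3, 10)),
                 filler(50), mutate_seq(r, c(5, 17)), filler(50),
                 mutate_seq(r, c(2, 20)), filler(50))
  aln_all <- map_reads(make_reads(r), c(ref1 = ref1), max_mismatch = 3,
                       mode = "all")
  aln_best <- map_reads(make_reads(r), c(ref1 = ref1), max_mismatch = 3,
                        mode = "best_strata")
  expect_gte(nrow(aln_all), 4)
  expect_equal(nrow(aln_best), 1)
  expect_equal(aln_best$mismatches, 0)
  expect_equal(aln_best$start, 50)
  expect_equal(aln_best$end - aln_best$start, 24)
  # best_strata output is a subset of all-mode output
  key <- function(a) paste(a$ref, a$start, a$strand)
  expect_true(all(key(aln_best) %in% key(aln_all)))

  # four perfect copies share the weight equally
  ref2 <- paste0(filler(30), r, filler(30), r, filler(30), r,
                 filler(30), r, filler(30))
  aln4 <- map_reads(make_reads(r), c(ref2 = ref2), max_mismatch = 0)
  expect_equal(nrow(aln4), 4)
  expect_equal(aln4$weight, rep(0.25, 4))
  expect_equal(sum(aln4$weight), 1)

  # minus-strand hit
  ref3 <- paste0(filler(40), revcomp(r), filler(40))
  aln_m <- map_reads(make_reads(r), c(ref3 = ref3), max_mismatch = 0)
  expect_equal(aln_m$strand, "-")
  expect_equal(aln_m$start, 40)

  # weighted conservation across a mixed read set
  reads <- make_reads(c(r, random_dna(1, 24)))
  aln <- map_reads(reads, c(ref2 = ref2), max_mismatch = 0)
  mapped <- length(unique(aln$read_id))
  expect_equal(sum(aln$weight), mapped)
})

test_that("mapper rejects bad references and skips N-containing reads", {
  expect_error(map_reads(make_reads("ACGTACGTACGTACGTACGTACGT"),
                         c(bad = "ACGTXZ")), "non-nucleotide")
  aln <- map_reads(make_reads("ACGTNACGTACGTACGTACGTACG"),
                   c(ref = random_dna(1, 200)))
  expect_equal(nrow(aln), 0)
})

test_that("tRNA-flank removal drops whole reads by any offending instance", {
  trna <- data.frame(chrom = "chr1", start = 1000L, end = 1072L)
  aln <- data.frame(
    read_id = c(1L, 2L, 3L, 3L),
    count = 1, ref = "chr1",
    start = c(1010L, 1172L, 1050L, 5000L),
    end = c(1035L, 1197L, 1075L, 5025L),
    strand = "+", n_hits = c(1L, 1L, 2L, 2L), weight = c(1, 1, .5, .5),
    stringsAsFactors = FALSE)
  out <- remove_trna_flanks(aln, trna, flank = 100L)
  # read 1 inside the flank: gone; read 3 has one inside instance: all gone
  expect_identical(unique(out$read_id), 2L)
  # read 2 starts exactly at the first base beyond the 100 nt flank
  expect_equal(nrow(out), 1)
})

test_that("FASTQ input applies the mean-quality pass filter", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@good", strrep("ACGT", 6), "+", strrep("I", 24),
               "@bad", strrep("TGCA", 6), "+", strrep("#", 24)), fq)
  reads <- read_fastq_reads(fq, min_mean_phred = 20)
  expect_identical(reads, strrep("ACGT", 6))
  expect_length(read_fastq_reads(fq, min_mean_phred = 0), 2)
})

test_that("collapsed FASTA and BED alignment round trips preserve content", {
  reads <- make_reads(c("ACGTACGTACGTACGTACGTACGT",
                        "TTTGGGCCCAAATTTGGGCCCAAT"), counts = c(7, 2))
  fa <- tempfile(fileext = ".fa")
  write_collapsed_fasta(reads, fa)
  back <- read_collapsed_fasta(fa)
  expect_equal(back[order(back$seq), ], reads[order(reads$seq), ],
               ignore_attr = TRUE)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t125\tr1_5\t1\t+",
               "chr1\t300\t325\tr2_3\t2\t-",
               "chr2\t40\t65\tr2_3\t2\t+"), bed)
  aln <- read_bed_alignments(bed)
  expect_equal(nrow(aln), 3)
  expect_equal(aln$weight, c(1, 0.5, 0.5))
  expect_equal(aln$count, c(5, 3, 3))
  expect_equal(library_stats(aln)$total_mappers, 8)
  expect_equal(library_stats(aln)$unique_mappers, 5)
})
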