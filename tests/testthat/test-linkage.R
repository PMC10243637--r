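pair_profile <- function() {
  aln <- data.frame(
    read_id = 1:2, count = 1, ref = "TE",
    start = c(100L, 85L), end = c(125L, 110L),
    strand = c("+", "-"), n_hits = 1L, weight = 1,
    stringsAsFactors = FALSE)
  # sense 5' at 100, antisense 5' at 109: a perfect 10-nt overlap
  end_profile(aln, "TE", 300L, 1e6)
}

test_that("a perfect ping-pong pair concentrates frequency at overlap 10", {
  pp <- pingpong_spectrum(pair_profile())
  f <- pp$spectrum
  expect_equal(f$frequency[f$offset == 10], 1)
  expect_equal(sum(f$frequency[f$offset != 10]), 0)
  # all background values equal: flagged zero-variance window
  expect_true(pp$zero_variance)
  expect_equal(pp$z, 0)
})

test_that("window z-score matches the hand-computed example", {
  f <- c(20, rep(1, 19))
  # inclusive reading of the window formula
  expect_equal(linkage_zscore(f, 1, exclude_link = FALSE),
               (20 - 1.95) / sqrt(mean((f - 1.95)^2)))
  expect_equal(round(linkage_zscore(f, 1, exclude_link = FALSE), 2), 4.36)
  # link-excluded background here is constant: z reported as 0
  expect_equal(linkage_zscore(f, 1), 0)
  # a noisy background gives an unbounded z
  f2 <- c(100, rep(c(1, 2), 10)[1:19])
  expect_gt(linkage_zscore(f2, 1), 10)
})

test_that("single-strand profiles are rejected", {
  aln <- sim_strand_pool(1000, 50, antisense_frac = 1)
  p <- end_profile(aln, "TE", 1000L, 1e6)
  expect_error(pingpong_spectrum(p), "both strands")
  expect_error(phasing_spectrum(p, strand = "sense"), "no sense reads")
})

test_that("engineered ping-pong pools give a strong +10 signal only", {
  set.seed(31)
  aln <- sim_pingpong_te(8000, n_pairs = 1000, n_background = 1000)
  p <- end_profile(aln, "TE", 8000L, 1e6)
  pp <- pingpong_spectrum(p)
  expect_gt(pp$z, 10)
  f <- pp$spectrum
  expect_equal(f$offset[which.max(f$frequency)], 10)
  # phasing statistic on the same pool stays at background level
  expect_lt(phasing_spectrum(p)$z, 3)
})

test_that("phased trails give a strong +1 signal in transcript orientation", {
  set.seed(32)
  sim <- sim_phased_te(5000, trail_len = 10, n_background = 2500)
  p <- end_profile(sim$alignments, "TE", nchar(sim$ref_seq), 1e6)
  ph <- phasing_spectrum(p)
  expect_gt(ph$z, 10)
  f <- ph$spectrum
  expect_equal(f$offset[which.max(f$frequency)], 1)
  expect_lt(pingpong_spectrum(p)$z, 3)
})

test_that("a head-to-tail pair places phasing mass at +1", {
  # antisense reads: [26, 51) then [0, 26): 3' end of the first at 26,
  # 5' end of the next at 25, i.e. +1 in transcript orientation
  aln <- data.frame(read_id = 1:2, count = 1, ref = "TE",
                    start = c(26L, 0L), end = c(51L, 26L), strand = "-",
                    n_hits = 1L, weight = 1, stringsAsFactors = FALSE)
  p <- end_profile(aln, "TE", 60L, 1e6)
  f <- phasing_spectrum(p)$spectrum
  expect_equal(f$frequency[f$offset == 1], 1)
  expect_equal(sum(f$frequency[f$offset != 1]), 0)
})

test_that("null pools keep both z-scores within +/-3 across 20 seeds", {
  for (s in 1:20) {
    set.seed(s)
    aln <- sim_strand_pool(5000, 4000, antisense_frac = 0.5)
    p <- end_profile(aln, "TE", 5000L, 1e6)
    expect_lt(abs(pingpong_spectrum(p)$z), 3)
    expect_lt(abs(phasing_spectrum(p)$z), 3)
  }
})

test_that("linkage frequency is bilinear and z is scale-invariant", {
  set.seed(33)
  aln <- sim_pingpong_te(3000, n_pairs = 200, n_background = 200)
  p1 <- end_profile(aln, "TE", 3000L, 1e6)
  aln2 <- aln; aln2$count <- 2
  p2 <- end_profile(aln2, "TE", 3000L, 1e6)
  f1 <- pingpong_spectrum(p1)$spectrum$frequency
  f2 <- pingpong_spectrum(p2)$spectrum$frequency
  expect_equal(f2, 4 * f1)
  expect_equal(pingpong_spectrum(p2)$z, pingpong_spectrum(p1)$z)
})

test_that("the spectrum is invariant under reference strand exchange", {
  set.seed(34)
  aln <- sim_pingpong_te(3000, n_pairs = 200, n_background = 200)
  p <- end_profile(aln, "TE", 3000L, 1e6)
  expect_equal(pingpong_spectrum(flip_profile(p))$spectrum$frequency,
               pingpong_spectrum(p)$spectrum$frequency)
})

test_that("downstream U frequencies are strand-aware and exact", {
  # sense read [0, 25) on a reference with T at position 25
  ref <- paste0(strrep("A", 25), "T", strrep("A", 24))
  aln <- data.frame(read_id = 1L, count = 1, ref = "TE", start = 0L,
                    end = 25L, strand = "+", n_hits = 1L, weight = 1,
                    stringsAsFactors = FALSE)
  u <- downstream_u_frequency(aln, ref, positions = 1:2)
  expect_equal(u$u_frequency, c(1, 0))

  # all-A reference never shows U downstream of a sense read
  u0 <- downstream_u_frequency(aln, strrep("A", 50), positions = 1:3)
  expect_equal(u0$u_frequency, rep(0, 3))

  # antisense read [10, 35): downstream +1 is reference position 9,
  # where an A reads as U on the precursor
  ref_a <- paste0(strrep("C", 9), "A", strrep("C", 40))
  aln_m <- data.frame(read_id = 1L, count = 1, ref = "TE", start = 10L,
                      end = 35L, strand = "-", n_hits = 1L, weight = 1,
                      stringsAsFactors = FALSE)
  um <- downstream_u_frequency(aln_m, ref_a, positions = 1:2)
  expect_equal(um$u_frequency, c(1, 0))

  # offsets outside the reference exclude the read rather than crash
  edge <- downstream_u_frequency(aln_m, strrep("C", 40), positions = -40:1)
  expect_true(all(is.na(edge$u_frequency) | edge$u_frequency >= 0))
})

test_that("the configured downstream-U probability is recovered", {
  set.seed(35)
  sim <- sim_phased_te(20000, p_u_downstream = 0.7)
  u <- downstream_u_frequency(sim$alignments, sim$ref_seq, positions = 1)
  tol <- 4 * sqrt(0.7 * 0.3 / 20000)
  expect_lt(abs(u$u_frequency - 0.7), tol)
})
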