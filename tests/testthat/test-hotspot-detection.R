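jt <- function(chrom, position, strand = "+",
               read_id = sprintf("j%04d", seq_along(position))) {
  n <- length(position)
  data.frame(read_id = read_id, chrom = rep_len(chrom, n),
             position = position, strand = rep_len(strand, n),
             prey_retained_side = rep_len("right", n),
             read_start = rep_len(20, n), stringsAsFactors = FALSE)
}

test_that("a dense window forms a one-window island with the Poisson score", {
  genome <- genome_model(c(chr1 = 1e7))
  # 12 junctions in window [1000, 1500); 8 singles scattered megabases apart
  j <- jt("chr1", c(1000:1011, seq(2e6, 9e6, by = 1e6)))
  cand <- call_islands(j, genome, seed = 1)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 1000)
  expect_equal(cand$end, 1500)
  expect_equal(cand$junction_count, 12)
  lambda_w <- 20 * 500 / (0.74 * 1e7)
  expect_equal(cand$island_score,
               -log(poisson_pmf_oracle(12, lambda_w)),
               tolerance = 1e-10)
})

test_that("islands split when eligible windows exceed the gap", {
  genome <- genome_model(c(chr1 = 1e7))
  # gap/window = 4: eligible windows 21 and 27 have 5 ineligible
  # windows between them and must split into two islands
  j <- jt("chr1", c(10000:10005, 13000:13005))
  cand <- call_islands(j, genome, seed = 2)
  expect_equal(nrow(cand), 2)
  # windows 21 and 26 (4 ineligible between): a single island spanning
  # the gap, trimmed to the eligible ends
  j2 <- jt("chr1", c(10000:10005, 12600:12605))
  cand2 <- call_islands(j2, genome, seed = 2)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$start, 10000)
  expect_equal(cand2$end, 13000)
  expect_equal(cand2$junction_count, 12)
})

test_that("redundancy capping keeps one junction per exact position and strand", {
  j <- jt("chr1", rep(5000, 4), strand = c("+", "+", "-", "-"))
  expect_equal(nrow(cap_redundancy(j, 1)), 2)
  expect_equal(nrow(cap_redundancy(j, 2)), 4)
})

test_that("islands are disjoint and separated by more than the gap", {
  genome <- genome_model(c(chr1 = 1e7))
  set.seed(31)
  pos <- sort(c(sample.int(1e7, 300),
                rep(seq(2e6, 8e6, by = 2e6), each = 8) +
                  sample(0:400, 32, replace = TRUE)))
  j <- jt("chr1", pos)
  cand <- call_islands(j, genome, seed = 32)
  if (nrow(cand) > 1) {
    o <- order(cand$start)
    expect_true(all(cand$start[o][-1] - cand$end[o][-nrow(cand)] > 2000))
  }
  expect_true(all(cand$end > cand$start))
  expect_true(all(cand$junction_count == cand$plus + cand$minus))
})

test_that("refinement drops bait-proximal, sparse and blacklisted candidates", {
  g <- make_toy_gene("K", c(90, 90, 90), chrom = "chr1",
                     tx_start = 7.00e6, intron_len = 2000)
  iv <- intron_interval(g, 1)
  genome <- genome_model(
    c(chr1 = 1e7), list(g),
    bait = bait_site("chr1", floor(mean(iv)), "K", 1),
    offtarget_blacklist = data.frame(chrom = "chr1", start = 3e6,
                                     end = 3.001e6))
  cand <- data.frame(
    chrom = "chr1",
    start = c(1e6, 2e6, 3e6, 6.2e6),
    end = c(1e6, 2e6, 3e6, 6.2e6) + 500,
    junction_count = c(10L, 4L, 10L, 10L),
    island_score = 50, plus = 5L, minus = 5L)
  cand$plus <- cand$junction_count - cand$minus
  # junctions: matching counts inside candidates, empty flanks
  j <- jt("chr1", unlist(mapply(function(s, n) s + seq_len(n) * 40,
                                cand$start, cand$junction_count)))
  ref <- refine_hotspots(cand, j, genome)
  # 2e6 has <5 junctions, 3e6 is blacklisted, 6.2e6 is within 2 Mb of
  # the bait; only 1e6 survives
  expect_equal(ref$start, 1e6)
  expect_true(all(ref$p_adjusted >= ref$p_local))
})

test_that("the local Poisson test matches direct pmf summation", {
  genome <- genome_model(c(chr1 = 1e7))
  # candidate [10000, 10500): 10 junctions; flanks [7500,10000) and
  # [10500,13000) hold 5 junctions
  j <- jt("chr1", c(10000 + seq(0, 450, by = 50),
                    c(8000, 8600, 9200, 11000, 12000)))
  cand <- data.frame(chrom = "chr1", start = 10000, end = 10500,
                     junction_count = 10L, island_score = 60,
                     plus = 5L, minus = 5L)
  ref <- refine_hotspots(cand, j, genome)
  expect_equal(nrow(ref), 1)
  # lambda_local = 5 * 500 / 5000 = 0.5
  expect_equal(ref$p_local, poisson_tail_oracle(10, 0.5),
               tolerance = 1e-10)
  expect_true(ref$p_adjusted <= 0.01)
  # kept even under an extreme multiplicity of 1e7 tests
  expect_true(min(1, ref$p_local * 1e7) <= 0.01)
})

test_that("flank regions exclude other candidate spans", {
  genome <- genome_model(c(chr1 = 1e7))
  # second candidate sits inside the first's right flank and holds a
  # dense clump that would otherwise inflate the local background
  j <- jt("chr1", c(10000 + seq(0, 450, by = 50),
                    11000 + 0:19,
                    c(8000, 9000, 12600)))
  cand <- data.frame(chrom = "chr1", start = c(10000, 11000),
                     end = c(10500, 11500),
                     junction_count = c(10L, 20L), island_score = 60,
                     plus = 5L, minus = 5L)
  ref <- refine_hotspots(cand, j, genome)
  first <- ref[ref$start == 10000, ]
  # usable flank = 5000 - 500 excluded = 4500 bp holding 3 junctions
  expect_equal(first$p_local,
               poisson_tail_oracle(10, 3 * 500 / 4500),
               tolerance = 1e-10)
})

test_that("hotspots in the same gene merge into one spanning interval", {
  a <- make_toy_gene("A", rep(90, 4), chrom = "chr1", tx_start = 1e6,
                     intron_len = 5000)
  b <- make_toy_gene("B", rep(90, 4), chrom = "chr1", tx_start = 2e6,
                     intron_len = 5000)
  genome <- genome_model(c(chr1 = 1e7), list(a, b))
  h <- data.frame(chrom = "chr1",
                  start = c(1.001e6, 1.008e6, 2.002e6, 5e6),
                  end = c(1.0015e6, 1.0085e6, 2.0025e6, 5.0005e6),
                  junction_count = c(6L, 8L, 5L, 7L),
                  island_score = c(10, 12, 9, 11),
                  plus = c(6L, 0L, 5L, 3L), minus = c(0L, 8L, 0L, 4L),
                  p_local = c(1e-6, 1e-8, 1e-5, 1e-4),
                  p_adjusted = c(1e-3, 1e-5, 1e-2, 1e-2),
                  gene_id = NA_character_, strand_bias = 0)
  m <- merge_by_gene(h, genome)
  expect_equal(nrow(m), 3)
  ga <- m[!is.na(m$gene_id) & m$gene_id == "A", ]
  expect_equal(ga$start, 1.001e6)
  expect_equal(ga$end, 1.0085e6)
  expect_equal(ga$junction_count, 14)
  expect_equal(ga$p_adjusted, 1e-5)
  expect_equal(ga$strand_bias, entropy_oracle(6 / 14), tolerance = 1e-12)
  expect_true(is.na(m$gene_id[m$start == 5e6]))
})

test_that("strand-bias score is entropy with the stated conventions", {
  expect_equal(strand_bias_score(0.5), 1)
  expect_equal(strand_bias_score(1), 0)
  expect_equal(strand_bias_score(0), 0)
  expect_equal(strand_bias_score(0.25), 0.811278, tolerance = 1e-6)
  expect_error(strand_bias(jt("chr1", numeric())), "empty hotspot")
  expect_equal(strand_bias(jt("chr1", 1:4, strand = c("+", "-", "+", "-"))),
               1)
})

test_that("strand-bias score is symmetric, monotone and bounded", {
  p <- seq(0, 0.5, length.out = 201)
  s <- strand_bias_score(p)
  expect_true(all(diff(s) > 0))
  expect_equal(strand_bias_score(1 - p), s)
  expect_true(all(s >= 0 & s <= 1))
})
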