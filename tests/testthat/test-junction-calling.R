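make_aln <- function(n = 1, read_id = sprintf("r%03d", seq_len(n)),
                     chrom = "chr1", strand = "+", aln_start = 1000,
                     aln_end = 1100, read_start = 20, matches = 80,
                     mismatches = 0, gap_opens = 0, max_gap_len = 0,
                     n_alignments_for_read = 1,
                     second_best_score_diff = 999,
                     primer_anchor_ok = TRUE, barcode = "LIB01") {
  data.frame(read_id = read_id, barcode = barcode,
             primer_anchor_ok = primer_anchor_ok, chrom = chrom,
             strand = strand, aln_start = aln_start, aln_end = aln_end,
             read_start = read_start, matches = matches,
             mismatches = mismatches, gap_opens = gap_opens,
             max_gap_len = max_gap_len,
             n_alignments_for_read = n_alignments_for_read,
             second_best_score_diff = second_best_score_diff,
             stringsAsFactors = FALSE)
}

test_that("alignment score penalises mismatches and gap openings", {
  expect_equal(alignment_score(make_aln(matches = 50)), 50)
  expect_equal(alignment_score(make_aln(matches = 40, mismatches = 5,
                                        gap_opens = 2)), 33)
  expect_error(alignment_score(data.frame(matches = 1)),
               "missing alignment statistics")
})

test_that("primer filter keeps only anchored reads", {
  recs <- make_aln(15, primer_anchor_ok = rep(c(TRUE, FALSE),
                                              c(10, 5)))
  expect_equal(nrow(filter_reads(recs)), 10)
  expect_identical(filter_reads(recs[recs$primer_anchor_ok, ]),
                   recs[recs$primer_anchor_ok, ])
})

test_that("alignment validity thresholds sit exactly at the stated bounds", {
  # score < 30 invalid, score 30 valid
  expect_equal(nrow(filter_alignments(make_aln(matches = 29))), 0)
  expect_equal(nrow(filter_alignments(make_aln(matches = 30))), 1)
  # multiple alignments: score difference < 4 invalid, 4 valid
  expect_equal(nrow(filter_alignments(
    make_aln(n_alignments_for_read = 2, second_best_score_diff = 3))), 0)
  expect_equal(nrow(filter_alignments(
    make_aln(n_alignments_for_read = 2, second_best_score_diff = 4))), 1)
  # gaps of 10 nt invalid, 9 valid
  expect_equal(nrow(filter_alignments(make_aln(max_gap_len = 10))), 0)
  expect_equal(nrow(filter_alignments(make_aln(max_gap_len = 9))), 1)
})

test_that("junctions sit at the 5' end of the aligned read", {
  j <- call_junction(make_aln(strand = "+", aln_start = 1000,
                              aln_end = 1100))
  expect_equal(j$position, 1000)
  expect_equal(j$prey_retained_side, "right")
  j <- call_junction(make_aln(strand = "-", aln_start = 1000,
                              aln_end = 1100))
  expect_equal(j$position, 1099)
  expect_equal(j$prey_retained_side, "left")
  # two reads covering the same fragment on the same strand agree
  two <- rbind(make_aln(read_id = "a", aln_start = 1000, aln_end = 1080),
               make_aln(read_id = "b", aln_start = 1000, aln_end = 1120))
  expect_equal(unique(call_junction(two)$position), 1000)
})

test_that("PCR-repeat collapsing follows the greedy <3 bp rule", {
  mk <- function(read_starts)
    call_junction(make_aln(length(read_starts),
                           read_start = read_starts))
  expect_equal(nrow(dedup(mk(c(5, 6)))), 1)
  expect_equal(nrow(dedup(mk(c(5, 9)))), 2)
  expect_equal(nrow(dedup(mk(c(5, 6, 8)))), 2)  # clusters {5,6},{8}
  # the cluster anchor (smallest read_start) survives
  j <- mk(c(6, 5))
  expect_equal(dedup(j)$read_id, "r002")
  # read_start ties break by read_id
  expect_equal(dedup(mk(c(5, 5)))$read_id, "r001")
})

test_that("dedup matches the quadratic clustering oracle", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(2:40, 1)
    j <- data.frame(
      read_id = sprintf("q%03d", sample(n)),
      chrom = "chr1",
      position = sample(1000:1003, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      prey_retained_side = "right",
      read_start = sample(0:12, n, replace = TRUE),
      stringsAsFactors = FALSE)
    expect_equal(sort(dedup(j)$read_id), dedup_oracle(j))
  }
})

test_that("dedup is idempotent", {
  set.seed(12)
  j <- data.frame(read_id = sprintf("q%02d", 1:30), chrom = "chr1",
                  position = sample(1:5, 30, replace = TRUE),
                  strand = "+", prey_retained_side = "right",
                  read_start = sample(0:10, 30, replace = TRUE),
                  stringsAsFactors = FALSE)
  once <- dedup(j)
  expect_identical(dedup(once), once)
})

test_that("ligation artifacts are removed at HaeIII cut positions only", {
  genome <- genome_model(c(chr1 = 1e5),
                         haeiii_sites = list(chr1 = c(500, 2000)))
  j <- call_junction(make_aln(3, aln_start = c(500, 501, 1997),
                              aln_end = c(600, 601, 2097)))
  kept <- remove_ligation_artifacts(j, genome)
  expect_equal(kept$position, c(501, 1997))
  # window relaxation catches near misses
  kept <- remove_ligation_artifacts(j, genome,
                                    filter_params(haeiii_window = 1))
  expect_equal(kept$position, 1997)
  empty <- genome_model(c(chr1 = 1e5))
  expect_equal(nrow(remove_ligation_artifacts(j, empty)), 3)
})

test_that("the cascade removes exactly the planted artifacts", {
  genome <- simulate_genome()
  params <- sim_params(n_junctions = 400, seed = 101)
  junctions <- simulate_pre_selection(genome, params)
  tab <- emit_alignment_table(junctions, genome, params, seed = 102)
  clean <- call_junctions(tab, genome)
  expect_setequal(clean$read_id, tab$read_id[tab$artifact == "none"])
  # and is a pure subset operation: re-running changes nothing
  tab2 <- tab[tab$artifact == "none", ]
  clean2 <- call_junctions(tab2, genome)
  expect_setequal(clean2$read_id, tab2$read_id)
})

test_that("alignment tables and junction BED round-trip through disk", {
  genome <- simulate_genome()
  params <- sim_params(n_junctions = 50, seed = 103)
  junctions <- simulate_pre_selection(genome, params)
  tab <- emit_alignment_table(junctions, genome, params, seed = 104)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(tab, tsv)
  expect_equal(read_alignment_tsv(tsv)$read_id, tab$read_id)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_junctions_bed(junctions, bed)
  back <- read_junctions_bed(bed)
  expect_setequal(back$read_id, junctions$read_id)
  expect_equal(back$position[match(junctions$read_id, back$read_id)],
               junctions$position)
  expect_true("prey_retained_side" %in% names(back))
})

test_that("PSL import reproduces score and ambiguity statistics", {
  psl <- withr::local_tempfile(fileext = ".psl")
  rows <- c(
    paste(c(80, 2, 0, 0, 1, 3, 0, 0, "+", "readA", 120, 10, 95,
            "chr1", 1e6, 5000, 5085, 1, 85, 10, 5000), collapse = "\t"),
    paste(c(60, 0, 0, 0, 0, 0, 0, 0, "-", "readB", 100, 5, 65,
            "chr2", 1e6, 9000, 9060, 1, 60, 5, 9000), collapse = "\t"),
    paste(c(55, 0, 0, 0, 0, 0, 0, 0, "+", "readB", 100, 5, 60,
            "chr1", 1e6, 100, 155, 1, 55, 5, 100), collapse = "\t"))
  writeLines(rows, psl)
  recs <- read_psl(psl)
  expect_equal(alignment_score(recs[recs$read_id == "readA", ]), 77)
  b <- recs[recs$read_id == "readB", ]
  expect_equal(unique(b$n_alignments_for_read), 2)
  expect_equal(unique(b$second_best_score_diff), 5)
})
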