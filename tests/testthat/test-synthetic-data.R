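test_that("empty and planted-hotspot libraries match their construction", {
  genome <- simulate_genome()
  empty <- simulate_pre_selection(genome, sim_params(n_junctions = 0,
                                                     seed = 1))
  expect_equal(nrow(empty), 0)
  ph <- data.frame(chrom = "chr1", center = 1e6, span = 500,
                   count = 50, plus_strand_fraction = 0.5)
  j <- simulate_pre_selection(genome,
                              sim_params(n_junctions = 200, seed = 2,
                                         planted_hotspots = ph))
  expect_equal(nrow(j), 250)
  in_span <- j$position >= 1e6 - 250 & j$position < 1e6 + 250 &
    j$chrom == "chr1"
  expect_gte(sum(in_span), 50)
  expect_equal(sum(j$origin == "hotspot:1"), 50)
  bad <- data.frame(chrom = "chr1", center = 100, span = 500,
                    count = 5, plus_strand_fraction = 0.5)
  expect_error(
    simulate_pre_selection(genome,
                           sim_params(planted_hotspots = bad, seed = 3)),
    "outside genome")
})

test_that("identical seeds reproduce identical libraries", {
  genome <- simulate_genome()
  p <- sim_params(n_junctions = 300, seed = 99)
  expect_identical(simulate_pre_selection(genome, p),
                   simulate_pre_selection(genome, p))
})

test_that("per-gene junction rates follow expression to the coupling power", {
  a <- make_toy_gene("A", rep(90, 3), tx_start = 1e5, expression = 10)
  b <- make_toy_gene("B", rep(90, 3), tx_start = 5e5, expression = 1)
  genome <- genome_model(c(chrT = 1e6), list(a, b))
  p <- sim_params(n_junctions = 10000, bait_proximity_fraction = 0,
                  gene_fraction = 1, transcription_coupling = 1,
                  seed = 4)
  j <- simulate_pre_selection(genome, p)
  n_a <- sum(j$origin == "gene:A")
  n_gene <- sum(j$origin %in% c("gene:A", "gene:B"))
  expect_equal(n_gene, 10000)
  p_expect <- 10 / 11
  sd3 <- 3 * sqrt(p_expect * (1 - p_expect) / n_gene)
  expect_lt(abs(n_a / n_gene - p_expect), sd3)
})

test_that("planted strand fractions and the genome-wide balance hold", {
  genome <- simulate_genome()
  ph <- data.frame(chrom = "chr1", center = c(1e6, 9e6),
                   span = 500, count = 400,
                   plus_strand_fraction = c(0.9, 0.5))
  j <- simulate_pre_selection(genome,
                              sim_params(n_junctions = 4000, seed = 5,
                                         planted_hotspots = ph))
  h1 <- j[j$origin == "hotspot:1", ]
  expect_lt(abs(mean(h1$strand == "+") - 0.9),
            3 * sqrt(0.9 * 0.1 / 400))
  rest <- j[j$origin != "hotspot:1", ]
  expect_lt(abs(mean(rest$strand == "+") - 0.5),
            3 * sqrt(0.25 / nrow(rest)))
  # retained side is tied to strand by the junction-calling convention
  expect_true(all(j$prey_retained_side ==
                    ifelse(j$strand == "+", "right", "left")))
})

test_that("selection returns a subset and is idempotent without noise", {
  genome <- simulate_genome()
  j <- simulate_pre_selection(genome, sim_params(n_junctions = 800,
                                                 seed = 6))
  sel <- selection_params(min_expression = 1)
  surv <- apply_selection(j, genome, sel = sel)
  expect_true(all(surv$read_id %in% j$read_id))
  expect_identical(apply_selection(surv, genome, sel = sel), surv)
  # survival noise thins the productive pool
  sel_n <- selection_params(min_expression = 1, survival_noise = 0.5,
                            seed = 7)
  surv_n <- apply_selection(j, genome, sel = sel_n)
  expect_lt(nrow(surv_n), nrow(surv))
  expect_true(all(surv_n$read_id %in% surv$read_id))
  # an all-intergenic library has nothing to select
  ig <- data.frame(read_id = "x", chrom = "chr1", position = 9.9e6,
                   strand = "+", prey_retained_side = "right",
                   read_start = 20, origin = "background",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(apply_selection(ig, genome, sel = sel)), 0)
})

test_that("every surviving junction is intronic and in frame", {
  genome <- simulate_genome()
  j <- simulate_pre_selection(genome, sim_params(n_junctions = 800,
                                                 seed = 8))
  sel <- selection_params(min_expression = 1)
  surv <- apply_selection(j, genome, sel = sel)
  calls <- classify_fusions(surv, genome, sel = sel)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$intronic))
  expect_true(all(calls$in_frame))
})

test_that("selection enriches intronic junctions and strand bias", {
  genome <- simulate_genome()
  j <- simulate_pre_selection(genome, sim_params(n_junctions = 2000,
                                                 seed = 9))
  sel <- selection_params(min_expression = 1)
  surv <- apply_selection(j, genome, sel = sel)
  pre_calls <- classify_fusions(j, genome, sel = sel)
  post_calls <- classify_fusions(surv, genome, sel = sel)
  expect_gt(mean(post_calls$intronic), mean(pre_calls$intronic))
  # within one partner gene, post-selection junctions are one-stranded
  in_a <- post_calls[!is.na(post_calls$partner_gene_id) &
                       post_calls$partner_gene_id == "PTNA", ]
  expect_gt(nrow(in_a), 0)
  expect_equal(strand_bias(in_a), 0)
})

test_that("alignment emission matches junctions and injects binomial artifacts", {
  genome <- simulate_genome()
  p0 <- sim_params(n_junctions = 100, seed = 10,
                   artifact_rates = list(pcr_duplicate = 0,
                                         low_score = 0, gapped = 0,
                                         multi_mapper = 0, haeiii = 0,
                                         primer_fail = 0))
  j <- simulate_pre_selection(genome, p0)
  tab <- emit_alignment_table(j, genome, p0, seed = 11)
  expect_equal(nrow(tab), 100)
  expect_true(all(tab$artifact == "none"))
  expect_true(all(alignment_score(tab) >= 30))
  # calling the clean table inverts the emission exactly
  called <- call_junction(tab)
  expect_equal(called$position[match(j$read_id, called$read_id)],
               j$position)
  # duplicate rate 0.5: extra rows are Binomial(100, 0.5)
  p5 <- sim_params(n_junctions = 100, seed = 10,
                   artifact_rates = list(pcr_duplicate = 0.5,
                                         low_score = 0.3, gapped = 0,
                                         multi_mapper = 0, haeiii = 0,
                                         primer_fail = 0))
  tab5 <- emit_alignment_table(j, genome, p5, seed = 12)
  n_dup <- sum(tab5$artifact == "pcr_duplicate")
  expect_lt(abs(n_dup - 50), 3 * sqrt(100 * 0.25))
  expect_true(all(alignment_score(
    tab5[tab5$artifact == "low_score", ]) < 30))
})

test_that("a fusion spec expands row-per-event and round-trips to CSV", {
  spec <- data.frame(kinase_gene = c("RET", "RET"),
                     partner_gene = c("CCDC6", "KIF5B"),
                     kinase_exon = c(12L, 12L),
                     partner_exon = c(1L, 15L),
                     count = c(3L, 0L))
  tab <- simulate_cosmic_table(spec, seed = 13)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$partner_gene == "CCDC6"))
  empty <- simulate_cosmic_table(spec[spec$count == 0, ], seed = 13)
  expect_equal(nrow(empty), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fusion_csv(tab, path)
  expect_equal(read_fusion_csv(path), tab)
})
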