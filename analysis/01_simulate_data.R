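#!/usr/bin/env Rscript
# Builds the study inputs: a two-chromosome toy genome carrying an
# ALK-like bait kinase and a panel of partner genes spanning the
# selection determinants, a pre-selection HTGTS junction library
# (bait-proximal clustering, transcription-coupled gene component,
# planted focal hotspots inside partner introns, no strand bias), and
# the raw alignment table with every artifact class injected.

suppressPackageStartupMessages(library(tkfusions))
dir.create("results", showWarnings = FALSE)

genome <- simulate_genome(seed = 42)
write_genome_json(genome, "results/genome.json")
export_genes_bed(genome, "results/genes.bed")

mid_intron <- function(gene, k)
  floor(mean(intron_interval(genome$genes[[gene]], k)))

# focal breakpoint clusters planted in introns of the partner panel:
# expressed in-frame partners (PTNA/PTNB/PTNE), a silent partner
# (PTNC), and an out-of-frame partner (PTND) -- only the first three
# can yield productive fusions
planted <- data.frame(
  chrom = "chr1",
  center = c(mid_intron("PTNA", 6), mid_intron("PTNB", 4),
             mid_intron("PTNE", 8), mid_intron("PTNC", 6),
             mid_intron("PTND", 5)),
  span = 400, count = 40, plus_strand_fraction = 0.5)

params <- sim_params(n_junctions = 2000, planted_hotspots = planted,
                     seed = 1)
junctions <- simulate_pre_selection(genome, params)
write_junctions_bed(junctions, "results/junctions_truth.bed")

alignments <- emit_alignment_table(junctions, genome, params, seed = 2)
write_alignment_tsv(alignments, "results/alignments.tsv")

cat("genome:", length(genome$chromosomes), "chromosomes,",
    length(genome$genes), "genes; bait in intron",
    genome$bait$bait_intron_index, "of", genome$bait$kinase_gene_id,
    "\n")
cat("pre-selection library:", nrow(junctions), "junctions (",
    sum(grepl("^hotspot:", junctions$origin)), "planted in",
    nrow(planted), "clusters )\n")
cat("alignment table:", nrow(alignments), "records;",
    sum(alignments$artifact != "none"), "injected artifacts\n")
print(table(alignments$artifact))
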