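# Independent oracles used across the suite. Each deliberately avoids
# the code path of the function it checks.

# binary entropy via natural-log Shannon entropy, rescaled to bits
entropy_oracle <- function(p) {
  h <- function(x) if (x <= 0 || x >= 1) 0 else -x * log(x)
  vapply(p, function(pi) (h(pi) + h(1 - pi)) / log(2), numeric(1))
}

# upper-tail Poisson P(X >= k) by direct pmf summation from the
# formula, accumulating the tail itself (no 1 - CDF cancellation)
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  if (lambda == 0) return(0)
  term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  acc <- 0
  i <- k
  while (term > acc * 1e-18 || i < k + 10) {
    acc <- acc + term
    i <- i + 1
    term <- term * lambda / i
    if (term == 0) break
  }
  acc
}

# Poisson pmf by formula (log scale) for island-score checks
poisson_pmf_oracle <- function(k, lambda) {
  exp(-lambda + k * log(lambda) - lgamma(k + 1))
}

# O(n^2) PCR-duplicate clustering: repeatedly pick the smallest
# remaining read_start (ties by read_id) as an anchor and remove
# everything within the window; the anchor survives its cluster
dedup_oracle <- function(junctions, window = 3) {
  key <- paste(junctions$chrom, junctions$position, junctions$strand)
  survivors <- character()
  for (grp in split(seq_len(nrow(junctions)), key)) {
    remaining <- grp
    while (length(remaining)) {
      lo <- min(junctions$read_start[remaining])
      at_lo <- remaining[junctions$read_start[remaining] == lo]
      anchor <- at_lo[order(junctions$read_id[at_lo])[1L]]
      members <- remaining[junctions$read_start[remaining] - lo < window]
      survivors <- c(survivors, junctions$read_id[anchor])
      remaining <- setdiff(remaining, members)
    }
  }
  sort(survivors)
}

# string-based reading-frame oracle: tag every base of the kinase CDS
# with its native codon phase, concatenate a partner prefix, and check
# that each retained kinase base keeps its phase in the fused frame
in_frame_oracle <- function(partner_cds, partner_intron, kinase_cds,
                            kinase_intron) {
  prefix_len <- sum(partner_cds[seq_len(partner_intron)])
  offset <- sum(kinase_cds[seq_len(kinase_intron)])
  total_k <- sum(kinase_cds)
  if (offset >= total_k) return(NA)
  native_phase <- (seq_len(total_k) - 1) %% 3
  suffix <- (offset + 1):total_k
  fused_pos <- prefix_len + seq_along(suffix)
  fused_phase <- (fused_pos - 1) %% 3
  all(fused_phase == native_phase[suffix])
}

# toy gene with prescribed per-exon CDS lengths; exons are sized to the
# CDS (plus slack for untranslated exon ends) and spaced by fixed introns
make_toy_gene <- function(gene_id, cds, strand = "+", chrom = "chrT",
                          tx_start = 1000, intron_len = 500,
                          expression = 10) {
  exon_len <- pmax(cds, 50)
  # genomic layout runs 5'->3' on the coding strand
  widths <- if (strand == "-") rev(exon_len) else exon_len
  starts <- tx_start + cumsum(c(0, head(widths + intron_len, -1)))
  ex <- cbind(start = starts, end = starts + widths)
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  gene_model(gene_id, chrom, strand, min(ex[, "start"]),
             max(ex[, "end"]), ex, cds, expression = expression)
}

# landscape fixture: 73 distinct partners over 7 kinases, of which 7
# partners recur with a second kinase
sharing_fixture <- function() {
  kinases <- sprintf("K%d", 1:7)
  spec <- rbind(
    data.frame(kinase_gene = rep(kinases, length.out = 66),
               partner_gene = sprintf("U%02d", 1:66), kinase_exon = 2L,
               partner_exon = 1L, count = 1L),
    data.frame(kinase_gene = kinases,
               partner_gene = sprintf("S%d", 1:7), kinase_exon = 2L,
               partner_exon = 1L, count = 2L),
    data.frame(kinase_gene = kinases[c(2:7, 1)],
               partner_gene = sprintf("S%d", 1:7), kinase_exon = 2L,
               partner_exon = 1L, count = 1L))
  simulate_cosmic_table(spec, seed = 61)
}
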