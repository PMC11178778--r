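#' Simulation parameters for pre-selection junction libraries
#'
#' The generator emulates the statistical structure of an HTGTS library
#' cloned before any functional selection: junctions cluster around the
#' bait DSB (within ~2 Mb), occur in genes at rates coupled to
#' transcription, show no strand bias, and are contaminated by the
#' artifact classes the filter cascade removes.
#'
#' @param n_junctions Number of background junctions (planted hotspot
#'   junctions are added on top).
#' @param bait_proximity_fraction Fraction of background junctions
#'   drawn from the bait-proximal component.
#' @param bait_proximity_span Half-width (bp) of the bait-proximal
#'   component (symmetric triangular decay).
#' @param transcription_coupling Exponent coupling per-gene junction
#'   rate to expression (`rate ~ expression^coupling`).
#' @param gene_fraction Fraction of non-bait background junctions drawn
#'   from the per-gene transcription-coupled component (the rest is
#'   uniform genome background).
#' @param planted_hotspots Data frame with columns `chrom`, `center`,
#'   `span`, `count`, `plus_strand_fraction`: focal clusters planted
#'   with known truth.
#' @param artifact_rates Named list of artifact injection fractions:
#'   `pcr_duplicate`, `low_score`, `gapped`, `multi_mapper`, `haeiii`,
#'   `primer_fail`.
#' @param seed RNG seed; identical seeds reproduce identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_junctions = 2000, bait_proximity_fraction = 0.3,
                       bait_proximity_span = 2e6,
                       transcription_coupling = 1, gene_fraction = 0.3,
                       planted_hotspots = NULL,
                       artifact_rates = list(pcr_duplicate = 0.2,
                                             low_score = 0.1,
                                             gapped = 0.05,
                                             multi_mapper = 0.05,
                                             haeiii = 0.05,
                                             primer_fail = 0.05),
                       seed = NULL) {
  if (is.null(planted_hotspots))
    planted_hotspots <- data.frame(chrom = character(),
                                   center = numeric(), span = numeric(),
                                   count = integer(),
                                   plus_strand_fraction = numeric())
  fr <- c(bait_proximity_fraction, gene_fraction,
          unlist(artifact_rates),
          planted_hotspots$plus_strand_fraction)
  stopifnot(n_junctions >= 0, all(fr >= 0 & fr <= 1),
            all(planted_hotspots$count >= 0))
  structure(list(n_junctions = n_junctions,
                 bait_proximity_fraction = bait_proximity_fraction,
                 bait_proximity_span = bait_proximity_span,
                 transcription_coupling = transcription_coupling,
                 gene_fraction = gene_fraction,
                 planted_hotspots = planted_hotspots,
                 artifact_rates = artifact_rates, seed = seed),
            class = "sim_params")
}

# evenly spaced exons; for '-' genes transcript order runs downward
make_exons <- function(tx_start, n_exons, exon_len, intron_len, strand) {
  starts <- tx_start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  ex <- cbind(start = starts, end = starts + exon_len)
  if (strand == "-") ex <- ex[rev(seq_len(n_exons)), , drop = FALSE]
  ex
}

#' Standard two-chromosome toy genome
#'
#' A 2 x 10 Mb genome carrying an ALK-like minus-strand kinase (`KIN1`,
#' 22 exons, bait DSB in intron 19 so exon 20 onward is retained in
#' fusions; acceptor phase 1 at exon 20) on chr2, and a panel of
#' partner genes on chr1 chosen to span the selection determinants:
#'
#' * `PTNA` (+, expression 50): EML4-like; introns 6 and 13 in frame
#'   with the kinase acceptor.
#' * `PTNB` (-, expression 20): in-frame introns on the minus strand.
#' * `PTNC` (+, expression 0): CD74-like silent partner, in-frame
#'   introns — productive only once expression is switched on.
#' * `PTND` (+, expression 30): phase-incompatible in every intron.
#' * `PTNE` (+, expression 40): in-frame; used with a stability map to
#'   model degraded fusion proteins.
#' * `PTNF`, `PTNG`: neutral expressed genes for the
#'   transcription-coupled background.
#'
#' HaeIII cut positions are drawn uniformly (about 30 per Mb) and one
#' off-target blacklist interval is placed on chr1.
#'
#' @param seed Seed for the HaeIII site draw.
#' @return A [genome_model()].
#' @export
simulate_genome <- function(seed = 42L) {
  set.seed(seed)
  chroms <- c(chr1 = 1e7, chr2 = 1e7)
  # kinase: 22 exons x 150 bp, 10-kb introns; cds 100 + 21 x 150
  kin_ex <- make_exons(6e6, 22L, 150, 10000, "-")
  kin <- gene_model("KIN1", "chr2", "-", 6e6, max(kin_ex[, "end"]),
                    kin_ex, c(100, rep(150, 21L)), expression = 15,
                    is_kinase = TRUE)
  # partner panel: 10 exons x 200 bp, 5-kb introns (span ~ 47 kb)
  partner <- function(id, tx_start, strand, cds1, expr, dimer = TRUE) {
    ex <- make_exons(tx_start, 10L, 200, 5000, strand)
    gene_model(id, "chr1", strand, tx_start, max(ex[, "end"]), ex,
               c(cds1, rep(150, 9L)), expression = expr,
               dimerization_domain = dimer)
  }
  # cds1 = 100 -> every donor phase 1 (in frame with KIN1 exon 20);
  # cds1 = 99 -> every donor phase 0 (never in frame)
  genes <- list(
    kin,
    partner("PTNA", 0.5e6, "+", 100, 50),
    partner("PTNB", 1.5e6, "-", 100, 20),
    partner("PTNC", 2.5e6, "+", 100, 0),
    partner("PTND", 3.5e6, "+", 99, 30),
    partner("PTNE", 4.5e6, "+", 100, 40),
    partner("PTNF", 6.0e6, "+", 99, 10, dimer = FALSE),
    partner("PTNG", 7.0e6, "-", 99, 5, dimer = FALSE))
  hae <- lapply(chroms, function(len) sort(sample.int(len, 300)) - 1)
  bait_iv <- intron_interval(kin, 19L)
  bait <- bait_site("chr2", floor(mean(bait_iv)), "KIN1", 19L,
                    primer_seq = "ACGTACGTACGTACGT")
  genome_model(chroms, genes, hae, bait,
               data.frame(chrom = "chr1", start = 8.2e6, end = 8.21e6))
}

draw_strand <- function(n, plus_fraction = 0.5) {
  ifelse(stats::runif(n) < plus_fraction, "+", "-")
}

junction_frame <- function(chrom, position, strand, origin, id_offset) {
  n <- length(position)
  data.frame(read_id = sprintf("r%06d", id_offset + seq_len(n)),
             chrom = chrom, position = floor(position), strand = strand,
             prey_retained_side = ifelse(strand == "+", "right", "left"),
             read_start = sample(10:40, n, replace = TRUE),
             origin = origin, stringsAsFactors = FALSE)
}

#' Simulate a pre-selection junction library
#'
#' Draws junction positions from a mixture of (i) uniform genome
#' background, (ii) a bait-proximal component with symmetric triangular
#' decay over `bait_proximity_span`, (iii) per-gene components with
#' rate proportional to `expression^transcription_coupling`, and (iv)
#' planted hotspots (added on top of `n_junctions`). Strand is 50/50
#' except where a planted hotspot specifies `plus_strand_fraction`; the
#' retained prey side follows the strand convention of the junction
#' caller. Every record carries a ground-truth `origin` label.
#'
#' @param genome A [genome_model()].
#' @param params A [sim_params()].
#' @return Junction table with `origin` truth labels.
#' @export
simulate_pre_selection <- function(genome, params = sim_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  ph <- params$planted_hotspots
  for (i in seq_len(nrow(ph))) {
    if (!ph$chrom[i] %in% names(genome$chromosomes))
      stop("planted hotspot on unknown chromosome ", ph$chrom[i])
    len <- genome$chromosomes[[ph$chrom[i]]]
    if (ph$center[i] - ph$span[i] / 2 < 0 ||
        ph$center[i] + ph$span[i] / 2 > len)
      stop("planted hotspot outside genome: ", ph$chrom[i], ":",
           ph$center[i])
  }
  out <- list()
  n_id <- 0L
  # (iv) planted hotspots
  for (i in seq_len(nrow(ph))) {
    cnt <- ph$count[i]
    if (cnt == 0) next
    pos <- stats::runif(cnt, ph$center[i] - ph$span[i] / 2,
                        ph$center[i] + ph$span[i] / 2)
    out[[length(out) + 1L]] <-
      junction_frame(ph$chrom[i], pos,
                     draw_strand(cnt, ph$plus_strand_fraction[i]),
                     paste0("hotspot:", i), n_id)
    n_id <- n_id + cnt
  }
  n <- params$n_junctions
  if (n > 0) {
    u <- stats::runif(n)
    bp <- if (is.null(genome$bait)) 0 else params$bait_proximity_fraction
    comp <- ifelse(u < bp, "bait",
                   ifelse(u < bp + (1 - bp) * params$gene_fraction,
                          "gene", "uniform"))
    # (ii) bait proximity: symmetric triangular over +/- span
    n_b <- sum(comp == "bait")
    if (n_b > 0) {
      b <- genome$bait
      span <- params$bait_proximity_span
      off <- (stats::runif(n_b) + stats::runif(n_b) - 1) * span
      pos <- pmin(pmax(b$position + off, 0),
                  genome$chromosomes[[b$chrom]] - 1)
      out[[length(out) + 1L]] <-
        junction_frame(b$chrom, pos, draw_strand(n_b), "bait_proximity",
                       n_id)
      n_id <- n_id + n_b
    }
    # (iii) transcription-coupled per-gene component
    n_g <- sum(comp == "gene")
    expr <- vapply(genome$genes, function(g) g$expression, numeric(1))
    wt <- expr ^ params$transcription_coupling
    if (n_g > 0 && length(wt) && sum(wt) > 0) {
      pick <- sample(names(genome$genes), n_g, replace = TRUE,
                     prob = wt / sum(wt))
      pos <- vapply(pick, function(id) {
        g <- genome$genes[[id]]
        stats::runif(1, g$tx_start, g$tx_end)
      }, numeric(1))
      out[[length(out) + 1L]] <-
        junction_frame(vapply(pick, function(id)
          genome$genes[[id]]$chrom, character(1)),
          pos, draw_strand(n_g), paste0("gene:", pick), n_id)
      n_id <- n_id + n_g
    } else {
      comp[comp == "gene"] <- "uniform"
    }
    # (i) uniform genome background
    n_u <- sum(comp == "uniform")
    if (n_u > 0) {
      chrom <- sample(names(genome$chromosomes), n_u, replace = TRUE,
                      prob = genome$chromosomes /
                        sum(genome$chromosomes))
      pos <- stats::runif(n_u) * genome$chromosomes[chrom]
      out[[length(out) + 1L]] <-
        junction_frame(chrom, pos, draw_strand(n_u), "background", n_id)
      n_id <- n_id + n_u
    }
  }
  if (!length(out))
    return(junction_frame(character(), numeric(), character(),
                          character(), 0L))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply functional selection to a junction library
#'
#' Emulates drug or in-vivo selection: only junctions classified as
#' productive fusions ([classify_fusions()]) survive, thinned further
#' by `survival_noise` (stochastic clone loss). Output rows are a
#' subset of input rows; with `survival_noise = 0` the operation is
#' deterministic and idempotent.
#'
#' @param junctions Junction table.
#' @param genome A [genome_model()].
#' @param bait A [bait_site()]; defaults to `genome$bait`.
#' @param sel A [selection_params()].
#' @return The surviving subset of `junctions`.
#' @export
apply_selection <- function(junctions, genome, bait = genome$bait,
                            sel = selection_params()) {
  calls <- classify_fusions(junctions, genome, bait, sel)
  keep <- calls$productive
  if (sel$survival_noise > 0) {
    if (!is.null(sel$seed)) set.seed(sel$seed)
    keep <- keep & stats::runif(nrow(junctions)) >= sel$survival_noise
  }
  out <- junctions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

rand_positions <- function(genome, n) {
  chrom <- sample(names(genome$chromosomes), n, replace = TRUE,
                  prob = genome$chromosomes / sum(genome$chromosomes))
  data.frame(chrom = chrom,
             position = floor(stats::runif(n) *
                                genome$chromosomes[chrom]),
             strand = draw_strand(n), stringsAsFactors = FALSE)
}

primary_alignment <- function(read_id, chrom, position, strand,
                              read_start, artifact,
                              matches = NULL) {
  n <- length(position)
  len <- sample(60:120, n, replace = TRUE)
  plus <- strand == "+"
  aln_start <- ifelse(plus, position, pmax(0, position + 1 - len))
  aln_end <- ifelse(plus, position + len, position + 1)
  if (is.null(matches)) matches <- aln_end - aln_start
  data.frame(read_id = read_id, barcode = "LIB01",
             primer_anchor_ok = TRUE, chrom = chrom, strand = strand,
             aln_start = aln_start, aln_end = aln_end,
             read_start = read_start, matches = matches,
             mismatches = 0L, gap_opens = 0L, max_gap_len = 0L,
             n_alignments_for_read = 1L,
             second_best_score_diff = 999, artifact = artifact,
             stringsAsFactors = FALSE)
}

#' Emit a raw alignment-record table with planted artifacts
#'
#' Produces one clean primary alignment per junction (score at least
#' 30, no gaps, unambiguous) whose coordinates invert the junction
#' caller's 5'-end rule, then injects, at the `artifact_rates`
#' fractions, the contaminant classes the filter cascade removes: PCR
#' duplicates (same junction, read start offset < 3), low-score
#' alignments (score < 30), gapped alignments (gap >= 10 nt),
#' ambiguous multi-mappers (second alignment within score difference
#' < 4), junctions placed exactly at HaeIII cut positions, and reads
#' missing the primer anchor. Injected rows are labelled in the
#' `artifact` truth column (`"none"` for clean rows); artifact read
#' ids sort after all clean ids so PCR de-duplication retains the
#' original.
#'
#' @param junctions Junction table (e.g. [simulate_pre_selection()]).
#' @param genome A [genome_model()].
#' @param params A [sim_params()] (for `artifact_rates`).
#' @param seed RNG seed; defaults to `params$seed`.
#' @return Alignment table with truth labels.
#' @export
emit_alignment_table <- function(junctions, genome,
                                 params = sim_params(),
                                 seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(junctions)
  clean <- primary_alignment(junctions$read_id, junctions$chrom,
                             junctions$position, junctions$strand,
                             junctions$read_start, "none")
  rates <- params$artifact_rates
  rate <- function(key) if (is.null(rates[[key]])) 0 else rates[[key]]
  parts <- list(clean)
  inject <- function(key) which(stats::runif(n) < rate(key))
  # PCR duplicates of clean rows
  idx <- inject("pcr_duplicate")
  if (length(idx)) {
    dup <- clean[idx, , drop = FALSE]
    dup$read_id <- paste0(dup$read_id, "_dup")
    dup$read_start <- dup$read_start + sample(1:2, length(idx),
                                              replace = TRUE)
    dup$artifact <- "pcr_duplicate"
    parts[[length(parts) + 1L]] <- dup
  }
  # low-score alignments at random positions
  idx <- inject("low_score")
  if (length(idx)) {
    rp <- rand_positions(genome, length(idx))
    ls <- primary_alignment(sprintf("zart_ls%05d", seq_along(idx)),
                            rp$chrom, rp$position, rp$strand,
                            sample(10:40, length(idx), replace = TRUE),
                            "low_score",
                            matches = sample(15:25, length(idx),
                                             replace = TRUE))
    parts[[length(parts) + 1L]] <- ls
  }
  # gapped alignments
  idx <- inject("gapped")
  if (length(idx)) {
    rp <- rand_positions(genome, length(idx))
    gp <- primary_alignment(sprintf("zart_gp%05d", seq_along(idx)),
                            rp$chrom, rp$position, rp$strand,
                            sample(10:40, length(idx), replace = TRUE),
                            "gapped")
    gp$gap_opens <- 1L
    gp$max_gap_len <- sample(10:25, length(idx), replace = TRUE)
    parts[[length(parts) + 1L]] <- gp
  }
  # ambiguous multi-mappers
  idx <- inject("multi_mapper")
  if (length(idx)) {
    rp <- rand_positions(genome, length(idx))
    mm <- primary_alignment(sprintf("zart_mm%05d", seq_along(idx)),
                            rp$chrom, rp$position, rp$strand,
                            sample(10:40, length(idx), replace = TRUE),
                            "multi_mapper")
    mm$n_alignments_for_read <- 2L
    mm$second_best_score_diff <- sample(0:3, length(idx), replace = TRUE)
    parts[[length(parts) + 1L]] <- mm
  }
  # HaeIII bait-ligation artifacts at cut positions
  idx <- inject("haeiii")
  if (length(idx) && length(genome$haeiii_sites)) {
    chrom <- sample(names(genome$haeiii_sites), length(idx),
                    replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample(genome$haeiii_sites[[ch]], 1L), numeric(1))
    hh <- primary_alignment(sprintf("zart_h3%05d", seq_along(idx)),
                            chrom, pos, draw_strand(length(idx)),
                            sample(10:40, length(idx), replace = TRUE),
                            "haeiii")
    parts[[length(parts) + 1L]] <- hh
  }
  # reads missing the primer anchor
  idx <- inject("primer_fail")
  if (length(idx)) {
    rp <- rand_positions(genome, length(idx))
    pf <- primary_alignment(sprintf("zart_pf%05d", seq_along(idx)),
                            rp$chrom, rp$position, rp$strand,
                            sample(10:40, length(idx), replace = TRUE),
                            "primer_fail")
    pf$primer_anchor_ok <- FALSE
    parts[[length(parts) + 1L]] <- pf
  }
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Expand a fusion specification into a COSMIC-like fusion table
#'
#' @param spec Data frame with columns `kinase_gene`, `partner_gene`,
#'   `kinase_exon`, `partner_exon`, `count` and optionally `tissue`
#'   (default `"NS"`) and `validated` (default TRUE): one row per
#'   distinct fusion event class with its multiplicity.
#' @param seed Seed for the row shuffle (row order never affects the
#'   landscape summaries; shuffling makes that visible).
#' @return Fusion table with one row per fusion event (`sample_id`,
#'   `tissue`, `kinase_gene`, `partner_gene`, `kinase_exon`,
#'   `partner_exon`, `validated`).
#' @export
simulate_cosmic_table <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spec$tissue)) spec$tissue <- "NS"
  if (is.null(spec$validated)) spec$validated <- TRUE
  stopifnot(all(spec$count >= 0))
  idx <- rep(seq_len(nrow(spec)), spec$count)
  out <- data.frame(
    sample_id = sprintf("S%06d", seq_along(idx)),
    tissue = spec$tissue[idx], kinase_gene = spec$kinase_gene[idx],
    partner_gene = spec$partner_gene[idx],
    kinase_exon = spec$kinase_exon[idx],
    partner_exon = spec$partner_exon[idx],
    validated = spec$validated[idx], stringsAsFactors = FALSE)
  if (!is.null(seed) && nrow(out) > 1L)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
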