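#' Gene model with exon structure, coding phases and expression
#'
#' Builds a single-transcript gene model. Coordinates are 0-based,
#' half-open (`[start, end)`). Exons are given in *transcript* order
#' (1-based, 5'-to-3' on the coding strand), so for a minus-strand gene
#' the first exon has the highest genomic coordinates. Intron `k` is the
#' genomic gap between exon `k` and exon `k + 1` in transcript order.
#'
#' @param gene_id Gene identifier (nonempty string).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end Transcript span in bp (0-based, half-open).
#' @param exons Two-column matrix or data.frame of exon `(start, end)`
#'   pairs in transcript order.
#' @param cds_exon_lengths Integer vector, per-exon coding length in bp
#'   (0 for untranslated exons); each entry must not exceed the exon
#'   length.
#' @param expression Non-negative transcription level (FPKM-like units).
#' @param is_kinase Logical; gene encodes a tyrosine kinase.
#' @param dimerization_domain Logical; gene encodes a dimerization or
#'   oligomerization domain (relevant for fusion partners).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end, exons,
                       cds_exon_lengths, expression = 0,
                       is_kinase = FALSE, dimerization_domain = FALSE) {
  stopifnot(is.character(gene_id), nzchar(gene_id),
            strand %in% c("+", "-"),
            tx_start < tx_end)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "double"
  dimnames(exons) <- list(NULL, c("start", "end"))
  n <- nrow(exons)
  if (n < 1L) stop("gene must have at least one exon")
  if (any(exons[, "start"] >= exons[, "end"]))
    stop("exon start must be < end")
  # transcript order: genomically ascending on '+', descending on '-'
  g_starts <- if (strand == "+") exons[, "start"] else rev(exons[, "start"])
  g_ends <- if (strand == "+") exons[, "end"] else rev(exons[, "end"])
  if (n > 1L && any(g_starts[-1L] < g_ends[-n]))
    stop("exons must be non-overlapping and in transcript order")
  cds_exon_lengths <- as.numeric(cds_exon_lengths)
  if (length(cds_exon_lengths) != n)
    stop("cds_exon_lengths must have one entry per exon")
  if (any(cds_exon_lengths < 0) ||
      any(cds_exon_lengths > exons[, "end"] - exons[, "start"]))
    stop("cds_exon_lengths must lie in [0, exon length]")
  if (any(exons[, "start"] < tx_start) || any(exons[, "end"] > tx_end))
    stop("exons must lie within [tx_start, tx_end)")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tx_start = tx_start, tx_end = tx_end, exons = exons,
                 cds_exon_lengths = cds_exon_lengths,
                 expression = expression, is_kinase = is_kinase,
                 dimerization_domain = dimerization_domain),
            class = "gene_model")
}

#' Bait double-strand-break site
#'
#' The programmed DSB anchoring one side of every junction: a fixed
#' position inside an intron of a kinase gene (e.g. intron 19 of an
#' ALK-like kinase, so that exon 20 onward is retained in the fusion).
#'
#' @param chrom Chromosome of the break.
#' @param position Break position in bp.
#' @param kinase_gene_id Gene containing the DSB.
#' @param bait_intron_index Intron number (transcript order) holding the
#'   break.
#' @param primer_seq Bait-side primer sequence (informational).
#' @return An object of class `bait_site`.
#' @export
bait_site <- function(chrom, position, kinase_gene_id, bait_intron_index,
                      primer_seq = "") {
  structure(list(chrom = chrom, position = position,
                 kinase_gene_id = kinase_gene_id,
                 bait_intron_index = as.integer(bait_intron_index),
                 primer_seq = primer_seq),
            class = "bait_site")
}

#' Genome model shared by all pipeline stages
#'
#' Holds chromosome lengths, gene models, HaeIII cut positions (source
#' of blunt-ligation artifacts), the bait DSB and an off-target
#' blacklist of intervals excluded from hotspot calling.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param genes List of [gene_model()] objects.
#' @param haeiii_sites Named list (per chromosome) of sorted cut
#'   positions in bp; each is the blunt cut between GG and CC.
#' @param bait A [bait_site()] or `NULL`.
#' @param offtarget_blacklist Data frame with columns `chrom`, `start`,
#'   `end` (0-based, half-open) of intervals to exclude.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes = list(), haeiii_sites = list(),
                         bait = NULL, offtarget_blacklist = NULL) {
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)),
            all(chromosomes > 0))
  if (is.null(offtarget_blacklist))
    offtarget_blacklist <- data.frame(chrom = character(),
                                      start = numeric(), end = numeric())
  names(genes) <- vapply(genes, function(g) g$gene_id, character(1))
  for (g in genes) {
    if (!g$chrom %in% names(chromosomes))
      stop("gene ", g$gene_id, " on unknown chromosome ", g$chrom)
    if (g$tx_end > chromosomes[[g$chrom]])
      stop("gene ", g$gene_id, " extends beyond its chromosome")
  }
  for (chrom in names(haeiii_sites)) {
    if (!chrom %in% names(chromosomes))
      stop("HaeIII sites on unknown chromosome ", chrom)
    s <- haeiii_sites[[chrom]]
    if (is.unsorted(s)) stop("haeiii_sites must be sorted ascending")
    if (any(s < 0) || any(s >= chromosomes[[chrom]]))
      stop("HaeIII site outside chromosome ", chrom)
  }
  if (!is.null(bait)) {
    stopifnot(inherits(bait, "bait_site"))
    kg <- genes[[bait$kinase_gene_id]]
    if (is.null(kg)) stop("bait kinase gene not in genome")
    iv <- intron_interval(kg, bait$bait_intron_index)
    if (bait$position < iv[1] || bait$position >= iv[2])
      stop("bait position not inside intron ", bait$bait_intron_index,
           " of ", bait$kinase_gene_id)
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 haeiii_sites = haeiii_sites, bait = bait,
                 offtarget_blacklist = offtarget_blacklist),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes), "bp,", length(x$genes), "gene(s)\n")
  if (!is.null(x$bait))
    cat("  bait:", x$bait$chrom, "@", x$bait$position, "in intron",
        x$bait$bait_intron_index, "of", x$bait$kinase_gene_id, "\n")
  invisible(x)
}

total_cds <- function(gene) sum(gene$cds_exon_lengths)

check_exon_index <- function(gene, exon_index) {
  if (!is.numeric(exon_index) || length(exon_index) != 1L ||
      exon_index < 1L || exon_index > nrow(gene$exons) ||
      exon_index != as.integer(exon_index))
    stop("unknown exon index ", exon_index, " for gene ", gene$gene_id)
}

#' Coding phase at an exon boundary
#'
#' The phase of a coding exon boundary is the cumulative coding length
#' modulo 3 at that boundary: `exon_start_phase` at the 5' edge of exon
#' `exon_index`, `exon_end_phase` at its 3' edge. A fusion joining a
#' partner intron to a kinase intron is in frame exactly when the
#' partner's donor end-phase equals the kinase's acceptor start-phase.
#'
#' @param gene A [gene_model()] with nonzero total coding length.
#' @param exon_index 1-based exon number in transcript order.
#' @return Integer phase in `{0, 1, 2}`.
#' @export
exon_start_phase <- function(gene, exon_index) {
  check_exon_index(gene, exon_index)
  if (total_cds(gene) == 0) stop("non-coding gene")
  sum(gene$cds_exon_lengths[seq_len(exon_index - 1L)]) %% 3
}

#' @rdname exon_start_phase
#' @export
exon_end_phase <- function(gene, exon_index) {
  check_exon_index(gene, exon_index)
  if (total_cds(gene) == 0) stop("non-coding gene")
  sum(gene$cds_exon_lengths[seq_len(exon_index)]) %% 3
}

#' Genomic interval of an intron, in transcript numbering
#'
#' @param gene A [gene_model()].
#' @param intron_index 1-based intron number; intron `k` separates exons
#'   `k` and `k + 1` in transcript order.
#' @return Numeric `(start, end)`, 0-based half-open genomic interval.
#' @export
intron_interval <- function(gene, intron_index) {
  if (intron_index < 1L || intron_index > nrow(gene$exons) - 1L)
    stop("unknown intron index ", intron_index, " for gene ", gene$gene_id)
  a <- gene$exons[intron_index, ]
  b <- gene$exons[intron_index + 1L, ]
  if (gene$strand == "+") c(a[["end"]], b[["start"]])
  else c(b[["end"]], a[["start"]])
}

locate_in_gene <- function(gene, position) {
  if (position < gene$tx_start || position >= gene$tx_end) return(NULL)
  ex <- gene$exons
  hit <- which(position >= ex[, "start"] & position < ex[, "end"])
  if (length(hit) == 1L)
    return(list(region = "exon", index = hit))
  for (k in seq_len(nrow(ex) - 1L)) {
    iv <- intron_interval(gene, k)
    if (position >= iv[1] && position < iv[2])
      return(list(region = "intron", index = k))
  }
  NULL  # inside tx span but before exon 1 / after last exon edge case
}

#' Locate a genomic position relative to gene structure
#'
#' Returns every gene whose body overlaps the position, with the exon or
#' intron (transcript numbering) containing it; if no gene overlaps, a
#' single intergenic row. Downstream consumers choosing a single gene
#' pick the one with the largest overlap of their interval of interest.
#'
#' @param genome A [genome_model()].
#' @param chrom,position Query position (0-based bp).
#' @return Data frame with columns `gene_id` (NA for intergenic),
#'   `region` (`"exon"`, `"intron"` or `"intergenic"`) and `index`.
#' @export
locate <- function(genome, chrom, position) {
  if (!chrom %in% names(genome$chromosomes))
    stop("unknown chromosome ", chrom)
  if (position < 0 || position >= genome$chromosomes[[chrom]])
    stop("position ", position, " outside chromosome ", chrom)
  out <- list()
  for (g in genome$genes) {
    if (g$chrom != chrom) next
    hit <- locate_in_gene(g, position)
    if (!is.null(hit))
      out[[length(out) + 1L]] <- data.frame(gene_id = g$gene_id,
                                            region = hit$region,
                                            index = hit$index)
  }
  if (!length(out))
    return(data.frame(gene_id = NA_character_, region = "intergenic",
                      index = NA_integer_))
  do.call(rbind, out)
}

# -- import / export ---------------------------------------------------

#' Read and write genome models as JSON
#'
#' A small JSON dialect for fixtures: chromosome lengths, gene records
#' (with exons in transcript order and per-exon CDS lengths), HaeIII cut
#' positions, bait and blacklist. Round-trips exactly.
#'
#' @param genome A [genome_model()].
#' @param path File path.
#' @return `read_genome_json` returns a [genome_model()];
#'   `write_genome_json` returns `path` invisibly.
#' @export
write_genome_json <- function(genome, path) {
  genes <- lapply(unname(genome$genes), function(g) {
    list(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
         tx_start = g$tx_start, tx_end = g$tx_end,
         exon_start = g$exons[, "start"], exon_end = g$exons[, "end"],
         cds_exon_lengths = g$cds_exon_lengths,
         expression = g$expression, is_kinase = g$is_kinase,
         dimerization_domain = g$dimerization_domain)
  })
  obj <- list(chromosomes = as.list(genome$chromosomes), genes = genes,
              haeiii_sites = genome$haeiii_sites,
              bait = if (is.null(genome$bait)) NULL else
                unclass(genome$bait),
              offtarget_blacklist = genome$offtarget_blacklist)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_genes <- if (is.data.frame(obj$genes)) nrow(obj$genes) else
    length(obj$genes)
  genes <- lapply(seq_len(n_genes), function(i) {
    g <- if (is.data.frame(obj$genes)) as.list(obj$genes[i, ]) else
      obj$genes[[i]]
    gene_model(g$gene_id, g$chrom, g$strand, g$tx_start, g$tx_end,
               cbind(start = unlist(g$exon_start),
                     end = unlist(g$exon_end)),
               unlist(g$cds_exon_lengths), g$expression,
               isTRUE(g$is_kinase), isTRUE(g$dimerization_domain))
  })
  bait <- NULL
  if (!is.null(obj$bait))
    bait <- bait_site(obj$bait$chrom, obj$bait$position,
                      obj$bait$kinase_gene_id, obj$bait$bait_intron_index,
                      if (is.null(obj$bait$primer_seq)) "" else
                        obj$bait$primer_seq)
  bl <- obj$offtarget_blacklist
  if (is.null(bl) || !nrow(as.data.frame(bl))) bl <- NULL
  genome_model(unlist(obj$chromosomes),
               genes,
               lapply(obj$haeiii_sites, as.numeric),
               bait,
               if (is.null(bl)) NULL else as.data.frame(bl))
}

#' Import gene models from GTF exon lines
#'
#' Reads a GTF file (1-based, inclusive coordinates; converted to
#' 0-based half-open internally), keeping `exon` features with
#' `gene_id` and `exon_number` attributes. Exon numbers are taken as
#' transcript order. CDS lengths default to the full exon length; pass
#' `cds_exon_lengths` to override per gene.
#'
#' @param path GTF file path.
#' @param chromosomes Named chromosome-length vector for the resulting
#'   [genome_model()].
#' @param cds_exon_lengths Optional named list (by gene_id) of per-exon
#'   CDS lengths.
#' @param expression Optional named numeric vector of expression levels.
#' @return A [genome_model()].
#' @export
import_gtf_genes <- function(path, chromosomes, cds_exon_lengths = list(),
                             expression = numeric()) {
  tab <- utils::read.table(path, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- c("seqname", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attribute")
  tab <- tab[tab$feature == "exon", , drop = FALSE]
  attr_field <- function(s, key) {
    m <- regmatches(s, regexpr(paste0(key, ' "?([^";]+)"?'), s))
    sub(paste0(key, ' "?([^";]+)"?'), "\\1", m)
  }
  tab$gene_id <- vapply(tab$attribute, attr_field, character(1), "gene_id")
  tab$exon_number <- as.integer(vapply(tab$attribute, attr_field,
                                       character(1), "exon_number"))
  genes <- lapply(split(tab, tab$gene_id), function(tg) {
    tg <- tg[order(tg$exon_number), , drop = FALSE]
    exons <- cbind(start = tg$start - 1, end = tg$end)  # to 0-based
    gid <- tg$gene_id[1L]
    cds <- cds_exon_lengths[[gid]]
    if (is.null(cds)) cds <- exons[, "end"] - exons[, "start"]
    expr <- if (gid %in% names(expression)) expression[[gid]] else 0
    gene_model(gid, tg$seqname[1L], tg$strand[1L],
               min(exons[, "start"]), max(exons[, "end"]),
               exons, cds, expr)
  })
  genome_model(chromosomes, genes)
}

#' Export gene bodies as BED
#'
#' @param genome A [genome_model()].
#' @param path Output path (BED6: chrom, start, end, gene_id, score 0,
#'   strand; 0-based half-open).
#' @return `path`, invisibly.
#' @export
export_genes_bed <- function(genome, path) {
  rows <- lapply(genome$genes, function(g)
    data.frame(chrom = g$chrom, start = g$tx_start, end = g$tx_end,
               name = g$gene_id, score = 0, strand = g$strand))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric(), strand = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Find HaeIII cut positions in sequences
#'
#' Scans sequences for the HaeIII recognition site GGCC and records the
#' blunt cut position at offset +2 (between GG and CC), 0-based.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return Named list of sorted cut positions per chromosome.
#' @export
scan_haeiii_sites <- function(seqs) {
  lapply(as.list(seqs), function(s) {
    hits <- gregexpr("(?=GGCC)", toupper(s), perl = TRUE)[[1L]]
    if (length(hits) == 1L && hits[1L] == -1L) return(numeric())
    sort(as.numeric(hits) - 1 + 2)
  })
}
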