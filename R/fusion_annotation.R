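#' Selection parameters for productive-fusion classification
#'
#' Encodes the determinants of whether a junction yields a productive
#' (oncogenic, selectable) kinase fusion: partner transcription above a
#' threshold, and fusion-protein stability above a threshold. Stability
#' is an input score per (partner gene, retained kinase exon) — it is a
#' measured property of the fusion protein, not predicted from
#' sequence.
#'
#' @param min_expression Minimum partner expression (FPKM-like units)
#'   for a productive fusion.
#' @param stability Data frame with columns `partner_gene`,
#'   `kinase_exon`, `stability` (scores in `[0, 1]`); pairs absent from
#'   the table default to 1.0.
#' @param stability_threshold Minimum stability score of a productive
#'   fusion.
#' @param survival_noise Probability that a productive clone is lost
#'   stochastically during selection.
#' @param seed RNG seed for the survival thinning.
#' @param allow_exonic Classify breakpoints inside exons as candidate
#'   productive events (default FALSE: exonic fusions are atypical,
#'   unstable weak drivers and are excluded).
#' @param require_dimerization Additionally require the partner to
#'   carry a dimerization/oligomerization domain (off by default; the
#'   association is correlative).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(min_expression = 1, stability = NULL,
                             stability_threshold = 0.5,
                             survival_noise = 0, seed = NULL,
                             allow_exonic = FALSE,
                             require_dimerization = FALSE) {
  if (is.null(stability))
    stability <- data.frame(partner_gene = character(),
                            kinase_exon = integer(),
                            stability = numeric())
  stopifnot(all(stability$stability >= 0 & stability$stability <= 1),
            survival_noise >= 0, survival_noise <= 1)
  structure(list(min_expression = min_expression, stability = stability,
                 stability_threshold = stability_threshold,
                 survival_noise = survival_noise, seed = seed,
                 allow_exonic = allow_exonic,
                 require_dimerization = require_dimerization),
            class = "selection_params")
}

stability_lookup <- function(sel, partner_gene, kinase_exon) {
  hit <- sel$stability$partner_gene == partner_gene &
    sel$stability$kinase_exon == kinase_exon
  if (any(hit)) sel$stability$stability[which(hit)[1L]] else 1.0
}

#' Is a junction orientation-compatible with a productive fusion?
#'
#' A productive fusion needs the partner's promoter-proximal (5')
#' portion joined upstream of the retained kinase portion, so the prey
#' side retained in the rearrangement must contain the partner's 5'
#' end: for a plus-strand partner the left (lower-coordinate) side,
#' for a minus-strand partner the right side. Junctions outside any
#' gene are never orientation-compatible.
#'
#' @param prey_retained_side `"left"` or `"right"`.
#' @param partner A [gene_model()] or `NULL` (intergenic).
#' @return Logical.
#' @export
orientation_compatible <- function(prey_retained_side, partner) {
  if (is.null(partner)) return(FALSE)
  stopifnot(prey_retained_side %in% c("left", "right"))
  if (partner$strand == "+") prey_retained_side == "left"
  else prey_retained_side == "right"
}

#' Is a partner-intron / kinase-intron fusion in frame?
#'
#' A fusion joining partner intron `partner_intron` (so partner exons
#' `1..partner_intron` are retained) to kinase intron `kinase_intron`
#' (so kinase exons `kinase_intron + 1` onward are retained) preserves
#' the kinase reading frame exactly when the partner's donor end-phase
#' equals the kinase's acceptor start-phase.
#'
#' @param partner,kinase [gene_model()] objects with coding sequence.
#' @param partner_intron,kinase_intron 1-based intron indices
#'   (transcript order).
#' @return Logical.
#' @export
fusion_in_frame <- function(partner, partner_intron, kinase,
                            kinase_intron) {
  exon_end_phase(partner, partner_intron) ==
    exon_start_phase(kinase, kinase_intron + 1L)
}

#' Classify junctions as productive kinase fusions
#'
#' Applies the four determinants of fusion selection to each junction:
#' orientation (the retained prey side must carry the partner's 5'
#' portion), breakpoint location (intronic; exonic breakpoints are
#' atypical and non-productive unless `allow_exonic`), reading frame
#' (partner donor phase must match the kinase acceptor phase at the
#' bait intron), partner transcription (expression at or above
#' `min_expression`), and fusion-protein stability (score at or above
#' `stability_threshold`). A junction is productive only when all hold.
#' When several genes overlap the junction, the gene with the largest
#' overlap of the junction position's containing gene body is used.
#'
#' @param junctions Junction table (`chrom`, `position`, `strand`,
#'   `prey_retained_side`, ...).
#' @param genome A [genome_model()].
#' @param bait A [bait_site()]; defaults to `genome$bait`.
#' @param sel A [selection_params()].
#' @return Fusion-call table: one row per junction with
#'   `partner_gene_id`, `partner_region`, `partner_index`,
#'   `kinase_exon`, `orientation_ok`, `intronic`, `in_frame`,
#'   `expressed`, `stability` and `productive` columns appended.
#' @export
classify_fusions <- function(junctions, genome, bait = genome$bait,
                             sel = selection_params()) {
  if (is.null(bait)) stop("no bait site supplied")
  kinase <- genome$genes[[bait$kinase_gene_id]]
  if (is.null(kinase)) stop("bait kinase gene not in genome")
  kinase_exon <- bait$bait_intron_index + 1L
  n <- nrow(junctions)
  out <- junctions
  out$partner_gene_id <- NA_character_
  out$partner_region <- NA_character_
  out$partner_index <- NA_integer_
  out$kinase_exon <- rep(kinase_exon, n)
  out$orientation_ok <- out$intronic <- out$in_frame <-
    out$expressed <- logical(n)
  out$stability <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    loc <- locate(genome, junctions$chrom[i], junctions$position[i])
    loc <- loc[!is.na(loc$gene_id), , drop = FALSE]
    if (!nrow(loc)) next
    if (nrow(loc) > 1L) {  # largest gene-body overlap with the position
      ov <- vapply(loc$gene_id, function(id) {
        g <- genome$genes[[id]]
        min(g$tx_end, junctions$position[i] + 1) -
          max(g$tx_start, junctions$position[i])
      }, numeric(1))
      loc <- loc[which.max(ov), , drop = FALSE]
    }
    partner <- genome$genes[[loc$gene_id]]
    out$partner_gene_id[i] <- partner$gene_id
    out$partner_region[i] <- loc$region
    out$partner_index[i] <- loc$index
    out$orientation_ok[i] <-
      orientation_compatible(junctions$prey_retained_side[i], partner)
    out$intronic[i] <- loc$region == "intron"
    out$expressed[i] <- partner$expression >= sel$min_expression
    out$stability[i] <- stability_lookup(sel, partner$gene_id,
                                         kinase_exon)
    if (loc$region == "intron" && total_cds(partner) > 0)
      out$in_frame[i] <- fusion_in_frame(partner, loc$index, kinase,
                                         bait$bait_intron_index)
  }
  exonic <- out$partner_region %in% "exon"
  location_ok <- out$intronic | (sel$allow_exonic & exonic)
  # reading frame is undefined mid-exon; the exonic escape hatch waives it
  frame_ok <- out$in_frame | (sel$allow_exonic & exonic)
  dimer_ok <- if (sel$require_dimerization)
    vapply(out$partner_gene_id, function(id)
      !is.na(id) && genome$genes[[id]]$dimerization_domain,
      logical(1)) else rep(TRUE, n)
  out$productive <- out$orientation_ok & location_ok & frame_ok &
    out$expressed & !is.na(out$stability) &
    out$stability >= sel$stability_threshold & dimer_ok
  out$productive[is.na(out$productive)] <- FALSE
  rownames(out) <- NULL
  out
}

#' Resistant-clone frequency per million cells
#'
#' @param n_clones Number of resistant clones counted.
#' @param n_cells Number of cells plated (e.g. 20 million).
#' @return Clones per million cells.
#' @export
clone_frequency <- function(n_clones, n_cells) {
  stopifnot(n_cells > 0, n_clones >= 0)
  n_clones / (n_cells / 1e6)
}

#' Write fusion calls as TSV
#'
#' @param calls Fusion-call table from [classify_fusions()].
#' @param path Output TSV path (header included).
#' @return `path`, invisibly.
#' @export
write_fusion_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
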