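#' Filter parameters for the junction-calling cascade
#'
#' Defaults follow the standard HTGTS cleanup: alignments scoring below
#' 30 are invalid, reads with multiple alignments closer than 4 score
#' points are ambiguous, alignments with a gap of 10 nt or more are
#' rejected, and reads mapping to the same junction whose start
#' positions in the read are less than 3 bp apart are PCR repeats.
#'
#' @param min_score Minimum BLAT-style alignment score (kept if
#'   `score >= min_score`).
#' @param ambiguity_score_diff Minimum best-minus-second-best score
#'   difference for a multiply-aligned read (kept if `diff >=` this).
#' @param max_gap Alignment gap length (bp) at or above which the
#'   alignment is invalid.
#' @param dedup_read_start_window Read-start distance (bp) below which
#'   two reads at the same junction collapse as PCR repeats.
#' @param haeiii_window Distance (bp) to a HaeIII cut position at or
#'   below which a junction is removed as a ligation artifact; 0 means
#'   exact cut-position equality.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_score = 30, ambiguity_score_diff = 4,
                          max_gap = 10, dedup_read_start_window = 3,
                          haeiii_window = 0) {
  stopifnot(min_score > 0, ambiguity_score_diff > 0, max_gap > 0,
            dedup_read_start_window > 0, haeiii_window >= 0)
  structure(list(min_score = min_score,
                 ambiguity_score_diff = ambiguity_score_diff,
                 max_gap = max_gap,
                 dedup_read_start_window = dedup_read_start_window,
                 haeiii_window = haeiii_window),
            class = "filter_params")
}

aln_required_cols <- c("read_id", "chrom", "strand", "aln_start",
                       "aln_end", "read_start", "matches", "mismatches",
                       "gap_opens", "max_gap_len")

check_alignment_table <- function(records) {
  miss <- setdiff(aln_required_cols, names(records))
  if (length(miss))
    stop("alignment table missing columns: ", paste(miss, collapse = ", "))
  if (any(records$aln_start >= records$aln_end))
    stop("aln_start must be < aln_end")
  invisible(records)
}

#' BLAT-style alignment score
#'
#' Score of a prey alignment: number of matching bases penalised for
#' mismatches and gap openings.
#'
#' @param records Alignment table (data frame) with columns `matches`,
#'   `mismatches`, `gap_opens`.
#' @return Integer vector of scores, one per record.
#' @export
alignment_score <- function(records) {
  need <- c("matches", "mismatches", "gap_opens")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing alignment statistics: ", paste(miss, collapse = ", "))
  if (anyNA(records[need]))
    stop("NA alignment statistics")
  records$matches - records$mismatches - records$gap_opens
}

#' Drop reads lacking the bait primer anchor
#'
#' Keeps only reads that begin with the bait primer plus the expected 5
#' downstream bases (recorded upstream as the `primer_anchor_ok` flag;
#' masking of barcode/primer/bait portions is represented by the
#' `read_start` offset, not by sequence handling).
#'
#' @param records Alignment table with a logical `primer_anchor_ok`.
#' @return The subset of `records` with the anchor present.
#' @export
filter_reads <- function(records) {
  if (!"primer_anchor_ok" %in% names(records))
    stop("alignment table missing column: primer_anchor_ok")
  records[as.logical(records$primer_anchor_ok), , drop = FALSE]
}

#' Drop invalid alignments
#'
#' Removes records with alignment score below `min_score`, reads with
#' multiple alignments whose best-minus-second-best score difference is
#' below `ambiguity_score_diff`, and alignments containing a gap of
#' `max_gap` nt or more.
#'
#' @param records Alignment table (primer-filtered).
#' @param params A [filter_params()].
#' @return The valid subset of `records`.
#' @export
filter_alignments <- function(records, params = filter_params()) {
  check_alignment_table(records)
  miss <- setdiff(c("n_alignments_for_read", "second_best_score_diff"),
                  names(records))
  if (length(miss))
    stop("missing alignment statistics: ", paste(miss, collapse = ", "))
  score <- alignment_score(records)
  multi <- !is.na(records$n_alignments_for_read) &
    records$n_alignments_for_read > 1
  ambiguous <- multi & records$second_best_score_diff <
    params$ambiguity_score_diff
  if (anyNA(records$max_gap_len)) stop("NA max_gap_len")
  keep <- score >= params$min_score & !ambiguous &
    records$max_gap_len < params$max_gap
  records[keep, , drop = FALSE]
}

#' Call junction positions from valid alignments
#'
#' The junction is the genomic position of the 5' end of the aligned
#' prey read: `aln_start` for a plus-strand alignment, `aln_end - 1`
#' for minus strand. The prey side retained in the rearranged allele
#' extends from the junction away from the read, so plus-strand
#' alignments retain the right (higher-coordinate) side and minus-strand
#' alignments the left.
#'
#' @param records Valid alignment table.
#' @return Junction table: `read_id`, `chrom`, `position`, `strand`,
#'   `prey_retained_side`, `read_start` (plus any extra columns carried
#'   through, e.g. truth labels).
#' @export
call_junction <- function(records) {
  check_alignment_table(records)
  plus <- records$strand == "+"
  out <- data.frame(read_id = records$read_id, chrom = records$chrom,
                    position = ifelse(plus, records$aln_start,
                                      records$aln_end - 1),
                    strand = records$strand,
                    prey_retained_side = ifelse(plus, "right", "left"),
                    read_start = records$read_start,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(records),
                   c(aln_required_cols, "barcode", "primer_anchor_ok",
                     "n_alignments_for_read", "second_best_score_diff"))
  for (col in extra) out[[col]] <- records[[col]]
  rownames(out) <- NULL
  out
}

#' Collapse PCR repeats among called junctions
#'
#' Within each (chrom, position, strand) group, reads whose start
#' positions in the read are less than `dedup_read_start_window` bp
#' apart are PCR repeats and collapse to one. Clusters form greedily in
#' ascending `read_start` order (a record joins the open cluster if its
#' read_start is within the window of the cluster's anchor); the
#' cluster anchor — smallest `read_start`, ties broken by `read_id` —
#' survives, which makes the operation idempotent: surviving
#' read_starts are always at least the window apart.
#'
#' @param junctions Junction table from [call_junction()].
#' @param params A [filter_params()].
#' @return De-duplicated junction table.
#' @export
dedup <- function(junctions, params = filter_params()) {
  if (!nrow(junctions)) return(junctions)
  if (!"read_start" %in% names(junctions))
    stop("junction table missing column: read_start")
  w <- params$dedup_read_start_window
  key <- paste(junctions$chrom, junctions$position, junctions$strand,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(junctions)), key), function(idx) {
    rs <- junctions$read_start[idx]
    ord <- order(rs, junctions$read_id[idx])
    idx <- idx[ord]; rs <- rs[ord]
    anchor <- rs[1L]
    survivors <- idx[1L]
    for (i in seq_along(idx)[-1L]) {
      if (rs[i] - anchor >= w) {
        survivors <- c(survivors, idx[i])
        anchor <- rs[i]
      }
    }
    survivors
  }), use.names = FALSE)
  out <- junctions[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove bait-ligation artifacts at HaeIII cut positions
#'
#' HTGTS libraries are prepared by HaeIII digestion, so random HaeIII
#' restriction fragments can ligate directly to the bait break site and
#' masquerade as junctions. Junctions at (or within `haeiii_window` bp
#' of) a listed HaeIII blunt-cut position are removed.
#'
#' @param junctions Junction table.
#' @param genome A [genome_model()] carrying `haeiii_sites`.
#' @param params A [filter_params()].
#' @return Filtered junction table.
#' @export
remove_ligation_artifacts <- function(junctions, genome,
                                      params = filter_params()) {
  if (!nrow(junctions)) return(junctions)
  w <- params$haeiii_window
  is_artifact <- vapply(seq_len(nrow(junctions)), function(i) {
    sites <- genome$haeiii_sites[[junctions$chrom[i]]]
    if (is.null(sites) || !length(sites)) return(FALSE)
    if (w == 0) junctions$position[i] %in% sites
    else min(abs(sites - junctions$position[i])) <= w
  }, logical(1))
  out <- junctions[!is_artifact, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full junction-calling cascade
#'
#' Applies, in order: primer-anchor filtering, alignment-validity
#' filtering, junction calling from the 5' end of the aligned read,
#' PCR-repeat collapsing, and HaeIII ligation-artifact removal. The
#' order is fixed; each stage is a pure subset operation on its input.
#'
#' @param records Raw alignment table (one demultiplexed library).
#' @param genome A [genome_model()].
#' @param params A [filter_params()].
#' @return Clean junction table.
#' @export
call_junctions <- function(records, genome, params = filter_params()) {
  records <- filter_reads(records)
  records <- filter_alignments(records, params)
  junctions <- call_junction(records)
  junctions <- dedup(junctions, params)
  remove_ligation_artifacts(junctions, genome, params)
}

# -- I/O ---------------------------------------------------------------

#' Read and write junction tables
#'
#' Junctions are written as BED6 (chrom, start, end = start + 1, name =
#' read_id, score 0, strand; 0-based half-open) with a sidecar TSV
#' carrying `read_start`, `prey_retained_side` and any provenance
#' columns, keyed by read_id.
#'
#' @param junctions Junction table.
#' @param path BED output path; the sidecar is written to
#'   `paste0(path, ".meta.tsv")`.
#' @return `write_junctions_bed` returns `path` invisibly;
#'   `read_junctions_bed` returns the junction table.
#' @export
write_junctions_bed <- function(junctions, path) {
  bed <- data.frame(chrom = junctions$chrom, start = junctions$position,
                    end = junctions$position + 1,
                    name = junctions$read_id, score = 0,
                    strand = junctions$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- junctions[, setdiff(names(junctions),
                              c("chrom", "position", "strand")),
                    drop = FALSE]
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_bed
#' @export
read_junctions_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")
  out <- data.frame(read_id = bed$name, chrom = bed$chrom,
                    position = bed$start, strand = bed$strand,
                    stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    out <- merge(out, meta, by = "read_id", sort = FALSE)
  }
  out
}

#' Read and write alignment tables as TSV
#'
#' @param records Alignment table.
#' @param path TSV path with a header row of the alignment-record
#'   columns.
#' @return `read_alignment_tsv` returns the table;
#'   `write_alignment_tsv` returns `path` invisibly.
#' @export
write_alignment_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
read_alignment_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Import PSL alignments into the alignment-record schema
#'
#' Maps the standard 21-column PSL layout (matches, misMatches, qNumInsert,
#' qBaseInsert, tNumInsert, tBaseInsert, strand, qStart, tStart, tEnd,
#' blockSizes, ...) onto the cascade's columns. `primer_anchor_ok` is
#' set TRUE (PSL carries no primer information) and per-read ambiguity
#' statistics are derived from repeated query names.
#'
#' @param path PSL file path (no header lines).
#' @return Alignment table.
#' @export
read_psl <- function(path) {
  psl <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(psl) < 17L) stop("not a PSL file: ", path)
  names(psl)[1:17] <- c("matches", "mismatches", "rep_matches", "n_count",
                        "q_num_insert", "q_base_insert", "t_num_insert",
                        "t_base_insert", "strand", "q_name", "q_size",
                        "q_start", "q_end", "t_name", "t_size", "t_start",
                        "t_end")
  gap_opens <- psl$q_num_insert + psl$t_num_insert
  max_gap <- pmax(psl$q_base_insert, psl$t_base_insert)
  score <- psl$matches - psl$mismatches - gap_opens
  n_aln <- stats::ave(score, psl$q_name, FUN = length)
  second_diff <- stats::ave(score, psl$q_name, FUN = function(s) {
    if (length(s) < 2L) Inf else {
      o <- sort(s, decreasing = TRUE); o[1L] - o[2L]
    }
  })
  data.frame(read_id = psl$q_name, barcode = NA_character_,
             primer_anchor_ok = TRUE, chrom = psl$t_name,
             strand = substr(psl$strand, 1L, 1L),
             aln_start = psl$t_start, aln_end = psl$t_end,
             read_start = psl$q_start, matches = psl$matches,
             mismatches = psl$mismatches, gap_opens = gap_opens,
             max_gap_len = max_gap, n_alignments_for_read = n_aln,
             second_best_score_diff = second_diff,
             stringsAsFactors = FALSE)
}
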