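#' Island-calling parameters
#'
#' Parameters of the window/gap island clustering used for candidate
#' hotspot detection, following SICER-style defaults for human data:
#' 500-bp windows, 2000-bp gaps, e-value 10, redundancy 1, effective
#' genome fraction 0.74. `fdr` is recorded for completeness; it only
#' applies when a control library is supplied, which this pipeline does
#' not use (the e-value path is operative).
#'
#' @param window Window size in bp.
#' @param gap Maximum gap (bp) of ineligible territory bridged within
#'   one island; must be a multiple of `window`.
#' @param fdr Recorded control-library FDR (inert here).
#' @param e_value Expected number of background islands tolerated
#'   genome-wide; calibrates the island score threshold.
#' @param redundancy Maximum junctions retained per exact
#'   (position, strand).
#' @param effective_genome_fraction Mappable fraction of the genome.
#' @param window_p0 Window eligibility p-value: a window is eligible
#'   when its junction count has upper-tail Poisson probability below
#'   this under the genome-wide background rate.
#' @return A list of class `island_params`.
#' @export
island_params <- function(window = 500, gap = 2000, fdr = 0.01,
                          e_value = 10, redundancy = 1,
                          effective_genome_fraction = 0.74,
                          window_p0 = 0.2) {
  stopifnot(window > 0, gap >= 0, gap %% window == 0,
            effective_genome_fraction > 0, effective_genome_fraction <= 1,
            window_p0 > 0, window_p0 <= 1, redundancy >= 1)
  structure(list(window = window, gap = gap, fdr = fdr,
                 e_value = e_value, redundancy = redundancy,
                 effective_genome_fraction = effective_genome_fraction,
                 window_p0 = window_p0),
            class = "island_params")
}

#' Hotspot refinement parameters
#'
#' @param bait_exclusion Half-width (bp) of the region around the bait
#'   DSB whose candidates are discarded (junctions there reflect
#'   bait-proximal rejoining, not genuine hotspots).
#' @param min_junctions Minimum junction count of a hotspot (candidates
#'   with fewer than this are dropped).
#' @param flank_multiple Local background is measured over flanks of
#'   this multiple of the hotspot length on each side.
#' @param adjusted_p_max Bonferroni-adjusted local Poisson p-value
#'   significance level.
#' @return A list of class `refine_params`.
#' @export
refine_params <- function(bait_exclusion = 2e6, min_junctions = 5,
                          flank_multiple = 5, adjusted_p_max = 0.01) {
  stopifnot(bait_exclusion > 0, min_junctions > 0, flank_multiple > 0,
            adjusted_p_max > 0)
  structure(list(bait_exclusion = bait_exclusion,
                 min_junctions = min_junctions,
                 flank_multiple = flank_multiple,
                 adjusted_p_max = adjusted_p_max),
            class = "refine_params")
}

#' Cap junction redundancy
#'
#' Keeps at most `redundancy` junctions per exact (chrom, position,
#' strand), in input order.
#'
#' @param junctions Junction table.
#' @param redundancy Cap per exact position/strand.
#' @return Capped junction table.
#' @export
cap_redundancy <- function(junctions, redundancy = 1) {
  if (!nrow(junctions)) return(junctions)
  key <- paste(junctions$chrom, junctions$position, junctions$strand,
               sep = "\r")
  keep <- stats::ave(seq_along(key), key, FUN = seq_along) <= redundancy
  out <- junctions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_island_table <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             junction_count = integer(), island_score = numeric(),
             plus = integer(), minus = integer(),
             stringsAsFactors = FALSE)
}

# islands from per-window counts of one chromosome; returns a data.frame
# of (win_start_idx, win_end_idx, score) using eligible-window trimming
islands_from_counts <- function(counts, k_min, gap_windows, lambda_w) {
  eligible <- which(counts >= k_min)
  if (!length(eligible))
    return(data.frame(first = integer(), last = integer(),
                      score = numeric()))
  grp <- cumsum(c(1L, diff(eligible) > gap_windows + 1L))
  win_score <- -stats::dpois(counts[eligible], lambda_w, log = TRUE)
  idx <- split(seq_along(eligible), factor(grp, levels = unique(grp)))
  data.frame(
    first = vapply(idx, function(i) eligible[i[1L]], integer(1)),
    last = vapply(idx, function(i) eligible[i[length(i)]], integer(1)),
    score = vapply(idx, function(i) sum(win_score[i]), numeric(1)),
    row.names = NULL)
}

# e-value score threshold: smallest score s such that the mean number of
# Monte-Carlo background islands scoring >= s is <= e_value
mc_score_threshold <- function(n_windows_per_chrom, k_min, gap_windows,
                               lambda_w, e_value, n_mc = 20) {
  scores <- numeric()
  for (i in seq_len(n_mc)) {
    for (nw in n_windows_per_chrom) {
      counts <- stats::rpois(nw, lambda_w)
      isl <- islands_from_counts(counts, k_min, gap_windows, lambda_w)
      scores <- c(scores, isl$score)
    }
  }
  m <- floor(e_value * n_mc)
  if (length(scores) <= m) return(-Inf)
  sort(scores, decreasing = TRUE)[m + 1L]
}

#' Call candidate junction islands against the genome-wide background
#'
#' Tiles each chromosome into fixed windows, computes the genome-wide
#' background rate per window `lambda_w = N * window /
#' (effective_genome_fraction * G)`, marks windows eligible when their
#' junction count is improbably high under `Poisson(lambda_w)` (upper
#' tail below `window_p0`), links eligible windows separated by at most
#' `gap` of ineligible territory into islands (trimmed to eligible
#' ends), scores each island as the sum over its eligible windows of
#' `-ln P(X = count)`, and retains islands scoring above a Monte-Carlo
#' calibrated threshold chosen so that the expected number of background
#' islands passing is at most `e_value`.
#'
#' @param junctions Deduplicated junction table; redundancy capping is
#'   applied internally.
#' @param genome A [genome_model()].
#' @param params An [island_params()].
#' @param seed Seed for the Monte-Carlo calibration.
#' @param n_mc Number of Monte-Carlo background genomes (>= 20).
#' @return Candidate hotspot table: `chrom`, `start`, `end`,
#'   `junction_count`, `island_score`, `plus`, `minus`.
#' @export
call_islands <- function(junctions, genome, params = island_params(),
                         seed = NULL, n_mc = 20) {
  junctions <- cap_redundancy(junctions, params$redundancy)
  if (!nrow(junctions)) return(empty_island_table())
  unknown <- setdiff(unique(junctions$chrom), names(genome$chromosomes))
  if (length(unknown))
    stop("junctions on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  w <- params$window
  gap_windows <- params$gap / w
  N <- nrow(junctions)
  G <- sum(genome$chromosomes)
  lambda_w <- N * w / (params$effective_genome_fraction * G)
  # smallest count k with P(X >= k; lambda_w) < window_p0
  k_min <- 0L
  while (stats::ppois(k_min - 1L, lambda_w, lower.tail = FALSE) >=
         params$window_p0)
    k_min <- k_min + 1L
  n_windows <- ceiling(genome$chromosomes / w)
  thr <- mc_score_threshold(n_windows, k_min, gap_windows, lambda_w,
                            params$e_value, n_mc)
  out <- list()
  for (chrom in names(genome$chromosomes)) {
    jc <- junctions[junctions$chrom == chrom, , drop = FALSE]
    if (!nrow(jc)) next
    nw <- n_windows[[chrom]]
    win <- floor(jc$position / w) + 1L
    counts <- tabulate(win, nbins = nw)
    isl <- islands_from_counts(counts, k_min, gap_windows, lambda_w)
    isl <- isl[isl$score > thr, , drop = FALSE]
    if (!nrow(isl)) next
    start <- (isl$first - 1L) * w
    end <- pmin(isl$last * w, genome$chromosomes[[chrom]])
    cnt <- plus <- minus <- integer(nrow(isl))
    for (i in seq_len(nrow(isl))) {
      inside <- jc$position >= start[i] & jc$position < end[i]
      cnt[i] <- sum(inside)
      plus[i] <- sum(inside & jc$strand == "+")
      minus[i] <- sum(inside & jc$strand == "-")
    }
    out[[chrom]] <- data.frame(chrom = chrom, start = start, end = end,
                               junction_count = cnt,
                               island_score = isl$score,
                               plus = plus, minus = minus,
                               stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_island_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# subtract a set of intervals (data.frame start/end) from one segment
subtract_intervals <- function(seg_start, seg_end, cut) {
  segs <- data.frame(start = seg_start, end = seg_end)
  if (!is.null(cut) && nrow(cut)) {
    cut <- cut[order(cut$start), , drop = FALSE]
    for (i in seq_len(nrow(cut))) {
      new <- list()
      for (j in seq_len(nrow(segs))) {
        s <- segs$start[j]; e <- segs$end[j]
        cs <- cut$start[i]; ce <- cut$end[i]
        if (ce <= s || cs >= e) {
          new[[length(new) + 1L]] <- c(s, e)
        } else {
          if (cs > s) new[[length(new) + 1L]] <- c(s, cs)
          if (ce < e) new[[length(new) + 1L]] <- c(ce, e)
        }
      }
      segs <- if (length(new))
        as.data.frame(do.call(rbind, new)) else
          data.frame(V1 = numeric(), V2 = numeric())
      names(segs) <- c("start", "end")
    }
  }
  segs[segs$end > segs$start, , drop = FALSE]
}

#' Refine candidate hotspots with exclusion rules and a local Poisson test
#'
#' Applies the three elimination rules: (1) candidates within the bait
#' exclusion region are discarded; (2) candidates with fewer than
#' `min_junctions` junctions are discarded (candidates overlapping the
#' genome's off-target blacklist are discarded at this stage too);
#' (3) each remaining candidate of length `L` with `c` junctions is
#' tested against its local background measured over flanks of
#' `flank_multiple * L` on each side (clipped to the chromosome and
#' excluding any other candidate span): `lambda_local =
#' max(flank_count * L / usable_flank_length, lambda_bg * L)`, where
#' `lambda_bg` is the genome-wide per-bp background rate — flooring
#' the local estimate at the global background (as peak callers such
#' as MACS2 do) stops downward flank fluctuations around
#' score-selected candidates from fabricating enrichment. Then
#' `p_local = P(X >= c; lambda_local)`, Bonferroni-adjusted by the
#' number of windows scanned genome-wide (the multiplicity of the
#' screen that nominated the candidates); kept when the adjusted
#' p-value is at most `adjusted_p_max`. A candidate with no usable
#' flank is tested against the background floor alone.
#'
#' @param candidates Candidate table from [call_islands()].
#' @param junctions The junction table used for island calling
#'   (redundancy capping is re-applied internally).
#' @param genome A [genome_model()] (bait and blacklist are read from
#'   it).
#' @param params A [refine_params()].
#' @param island Island parameters (for redundancy and the genome-wide
#'   fallback rate).
#' @return Refined hotspot table with `p_local`, `p_adjusted`,
#'   `strand_bias` and `gene_id` (NA until [merge_by_gene()]) columns.
#' @export
refine_hotspots <- function(candidates, junctions, genome,
                            params = refine_params(),
                            island = island_params()) {
  junctions <- cap_redundancy(junctions, island$redundancy)
  cand <- candidates
  if (!nrow(cand)) return(annotate_hotspot_columns(cand))
  # rule 1: bait exclusion region
  if (!is.null(genome$bait)) {
    b <- genome$bait
    drop1 <- cand$chrom == b$chrom &
      intervals_overlap(cand$start, cand$end,
                        b$position - params$bait_exclusion,
                        b$position + params$bait_exclusion)
    cand <- cand[!drop1, , drop = FALSE]
  }
  # rule 2: junction number < min_junctions; off-target blacklist
  cand <- cand[cand$junction_count >= params$min_junctions, , drop = FALSE]
  bl <- genome$offtarget_blacklist
  if (nrow(cand) && !is.null(bl) && nrow(bl)) {
    hit <- vapply(seq_len(nrow(cand)), function(i) {
      any(bl$chrom == cand$chrom[i] &
            intervals_overlap(cand$start[i], cand$end[i],
                              bl$start, bl$end))
    }, logical(1))
    cand <- cand[!hit, , drop = FALSE]
  }
  if (!nrow(cand)) return(annotate_hotspot_columns(cand))
  # rule 3: local Poisson enrichment. Bonferroni multiplicity is the
  # genome-wide window scan (candidates are score-selected maxima, so
  # adjusting only over survivors does not control the family-wise
  # error of the screen)
  n_cand <- nrow(cand)
  G <- sum(genome$chromosomes)
  n_tests <- sum(ceiling(genome$chromosomes / island$window))
  rate_bp <- nrow(junctions) / (island$effective_genome_fraction * G)
  p_local <- numeric(n_cand)
  for (i in seq_len(n_cand)) {
    L <- cand$end[i] - cand$start[i]
    chrom_len <- genome$chromosomes[[cand$chrom[i]]]
    fl <- params$flank_multiple * L
    others <- candidates[candidates$chrom == cand$chrom[i] &
                           !(candidates$start == cand$start[i] &
                               candidates$end == cand$end[i]),
                         c("start", "end"), drop = FALSE]
    segs <- rbind(
      subtract_intervals(max(0, cand$start[i] - fl), cand$start[i], others),
      subtract_intervals(cand$end[i], min(chrom_len, cand$end[i] + fl),
                         others))
    usable <- sum(segs$end - segs$start)
    lambda_flank <- 0
    if (usable > 0) {
      jc <- junctions[junctions$chrom == cand$chrom[i], , drop = FALSE]
      flank_count <- 0L
      for (j in seq_len(nrow(segs)))
        flank_count <- flank_count +
          sum(jc$position >= segs$start[j] & jc$position < segs$end[j])
      lambda_flank <- flank_count * L / usable
    }
    lambda_local <- max(lambda_flank, rate_bp * L)
    p_local[i] <- stats::ppois(cand$junction_count[i] - 1L, lambda_local,
                               lower.tail = FALSE)
  }
  cand$p_local <- p_local
  cand$p_adjusted <- pmin(1, p_local * n_tests)
  cand <- cand[cand$p_adjusted <= params$adjusted_p_max, , drop = FALSE]
  annotate_hotspot_columns(cand)
}

annotate_hotspot_columns <- function(hotspots) {
  if (!"p_local" %in% names(hotspots)) hotspots$p_local <- numeric(0)
  if (!"p_adjusted" %in% names(hotspots))
    hotspots$p_adjusted <- numeric(0)
  hotspots$gene_id <- rep(NA_character_, nrow(hotspots))
  hotspots$strand_bias <- if (nrow(hotspots))
    strand_bias_score(hotspots$plus /
                        (hotspots$plus + hotspots$minus)) else numeric(0)
  rownames(hotspots) <- NULL
  hotspots
}

# gene with the largest overlap of [start, end), or NA
assign_gene <- function(genome, chrom, start, end) {
  best <- NA_character_; best_ov <- 0
  for (g in genome$genes) {
    if (g$chrom != chrom) next
    ov <- min(end, g$tx_end) - max(start, g$tx_start)
    if (ov > best_ov) { best_ov <- ov; best <- g$gene_id }
  }
  best
}

#' Merge refined hotspots lying in the same gene
#'
#' Each hotspot is assigned to the overlapping gene with the largest
#' overlap; hotspots sharing a gene merge into one spanning interval
#' with summed junction and strand counts (strand bias recomputed, the
#' smallest adjusted p-value retained). Gene-less hotspots pass through.
#'
#' @param hotspots Refined hotspot table.
#' @param genome A [genome_model()].
#' @return Hotspot table with `gene_id` filled and same-gene rows
#'   merged.
#' @export
merge_by_gene <- function(hotspots, genome) {
  if (!nrow(hotspots)) return(hotspots)
  hotspots$gene_id <- vapply(seq_len(nrow(hotspots)), function(i)
    assign_gene(genome, hotspots$chrom[i], hotspots$start[i],
                hotspots$end[i]), character(1))
  keyed <- !is.na(hotspots$gene_id)
  merged <- lapply(split(hotspots[keyed, , drop = FALSE],
                         hotspots$gene_id[keyed]), function(h) {
    data.frame(chrom = h$chrom[1L], start = min(h$start),
               end = max(h$end),
               junction_count = sum(h$junction_count),
               island_score = sum(h$island_score),
               plus = sum(h$plus), minus = sum(h$minus),
               p_local = min(h$p_local), p_adjusted = min(h$p_adjusted),
               gene_id = h$gene_id[1L],
               strand_bias = strand_bias_score(sum(h$plus) /
                                                 sum(h$plus + h$minus)),
               stringsAsFactors = FALSE)
  })
  cols <- c("chrom", "start", "end", "junction_count", "island_score",
            "plus", "minus", "p_local", "p_adjusted", "gene_id",
            "strand_bias")
  out <- rbind(do.call(rbind, c(merged, list(make.row.names = FALSE))),
               hotspots[!keyed, cols, drop = FALSE])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Entropy strand-bias score
#'
#' `strand_bias_score(p)` evaluates the binary entropy
#' `S = -p log2(p) - (1 - p) log2(1 - p)` (with `0 log2 0 := 0`) of a
#' plus-strand fraction `p`; `strand_bias(junctions)` computes it from
#' a hotspot's junction table. `S = 1` means no strand bias (equal
#' plus/minus), `S = 0` means 100% strand-biased.
#'
#' @param p Plus-strand fraction(s) in `[0, 1]`.
#' @return Score(s) in `[0, 1]`.
#' @export
strand_bias_score <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(x) ifelse(x == 0, 0, -x * log2(x))
  term(p) + term(1 - p)
}

#' @rdname strand_bias_score
#' @param junctions Junction table with a `strand` column (at least one
#'   row).
#' @export
strand_bias <- function(junctions) {
  if (!nrow(junctions)) stop("empty hotspot: strand bias undefined")
  strand_bias_score(mean(junctions$strand == "+"))
}

#' Read and write hotspot tables
#'
#' Hotspots are written as BED6+ (chrom, start, end, name, score =
#' junction count, strand ".") with extra columns `junction_count`,
#' `island_score`, `p_local`, `p_adjusted`, `gene_id`, `plus`, `minus`,
#' `strand_bias`, header included.
#'
#' @param hotspots Hotspot table.
#' @param path Output TSV path.
#' @return `write_hotspots_tsv` returns `path` invisibly;
#'   `read_hotspots_tsv` returns the table.
#' @export
write_hotspots_tsv <- function(hotspots, path) {
  utils::write.table(hotspots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hotspots_tsv
#' @export
read_hotspots_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
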