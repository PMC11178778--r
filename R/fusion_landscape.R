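#' Keep fusions with validated mRNA junction positions
#'
#' @param table Fusion table with a logical `validated` column.
#' @return Rows with `validated = TRUE`.
#' @export
filter_validated <- function(table) {
  out <- table[as.logical(table$validated), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage with half-up rounding at a printed precision
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals`
#' places (so 81.25 at 0 decimals prints 81, 2.597 at 1 decimal prints
#' 2.6), matching how fusion-landscape percentages are reported.
#'
#' @param numerator,denominator Counts (`denominator > 0`).
#' @param decimals Decimal places.
#' @return Rounded percentage.
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  floor(x * 10^decimals + 0.5) / 10^decimals
}

#' Partner-gene frequency for one kinase
#'
#' @param table Fusion table.
#' @param kinase_gene Kinase gene symbol.
#' @return Data frame (`partner_gene`, `count`, `fraction`) sorted by
#'   decreasing count; fractions sum to 1.
#' @export
partner_frequency <- function(table, kinase_gene) {
  rows <- table[table$kinase_gene == kinase_gene, , drop = FALSE]
  if (!nrow(rows))
    return(data.frame(partner_gene = character(), count = integer(),
                      fraction = numeric()))
  cnt <- sort(table(rows$partner_gene), decreasing = TRUE)
  data.frame(partner_gene = names(cnt), count = as.integer(cnt),
             fraction = as.integer(cnt) / nrow(rows),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partner sharing across kinase genes
#'
#' A partner gene is shared when it fuses with at least two distinct
#' kinase genes (a partner recurring with one kinase across tissues
#' counts once). The shared fraction is over distinct partner genes.
#'
#' @param table Fusion table.
#' @return List with `n_partners_total`, `n_shared`, `shared_fraction`
#'   (a half-up percentage at 1 decimal), and `partner_kinases`, a
#'   named list of the kinase set per partner.
#' @export
partner_sharing <- function(table) {
  pk <- lapply(split(table$kinase_gene, table$partner_gene),
               function(k) sort(unique(k)))
  n_total <- length(pk)
  n_shared <- sum(vapply(pk, length, integer(1)) >= 2L)
  list(n_partners_total = n_total, n_shared = n_shared,
       shared_fraction = if (n_total) percent(n_shared, n_total, 1)
       else NA_real_,
       partner_kinases = pk)
}

#' Exon-usage distribution of a gene in fusions
#'
#' @param table Fusion table.
#' @param gene Gene symbol.
#' @param role `"kinase"` (tally `kinase_exon` of rows where the gene
#'   is the kinase) or `"partner"` (tally `partner_exon`).
#' @return Data frame (`exon`, `count`, `percentage`) with half-up
#'   percentages at 1 decimal; counts sum to the gene's row count.
#' @export
exon_usage <- function(table, gene, role = c("kinase", "partner")) {
  role <- match.arg(role)
  rows <- if (role == "kinase")
    table[table$kinase_gene == gene, , drop = FALSE]
  else table[table$partner_gene == gene, , drop = FALSE]
  if (!nrow(rows)) stop("gene ", gene, " does not occur in role ", role)
  ex <- if (role == "kinase") rows$kinase_exon else rows$partner_exon
  cnt <- table(ex)
  data.frame(exon = as.integer(names(cnt)), count = as.integer(cnt),
             percentage = percent(as.integer(cnt), nrow(rows), 1),
             row.names = NULL)
}

#' Fraction of hotspots falling in known fusion-partner genes
#'
#' @param hotspots Hotspot table with a `gene_id` column (NA for
#'   intergenic hotspots).
#' @param known_partners Character vector of partner gene symbols.
#' @param decimals Decimal places of the reported percentage.
#' @return List with `n_in_partners`, `n_total`, `fraction`.
#' @export
hotspot_partner_overlap <- function(hotspots, known_partners,
                                    decimals = 1) {
  n_total <- nrow(hotspots)
  n_in <- sum(!is.na(hotspots$gene_id) &
                hotspots$gene_id %in% known_partners)
  list(n_in_partners = n_in, n_total = n_total,
       fraction = if (n_total) percent(n_in, n_total, decimals) else
         NA_real_)
}

#' Read and write fusion tables as CSV
#'
#' Header: `sample_id, tissue, kinase_gene, partner_gene, kinase_exon,
#' partner_exon, validated`.
#'
#' @param table Fusion table.
#' @param path CSV path.
#' @return `read_fusion_csv` returns the table; `write_fusion_csv`
#'   returns `path` invisibly.
#' @export
write_fusion_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fusion_csv
#' @export
read_fusion_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
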