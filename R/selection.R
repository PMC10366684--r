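#' Select and rank candidate germline promoters
#'
#' Combines the expression and annotation inputs: computes each gene's
#' germline TPM and relative germline fraction, extracts its promoter region,
#' and keeps candidates passing all thresholds. Genes whose promoter cannot
#' be defined (no upstream protein-coding neighbor, or an overlapping
#' neighbor) are dropped silently: they are not designable under this
#' promoter definition.
#'
#' The thresholds on absolute and relative germline expression have no
#' canonical values; the defaults (TPM >= 100, fraction >= 0.4) are exposed
#' and documented rather than hard-coded deep in the pipeline. The length
#' cut-off is inclusive: a promoter of exactly `max_length_bp` is kept.
#'
#' Ranking key: relative germline fraction (descending), then germline TPM
#' (descending), ties broken lexicographically by `gene_id`, so results are
#' deterministic and independent of input row order.
#'
#' @param table A `tissue_expression` table.
#' @param ann A `gene_annotation` data frame sharing identifiers with `table`.
#' @param min_germline_tpm Minimum absolute germline TPM (default 100).
#' @param min_fraction Minimum relative germline fraction (default 0.4).
#' @param max_length_bp Maximum promoter length in bp, inclusive
#'   (default 1000).
#' @param n_top Optional cap on the number of returned candidates.
#' @return Data frame of candidates, one per row, with region coordinates,
#'   `length_bp`, `germline_tpm`, `relative_germline_fraction`,
#'   `adjacent_gene_id` and `adjacent_boundary`, sorted by the ranking key.
#' @export
select_candidates <- function(table, ann,
                              min_germline_tpm = 100,
                              min_fraction = 0.4,
                              max_length_bp = 1000,
                              n_top = NULL) {
  stopifnot(inherits(table, "tissue_expression"), inherits(ann, "gene_annotation"))
  shared <- intersect(table$gene_id, ann$gene_id)
  if (!length(shared))
    pf_stop("load", "expression table and annotation share no gene identifiers")

  fr <- tissue_fractions(table)
  keep <- table$gene_id %in% shared &
    !is.na(fr$germline) &
    table$germline >= min_germline_tpm &
    fr$germline >= min_fraction
  ids <- table$gene_id[keep]

  rows <- lapply(ids, function(g) {
    reg <- tryCatch(extract_promoter_region(ann, g),
                    promforge_no_neighbor = function(e) NULL,
                    promforge_overlap = function(e) NULL)
    if (is.null(reg) || reg$length_bp > max_length_bp || reg$length_bp == 0L)
      return(NULL)
    reg$germline_tpm <- table$germline[match(g, table$gene_id)]
    reg$relative_germline_fraction <- fr$germline[match(g, fr$gene_id)]
    reg
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      length_bp = integer(), adjacent_gene_id = character(),
                      adjacent_boundary = character(), germline_tpm = numeric(),
                      relative_germline_fraction = numeric(),
                      stringsAsFactors = FALSE)
  }
  ord <- order(-out$relative_germline_fraction, -out$germline_tpm, out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(n_top)) out <- head(out, n_top)
  out
}
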