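#' The fixed tissue set used for specificity ranking
#'
#' Relative germline expression is always computed over these five major
#' tissues, in this order.
#' @export
TISSUES <- c("germline", "neurons", "intestine", "hypodermis", "muscle")

#' Read a gene-by-tissue TPM table
#'
#' Expects a TSV with header
#' `gene_id<TAB>germline<TAB>neurons<TAB>intestine<TAB>hypodermis<TAB>muscle`.
#' Every gene must have a value for every tissue; missing or negative values
#' are an error at load time, never a silent zero.
#'
#' @param path TSV file.
#' @return A validated `data.frame` (class `tissue_expression`) with one row
#'   per gene.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_tissue_expression(df)
}

#' Validate a data frame as a tissue expression table
#'
#' @param df Data frame with columns `gene_id` and the five [TISSUES].
#' @return The data frame with class `tissue_expression` prepended.
#' @export
as_tissue_expression <- function(df) {
  need <- c("gene_id", TISSUES)
  missing <- setdiff(need, names(df))
  if (length(missing))
    pf_stop("load", "expression table is missing column(s): %s",
            paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    pf_stop("load", "duplicate gene_id in expression table")
  vals <- as.matrix(df[TISSUES])
  if (!is.numeric(vals) || anyNA(vals))
    pf_stop("load", "expression table has missing or non-numeric TPM values")
  if (any(vals < 0))
    pf_stop("load", "expression table has negative TPM values")
  structure(df[need], class = c("tissue_expression", "data.frame"))
}

#' Relative expression of a gene in one tissue
#'
#' A gene's TPM in `tissue` divided by the sum of its TPM over the fixed
#' five-tissue set. A gene with zero expression in all five tissues has no
#' defined fraction and raises a `promforge_undefined_fraction` error.
#'
#' @param table A `tissue_expression` table.
#' @param gene Gene identifier.
#' @param tissue One of [TISSUES] (default `"germline"`).
#' @return Numeric fraction in `[0, 1]`.
#' @export
#' @examples
#' tab <- as_tissue_expression(data.frame(
#'   gene_id = "g1", germline = 50, neurons = 12.5, intestine = 12.5,
#'   hypodermis = 12.5, muscle = 12.5))
#' relative_tissue_fraction(tab, "g1")  # 0.5
relative_tissue_fraction <- function(table, gene, tissue = "germline") {
  tissue <- match.arg(tissue, TISSUES)
  i <- match(gene, table$gene_id)
  if (is.na(i)) pf_stop("missing_gene", "gene '%s' not in expression table", gene)
  tot <- sum(as.numeric(table[i, TISSUES]))
  if (tot == 0)
    pf_stop("undefined_fraction",
            "gene '%s' has zero TPM in all five tissues; fraction undefined", gene)
  as.numeric(table[i, tissue]) / tot
}

#' Per-gene relative fractions for every tissue
#'
#' Vectorized companion of [relative_tissue_fraction()]: returns, for each
#' gene, its fraction in each of the five tissues (rows sum to 1). Genes with
#' all-zero TPM get `NA` fractions (they cannot satisfy any expression
#' threshold downstream).
#'
#' @param table A `tissue_expression` table.
#' @return Data frame `gene_id` plus one fraction column per tissue.
#' @export
tissue_fractions <- function(table) {
  vals <- as.matrix(table[TISSUES])
  tot <- rowSums(vals)
  frac <- sweep(vals, 1, tot, "/")
  frac[tot == 0, ] <- NA_real_
  cbind(data.frame(gene_id = table$gene_id, stringsAsFactors = FALSE),
        as.data.frame(frac))
}
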