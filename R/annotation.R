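#' Build a validated gene annotation table
#'
#' The annotation is a plain data frame with one row per gene and 0-based
#' half-open coordinates of the *coding span* (start codon through stop
#' codon). GFF3 input (1-based closed) is converted at the boundary by
#' [read_gene_annotation()].
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `is_protein_coding`
#'   (logical); optional `trans_spliced`.
#' @param chrom_lengths Optional named integer vector; when given, coordinates
#'   are checked against chromosome lengths.
#' @return Data frame of class `gene_annotation`.
#' @export
as_gene_annotation <- function(df, chrom_lengths = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "is_protein_coding")
  missing <- setdiff(need, names(df))
  if (length(missing))
    pf_stop("load", "annotation is missing column(s): %s",
            paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id)) pf_stop("load", "duplicate gene_id in annotation")
  if (!all(df$strand %in% c("+", "-")))
    pf_stop("load", "annotation strand must be '+' or '-'")
  if (any(df$start >= df$end))
    pf_stop("load", "annotation has intervals with start >= end")
  if (any(df$start < 0)) pf_stop("load", "annotation has negative coordinates")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$chrom]
    if (anyNA(len) || any(df$end > len))
      pf_stop("load", "annotation coordinates exceed chromosome lengths")
  }
  if (is.null(df$trans_spliced)) df$trans_spliced <- NA
  rownames(df) <- NULL
  structure(df[c(need, "trans_spliced")],
            class = c("gene_annotation", "data.frame"))
}

#' Read gene annotation from GFF3
#'
#' Imports `gene` features via [rtracklayer::import()], keeps their biotype
#' (attribute key configurable, matching common GFF3 dialects) and converts
#' to the internal 0-based half-open convention. The gene interval is taken
#' as the coding span; annotations where the gene feature extends beyond the
#' CDS (UTRs) should be reduced to CDS spans upstream of this reader.
#'
#' @param path GFF3 file.
#' @param fasta Optional genome FASTA used to validate coordinates.
#' @param biotype_attr GFF3 attribute holding the biotype
#'   (default `"biotype"`).
#' @return A `gene_annotation` data frame.
#' @export
read_gene_annotation <- function(path, fasta = NULL, biotype_attr = "biotype") {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  md <- S4Vectors::mcols(gr)
  biotype <- if (biotype_attr %in% names(md)) as.character(md[[biotype_attr]])
             else rep("protein_coding", length(gr))
  gene_id <- if ("ID" %in% names(md)) as.character(md$ID)
             else as.character(md$Name)
  ts <- if ("trans_spliced" %in% names(md))
    as.logical(md$trans_spliced) else NA
  chrom_lengths <- NULL
  if (!is.null(fasta)) {
    g <- read_fasta(fasta)
    chrom_lengths <- setNames(nchar(g), names(g))
  }
  as_gene_annotation(data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GFF3 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_protein_coding = biotype == "protein_coding",
    trans_spliced = ts,
    stringsAsFactors = FALSE
  ), chrom_lengths = chrom_lengths)
}

#' Write gene annotation to GFF3
#'
#' Inverse of [read_gene_annotation()]; used by the synthetic-data module.
#'
#' @param ann A `gene_annotation` data frame.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$type <- "gene"
  gr$source <- "promforge"
  gr$ID <- ann$gene_id
  gr$biotype <- ifelse(ann$is_protein_coding, "protein_coding", "ncRNA")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract a candidate gene's promoter region
#'
#' The promoter is the intergenic interval from the nearest *upstream*
#' protein-coding neighbor's proximal coding boundary up to (and excluding)
#' the candidate's start codon. Upstream means 5' of the start codon on the
#' candidate's strand. Non-coding genes are skipped when searching for the
#' neighbor. The adjacent boundary is the neighbor's stop codon when the two
#' genes are tandem (same strand) and its start codon when they are
#' head-to-head (opposite strand).
#'
#' @param ann A `gene_annotation` data frame.
#' @param gene Candidate gene identifier.
#' @return One-row data frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `length_bp`, `adjacent_gene_id`,
#'   `adjacent_boundary` (`"start_codon"` or `"stop_codon"`).
#' @export
extract_promoter_region <- function(ann, gene) {
  i <- match(gene, ann$gene_id)
  if (is.na(i)) pf_stop("missing_gene", "gene '%s' not in annotation", gene)
  cand <- ann[i, ]
  same <- ann[ann$chrom == cand$chrom & ann$gene_id != gene &
                ann$is_protein_coding, , drop = FALSE]
  if (cand$strand == "+") {
    up <- same[same$end <= cand$start, , drop = FALSE]
    overlapping <- same[same$start < cand$start & same$end > cand$start, , drop = FALSE]
    if (nrow(overlapping))
      pf_stop("overlap", "coding span of '%s' overlaps candidate '%s' start codon",
              overlapping$gene_id[1], gene)
    if (!nrow(up))
      pf_stop("no_neighbor", "no upstream protein-coding neighbor for '%s'", gene)
    nb <- up[which.max(up$end), ]
    region <- c(nb$end, cand$start)
  } else {
    up <- same[same$start >= cand$end, , drop = FALSE]
    overlapping <- same[same$start < cand$end & same$end > cand$end, , drop = FALSE]
    if (nrow(overlapping))
      pf_stop("overlap", "coding span of '%s' overlaps candidate '%s' start codon",
              overlapping$gene_id[1], gene)
    if (!nrow(up))
      pf_stop("no_neighbor", "no upstream protein-coding neighbor for '%s'", gene)
    nb <- up[which.min(up$start), ]
    region <- c(cand$end, nb$start)
  }
  data.frame(
    gene_id = gene,
    chrom = cand$chrom,
    start = region[1],
    end = region[2],
    strand = cand$strand,
    length_bp = region[2] - region[1],
    adjacent_gene_id = nb$gene_id,
    adjacent_boundary = if (nb$strand == cand$strand) "stop_codon" else "start_codon",
    stringsAsFactors = FALSE)
}

#' Fetch a promoter region's sequence from the genome
#'
#' Returns the region on the candidate's strand orientation (reverse
#' complemented for minus-strand candidates), so the returned string reads
#' 5' to 3' toward the start codon.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param region One-row region data frame from [extract_promoter_region()].
#' @return Character scalar.
#' @export
promoter_sequence <- function(genome, region) {
  chrom <- genome[[region$chrom]]
  if (is.null(chrom)) pf_stop("load", "chromosome '%s' not in genome", region$chrom)
  s <- substr(chrom, region$start + 1L, region$end)
  if (region$strand == "-") revcomp(s) else s
}
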