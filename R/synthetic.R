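## Synthetic-data generators. Every generator is a pure function of
## (parameters, seed): it runs inside a local RNG scope and records its
## planted ground truth in a `truth` list that serializes to JSON losslessly.

with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Serialize a ground-truth record next to a generated dataset
#'
#' @param truth Truth list from any generator.
#' @param path Output JSON path (conventionally `truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a serialized ground-truth record
#' @param path JSON file written by [write_truth()].
#' @return Truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate a synthetic genome and gene annotation
#'
#' Lays protein-coding genes along one chromosome with controllable
#' intergenic gaps: `n_short` of the inter-gene gaps are drawn from the
#' short range (designable promoters) and the rest from the long range.
#' Strands flip with probability `strand_flip_prob`, so tandem and
#' head-to-head neighbor configurations are both represented. The gene
#' interval is the coding span, so a gene's strand-aware upstream gap IS the
#' promoter length that [extract_promoter_region()] recovers; the truth
#' records exactly the genes whose upstream gap is at most 1000 bp (equal to
#' the `n_short` planted genes whenever `strand_flip_prob = 0`).
#'
#' @param n_genes Number of genes (>= 2).
#' @param intergenic List with `short` and `long` gap ranges (bp) and
#'   `n_short`, the number of genes planted with a short upstream gap.
#' @param strand_flip_prob Probability that a gene's strand differs from its
#'   left neighbor's.
#' @param gene_length Range of coding-span lengths.
#' @param chrom Chromosome name.
#' @param seed RNG seed.
#' @return List `genome` (named character), `annotation`
#'   (`gene_annotation`), `truth` (planted short-gap gene ids, parameters).
#' @export
synth_genome_annotation <- function(n_genes = 50,
                                    intergenic = list(short = c(200, 900),
                                                      long = c(1500, 4000),
                                                      n_short = 10),
                                    strand_flip_prob = 0.3,
                                    gene_length = c(500, 2000),
                                    chrom = "chrI",
                                    seed = 1) {
  if (n_genes < 2) pf_stop("config", "need at least 2 genes")
  if (any(unlist(intergenic[c("short", "long")]) < 0))
    pf_stop("config", "intergenic gaps must be non-negative")
  if (intergenic$n_short > n_genes - 1)
    pf_stop("config", "cannot plant more short gaps than genes with an upstream neighbor")
  with_rng(seed, {
    lens <- sample(gene_length[1]:gene_length[2], n_genes, replace = TRUE)
    # genes 2..n have an upstream gap; choose which are short
    short_idx <- sort(sample(2:n_genes, intergenic$n_short))
    gaps <- sample(intergenic$long[1]:intergenic$long[2], n_genes, replace = TRUE)
    gaps[short_idx] <- sample(intergenic$short[1]:intergenic$short[2],
                              intergenic$n_short, replace = TRUE)
    gaps[1] <- 2000L  # leading margin before the first gene
    strand <- character(n_genes)
    strand[1] <- "+"
    for (i in seq_len(n_genes - 1))
      strand[i + 1] <- if (runif(1) < strand_flip_prob)
        setdiff(c("+", "-"), strand[i]) else strand[i]
    starts <- cumsum(gaps) + cumsum(c(0L, lens[-n_genes]))
    ends <- starts + lens
    genome_len <- ends[n_genes] + 1000L
    genome <- setNames(random_dna(genome_len), chrom)
    ann <- as_gene_annotation(data.frame(
      gene_id = sprintf("gene%03d", seq_len(n_genes)),
      chrom = chrom, start = as.integer(starts), end = as.integer(ends),
      strand = strand, is_protein_coding = TRUE, stringsAsFactors = FALSE))
    # the promoter gap is strand-aware: a plus-strand gene's upstream gap is
    # the gap to its left, a minus-strand gene's is the gap to its right
    # (genes at the chromosome edge have none)
    upstream_gap <- ifelse(strand == "+",
                           c(NA_integer_, as.integer(gaps[-1])),
                           c(as.integer(gaps[-1]), NA_integer_))
    designable <- !is.na(upstream_gap) & upstream_gap <= 1000L
    has_gap <- !is.na(upstream_gap)
    truth <- list(
      planted_short_gap_gene_ids = ann$gene_id[designable],
      upstream_gap_bp = setNames(as.list(upstream_gap[has_gap]),
                                 ann$gene_id[has_gap]),
      strand_flip_prob = strand_flip_prob, n_genes = n_genes,
      intergenic = intergenic, rng_seed = seed)
    list(genome = genome, annotation = ann, truth = truth)
  })
}

#' Generate a tissue TPM table with planted germline enrichment
#'
#' Non-enriched genes express a baseline in every tissue; enriched genes
#' express `enrichment_fold` times the baseline in the germline. Values carry
#' multiplicative lognormal noise with coefficient of variation `noise_cv`
#' (mean-1 parameterization, so `noise_cv = 0` is the exact noiseless limit).
#' With `renormalize = TRUE` (the default, honoring TPM semantics) each
#' tissue column is scaled to one million; the planted relative germline
#' fraction then shifts slightly from the unnormalized analytic value
#' `fold / (fold + 4)` in proportion to the enriched genes' share of total
#' germline expression.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_enriched Number of genes planted as germline-enriched.
#' @param enrichment_fold Germline fold-change of enriched genes.
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param base_tpm Baseline per-tissue expression before renormalization.
#' @param renormalize Scale each tissue column to 1e6?
#' @param seed RNG seed.
#' @return List `table` (`tissue_expression`), `truth`.
#' @export
synth_expression <- function(gene_ids, n_enriched = 5, enrichment_fold = 10,
                             noise_cv = 0.1, base_tpm = 100,
                             renormalize = TRUE, seed = 1) {
  n <- length(gene_ids)
  if (n_enriched > n) pf_stop("config", "n_enriched exceeds the number of genes")
  with_rng(seed, {
    enriched <- sort(sample(gene_ids, n_enriched))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- function(k) if (noise_cv == 0) rep(1, k)
      else rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    vals <- matrix(base_tpm * noise(n * 5L), nrow = n,
                   dimnames = list(NULL, TISSUES))
    is_enr <- gene_ids %in% enriched
    vals[is_enr, "germline"] <- vals[is_enr, "germline"] * enrichment_fold
    if (renormalize) vals <- sweep(vals, 2, colSums(vals), "/") * 1e6
    tab <- as_tissue_expression(cbind(
      data.frame(gene_id = gene_ids, stringsAsFactors = FALSE),
      as.data.frame(vals)))
    truth <- list(enriched_gene_ids = enriched,
                  enrichment_fold = enrichment_fold, noise_cv = noise_cv,
                  base_tpm = base_tpm, renormalized = renormalize,
                  rng_seed = seed)
    list(table = tab, truth = truth)
  })
}

#' Generate a sequence with planted homopolymers and type-IIS sites
#'
#' The background is rejection-sampled until it contains no accidental run of
#' `run_threshold` bp or more and no enzyme site; planted elements are then
#' placed at non-overlapping positions (with clean flanking bases) and the
#' final sequence is verified to contain exactly the planted violations.
#'
#' @param seq_len Sequence length.
#' @param n_runs Number of homopolymer runs to plant.
#' @param run_lengths Length(s) of the planted runs (recycled).
#' @param n_sites Number of enzyme sites to plant.
#' @param site_strands Strand(s) of the planted sites (recycled).
#' @param run_threshold Violation threshold used for background hygiene.
#' @param enzyme A [type_iis_enzyme()].
#' @param seed RNG seed.
#' @return List `sequence`, `truth` (data frame of planted elements:
#'   `kind`, `position` 0-based, `length`, `detail` = base or strand).
#' @export
plant_violations <- function(seq_len = 1000, n_runs = 1, run_lengths = 13,
                             n_sites = 0, site_strands = "+",
                             run_threshold = 10, enzyme = bsai(), seed = 1) {
  config <- domestication_config(run_threshold = run_threshold,
                                 enzymes = setNames(enzyme$recognition,
                                                    enzyme$name))
  run_lengths <- as.integer(rep_len(run_lengths, max(n_runs, 1L))[seq_len(n_runs)])
  site_strands <- rep_len(site_strands, max(n_sites, 1L))[seq_len(n_sites)]
  site_len <- nchar(enzyme$recognition)
  need <- sum(run_lengths + 2L) + n_sites * (site_len + 2L)
  if (need > seq_len)
    pf_stop("config", "planted elements (%d bp with buffers) do not fit in %d bp",
            need, seq_len)
  with_rng(seed, {
    for (attempt in 1:200) {
      seq <- random_dna(seq_len)
      # scrub accidental violations from the background
      for (scrub in 1:50) {
        v <- scan_violations(seq, config)
        if (!nrow(v$runs) && !nrow(v$sites)) break
        pos <- c(v$runs$start, v$sites$position)
        for (p in pos) {
          w <- max(run_threshold, site_len)
          repl <- random_dna(w)
          seq <- paste0(substr(seq, 1, p), repl,
                        substr(seq, p + w + 1L, seq_len))
        }
      }
      if (nrow(scan_violations(seq, config)$runs) ||
          nrow(scan_violations(seq, config)$sites)) next

      widths <- as.integer(c(run_lengths, rep(site_len, n_sites)))
      if (length(widths)) {
        # sample non-overlapping placements (1 bp buffer on each side)
        ok <- FALSE
        for (try in 1:100) {
          starts <- sort(sample.int(seq_len - max(widths) - 2L,
                                    length(widths))) + 1L
          o <- order(starts)
          if (all(diff(starts[o]) > widths[o][-length(widths)] + 2L)) {
            ok <- TRUE; break
          }
        }
        if (!ok) next
        truth <- data.frame(kind = rep(c("homopolymer", "type_iis"),
                                       c(n_runs, n_sites)),
                            position = starts, length = widths,
                            detail = NA_character_, stringsAsFactors = FALSE)
        for (i in seq_len(nrow(truth))) {
          p <- truth$position[i]; w <- truth$length[i]
          if (truth$kind[i] == "homopolymer") {
            b <- sample(c("A", "C", "G", "T"), 1)
            truth$detail[i] <- b
            other <- sample(setdiff(c("A", "C", "G", "T"), b), 2, replace = TRUE)
            insert <- paste0(other[1], strrep(b, w), other[2])
          } else {
            truth$detail[i] <- site_strands[sum(truth$kind[seq_len(i)] == "type_iis")]
            rec <- if (truth$detail[i] == "+") enzyme$recognition
                   else revcomp(enzyme$recognition)
            insert <- paste0("T", rec, "A")
          }
          seq <- paste0(substr(seq, 1, p - 1L), insert,
                        substr(seq, p + nchar(insert), seq_len))
        }
        truth <- truth[order(truth$position), ]
        rownames(truth) <- NULL
        # verify the final sequence shows exactly the planted violations
        v <- scan_violations(seq, config)
        runs_ok <- identical(v$runs$start,
                             truth$position[truth$kind == "homopolymer"]) &&
          identical(v$runs$length, truth$length[truth$kind == "homopolymer"])
        sites_ok <- identical(v$sites$position,
                              truth$position[truth$kind == "type_iis"]) &&
          identical(v$sites$strand, truth$detail[truth$kind == "type_iis"])
        if (!runs_ok || !sites_ok) next
      } else {
        truth <- data.frame(kind = character(), position = integer(),
                            length = integer(), detail = character(),
                            stringsAsFactors = FALSE)
      }
      return(list(sequence = seq, truth = truth))
    }
    pf_stop("config", "could not construct a clean background with the planted elements")
  })
}

#' Generate a synthetic COPAS event table with planted expression levels
#'
#' Emulates a mixed-stage worm population: per strain, each event is an adult
#' with probability `adult_fraction` (TOF from the adult normal component)
#' or a larva (larval component). Extinction is uniform in a clean band for
#' real animals and, with probability `debris_rate`, drawn from a heavy tail
#' above the debris threshold. Adult green fluorescence is lognormal with the
#' strain's planted fold-change over control multiplying the scale, so the
#' ratio of gated strain means to the control mean recovers the fold exactly
#' in expectation; larvae and debris show fold-independent background.
#'
#' @param strains Named numeric vector: strain -> fold-change over control
#'   (control fold = 1).
#' @param n_events Events per strain (scalar or per-strain vector).
#' @param adult_fraction Probability an event is an adult.
#' @param adult_tof,larval_tof `c(mean, sd)` of the TOF components.
#' @param debris_rate Probability an event is high-extinction debris.
#' @param extinction_range Clean-event extinction band (uniform).
#' @param debris_threshold Extinction above which debris lives.
#' @param green_meanlog,green_sdlog Lognormal parameters of control adult
#'   green fluorescence.
#' @param background_green `c(meanlog, sdlog)` of larval/debris background.
#' @param seed RNG seed.
#' @return List `events` (data frame `strain`, `tof`, `extinction`, `green`,
#'   `is_adult`), `truth`.
#' @export
synth_copas <- function(strains, n_events = 200, adult_fraction = 0.3,
                        adult_tof = c(1650, 50), larval_tof = c(600, 150),
                        debris_rate = 0.02,
                        extinction_range = c(10000, 30000),
                        debris_threshold = 35000,
                        green_meanlog = log(100), green_sdlog = 0.5,
                        background_green = c(log(30), 0.3), seed = 1) {
  stopifnot(length(strains) >= 1, !is.null(names(strains)))
  if (any(n_events < 1)) pf_stop("config", "n_events must be >= 1")
  n_events <- rep_len(n_events, length(strains))
  with_rng(seed, {
    rows <- lapply(seq_along(strains), function(i) {
      n <- n_events[i]
      adult <- rbinom(n, 1, adult_fraction) == 1
      tof <- ifelse(adult, rnorm(n, adult_tof[1], adult_tof[2]),
                    rnorm(n, larval_tof[1], larval_tof[2]))
      tof <- pmax(tof, 0)
      debris <- rbinom(n, 1, debris_rate) == 1
      extinction <- runif(n, extinction_range[1], extinction_range[2])
      extinction[debris] <- debris_threshold +
        rexp(sum(debris), rate = 1 / 10000)
      green <- ifelse(adult,
                      rlnorm(n, green_meanlog + log(strains[i]), green_sdlog),
                      rlnorm(n, background_green[1], background_green[2]))
      data.frame(strain = names(strains)[i], tof = tof,
                 extinction = extinction, green = green, is_adult = adult,
                 stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, rows)
    rownames(events) <- NULL
    truth <- list(planted_relative_levels = as.list(strains),
                  n_events = setNames(as.list(n_events), names(strains)),
                  adult_fraction = adult_fraction, debris_rate = debris_rate,
                  adult_tof = adult_tof, larval_tof = larval_tof,
                  green_meanlog = green_meanlog, green_sdlog = green_sdlog,
                  rng_seed = seed)
    list(events = events, truth = truth)
  })
}
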