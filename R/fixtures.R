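#' The characterized promoter panel
#'
#' The twenty promoter sequences of the published characterization panel (two
#' expression controls plus eighteen candidates), exactly as synthesized:
#' endogenous promoter, then the 15 bp cloning linker `aaaagcaggctaaaa`
#' (lowercase), then the reporter start codon (uppercase `ATG`). Lengths
#' quoted for the panel (254-880 bp for the candidates) refer to the
#' endogenous portion, i.e. the sequence minus the 18 bp linker+ATG tail.
#'
#' @param strip One of `"none"` (the sequence as synthesized), `"atg"`
#'   (drop the trailing ATG), or `"linker_atg"` (endogenous promoter only).
#' @return Named character vector of 20 sequences.
#' @export
promoter_panel <- function(strip = c("none", "atg", "linker_atg")) {
  strip <- match.arg(strip)
  seqs <- read_fasta(system.file("extdata", "promoter_panel.fasta",
                                 package = "promforge", mustWork = TRUE))
  drop <- switch(strip, none = 0L, atg = 3L, linker_atg = 18L)
  if (drop) seqs <- substr(seqs, 1L, nchar(seqs) - drop)
  seqs
}

#' Metadata for the promoter panel
#'
#' @return Data frame: `promoter_id`, `gene`, `role`
#'   (`"control"`/`"candidate"`), `linker`, `has_atg`, `total_length_bp`,
#'   `endogenous_length_bp`.
#' @export
promoter_panel_metadata <- function() {
  read.delim(system.file("extdata", "promoter_panel_metadata.tsv",
                         package = "promforge", mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Expression-pattern classification of the candidate promoters
#'
#' The visual classification of the eighteen candidate promoters from
#' single-copy reporter insertions: six with somatic and germline
#' expression, three with no detectable expression, nine germline-specific.
#'
#' @return Data frame `promoter_id`, `pattern`.
#' @export
expression_patterns <- function() {
  read.delim(system.file("extdata", "expression_patterns.tsv",
                         package = "promforge", mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Published per-strain gated event counts
#'
#' Gated adult event counts of the COPAS quantification (54-238 events per
#' strain; `NegCtrl` is non-transgenic N2). Used to size realistic synthetic
#' cytometry runs.
#'
#' @return Data frame `strain`, `n_events`.
#' @export
copas_event_counts <- function() {
  read.delim(system.file("extdata", "copas_event_counts.tsv",
                         package = "promforge", mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' The published six-component injection mix
#'
#' @return Data frame `component`, `concentration_ng_ul` (sums to
#'   100 ng/ul).
#' @export
injection_mix_components <- function() {
  read.delim(system.file("extdata", "injection_mix.tsv",
                         package = "promforge", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
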