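#' Reverse complement of a DNA string
#'
#' Case-preserving reverse complement over the ACGT alphabet.
#'
#' @param seq Character scalar of A/C/G/T (either case).
#' @return Character scalar.
#' @export
#' @examples
#' revcomp("GGTCTC")  # "GAGACC"
revcomp <- function(seq) {
  check_alphabet(seq)
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Error (classed) on any character outside ACGT/acgt.
check_alphabet <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTacgt]", seq))
    pf_stop("alphabet", "%s contains non-ACGT characters", what)
  invisible(seq)
}

## Deterministic random ACGT string (uses the current RNG stream).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Read a DNA FASTA file as a named character vector
#'
#' Wrapper over [Biostrings::readBStringSet()] (BString rather than DNAString
#' so that the lower/upper case of the input is preserved: the promoter panel
#' marks the reporter ATG in uppercase). Each sequence is validated against
#' the ACGT alphabet.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- setNames(as.character(x), names(x))
  for (i in seq_along(out)) check_alphabet(out[[i]], names(out)[i])
  out
}

#' Write named sequences to FASTA
#'
#' Case-preserving counterpart of [read_fasta()].
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
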