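#' Synthetic stand-in destination vector
#'
#' The real destination plasmid for the reporter panel is unpublished, so the
#' package ships a synthetic stand-in with the documented architecture: two
#' BsaI acceptor sites cutting outward of a stuffer (dropout), the `aaaa`
#' consensus start site immediately followed by the reporter ATG, a gfp body
#' carrying two nuclear localization signals, a tbb-2-style 3' UTR segment,
#' and a backbone stub standing in for the selection fragment and homology
#' arms. All non-structural segments are deterministic pseudo-random DNA,
#' domesticated so the only BsaI sites on the circle are the two acceptors.
#'
#' Digesting the destination drops the stuffer and leaves a backbone fragment
#' with 5' overhang `overhang3` (default `aaaa`, the last 4 nt of the cloning
#' linker) and 3' overhang `overhang5` (default `ggag`), so a promoter+linker
#' part flanked with the same overhangs by [add_flanks()] ligates into a
#' circle where the promoter is immediately followed by
#' `aaaagcaggctaaaaATG`.
#'
#' @param overhang5 4 nt overhang at the promoter's 5' junction.
#' @param overhang3 4 nt overhang at the linker/ATG junction.
#' @param enzyme A [type_iis_enzyme()].
#' @param seed Seed for the pseudo-random filler segments.
#' @return A circular [construct()] with annotated features.
#' @export
synthetic_destination <- function(overhang5 = "ggag", overhang3 = "aaaa",
                                  enzyme = bsai(), seed = 42) {
  stopifnot(nchar(overhang5) == 4L, nchar(overhang3) == 4L)
  config <- domestication_config(enzymes = setNames(enzyme$recognition,
                                                    enzyme$name))
  clean_dna <- function(n, subseed) with_rng(subseed, {
    domesticate(random_dna(n), config)$edited
  })
  for (sub in seed + 0:24) {
    stuffer <- clean_dna(30L, sub)
    gfp_body <- clean_dna(177L, sub + 1000L)    # ATG + body = gfp with 2x NLS
    utr <- clean_dna(90L, sub + 2000L)          # tbb-2-style 3' UTR segment
    backbone <- clean_dna(240L, sub + 3000L)    # selection fragment + homology arms
    parts <- list(
      acceptor_overhang_5 = tolower(overhang5),
      spacer_l = "t",
      acceptor_site_l = revcomp(enzyme$recognition),
      stuffer = stuffer,
      acceptor_site_r = enzyme$recognition,
      spacer_r = "a",
      consensus_start = tolower(overhang3),
      gfp_nls = paste0("ATG", gfp_body),
      utr3 = utr,
      backbone = backbone)
    seqc <- paste(unlist(parts), collapse = "")
    sites <- find_type_iis_sites(paste0(seqc, substr(seqc, 1, 12)),
                                 enzyme$recognition)
    sites <- sites[sites$position < nchar(seqc), , drop = FALSE]
    if (nrow(sites) == 2L) {
      lens <- nchar(unlist(parts))
      starts <- cumsum(c(0L, lens[-length(lens)]))
      feats <- data.frame(name = names(parts), start = starts,
                          end = starts + lens, strand = "+",
                          stringsAsFactors = FALSE)
      return(construct(seqc, "circular", features = feats))
    }
  }
  pf_stop("config", "could not build a clean destination (junction sites persisted)")
}

#' Feature sequence of a construct
#'
#' @param x A [construct()] with a features table.
#' @param name Feature name.
#' @return Character scalar.
#' @export
feature_sequence <- function(x, name) {
  stopifnot(inherits(x, "construct"), !is.null(x$features))
  i <- match(name, x$features$name)
  if (is.na(i)) pf_stop("missing_feature", "no feature named '%s'", name)
  substr(x$sequence, x$features$start[i] + 1L, x$features$end[i])
}
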