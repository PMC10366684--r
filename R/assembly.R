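#' Type-IIS enzyme description
#'
#' Cut geometry: the top strand is cut `spacer_len` nt downstream of the
#' recognition sequence and the bottom strand `spacer_len + overhang_len` nt
#' downstream, leaving a 4 nt 5' overhang (standard BsaI geometry, N1/N5).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence read on the strand the enzyme
#'   binds.
#' @param spacer_len Nt between recognition and the top-strand cut.
#' @param overhang_len Length of the 5' overhang left by the cut.
#' @return List of class `type_iis_enzyme`.
#' @export
type_iis_enzyme <- function(name, recognition, spacer_len = 1L,
                            overhang_len = 4L) {
  check_alphabet(recognition, "recognition sequence")
  structure(list(name = name, recognition = toupper(recognition),
                 spacer_len = as.integer(spacer_len),
                 overhang_len = as.integer(overhang_len)),
            class = "type_iis_enzyme")
}

#' BsaI
#'
#' Recognition GGTCTC(N1), leaving 4 nt 5' overhangs.
#' @return A [type_iis_enzyme()].
#' @export
bsai <- function() type_iis_enzyme("BsaI", "GGTCTC", 1L, 4L)

#' A DNA construct (linear or circular)
#'
#' @param sequence Top-strand sequence.
#' @param topology `"linear"` or `"circular"`.
#' @param features Optional data frame `name`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @return List of class `construct`.
#' @export
construct <- function(sequence, topology = c("linear", "circular"),
                      features = NULL) {
  check_alphabet(sequence)
  topology <- match.arg(topology)
  if (!is.null(features))
    stopifnot(all(c("name", "start", "end", "strand") %in% names(features)))
  structure(list(sequence = sequence, topology = topology,
                 features = features), class = "construct")
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("<construct> %s, %d bp, %d feature(s)\n", x$topology,
              nchar(x$sequence),
              if (is.null(x$features)) 0L else nrow(x$features)))
  if (!is.null(x$features)) print(x$features)
  invisible(x)
}

#' Canonical form of a circular sequence
#'
#' The lexicographically minimal rotation of the lowercase sequence or of its
#' reverse complement, giving an origin- and strand-independent key for
#' comparing circular molecules.
#'
#' @param seq Circular top-strand sequence.
#' @return Character scalar.
#' @export
canonical_rotation <- function(seq) {
  min_rot <- function(s) {
    n <- nchar(s)
    if (n == 0L) return(s)
    d <- paste0(s, s)
    rots <- substring(d, seq_len(n), seq_len(n) + n - 1L)
    min(rots)
  }
  s <- tolower(seq)
  min(min_rot(s), min_rot(tolower(revcomp(s))))
}

#' Compare two constructs for sequence identity
#'
#' Circular constructs compare equal under rotation and strand flip.
#'
#' @param a,b `construct` objects.
#' @return Logical.
#' @export
constructs_identical <- function(a, b) {
  if (a$topology != b$topology) return(FALSE)
  if (a$topology == "circular")
    canonical_rotation(a$sequence) == canonical_rotation(b$sequence)
  else
    tolower(a$sequence) == tolower(b$sequence)
}

## Internal: 0-based top-strand cut positions for all sites of an enzyme.
## For a plus-strand site at p the top cut is at p + len + spacer; for a
## minus-strand site the top cut is at p - spacer - overhang. The bottom cut
## is always top + overhang (5' overhangs).
cut_positions <- function(seq, enzyme, circular = FALSE) {
  n <- nchar(seq)
  len <- nchar(enzyme$recognition)
  s <- if (circular) paste0(seq, substr(seq, 1L, len - 1L)) else seq
  sites <- find_type_iis_sites(s, enzyme$recognition)
  if (circular) sites <- sites[sites$position < n, , drop = FALSE]
  if (!nrow(sites)) return(integer(0))
  cuts <- ifelse(sites$strand == "+",
                 sites$position + len + enzyme$spacer_len,
                 sites$position - enzyme$spacer_len - enzyme$overhang_len)
  if (circular) cuts <- cuts %% n
  sort(unique(as.integer(cuts)))
}

#' Digest a molecule with a type-IIS enzyme
#'
#' Fragments are reported on the top strand; by convention each fragment's
#' sequence includes its right-hand 4 nt overhang region, so the sum of
#' fragment lengths equals the input length plus 4 nt per cut. The 5'
#' overhang of a fragment is its first 4 nt (empty string = blunt); the
#' recorded 3' overhang is the 4 nt top-strand region that the next
#' fragment's 5' overhang must equal for ligation.
#'
#' @param seq Top-strand sequence.
#' @param enzyme A [type_iis_enzyme()].
#' @param topology `"linear"` or `"circular"`.
#' @return Data frame, one fragment per row: `sequence`,
#'   `five_prime_overhang`, `three_prime_overhang` (empty = blunt), `start`,
#'   `end` (0-based top-strand cut coordinates in the parent).
#' @export
digest <- function(seq, enzyme = bsai(), topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  check_alphabet(seq)
  n <- nchar(seq)
  oh <- enzyme$overhang_len
  circular <- topology == "circular"
  cuts <- cut_positions(seq, enzyme, circular = circular)
  if (circular) {
    if (!length(cuts))
      return(data.frame(sequence = seq, five_prime_overhang = "",
                        three_prime_overhang = "", start = 0L, end = n,
                        stringsAsFactors = FALSE))
    d <- paste0(seq, seq)
    ends <- c(cuts[-1L], cuts[1L] + n)
    data.frame(
      sequence = substring(d, cuts + 1L, ends + oh),
      five_prime_overhang = substring(d, cuts + 1L, cuts + oh),
      three_prime_overhang = substring(d, ends + 1L, ends + oh),
      start = cuts, end = as.integer(ends %% n),
      stringsAsFactors = FALSE)
  } else {
    if (length(cuts) && (min(cuts) < 0L || max(cuts) + oh > n))
      pf_stop("truncation",
              "cut site too close to a sequence end for a full %d nt overhang", oh)
    b <- c(0L, cuts, n)
    starts <- b[-length(b)]
    ends <- b[-1L]
    seq_ends <- pmin(ends + oh, n)
    data.frame(
      sequence = substring(seq, starts + 1L, seq_ends),
      five_prime_overhang = ifelse(starts %in% cuts,
                                   substring(seq, starts + 1L, starts + oh), ""),
      three_prime_overhang = ifelse(ends %in% cuts,
                                    substring(seq, ends + 1L, ends + oh), ""),
      start = starts, end = ends, stringsAsFactors = FALSE)
  }
}

#' Core of a digestion fragment
#'
#' Strips the overhang regions from both overhung ends, recovering the part
#' that was placed between the donor sites by [add_flanks()].
#'
#' @param frag One row of a [digest()] result (data frame or list).
#' @param enzyme A [type_iis_enzyme()].
#' @return Character scalar.
#' @export
fragment_core <- function(frag, enzyme = bsai()) {
  s <- frag$sequence
  oh <- enzyme$overhang_len
  if (nzchar(frag$five_prime_overhang)) s <- substr(s, oh + 1L, nchar(s))
  if (nzchar(frag$three_prime_overhang)) s <- substr(s, 1L, nchar(s) - oh)
  s
}

#' Assemble parts into a destination by Golden Gate digestion/ligation
#'
#' Digests every part (linear) and the destination (circular), keeps the
#' fragments free of the enzyme's recognition sequence, builds the
#' overhang-complementarity graph and searches for circular ligation
#' products. Exactly one distinct circular product must exist; zero products
#' raise `promforge_assembly_failure` and more than one (e.g. two parts
#' carrying the same overhang pair) raise `promforge_assembly_ambiguity`.
#'
#' @param parts Character vector of flanked fragment sequences (named names
#'   become feature names), or a [digest()]-style data frame of fragments.
#' @param destination A circular [construct()] carrying acceptor sites.
#' @param enzyme A [type_iis_enzyme()].
#' @return A circular [construct()] whose features record where each ligated
#'   fragment landed.
#' @export
assemble <- function(parts, destination, enzyme = bsai()) {
  stopifnot(inherits(destination, "construct"),
            destination$topology == "circular")
  frags <- list()
  add_frags <- function(df, label) {
    for (i in seq_len(nrow(df))) {
      f <- df[i, ]
      if (nrow(find_type_iis_sites(f$sequence, enzyme$recognition))) next
      if (!nzchar(f$five_prime_overhang) || !nzchar(f$three_prime_overhang)) next
      frags[[length(frags) + 1L]] <<- list(
        sequence = f$sequence, five = tolower(f$five_prime_overhang),
        three = tolower(f$three_prime_overhang), source = label)
    }
  }
  if (is.data.frame(parts)) {
    add_frags(parts, "part")
  } else {
    nms <- names(parts) %||% paste0("part", seq_along(parts))
    for (i in seq_along(parts))
      add_frags(digest(parts[[i]], enzyme, "linear"), nms[i])
  }
  add_frags(digest(destination$sequence, enzyme, "circular"), "backbone")
  if (!length(frags))
    pf_stop("assembly_failure", "no ligatable enzyme-free fragments in the pool")

  nf <- length(frags)
  fives <- vapply(frags, `[[`, "", "five")
  threes <- vapply(frags, `[[`, "", "three")
  cycles <- list()
  # enumerate simple cycles whose smallest member index is the DFS root,
  # so each cycle is found once (up to rotation)
  search <- function(root, path) {
    last <- path[length(path)]
    nxt <- which(fives == threes[last])
    for (v in nxt) {
      if (v == root && length(path) >= 1L) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (v > root && !(v %in% path)) {
        search(root, c(path, v))
      }
    }
  }
  for (r in seq_len(nf)) search(r, r)
  if (!length(cycles))
    pf_stop("assembly_failure",
            "no circular product: overhangs do not close a cycle")

  ligate <- function(idx) {
    oh <- enzyme$overhang_len
    pieces <- vapply(idx, function(i) {
      s <- frags[[i]]$sequence
      substr(s, 1L, nchar(s) - oh)  # drop right overhang; next piece supplies it
    }, "")
    paste(pieces, collapse = "")
  }
  prods <- vapply(cycles, ligate, "")
  keys <- vapply(prods, canonical_rotation, "")
  uniq <- !duplicated(keys)
  if (sum(uniq) > 1L)
    pf_stop("assembly_ambiguity",
            "%d distinct circular products possible (lengths: %s)",
            sum(uniq), paste(nchar(prods[uniq]), collapse = ", "))
  idx <- cycles[[which(uniq)[1L]]]
  product <- prods[[which(uniq)[1L]]]
  lens <- vapply(idx, function(i)
    nchar(frags[[i]]$sequence) - enzyme$overhang_len, 0L)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  feats <- data.frame(
    name = vapply(idx, function(i) frags[[i]]$source, ""),
    start = starts, end = starts + lens, strand = "+",
    stringsAsFactors = FALSE)
  construct(product, "circular", features = feats)
}

#' Verify an assembled construct against design expectations
#'
#' Checks that each expected feature sequence occurs on the forward strand of
#' the (circular) construct, that the features appear in the stated cyclic
#' order, that no recognition site of the assembly enzyme survives, and
#' optionally summarizes an in silico digest with another enzyme.
#'
#' @param construct A [construct()].
#' @param expectations Named character vector of feature sequences, in
#'   expected 5' to 3' order.
#' @param enzyme Assembly enzyme whose sites must be absent.
#' @param digest_enzyme Optional [type_iis_enzyme()] for a restriction
#'   summary.
#' @return List `feature_found`, `orientation_ok`, `order_ok`, `enzyme_free`,
#'   `digest_fragments`, `ok`.
#' @export
verify_construct <- function(construct, expectations, enzyme = bsai(),
                             digest_enzyme = NULL) {
  s <- tolower(construct$sequence)
  n <- nchar(s)
  d <- if (construct$topology == "circular") paste0(s, s) else s
  pos <- rev_hit <- setNames(rep(NA_integer_, length(expectations)),
                             names(expectations))
  for (nm in names(expectations)) {
    pat <- tolower(expectations[[nm]])
    hit <- regexpr(pat, d, fixed = TRUE)
    if (hit > 0L && hit <= n) pos[nm] <- as.integer(hit)
    rc_hit <- regexpr(tolower(revcomp(pat)), d, fixed = TRUE)
    rev_hit[nm] <- rc_hit > 0L
  }
  feature_found <- !is.na(pos) | as.logical(rev_hit)
  orientation_ok <- !is.na(pos)
  order_ok <- FALSE
  if (all(!is.na(pos))) {
    rot <- (pos - pos[1L]) %% n
    order_ok <- !is.unsorted(rot)
  }
  sites <- if (construct$topology == "circular")
    cut_positions(construct$sequence, enzyme, circular = TRUE)
  else cut_positions(construct$sequence, enzyme)
  dig <- if (!is.null(digest_enzyme))
    digest(construct$sequence, digest_enzyme, construct$topology) else NULL
  list(feature_found = feature_found,
       orientation_ok = orientation_ok,
       order_ok = order_ok,
       enzyme_free = length(sites) == 0L,
       digest_fragments = dig,
       ok = all(feature_found) && all(orientation_ok) && order_ok &&
         length(sites) == 0L)
}

#' Sum an injection mix
#'
#' @param components Data frame with columns `name` (or `component`) and
#'   `concentration` (ng/ul; column `concentration_ng_ul` also accepted).
#' @return List of class `injection_mix`: `total_ng_ul` and the echoing
#'   `recipe` table.
#' @export
#' @examples
#' injection_mix(data.frame(name = c("a", "b"), concentration = c(25, 75)))
injection_mix <- function(components) {
  if (is.data.frame(components)) {
    nm <- components$name %||% components$component
    conc <- as.numeric(components$concentration %||% components$concentration_ng_ul)
  } else {
    nm <- names(components) %||% paste0("component", seq_along(components))
    conc <- as.numeric(components)
  }
  if (is.null(nm) || is.null(conc) || !length(conc))
    pf_stop("mix", "injection mix needs at least one named concentration")
  if (anyNA(conc) || any(conc <= 0))
    pf_stop("mix", "injection mix concentrations must be positive")
  structure(list(total_ng_ul = sum(conc),
                 recipe = data.frame(name = nm, concentration_ng_ul = conc,
                                     stringsAsFactors = FALSE)),
            class = "injection_mix")
}

#' @export
print.injection_mix <- function(x, ...) {
  print(x$recipe)
  cat(sprintf("total: %g ng/ul\n", x$total_ng_ul))
  invisible(x)
}
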