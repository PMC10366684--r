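#' Domestication configuration
#'
#' Parameters for making a sequence synthesis- and Golden-Gate-ready:
#' the homopolymer run threshold, the type-IIS recognition sequences that
#' must be absent (on both strands), and the fixed 15 bp cloning linker
#' (11 bp partial attB1 followed by the `aaaa` consensus start site) placed
#' between the promoter and the reporter start codon.
#'
#' @param run_threshold Minimum homopolymer length considered a violation
#'   (default 10 bp; must be >= 2).
#' @param enzymes Named character vector of recognition sequences
#'   (default `c(BsaI = "GGTCTC")`).
#' @param linker The 15 bp cloning linker (lowercase).
#' @return List of class `domestication_config`.
#' @export
domestication_config <- function(run_threshold = 10L,
                                 enzymes = c(BsaI = "GGTCTC"),
                                 linker = "aaaagcaggctaaaa") {
  stopifnot(run_threshold >= 2, nchar(linker) == 15L)
  for (e in enzymes) check_alphabet(e, "recognition sequence")
  structure(list(run_threshold = as.integer(run_threshold),
                 enzymes = toupper(enzymes), linker = tolower(linker)),
            class = "domestication_config")
}

#' Find maximal homopolymer runs
#'
#' Case-insensitive scan for maximal single-base runs of at least `min_len`;
#' a run is never reported inside a longer run.
#'
#' @param seq DNA string.
#' @param min_len Minimum run length (>= 2).
#' @return Data frame `start` (0-based), `length`, `base` (uppercase),
#'   sorted by start.
#' @export
#' @examples
#' find_homopolymers("ccAAAAAAAAAAcc", 10)  # one 10 bp A-run at 2
find_homopolymers <- function(seq, min_len = 10L) {
  stopifnot(min_len >= 2)
  check_alphabet(seq)
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  data.frame(start = (ends - r$lengths)[keep],
             length = r$lengths[keep],
             base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Find type-IIS recognition sites on both strands
#'
#' Matches of `recognition` on the plus strand and of its reverse complement
#' on the minus strand, both reported in plus-strand coordinates; overlapping
#' matches are all reported.
#'
#' @param seq DNA string.
#' @param recognition Recognition sequence (>= 4 nt), e.g. `"GGTCTC"` (BsaI).
#' @return Data frame `position` (0-based, plus-strand coordinate of the
#'   match start), `strand`, sorted by position.
#' @export
#' @examples
#' find_type_iis_sites("ttGGTCTCtt")  # one plus-strand site at 2
#' find_type_iis_sites("ttGAGACCtt")  # one minus-strand site at 2
find_type_iis_sites <- function(seq, recognition = "GGTCTC") {
  stopifnot(nchar(recognition) >= 4)
  check_alphabet(seq)
  s <- toupper(seq)
  scan1 <- function(pat) {
    # lookahead so self-overlapping matches are all reported
    m <- gregexpr(paste0("(?=", toupper(pat), ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  fwd <- scan1(recognition)
  rc <- revcomp(toupper(recognition))
  rev <- if (identical(rc, toupper(recognition))) integer(0) else scan1(rc)
  out <- data.frame(position = c(fwd, rev),
                    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

## Internal: all violations of a config in one scan.
scan_violations <- function(seq, config) {
  runs <- find_homopolymers(seq, config$run_threshold)
  sites <- do.call(rbind, lapply(names(config$enzymes), function(nm) {
    st <- find_type_iis_sites(seq, config$enzymes[[nm]])
    if (nrow(st)) st$enzyme <- nm
    st
  }))
  if (is.null(sites))
    sites <- data.frame(position = integer(), strand = character(),
                        enzyme = character(), stringsAsFactors = FALSE)
  list(runs = runs, sites = sites)
}

## Internal: would substituting position pos (0-based) with base alt create a
## NEW violation covering pos (a run >= threshold through pos, or an enzyme
## site overlapping pos)? Violations elsewhere in the sequence are the
## caller's business and must not veto the edit.
introduces_violation <- function(seq, pos, alt, config) {
  n <- nchar(seq)
  up <- toupper(seq)
  altU <- toupper(alt)
  base_at <- function(i) substr(up, i + 1L, i + 1L)
  run <- 1L
  i <- pos - 1L
  while (i >= 0L && base_at(i) == altU) { run <- run + 1L; i <- i - 1L }
  i <- pos + 1L
  while (i < n && base_at(i) == altU) { run <- run + 1L; i <- i + 1L }
  if (run >= config$run_threshold) return(TRUE)
  for (rec in config$enzymes) {
    len <- nchar(rec)
    rc <- toupper(revcomp(rec))
    starts <- max(0L, pos - len + 1L):pos
    starts <- starts[starts + len <= n]
    for (s in starts) {
      window <- paste0(substr(up, s + 1L, pos), altU,
                       substr(up, pos + 2L, s + len))
      if (window == toupper(rec) || window == rc) return(TRUE)
    }
  }
  FALSE
}

## Internal: preference order for replacement bases: transition of the
## reference first (A<->G, C<->T keeps base composition character), then the
## two transversions in alphabetical order.
alt_candidates <- function(ref) {
  ref <- toupper(ref)
  transition <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
  c(transition, setdiff(c("A", "C", "G", "T"), c(ref, transition)))
}

## Internal: substitute one base preserving the case at that position.
substitute_base <- function(seq, pos, alt) {
  ref <- substr(seq, pos + 1L, pos + 1L)
  alt <- if (ref %in% letters || ref == tolower(ref)) tolower(alt) else toupper(alt)
  paste0(substr(seq, 1L, pos), alt, substr(seq, pos + 2L, nchar(seq)))
}

#' Domesticate a sequence for synthesis and Golden Gate assembly
#'
#' Removes every homopolymer run of `run_threshold` bp or more and every
#' type-IIS recognition site (either strand) using single-base
#' substitutions, spending the minimum number of edits: a run of length L is
#' split by `floor(L / run_threshold)` substitutions placed every
#' `run_threshold`-th base, and an isolated site costs one substitution (at
#' the third base of the recognition hexamer). Replacement bases are chosen
#' by a fixed preference order (transition first) subject to not creating a
#' new violation, so the procedure is fully deterministic; `seed` is accepted
#' for interface stability but unused. Case is preserved; comparisons are
#' case-insensitive.
#'
#' @param seq DNA string (non-empty).
#' @param config A [domestication_config()].
#' @param seed Ignored (the default policy is deterministic).
#' @return List of class `domesticated_promoter`: `original`, `edited`, and
#'   `edits` (data frame `position` 0-based, `ref`, `alt`, `reason`).
#' @export
#' @examples
#' d <- domesticate("ccttGGTCTCaaAAAAAAAAAAAAcc")
#' d$edits
domesticate <- function(seq, config = domestication_config(), seed = NULL) {
  check_alphabet(seq)
  if (!nchar(seq)) pf_stop("unsatisfiable", "cannot domesticate an empty sequence")
  original <- seq
  edits <- list()
  for (iter in 1:25) {
    v <- scan_violations(seq, config)
    if (!nrow(v$runs) && !nrow(v$sites)) break
    if (iter == 25L)
      pf_stop("unsatisfiable",
              "domestication did not converge (%d run(s), %d site(s) remain); config may be unsatisfiable",
              nrow(v$runs), nrow(v$sites))
    targets <- list()
    if (nrow(v$runs)) {
      for (i in seq_len(nrow(v$runs))) {
        L <- v$runs$length[i]
        k <- seq_len(L %/% config$run_threshold)
        for (p in v$runs$start[i] + k * config$run_threshold - 1L)
          targets[[length(targets) + 1L]] <- list(pos = p, reason = "homopolymer")
      }
    }
    if (nrow(v$sites)) {
      for (i in seq_len(nrow(v$sites)))
        targets[[length(targets) + 1L]] <-
          list(pos = v$sites$position[i] + 2L, reason = "type_iis",
               site_pos = v$sites$position[i],
               recognition = config$enzymes[[v$sites$enzyme[i]]],
               site_strand = v$sites$strand[i])
    }
    for (t in targets) {
      # an earlier edit this pass may already have cleared this violation
      # (runs and sites can overlap); skip spent targets to stay minimal
      if (t$reason == "homopolymer") {
        w0 <- max(0L, t$pos - config$run_threshold)
        w1 <- min(nchar(seq), t$pos + config$run_threshold)
        still <- find_homopolymers(substr(seq, w0 + 1L, w1), config$run_threshold)
        if (!nrow(still) ||
            !any(w0 + still$start <= t$pos & w0 + still$start + still$length > t$pos))
          next
      } else {
        want <- if (t$site_strand == "+") t$recognition else revcomp(t$recognition)
        here <- toupper(substr(seq, t$site_pos + 1L,
                               t$site_pos + nchar(t$recognition)))
        if (here != toupper(want)) next
      }
      done <- FALSE
      for (pos in c(t$pos, t$pos - 1L, t$pos + 1L)) {  # tiny fallback shift
        if (pos < 0L || pos >= nchar(seq)) next
        ref <- substr(seq, pos + 1L, pos + 1L)
        for (alt in alt_candidates(ref)) {
          if (!introduces_violation(seq, pos, alt, config)) {
            seq <- substitute_base(seq, pos, alt)
            edits[[length(edits) + 1L]] <- data.frame(
              position = pos, ref = ref,
              alt = substr(seq, pos + 1L, pos + 1L),
              reason = t$reason, stringsAsFactors = FALSE)
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      # if no safe base exists the next scan pass re-targets what remains
    }
  }
  edits <- if (length(edits)) do.call(rbind, edits)
           else data.frame(position = integer(), ref = character(),
                           alt = character(), reason = character(),
                           stringsAsFactors = FALSE)
  structure(list(original = original, edited = seq, edits = edits),
            class = "domesticated_promoter")
}

#' @export
print.domesticated_promoter <- function(x, ...) {
  cat(sprintf("Domesticated sequence: %d bp, %d edit(s)\n",
              nchar(x$edited), nrow(x$edits)))
  if (nrow(x$edits)) print(x$edits)
  invisible(x)
}

#' Append the 15 bp cloning linker
#'
#' Adds the fixed linker (partial attB1 followed by the `aaaa` consensus
#' start site) to the 3' end of a promoter; the reporter ATG follows
#' immediately in the final construct. Output length is always input + 15.
#'
#' @param seq DNA string (may be empty).
#' @param config A [domestication_config()] carrying the linker.
#' @return Character scalar.
#' @export
append_cloning_linker <- function(seq, config = domestication_config()) {
  if (nchar(seq)) check_alphabet(seq)
  paste0(seq, config$linker)
}

#' Flank a clean part with outward-cutting type-IIS donor sites
#'
#' Produces a synthesis-ready fragment:
#' `recognition + 1 nt spacer + overhang5 | part | overhang3 + 1 nt spacer +
#' reverse-complement recognition`. Both sites cut inward, so digestion
#' releases `overhang5 + part + overhang3` with the two 4 nt sticky ends.
#'
#' @param part Internally clean DNA string (no runs, no sites).
#' @param overhang5,overhang3 Distinct 4 nt overhangs.
#' @param config A [domestication_config()].
#' @param enzyme A [type_iis_enzyme()]; default BsaI.
#' @return Character scalar (the flanked fragment).
#' @export
add_flanks <- function(part, overhang5, overhang3,
                       config = domestication_config(), enzyme = bsai()) {
  check_alphabet(part, "part")
  check_alphabet(overhang5, "overhang5")
  check_alphabet(overhang3, "overhang3")
  if (nchar(overhang5) != 4L || nchar(overhang3) != 4L)
    pf_stop("overhang", "overhangs must be exactly 4 nt")
  if (tolower(overhang5) == tolower(overhang3))
    pf_stop("overhang", "identical 5' and 3' overhangs make ligation ambiguous")
  v <- scan_violations(part, config)
  if (nrow(v$runs) || nrow(v$sites))
    pf_stop("dirty_part",
            "part has %d internal run(s) and %d internal site(s); domesticate first",
            nrow(v$runs), nrow(v$sites))
  fragment <- paste0(enzyme$recognition, "a", overhang5, part,
                     overhang3, "t", revcomp(enzyme$recognition))
  # a junction (flank+overhang+part boundary) can itself spell a recognition
  # site; that is a design error in the overhang choice, not a dirty part
  if (nrow(find_type_iis_sites(fragment, enzyme$recognition)) != 2L)
    pf_stop("overhang",
            "overhang/part junction creates an extra %s site; pick different overhangs",
            enzyme$name)
  fragment
}

#' Validate a flanked fragment
#'
#' Reporting operation: counts homopolymer runs, classifies enzyme sites as
#' flank (the outermost plus-strand site at the left end and minus-strand
#' site at the right end, cutting inward) versus internal, and checks
#' orientation.
#'
#' @param fragment DNA string.
#' @param config A [domestication_config()].
#' @param enzyme A [type_iis_enzyme()].
#' @return List `internal_runs`, `internal_sites`, `flank_sites`,
#'   `orientation_ok`, `ok`.
#' @export
validate_part <- function(fragment, config = domestication_config(),
                          enzyme = bsai()) {
  v <- scan_violations(fragment, config)
  n <- nchar(fragment)
  rl <- nchar(enzyme$recognition)
  is_left_flank <- v$sites$strand == "+" & v$sites$position == 0L
  is_right_flank <- v$sites$strand == "-" & v$sites$position == n - rl
  flank_sites <- sum(is_left_flank) + sum(is_right_flank)
  internal_sites <- nrow(v$sites) - flank_sites
  orientation_ok <- sum(is_left_flank) == 1L && sum(is_right_flank) == 1L
  list(internal_runs = nrow(v$runs),
       internal_sites = internal_sites,
       flank_sites = flank_sites,
       orientation_ok = orientation_ok,
       ok = nrow(v$runs) == 0L && internal_sites == 0L && orientation_ok)
}

#' Write a domestication edit report
#'
#' TSV with 1-based positions, matching common edit-report conventions.
#'
#' @param edits Named list of `domesticated_promoter` objects.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_edit_report <- function(edits, path) {
  rows <- lapply(names(edits), function(id) {
    e <- edits[[id]]$edits
    if (!nrow(e)) return(NULL)
    data.frame(seq_id = id, position = e$position + 1L, ref = e$ref,
               alt = e$alt, reason = e$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seq_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      reason = character())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
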