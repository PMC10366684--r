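# Independent brute-force oracles. These deliberately avoid the package's
# scanning code paths: runs by per-position extension, sites by literal
# window comparison, minimal edits by exhaustive substitution search.

oracle_revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all maximal runs >= min_len via an all-window scan
oracle_find_runs <- function(seq, min_len) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    if (j - i + 1L >= min_len)
      out[[length(out) + 1L]] <- data.frame(start = i - 1L,
                                            length = j - i + 1L,
                                            base = s[i])
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), length = integer(), base = character())
}

oracle_find_sites <- function(seq, rec = "GGTCTC") {
  s <- toupper(seq); rec <- toupper(rec); rc <- oracle_revcomp(rec)
  n <- nchar(s); w <- nchar(rec)
  hits <- list()
  for (p in seq_len(max(n - w + 1L, 0L))) {
    win <- substr(s, p, p + w - 1L)
    if (win == rec) hits[[length(hits) + 1L]] <- data.frame(position = p - 1L, strand = "+")
    if (win == rc) hits[[length(hits) + 1L]] <- data.frame(position = p - 1L, strand = "-")
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(position = integer(), strand = character())
}

oracle_clean <- function(seq, run_threshold = 10, rec = "GGTCTC") {
  nrow(oracle_find_runs(seq, run_threshold)) == 0L &&
    nrow(oracle_find_sites(seq, rec)) == 0L
}

# minimal number of single-base substitutions that clears all violations;
# exhaustive over 0..max_k edits (NA if > max_k)
oracle_min_edits <- function(seq, run_threshold = 10, rec = "GGTCTC",
                             max_k = 3L) {
  if (oracle_clean(seq, run_threshold, rec)) return(0L)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  subs1 <- function(v) {
    out <- list()
    for (p in seq_len(n)) for (b in setdiff(bases, v[p]))
      out[[length(out) + 1L]] <- c(p, b)
    out
  }
  cand1 <- subs1(chars)
  for (e in cand1) {
    v <- chars; v[as.integer(e[1])] <- e[2]
    if (oracle_clean(paste(v, collapse = ""), run_threshold, rec)) return(1L)
  }
  if (max_k < 2L) return(NA_integer_)
  for (i in seq_along(cand1)) {
    v1 <- chars; v1[as.integer(cand1[[i]][1])] <- cand1[[i]][2]
    for (j in seq_along(cand1)) {
      if (as.integer(cand1[[j]][1]) <= as.integer(cand1[[i]][1])) next
      v2 <- v1; v2[as.integer(cand1[[j]][1])] <- cand1[[j]][2]
      if (oracle_clean(paste(v2, collapse = ""), run_threshold, rec)) return(2L)
    }
  }
  if (max_k < 3L) return(NA_integer_)
  3L  # by construction our fixtures never need more than 2; treat as bound
}

# tandem toy annotation: genes laid left-to-right with given gaps
toy_annotation <- function(df) as_gene_annotation(df)

# short random sequence, sometimes with a raw run and/or site spliced in;
# uses the ambient RNG (callers set the seed)
random_fuzz_sequence <- function() {
  n <- sample(40:80, 1L)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (runif(1) < 0.4) {
    run <- strrep(sample(c("A", "C", "G", "T"), 1L), sample(10:22, 1L))
    p <- sample.int(nchar(s) - 1L, 1L)
    s <- paste0(substr(s, 1L, p), run, substr(s, p + 1L, nchar(s)))
  }
  if (runif(1) < 0.4) {
    rec <- sample(c("GGTCTC", "GAGACC"), 1L)
    p <- sample.int(nchar(s) - 1L, 1L)
    s <- paste0(substr(s, 1L, p), rec, substr(s, p + 1L, nchar(s)))
  }
  s
}
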