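test_that("find_homopolymers reports maximal runs only", {
  expect_equal(find_homopolymers("AAAAAAAAAA", 10),
               data.frame(start = 0L, length = 10L, base = "A"))
  expect_identical(nrow(find_homopolymers("ACGTACGTACGT", 2)), 0L)
  expect_error(find_homopolymers("ACGN", 2), class = "promforge_alphabet")

  pv <- plant_violations(seq_len = 1000, n_runs = 1, run_lengths = 13, seed = 4)
  got <- find_homopolymers(pv$sequence, 10)
  expect_equal(got, oracle_find_runs(pv$sequence, 10), ignore_attr = TRUE)
  expect_equal(got$start, pv$truth$position)
  expect_equal(got$length, 13L)
})

test_that("find_type_iis_sites sees both strands and overlaps", {
  expect_equal(find_type_iis_sites("ttGGTCTCtt"),
               data.frame(position = 2L, strand = "+"))
  expect_equal(find_type_iis_sites("ttGAGACCtt"),
               data.frame(position = 2L, strand = "-"))
  # self-overlapping recognition: every window reported
  expect_equal(find_type_iis_sites("CACACACA", "CACA")$position, c(0L, 2L, 4L))
  for (seed in 1:5) {
    pv <- plant_violations(seq_len = 400, n_runs = 0, n_sites = 2,
                           site_strands = c("+", "-"), seed = seed)
    expect_equal(find_type_iis_sites(pv$sequence),
                 oracle_find_sites(pv$sequence), ignore_attr = TRUE)
  }
})

test_that("domesticate spends the minimal number of edits", {
  ctx <- "cgtacgatcg"
  run12 <- paste0(ctx, strrep("A", 12), ctx)
  d12 <- domesticate(run12)
  expect_identical(nrow(d12$edits), 1L)
  expect_identical(oracle_min_edits(run12), 1L)
  expect_true(oracle_clean(d12$edited))

  run20 <- paste0(ctx, strrep("A", 20), ctx)
  d20 <- domesticate(run20)
  expect_identical(nrow(d20$edits), 2L)
  expect_identical(oracle_min_edits(run20), 2L)
  expect_true(max(oracle_find_runs(d20$edited, 2)$length) <= 9)

  clean <- "acgtacgtacgtacgt"
  dc <- domesticate(clean)
  expect_identical(dc$edited, clean)
  expect_identical(nrow(dc$edits), 0L)
})

test_that("domesticate is idempotent, length-preserving and case-preserving", {
  pv <- plant_violations(seq_len = 300, n_runs = 2, run_lengths = c(11, 15),
                         n_sites = 1, seed = 12)
  mixed <- paste0(tolower(substr(pv$sequence, 1, 150)),
                  toupper(substr(pv$sequence, 151, 300)))
  d1 <- domesticate(mixed)
  expect_identical(nchar(d1$edited), nchar(mixed))
  d2 <- domesticate(d1$edited)
  expect_identical(d2$edited, d1$edited)
  expect_identical(nrow(d2$edits), 0L)
  # case pattern untouched
  expect_identical(gsub("[ACGT]", "X", gsub("[acgt]", "x", d1$edited)),
                   gsub("[ACGT]", "X", gsub("[acgt]", "x", mixed)))
  # applying the edit log to the original reproduces the edited sequence
  rebuilt <- strsplit(mixed, "")[[1]]
  for (i in seq_len(nrow(d1$edits)))
    rebuilt[d1$edits$position[i] + 1L] <- d1$edits$alt[i]
  expect_identical(paste(rebuilt, collapse = ""), d1$edited)
})

test_that("aggressive thresholds still converge or fail loudly", {
  d <- domesticate(strrep("A", 12),
                   domestication_config(run_threshold = 2))
  expect_identical(nrow(d$edits), 6L)  # floor(12/2)
  expect_true(nrow(find_homopolymers(d$edited, 2)) == 0L)
  expect_error(domesticate(""), class = "promforge_unsatisfiable")
})

test_that("append_cloning_linker adds exactly the 15 bp linker", {
  expect_identical(append_cloning_linker(""), "aaaagcaggctaaaa")
  expect_identical(nchar(append_cloning_linker("")), 15L)
  s <- "ACGTACGT"
  expect_identical(nchar(append_cloning_linker(s)), nchar(s) + 15L)
  # the panel's own entries are endogenous promoter + linker + ATG
  panel <- promoter_panel()
  endo <- promoter_panel(strip = "linker_atg")
  expect_identical(unname(paste0(vapply(endo, append_cloning_linker, ""), "ATG")),
                   unname(panel))
})

test_that("add_flanks builds a two-site fragment and rejects bad input", {
  part <- "ccttggaaccttggaacc"
  frag <- add_flanks(part, "AATG", "GCTT")
  sites <- find_type_iis_sites(frag)
  expect_identical(nrow(sites), 2L)
  expect_setequal(sites$strand, c("+", "-"))
  expect_error(add_flanks(part, "AATG", "AATG"), class = "promforge_overhang")
  expect_error(add_flanks(part, "AATG", "GCT"), class = "promforge_overhang")
  dirty <- paste0("cc", "GGTCTC", part)
  expect_error(add_flanks(dirty, "AATG", "GCTT"), class = "promforge_dirty_part")
})

test_that("validate_part separates flank from internal violations", {
  part <- "ccttggaaccttggaacc"
  frag <- add_flanks(part, "AATG", "GCTT")
  rep1 <- validate_part(frag)
  expect_identical(rep1$flank_sites, 2L)
  expect_identical(rep1$internal_sites, 0L)
  expect_identical(rep1$internal_runs, 0L)
  expect_true(rep1$orientation_ok && rep1$ok)

  planted <- paste0(substr(frag, 1, 15), "GGTCTC",
                    substr(frag, 16, nchar(frag)))
  rep2 <- validate_part(planted)
  expect_identical(rep2$internal_sites, 1L)
  expect_false(rep2$ok)
})

test_that("soundness fuzz: domestication never leaves or creates violations", {
  set.seed(99)
  n_fuzz <- 400  # acceptance runs the full 10,000-sequence sweep
  for (i in seq_len(n_fuzz)) {
    s <- random_fuzz_sequence()
    d <- domesticate(s)
    expect_true(oracle_clean(d$edited), info = s)
    expect_identical(nchar(d$edited), nchar(s))
  }
})
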