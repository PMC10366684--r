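test_that("generators are pure functions of (parameters, seed)", {
  a <- synth_genome_annotation(n_genes = 20, seed = 3)
  b <- synth_genome_annotation(n_genes = 20, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$genome,
                         synth_genome_annotation(n_genes = 20, seed = 4)$genome))

  expect_identical(synth_expression(letters, seed = 5),
                   synth_expression(letters, seed = 5))
  expect_identical(plant_violations(seed = 6), plant_violations(seed = 6))
  expect_identical(synth_copas(c(a = 1, b = 3), seed = 7),
                   synth_copas(c(a = 1, b = 3), seed = 7))
  # two seeds: different tables, same truth structure
  e1 <- synth_expression(letters, seed = 1)
  e2 <- synth_expression(letters, seed = 2)
  expect_false(identical(e1$table, e2$table))
  expect_identical(names(e1$truth), names(e2$truth))
})

test_that("planted short upstream gaps are exactly the designable promoters", {
  g <- synth_genome_annotation(n_genes = 50,
                               intergenic = list(short = c(200, 900),
                                                 long = c(1500, 4000),
                                                 n_short = 10),
                               seed = 14)
  recovered <- Filter(Negate(is.null), lapply(g$annotation$gene_id,
    function(id) {
      reg <- tryCatch(extract_promoter_region(g$annotation, id),
                      promforge_no_neighbor = function(e) NULL)
      if (!is.null(reg) && reg$length_bp <= 1000) id else NULL
    }))
  expect_setequal(unlist(recovered), g$truth$planted_short_gap_gene_ids)

  # without strand flips the planted count is exactly n_short
  g0 <- synth_genome_annotation(n_genes = 50, strand_flip_prob = 0, seed = 14)
  expect_identical(length(g0$truth$planted_short_gap_gene_ids), 10L)
})

test_that("strand_flip_prob = 0 forces all-tandem stop_codon boundaries", {
  g <- synth_genome_annotation(n_genes = 15, strand_flip_prob = 0, seed = 2)
  bounds <- vapply(g$annotation$gene_id[-1], function(id)
    extract_promoter_region(g$annotation, id)$adjacent_boundary, "")
  expect_true(all(bounds == "stop_codon"))
})

test_that("expression fractions hit the analytic values in the noiseless limit", {
  ids <- sprintf("g%03d", 1:50)
  e0 <- synth_expression(ids, n_enriched = 5, enrichment_fold = 10,
                         noise_cv = 0, renormalize = FALSE, seed = 1)
  fr <- tissue_fractions(e0$table)
  enr <- fr$gene_id %in% e0$truth$enriched_gene_ids
  expect_equal(fr$germline[enr], rep(10 / 14, 5), tolerance = 1e-12)
  expect_equal(fr$germline[!enr], rep(1 / 5, 45), tolerance = 1e-12)

  # with noise and a small enriched minority, enrichment survives TPM
  # renormalization
  ids500 <- sprintf("g%03d", 1:500)
  e1 <- synth_expression(ids500, n_enriched = 5, enrichment_fold = 10,
                         noise_cv = 0.1, seed = 3)
  fr1 <- tissue_fractions(e1$table)
  enr1 <- fr1$gene_id %in% e1$truth$enriched_gene_ids
  expect_gt(mean(fr1$germline[enr1]), 0.6)
  expect_lt(abs(mean(fr1$germline[!enr1]) - 0.2), 0.02)
})

test_that("plant_violations plants exactly what it reports", {
  pv <- plant_violations(seq_len = 800, n_runs = 1, run_lengths = 13,
                         n_sites = 1, site_strands = "-", seed = 10)
  runs <- find_homopolymers(pv$sequence, 10)
  sites <- find_type_iis_sites(pv$sequence)
  truth_run <- pv$truth[pv$truth$kind == "homopolymer", ]
  truth_site <- pv$truth[pv$truth$kind == "type_iis", ]
  expect_identical(runs$start, truth_run$position)
  expect_identical(runs$length, truth_run$length)
  expect_identical(runs$base, truth_run$detail)
  expect_identical(sites$position, truth_site$position)
  expect_identical(sites$strand, "-")

  clean <- plant_violations(seq_len = 500, n_runs = 0, n_sites = 0, seed = 20)
  expect_identical(nrow(domesticate(clean$sequence)$edits), 0L)
  expect_error(plant_violations(seq_len = 30, n_runs = 3, run_lengths = 13,
                                seed = 1),
               class = "promforge_config")
})

test_that("synth_copas honors planted folds and stage mixture", {
  sc <- synth_copas(c(control = 1, s5 = 5), n_events = 5000, seed = 8)
  s <- relative_to_control(summarize_strains(gate_adults(sc$events)),
                           "control", "ratio")
  expect_lt(abs(s$relative_to_control[s$strain == "s5"] / 5 - 1), 0.05)

  # debris-free, tight adult TOF: the gate passes every event
  tight <- synth_copas(c(s = 1), n_events = 2000, adult_fraction = 1,
                       adult_tof = c(1650, 10), debris_rate = 0, seed = 9)
  expect_identical(nrow(gate_adults(tight$events)), 2000L)
})

test_that("truth records round-trip through JSON losslessly", {
  g <- synth_genome_annotation(n_genes = 10,
                               intergenic = list(short = c(200, 900),
                                                 long = c(1500, 4000),
                                                 n_short = 3),
                               seed = 12)
  tf <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, tf)
  back <- read_truth(tf)
  expect_identical(back$planted_short_gap_gene_ids,
                   g$truth$planted_short_gap_gene_ids)
  expect_identical(unlist(back$upstream_gap_bp),
                   unlist(lapply(g$truth$upstream_gap_bp, as.integer)))
  # JSON has one number type, so 12 comes back integer; compare by value
  expect_equal(back$rng_seed, g$truth$rng_seed)
})
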