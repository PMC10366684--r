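ev <- function(tof, ext, green = 100, strain = "s") {
  data.frame(strain = strain, tof = tof, extinction = ext, green = green,
             stringsAsFactors = FALSE)
}

test_that("gating applies inclusive TOF bounds and a strict extinction bound", {
  events <- rbind(ev(1499, 100), ev(1500, 100), ev(1800, 100), ev(1801, 100),
                  ev(1600, 35000), ev(1600, 34999))
  g <- gate_adults(events)
  expect_identical(g$tof, c(1500, 1800, 1600))
  expect_identical(g$extinction, c(100, 100, 34999))
  expect_identical(attr(g, "gating")$tof_inclusive, TRUE)
})

test_that("gating recovers a planted adult fraction and is monotone", {
  sc <- synth_copas(c(s = 1), n_events = 10000, adult_fraction = 0.3,
                    debris_rate = 0, seed = 31)
  g <- gate_adults(sc$events)
  frac <- nrow(g) / nrow(sc$events)
  p_window <- diff(pnorm(c(1500, 1800), 1650, 50))
  expect_lt(abs(frac - 0.3 * p_window), 0.03)

  wide <- gate_adults(sc$events, gating_config(tof_min = 1000, tof_max = 2500,
                                               extinction_max = 50000))
  key <- function(d) paste(d$tof, d$extinction, d$green)
  expect_true(all(key(g) %in% key(wide)))
})

test_that("strain summaries use mean and n-1 SEM", {
  events <- ev(rep(1600, 3), 100, green = c(1, 2, 3))
  s <- summarize_strain(events, "s")
  expect_identical(s$mean_green, 2)
  expect_equal(s$sem_green, 1 / sqrt(3))
  single <- summarize_strain(ev(1600, 100, green = 7), "s")
  expect_true(is.na(single$sem_green))
  expect_error(summarize_strain(events, "ghost"),
               class = "promforge_missing_strain")

  # permutation invariance
  sc <- synth_copas(c(a = 1, b = 4), n_events = 300, seed = 17)
  g <- gate_adults(sc$events)
  expect_equal(summarize_strains(g),
               summarize_strains(g[rev(seq_len(nrow(g))), ]))
})

test_that("large-sample mean is within 3 SEM of the lognormal analytic mean", {
  mu <- log(100); sig <- 0.5
  sc <- synth_copas(c(s = 1), n_events = 10000, adult_fraction = 1,
                    debris_rate = 0, green_meanlog = mu, green_sdlog = sig,
                    seed = 23)
  s <- summarize_strain(gate_adults(sc$events), "s")
  expect_lt(abs(s$mean_green - exp(mu + sig^2 / 2)), 3 * s$sem_green)
})

test_that("baseline subtraction and relative modes behave as documented", {
  summaries <- data.frame(strain = c("N2", "a", "b"), n_gated = 10L,
                          mean_green = c(100, 350, 350), sem_green = 1)
  bs <- baseline_subtract(summaries, "N2")
  expect_identical(bs$baseline_subtracted_mean, c(0, 250, 250))
  expect_identical(diff(bs$baseline_subtracted_mean[2:3]),
                   diff(summaries$mean_green[2:3]))
  rr <- relative_to_control(summaries, "N2", "ratio")
  expect_identical(rr$relative_to_control, c(1, 3.5, 3.5))
  expect_identical(attr(rr, "relative_mode"), "ratio")
  rd <- relative_to_control(summaries, "N2", "difference")
  expect_identical(rd$relative_to_control, c(0, 250, 250))
  expect_error(baseline_subtract(summaries, "missing"),
               class = "promforge_missing_control")
  zero <- summaries; zero$mean_green[1] <- 0
  expect_error(relative_to_control(zero, "N2", "ratio"),
               class = "promforge_zero_control")
})

test_that("planted fold-changes are recovered by ratio normalization", {
  folds <- c(control = 1, x2 = 2, x5 = 5, x10 = 10)
  sc <- synth_copas(folds, n_events = 5000, seed = 41)
  s <- relative_to_control(summarize_strains(gate_adults(sc$events)),
                           "control", "ratio")
  got <- setNames(s$relative_to_control, s$strain)[names(folds)]
  expect_true(all(abs(got / folds - 1) < 0.05))
})

test_that("visual scores aggregate per strain with blinding decoded", {
  scores <- data.frame(strain = c("c1", "c1", "c1", "c2", "c2", "c2"),
                       plate = rep(1:3, 2), score = c(4L, 4L, 3L, 0L, 0L, 0L))
  blinding <- c(c1 = "bright", c2 = "dark")
  s <- score_summary(scores, blinding)
  bright <- s[s$strain == "bright", ]
  expect_equal(bright$mean_score, mean(c(4, 4, 3)), tolerance = 1e-12)
  expect_equal(bright$sem_score, sd(c(4, 4, 3)) / sqrt(3), tolerance = 1e-12)
  expect_identical(s$mean_score[s$strain == "dark"], 0)
  expect_error(score_summary(scores, c(c1 = "bright")),
               class = "promforge_blind_code")
  bad <- scores; bad$score[1] <- 5L
  expect_error(score_summary(bad), class = "promforge_score")
})

test_that("visual means and cytometry ratios agree on concordant data", {
  folds <- c(ctrl = 1, lo = 2, mid = 5, hi = 12, top = 20)
  sc <- synth_copas(folds, n_events = 2000, seed = 13)
  s <- relative_to_control(summarize_strains(gate_adults(sc$events)),
                           "ctrl", "ratio")
  ratios <- setNames(s$relative_to_control, s$strain)
  # monotone mapping of planted folds to 0..4 plate scores
  level <- setNames(as.integer(cut(folds, c(0, 1.5, 3, 8, 15, Inf))) - 1L,
                    names(folds))
  scores <- data.frame(strain = rep(names(folds), each = 3),
                       plate = 1:3, score = rep(level, each = 3))
  vs <- score_summary(scores)
  common <- vs$strain
  rho <- cor(vs$mean_score, ratios[common], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("pattern counting enforces the closed set and uniqueness", {
  counts <- classify_and_count(expression_patterns())
  expect_identical(counts, c(somatic_and_germline = 6L, none = 3L,
                             germline_specific = 9L))
  expect_identical(sum(counts), nrow(expression_patterns()))
  empty <- data.frame(promoter_id = character(), pattern = character())
  expect_identical(unname(classify_and_count(empty)), c(0L, 0L, 0L))
  one <- data.frame(promoter_id = "p", pattern = "none")
  expect_identical(classify_and_count(one)[["none"]], 1L)
  dup <- data.frame(promoter_id = c("p", "p"), pattern = "none")
  expect_error(classify_and_count(dup), class = "promforge_duplicate")
  alien <- data.frame(promoter_id = "p", pattern = "pansomatic")
  expect_error(classify_and_count(alien), class = "promforge_pattern")
})
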