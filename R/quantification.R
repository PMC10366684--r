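#' COPAS gating configuration
#'
#' Defaults reproduce the published adult gate: time of flight between 1500
#' and 1800 (bounds inclusive) and peak-height extinction strictly below
#' 35,000. Both boundary conventions are configurable and recorded in the
#' gated output's metadata.
#'
#' @param tof_min,tof_max Time-of-flight window (instrument units).
#' @param extinction_max Upper extinction bound (instrument units).
#' @param tof_inclusive Include events exactly at the TOF bounds?
#' @param extinction_strict Exclude events exactly at `extinction_max`?
#' @return List of class `gating_config`.
#' @export
gating_config <- function(tof_min = 1500, tof_max = 1800,
                          extinction_max = 35000,
                          tof_inclusive = TRUE, extinction_strict = TRUE) {
  if (tof_min >= tof_max) pf_stop("config", "tof_min must be < tof_max")
  if (extinction_max <= 0) pf_stop("config", "extinction_max must be positive")
  structure(list(tof_min = tof_min, tof_max = tof_max,
                 extinction_max = extinction_max,
                 tof_inclusive = tof_inclusive,
                 extinction_strict = extinction_strict),
            class = "gating_config")
}

#' Read a COPAS event table
#'
#' Accepts the documented CSV/TSV schema `strain,tof,extinction,green[,red]`
#' or any vendor export via `column_map`, which maps the canonical names to
#' the file's column names.
#'
#' @param path CSV (`.csv`) or TSV file.
#' @param column_map Named character vector, canonical -> file column.
#' @return Data frame with columns `strain`, `tof`, `extinction`, `green`.
#' @export
read_copas_events <- function(path,
                              column_map = c(strain = "strain", tof = "tof",
                                             extinction = "extinction",
                                             green = "green")) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, stringsAsFactors = FALSE)
  else read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(column_map), names(df))
  if (length(missing))
    pf_stop("load", "event table is missing column(s): %s",
            paste(missing, collapse = ", "))
  out <- data.frame(strain = as.character(df[[column_map[["strain"]]]]),
                    tof = as.numeric(df[[column_map[["tof"]]]]),
                    extinction = as.numeric(df[[column_map[["extinction"]]]]),
                    green = as.numeric(df[[column_map[["green"]]]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$tof) || anyNA(out$extinction) || anyNA(out$green))
    pf_stop("load", "event table has missing measurements")
  if (any(out$tof < 0) || any(out$extinction < 0))
    pf_stop("load", "tof and extinction must be non-negative")
  out
}

#' Gate adult animals from a mixed-stage COPAS run
#'
#' Keeps events inside the TOF window and below the extinction bound;
#' order-preserving. The applied conventions are attached as attribute
#' `"gating"`.
#'
#' @param events Event data frame (see [read_copas_events()]).
#' @param config A [gating_config()].
#' @return The gated subset of `events`.
#' @export
gate_adults <- function(events, config = gating_config()) {
  tof_ok <- if (config$tof_inclusive)
    events$tof >= config$tof_min & events$tof <= config$tof_max
  else events$tof > config$tof_min & events$tof < config$tof_max
  ext_ok <- if (config$extinction_strict)
    events$extinction < config$extinction_max
  else events$extinction <= config$extinction_max
  out <- events[tof_ok & ext_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gating") <- unclass(config)
  out
}

#' Summarize green fluorescence for one strain
#'
#' @param events Gated event data frame.
#' @param strain Strain label.
#' @return One-row data frame `strain`, `n_gated`, `mean_green`, `sem_green`
#'   (`NA` when n < 2; SEM uses the n-1 sample standard deviation).
#' @export
summarize_strain <- function(events, strain) {
  g <- events$green[events$strain == strain]
  if (!length(g))
    pf_stop("missing_strain", "no gated events for strain '%s'", strain)
  data.frame(strain = strain, n_gated = length(g), mean_green = mean(g),
             sem_green = if (length(g) >= 2L) sd(g) / sqrt(length(g)) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Summarize all strains in a gated event table
#'
#' @param events Gated event data frame.
#' @return Data frame with one row per strain (see [summarize_strain()]),
#'   ordered by strain label.
#' @export
summarize_strains <- function(events) {
  strains <- sort(unique(events$strain))
  out <- do.call(rbind, lapply(strains, summarize_strain, events = events))
  rownames(out) <- NULL
  out
}

#' Subtract the non-transgenic baseline
#'
#' Subtracts the control strain's mean green value from every strain's mean;
#' the control's own baseline-subtracted mean is exactly 0 and differences
#' between strains are preserved.
#'
#' @param summaries Output of [summarize_strains()].
#' @param control_strain Label of the non-transgenic control.
#' @return `summaries` with an added `baseline_subtracted_mean` column.
#' @export
baseline_subtract <- function(summaries, control_strain) {
  i <- match(control_strain, summaries$strain)
  if (is.na(i))
    pf_stop("missing_control", "control strain '%s' not in summaries",
            control_strain)
  summaries$baseline_subtracted_mean <-
    summaries$mean_green - summaries$mean_green[i]
  summaries
}

#' Express strain means relative to a control
#'
#' `difference` mode is baseline subtraction; `ratio` mode divides each
#' strain's mean by the control mean. The mode is recorded as attribute
#' `"relative_mode"` so downstream tables never silently mix the two.
#'
#' @param summaries Output of [summarize_strains()].
#' @param control_strain Control strain label.
#' @param mode `"difference"` or `"ratio"`.
#' @return `summaries` with an added `relative_to_control` column.
#' @export
relative_to_control <- function(summaries, control_strain,
                                mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  i <- match(control_strain, summaries$strain)
  if (is.na(i))
    pf_stop("missing_control", "control strain '%s' not in summaries",
            control_strain)
  ctrl <- summaries$mean_green[i]
  if (mode == "ratio") {
    if (ctrl == 0)
      pf_stop("zero_control", "control mean is zero; ratio undefined")
    summaries$relative_to_control <- summaries$mean_green / ctrl
  } else {
    summaries$relative_to_control <- summaries$mean_green - ctrl
  }
  attr(summaries, "relative_mode") <- mode
  summaries
}

#' Summarize blinded visual scores
#'
#' Scores are integers 0 (no detectable expression at 20x) through 4
#' (detectable at 2x without zoom), recorded per plate replicate (three
#' plates per strain in the published design). An optional blinding map
#' (named vector, blind code -> strain) is applied before aggregation.
#'
#' @param scores Data frame `strain` (or blind code), `plate`, `score`.
#' @param blinding Optional named character vector decoding blind labels.
#' @return Data frame `strain`, `n_plates`, `mean_score`, `sem_score`.
#' @export
score_summary <- function(scores, blinding = NULL) {
  stopifnot(all(c("strain", "score") %in% names(scores)))
  if (!all(scores$score %in% 0:4))
    pf_stop("score", "visual scores must be integers in 0..4")
  if (!is.null(blinding)) {
    unknown <- setdiff(unique(scores$strain), names(blinding))
    if (length(unknown))
      pf_stop("blind_code", "unknown blind code(s): %s",
              paste(unknown, collapse = ", "))
    scores$strain <- unname(blinding[scores$strain])
  }
  agg <- aggregate(score ~ strain, scores, function(x)
    c(n = length(x), mean = mean(x),
      sem = if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_))
  data.frame(strain = agg$strain,
             n_plates = as.integer(agg$score[, "n"]),
             mean_score = agg$score[, "mean"],
             sem_score = agg$score[, "sem"],
             stringsAsFactors = FALSE)
}

#' The closed set of expression-pattern categories
#' @export
EXPRESSION_PATTERNS <- c("somatic_and_germline", "none", "germline_specific")

#' Count promoters per expression pattern
#'
#' @param records Data frame `promoter_id`, `pattern`; each promoter must
#'   appear exactly once and patterns come from [EXPRESSION_PATTERNS].
#' @return Named integer vector of counts over the full closed set.
#' @export
classify_and_count <- function(records) {
  stopifnot(all(c("promoter_id", "pattern") %in% names(records)))
  if (anyDuplicated(records$promoter_id))
    pf_stop("duplicate", "promoter(s) classified more than once: %s",
            paste(unique(records$promoter_id[duplicated(records$promoter_id)]),
                  collapse = ", "))
  bad <- setdiff(unique(records$pattern), EXPRESSION_PATTERNS)
  if (length(bad))
    pf_stop("pattern", "unknown pattern(s): %s", paste(bad, collapse = ", "))
  counts <- table(factor(records$pattern, levels = EXPRESSION_PATTERNS))
  setNames(as.integer(counts), EXPRESSION_PATTERNS)
}

#' Write a strain summary table
#'
#' @param summaries Summary data frame (after [relative_to_control()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_strain_summary <- function(summaries, path) {
  out <- data.frame(strain = summaries$strain, n = summaries$n_gated,
                    mean = summaries$mean_green, sem = summaries$sem_green,
                    baseline_subtracted =
                      summaries$baseline_subtracted_mean %||% NA_real_,
                    relative_mode = attr(summaries, "relative_mode") %||% NA,
                    relative_value = summaries$relative_to_control %||% NA_real_)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
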