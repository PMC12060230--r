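#' Read a recording-level song trait table
#'
#' Reads a tab-separated file with one row per 30-minute song recording.
#' Mandatory columns are `strain_id`, `cohort`, `replicate_id`,
#' `song_seconds_per_min` (seconds of song per minute of assay) and
#' `sine_seconds_total` (total seconds of characterised sine song in the
#' recording). Every remaining numeric column is treated as a song trait
#' (counts/min, seconds, Hz, probabilities, ratios or arbitrary amplitude
#' units). Unparseable numeric cells become `NA` with a warning; missing
#' values are propagated as missing, never as zero.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @return A tibble with one row per recording.
#' @export
read_recordings <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA"))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    warn(sprintf(
      "%d cell(s) could not be parsed and were set to missing (first at row %d, column %d)",
      nrow(probs), probs$row[1], probs$col[1]
    ))
  }
  check_columns(x, recording_required_cols(), "recordings file")
  as_tibble(x)
}

#' Write a recording-level trait table
#'
#' @param records A recordings tibble (see [read_recordings()]).
#' @param path Output path; tab-separated, UTF-8.
#' @return `records`, invisibly.
#' @export
write_recordings <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(records)
}

recording_required_cols <- function() {
  c("strain_id", "cohort", "replicate_id",
    "song_seconds_per_min", "sine_seconds_total")
}

# Trait columns = numeric columns that are not bookkeeping fields.
trait_columns <- function(records) {
  candidates <- setdiff(names(records),
                        c(recording_required_cols(), "assay_day"))
  candidates[vapply(records[candidates], is.numeric, logical(1))]
}

#' Filter song recordings on minimum song and maximum sine amounts
#'
#' A recording is retained iff it contains at least `min_song` seconds of
#' song per minute and at most `max_sine` total seconds of sine song
#' (aberrantly high sine totals indicate a recording-equipment failure).
#' Boundary values are retained: exclusion fires only on strict violation.
#' Recordings with a missing quality field are excluded.
#'
#' @param records A recordings tibble.
#' @param min_song Minimum seconds of song per minute (default 1).
#' @param max_sine Maximum total seconds of sine song per recording
#'   (default 55). Applied per recording; see the package vignette for the
#'   rationale and how to rescale it if your assays are not 30 minutes.
#' @return The retained rows, with the exclusion report (one row per excluded
#'   recording, with the triggering rule) attached as attribute
#'   `"exclusions"`; retrieve it with [exclusion_report()].
#' @export
filter_recordings <- function(records, min_song = 1, max_sine = 55) {
  check_columns(records, recording_required_cols(), "records")
  song <- records$song_seconds_per_min
  sine <- records$sine_seconds_total
  low_song  <- !is.na(song) & song < min_song
  high_sine <- !is.na(sine) & sine > max_sine
  missing_qc <- is.na(song) | is.na(sine)
  keep <- !low_song & !high_sine & !missing_qc
  rule <- dplyr::case_when(
    low_song & high_sine ~ "low_song;high_sine",
    low_song             ~ "low_song",
    high_sine            ~ "high_sine",
    missing_qc           ~ "missing_qc_field",
    TRUE                 ~ NA_character_
  )
  report <- records[!keep, c("strain_id", "cohort", "replicate_id",
                             "song_seconds_per_min", "sine_seconds_total")]
  report$rule <- rule[!keep]
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusions") <- as_tibble(report)
  out
}

#' Exclusion report of a filtered recordings table
#'
#' @param records The result of [filter_recordings()].
#' @return A tibble with one row per excluded recording and its rule.
#' @export
exclusion_report <- function(records) {
  rep <- attr(records, "exclusions")
  if (is.null(rep)) {
    abort("no exclusion report attached; did you call filter_recordings()?")
  }
  rep
}

#' Strain-level trait means with per-trait zero exclusion
#'
#' Collapses retained recordings to one row per strain. For each trait the
#' strain value is the mean over replicates whose value is neither zero nor
#' missing: the song-analysis software emits zero when it failed to measure a
#' trait, so zeros are treated as unmeasured for that trait only (the
#' recording still contributes to other traits). A cell is missing iff no
#' replicate qualified. Per-cell replicate counts are attached as attribute
#' `"replicate_counts"` (same shape as the table).
#'
#' @param records Filtered recordings (see [filter_recordings()]).
#' @param traits Character vector of trait columns; default all numeric
#'   trait columns.
#' @return A tibble with columns `strain_id`, `cohort`, then one column per
#'   trait.
#' @export
strain_trait_means <- function(records, traits = NULL) {
  check_columns(records, c("strain_id", "cohort", "replicate_id"), "records")
  if (anyDuplicated(records[c("strain_id", "replicate_id")]) > 0) {
    dup <- records[duplicated(records[c("strain_id", "replicate_id")]), ]
    abort(sprintf("duplicate (strain, replicate) keys, e.g. (%s, %s)",
                  dup$strain_id[1], dup$replicate_id[1]))
  }
  if (is.null(traits)) traits <- trait_columns(records)
  mean_nonzero <- function(v) {
    v <- v[!is.na(v) & v != 0]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  n_nonzero <- function(v) sum(!is.na(v) & v != 0)
  means <- records %>%
    group_by(.data$strain_id, .data$cohort) %>%
    summarise(across(all_of(traits), mean_nonzero), .groups = "drop") %>%
    arrange(.data$strain_id)
  counts <- records %>%
    group_by(.data$strain_id, .data$cohort) %>%
    summarise(across(all_of(traits), n_nonzero), .groups = "drop") %>%
    arrange(.data$strain_id)
  attr(means, "replicate_counts") <- counts
  means
}

#' Pairwise Pearson correlations between traits across strains
#'
#' Computes Pearson's r with its raw two-sided p-value for every trait pair,
#' using pairwise-complete strains. Each pair is assigned a significance tier
#' by raw p: `"1e-9"`, `"1e-6"`, `"1e-3"`, `"0.05"` (strict `<` thresholds)
#' or `"none"`. Pairs with fewer than 3 complete strains are flagged
#' not-computable (`computable = FALSE`, `r = NA`).
#'
#' @param table A strain trait table (see [strain_trait_means()]).
#' @param cohort Optional cohort label(s) to subset strains before
#'   correlating (e.g. `"FR"`).
#' @param traits Trait columns; default all numeric columns.
#' @return A long tibble with columns `trait_a`, `trait_b`, `r`, `p`, `n`,
#'   `tier`, `computable`, containing all ordered pairs including the
#'   diagonal, so that pivoting yields a symmetric matrix with unit diagonal.
#' @export
trait_correlations <- function(table, cohort = NULL, traits = NULL) {
  if (!is.null(cohort)) table <- table[table$cohort %in% cohort, , drop = FALSE]
  if (is.null(traits)) {
    traits <- setdiff(names(table), c("strain_id", "cohort"))
    traits <- traits[vapply(table[traits], is.numeric, logical(1))]
  }
  m <- as.matrix(table[traits])
  pairs <- tidyr::expand_grid(trait_a = traits, trait_b = traits)
  res <- purrr::pmap_dfr(pairs, function(trait_a, trait_b) {
    x <- m[, trait_a]
    y <- m[, trait_b]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) {
      return(tibble(trait_a = trait_a, trait_b = trait_b, r = NA_real_,
                    p = NA_real_, n = n, computable = FALSE))
    }
    if (trait_a == trait_b) {
      return(tibble(trait_a = trait_a, trait_b = trait_b, r = 1,
                    p = 0, n = n, computable = TRUE))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "pearson"))
    tibble(trait_a = trait_a, trait_b = trait_b,
           r = unname(ct$estimate), p = ct$p.value, n = n, computable = TRUE)
  })
  res$tier <- correlation_tier(res$p)
  res
}

correlation_tier <- function(p) {
  dplyr::case_when(
    is.na(p)    ~ NA_character_,
    p < 1e-9    ~ "1e-9",
    p < 1e-6    ~ "1e-6",
    p < 1e-3    ~ "1e-3",
    p < 0.05    ~ "0.05",
    TRUE        ~ "none"
  )
}

#' Pivot long trait correlations to a symmetric matrix
#'
#' @param correlations Output of [trait_correlations()].
#' @param value Which column to spread: `"r"` (default) or `"p"`.
#' @return A symmetric numeric matrix with traits as dimnames.
#' @export
correlation_matrix <- function(correlations, value = c("r", "p")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    correlations[c("trait_a", "trait_b", value)],
    names_from = "trait_b", values_from = all_of(value)
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$trait_a
  m[rownames(m), , drop = FALSE]
}
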