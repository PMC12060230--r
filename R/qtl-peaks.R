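#' Contiguous runs of genome-wide significant windows
#'
#' Finds maximal runs of consecutive unmasked windows with `lod >= threshold`.
#' Runs never span two adjacency units (chromosomes by default, so a run may
#' cross a centromere between two arms of the same chromosome whose windows
#' are contiguous in the panel; set `adjacency = "arm"` to break runs at arm
#' boundaries). A masked window interrupts a run; bridging across masked
#' stretches is handled later by [extend_through_masked()].
#'
#' @param profile A `lod_profile` (see [lod_scan()]).
#' @param threshold Genome-wide LOD significance threshold (see
#'   [perm_threshold()]).
#' @param adjacency `"chromosome"` (default) or `"arm"`.
#' @return A tibble with one row per run: `region_id`, `unit`, `start_idx`,
#'   `end_idx` (row indices into `profile`), `max_lod`, `peak_idx`
#'   (leftmost window attaining the maximum).
#' @export
significant_regions <- function(profile, threshold,
                                adjacency = c("chromosome", "arm")) {
  adjacency <- match.arg(adjacency)
  unit <- adjacency_unit(profile$arm, adjacency)
  sig <- !profile$masked & !is.na(profile$lod) & profile$lod >= threshold
  runs <- contiguous_runs(sig, unit)
  if (nrow(runs) == 0) {
    return(tibble(region_id = integer(), unit = character(),
                  start_idx = integer(), end_idx = integer(),
                  max_lod = numeric(), peak_idx = integer()))
  }
  runs$region_id <- seq_len(nrow(runs))
  runs$max_lod <- NA_real_
  runs$peak_idx <- NA_integer_
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start_idx[i]:runs$end_idx[i]
    lods <- profile$lod[idx]
    runs$max_lod[i] <- max(lods, na.rm = TRUE)
    runs$peak_idx[i] <- idx[which.max(lods)]
  }
  runs[c("region_id", "unit", "start_idx", "end_idx", "max_lod", "peak_idx")]
}

adjacency_unit <- function(arm, adjacency) {
  if (adjacency == "arm") as.character(arm) else sub("[LR]$", "", arm)
}

contiguous_runs <- function(flag, unit) {
  n <- length(flag)
  if (n == 0 || !any(flag)) {
    return(tibble(unit = character(), start_idx = integer(),
                  end_idx = integer()))
  }
  newrun <- flag & (c(TRUE, !flag[-n]) | c(TRUE, unit[-n] != unit[-1]))
  run_id <- cumsum(newrun)
  run_id[!flag] <- NA
  idx <- which(flag)
  starts <- tapply(idx, run_id[idx], min)
  ends <- tapply(idx, run_id[idx], max)
  tibble(unit = unit[as.integer(starts)],
         start_idx = as.integer(starts), end_idx = as.integer(ends))
}

#' Merge neighbouring significant runs separated by shallow valleys
#'
#' Two adjacent runs on the same adjacency unit are merged when the minimum
#' LOD over the valley strictly between them is greater than the shorter
#' peak's maximum LOD minus `lod_drop`: a 1.5-LOD support interval for the
#' shorter peak would then include the taller peak, so they are treated as
#' one QTL region. The valley minimum is taken over unmasked windows only;
#' if every window between two runs is masked, the runs are merged. The
#' rule is applied left to right and iterated to a fixed point; a merged
#' region's maximum is the maximum over its constituents.
#'
#' @param runs Output of [significant_regions()].
#' @param profile The `lod_profile` the runs were derived from.
#' @param lod_drop LOD drop defining support (default 1.5).
#' @return A tibble in the same shape as `runs`, with `region_id` renumbered.
#' @export
merge_regions <- function(runs, profile, lod_drop = 1.5) {
  if (nrow(runs) <= 1) return(runs)
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < nrow(runs)) {
      if (runs$unit[i] == runs$unit[i + 1]) {
        between <- seq(runs$end_idx[i] + 1, runs$start_idx[i + 1] - 1)
        between <- between[between >= runs$end_idx[i] + 1 &
                             between <= runs$start_idx[i + 1] - 1]
        lods <- profile$lod[between][!profile$masked[between]]
        valley_min <- if (length(lods) == 0) Inf else min(lods, na.rm = TRUE)
        shorter_max <- min(runs$max_lod[i], runs$max_lod[i + 1])
        if (valley_min > shorter_max - lod_drop) {
          runs$end_idx[i] <- runs$end_idx[i + 1]
          if (runs$max_lod[i + 1] > runs$max_lod[i]) {
            runs$max_lod[i] <- runs$max_lod[i + 1]
            runs$peak_idx[i] <- runs$peak_idx[i + 1]
          }
          runs <- runs[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
          next
        }
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  runs$region_id <- seq_len(nrow(runs))
  runs
}

#' Inclusive and restrictive confidence intervals of a QTL region
#'
#' Within a region, the qualifying windows are the unmasked windows whose
#' LOD is strictly greater than the region's maximum LOD minus `lod_drop`.
#' The inclusive CI is the contiguous span from the leftmost to the
#' rightmost qualifying window (it may contain non-qualifying windows). The
#' restrictive CI is the set of maximal runs of qualifying windows and may
#' be noncontiguous; these sub-peak intervals are the most likely to contain
#' the causative locus. Masked windows inside the region do not break a
#' restrictive run (they carry no LOD and are bridged).
#'
#' @param region A one-row slice of the output of [merge_regions()] (or
#'   [significant_regions()]).
#' @param profile The `lod_profile`.
#' @param lod_drop LOD drop defining support (default 1.5).
#' @return A list with `inclusive` (one-row tibble: `start_idx`, `end_idx`,
#'   `start`, `end`) and `restrictive` (tibble of segments, same columns).
#' @export
confidence_intervals <- function(region, profile, lod_drop = 1.5) {
  idx <- region$start_idx:region$end_idx
  cutoff <- region$max_lod - lod_drop
  qual <- idx[!profile$masked[idx] & !is.na(profile$lod[idx]) &
                profile$lod[idx] > cutoff]
  ci_from_qualifying(qual, profile)
}

ci_from_qualifying <- function(qual, profile) {
  stopifnot(length(qual) > 0)
  inc_idx <- range(qual)
  inclusive <- tibble(
    start_idx = inc_idx[1], end_idx = inc_idx[2],
    start = profile$start[inc_idx[1]], end = profile$end[inc_idx[2]]
  )
  # restrictive runs: qualifying windows, with masked windows bridged
  span <- inc_idx[1]:inc_idx[2]
  state <- ifelse(span %in% qual, "q",
                  ifelse(profile$masked[span], "m", "x"))
  keep <- state != "m"
  kept <- span[keep]
  breaks <- state[keep] == "x"
  seg_id <- cumsum(c(TRUE, breaks[-1] | breaks[-length(breaks)]))
  segs <- tibble(idx = kept, q = !breaks, seg = seg_id) %>%
    filter(.data$q) %>%
    group_by(.data$seg) %>%
    summarise(start_idx = min(.data$idx), end_idx = max(.data$idx),
              .groups = "drop")
  restrictive <- tibble(
    start_idx = segs$start_idx, end_idx = segs$end_idx,
    start = profile$start[segs$start_idx], end = profile$end[segs$end_idx]
  )
  list(inclusive = inclusive, restrictive = restrictive)
}

#' Extend a confidence interval through masked windows
#'
#' A CI whose boundary window is adjacent to a masked window is extended
#' across the masked stretch: extension proceeds window by window and stops
#' at the first unmasked window that fails the CI criterion
#' (`lod <= max_lod - lod_drop`), which is itself excluded -- the masked
#' stretch up to it remains inside the inclusive CI. If the first unmasked
#' window beyond the stretch qualifies, it is included and extension
#' continues. A masked stretch running to the end of the adjacency unit
#' extends the CI to the unit end with a warning.
#'
#' @param ci Output of [confidence_intervals()].
#' @param region The region row the CI belongs to.
#' @param profile The `lod_profile`.
#' @param lod_drop LOD drop defining support (default 1.5).
#' @param adjacency `"chromosome"` (default) or `"arm"`.
#' @return A list like `ci`, with the inclusive CI (and, when extension
#'   uncovered new qualifying windows, the restrictive segments) updated.
#' @export
extend_through_masked <- function(ci, region, profile, lod_drop = 1.5,
                                  adjacency = c("chromosome", "arm")) {
  adjacency <- match.arg(adjacency)
  unit <- adjacency_unit(profile$arm, adjacency)
  cutoff <- region$max_lod - lod_drop
  qual_flag <- !profile$masked & !is.na(profile$lod) & profile$lod > cutoff

  lo <- ci$inclusive$start_idx
  hi <- ci$inclusive$end_idx
  extend_side <- function(b, step) {
    # returns the new boundary index on this side
    extending <- FALSE
    repeat {
      nb <- b + step
      if (nb < 1 || nb > nrow(profile) || unit[nb] != unit[b]) return(b)
      if (profile$masked[nb]) {
        # walk across the masked stretch
        w <- nb
        while (w + step >= 1 && w + step <= nrow(profile) &&
               unit[w + step] == unit[w] && profile$masked[w + step]) {
          w <- w + step
        }
        nxt <- w + step
        if (nxt < 1 || nxt > nrow(profile) || unit[nxt] != unit[w]) {
          warn("masked stretch reaches the end of the chromosome; CI extended to the end")
          return(w)
        }
        if (qual_flag[nxt]) {
          b <- nxt  # include the qualifying window and keep going
          extending <- TRUE
        } else {
          return(w)  # stretch included, failing window excluded
        }
      } else if (extending && qual_flag[nb]) {
        b <- nb  # newly uncovered qualifying run continues the CI
      } else {
        return(b)
      }
    }
  }
  new_lo <- extend_side(lo, -1L)
  new_hi <- extend_side(hi, +1L)
  if (new_lo == lo && new_hi == hi) return(ci)
  qual <- which(qual_flag)
  qual <- qual[qual >= min(new_lo, lo) & qual <= max(new_hi, hi)]
  out <- ci_from_qualifying(sort(unique(qual)), profile)
  # inclusive CI also covers bridged masked stretches at the flanks
  out$inclusive$start_idx <- min(out$inclusive$start_idx, new_lo)
  out$inclusive$end_idx <- max(out$inclusive$end_idx, new_hi)
  out$inclusive$start <- profile$start[out$inclusive$start_idx]
  out$inclusive$end <- profile$end[out$inclusive$end_idx]
  out
}

#' Call QTL regions from a LOD profile
#'
#' Runs the full peak pipeline: significant runs, valley merging, inclusive
#' and restrictive confidence intervals, and extension of CIs through
#' masked windows. Ties at the maximum LOD are resolved to the leftmost
#' window.
#'
#' @param profile A `lod_profile` (see [lod_scan()]).
#' @param threshold Genome-wide LOD threshold.
#' @param lod_drop LOD drop defining support intervals (default 1.5).
#' @param adjacency `"chromosome"` (default) or `"arm"`.
#' @param p_fun Optional function mapping a peak LOD to a genome-wide
#'   p-value (see [perm_threshold()]).
#' @return A tibble with one row per QTL region: `region_id`, `arm` (of the
#'   peak window), `peak_window`, `peak_idx`, `peak_start`, `peak_end`,
#'   `max_lod`, `genomewide_p`, `inclusive_start`, `inclusive_end` (bp), and
#'   a list-column `restrictive` of segment tibbles.
#' @export
find_qtl_regions <- function(profile, threshold, lod_drop = 1.5,
                             adjacency = c("chromosome", "arm"),
                             p_fun = NULL) {
  adjacency <- match.arg(adjacency)
  runs <- significant_regions(profile, threshold, adjacency)
  if (nrow(runs) == 0) {
    return(tibble(region_id = integer(), arm = character(),
                  peak_window = character(), peak_idx = integer(),
                  peak_start = numeric(), peak_end = numeric(),
                  max_lod = numeric(), genomewide_p = numeric(),
                  inclusive_start = numeric(), inclusive_end = numeric(),
                  restrictive = list()))
  }
  regions <- merge_regions(runs, profile, lod_drop)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    ci <- confidence_intervals(reg, profile, lod_drop)
    ci <- extend_through_masked(ci, reg, profile, lod_drop, adjacency)
    tibble(
      region_id = reg$region_id,
      arm = profile$arm[reg$peak_idx],
      peak_window = as.character(profile$window[reg$peak_idx]),
      peak_idx = reg$peak_idx,
      peak_start = profile$start[reg$peak_idx],
      peak_end = profile$end[reg$peak_idx],
      max_lod = reg$max_lod,
      genomewide_p = if (is.null(p_fun)) NA_real_ else p_fun(reg$max_lod),
      inclusive_start = ci$inclusive$start,
      inclusive_end = ci$inclusive$end,
      inclusive_start_idx = ci$inclusive$start_idx,
      inclusive_end_idx = ci$inclusive$end_idx,
      restrictive = list(ci$restrictive)
    )
  })
  out
}

#' Write QTL confidence intervals as a BED file
#'
#' Emits 0-based half-open intervals, sorted by arm and start, one line per
#' inclusive CI or per restrictive segment.
#'
#' @param regions Output of [find_qtl_regions()].
#' @param profile The `lod_profile` used to call the regions (for arm
#'   lookup).
#' @param path Output path.
#' @param which `"inclusive"` or `"restrictive"`.
#' @return The BED tibble, invisibly.
#' @export
write_regions_bed <- function(regions, profile, path,
                              which = c("inclusive", "restrictive")) {
  which <- match.arg(which)
  if (which == "inclusive") {
    bed <- tibble(chrom = regions$arm,
                  start = regions$inclusive_start,
                  end = regions$inclusive_end,
                  name = sprintf("region_%d", regions$region_id))
  } else {
    bed <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      seg <- regions$restrictive[[i]]
      tibble(chrom = profile$arm[seg$start_idx],
             start = seg$start, end = seg$end,
             name = sprintf("region_%d.%d", regions$region_id[i],
                            seq_len(nrow(seg))))
    })
  }
  bed <- arrange(bed, .data$chrom, .data$start)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(bed)
}
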