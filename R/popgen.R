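#' Construct a haplotype panel
#'
#' A haplotype panel holds one population's phased (or pseudo-haploid)
#' biallelic genotypes: a haplotype-by-site matrix of 0/1 alleles (NA
#' allowed) with strictly increasing site positions on one chromosome arm.
#'
#' @param haps Matrix, haplotypes in rows, sites in columns; values 0, 1 or
#'   NA.
#' @param pos Site positions in bp (1-based, strictly increasing).
#' @param arm Chromosome arm label.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, pos, arm = "chr") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  vals <- haps[!is.na(haps)]
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L))) {
    abort("alleles must be 0, 1 or NA")
  }
  if (length(pos) != ncol(haps)) {
    abort("pos must have one entry per site")
  }
  if (any(diff(pos) <= 0)) abort("site positions must be strictly increasing")
  structure(list(haps = haps, pos = as.numeric(pos), arm = arm),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites on %s\n",
              nrow(x$haps), ncol(x$haps), x$arm))
  invisible(x)
}

#' Read a haplotype panel from a TSV matrix
#'
#' Expects a tab-separated file whose first column is the site position and
#' whose remaining columns are haplotypes (0/1, blank or NA for missing).
#'
#' @param path Input path.
#' @param arm Chromosome arm label.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes <- function(path, arm = "chr") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  pos <- x[[1]]
  haps <- t(as.matrix(x[, -1]))
  haplotype_panel(haps, pos, arm)
}

#' Hudson-form per-site Fst from allele counts
#'
#' For derived-allele counts in two population samples, computes the
#' Hudson-form estimator with finite-sample correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`. The ratio is undefined (NA) when the
#' denominator is zero, i.e. when the site is monomorphic for the same
#' allele in both samples; such sites are excluded from window summaries.
#' Small negative values at undifferentiated sites are expected and are not
#' truncated. All arguments are vectorised over sites.
#'
#' @param count1,count2 Derived-allele counts in samples 1 and 2.
#' @param n1,n2 Allelic sample sizes (>= 2).
#' @return A tibble with columns `num`, `den`, `fst`.
#' @export
site_fst <- function(count1, n1, count2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) abort("sample sizes must be >= 2")
  if (any(count1 < 0 | count1 > n1, na.rm = TRUE) ||
      any(count2 < 0 | count2 > n2, na.rm = TRUE)) {
    abort("allele counts must lie in [0, n]")
  }
  p1 <- count1 / n1
  p2 <- count2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble(num = num, den = den, fst = ifelse(den == 0, NA_real_, num / den))
}

#' Per-site Fst between two haplotype panels
#'
#' Computes derived-allele counts per site (ignoring missing genotypes) and
#' applies [site_fst()]. Optionally downsamples each panel to a fixed number
#' of haplotypes first, e.g. to match allelic sample sizes to the number of
#' phenotyped strains when building a null distribution for
#' [qst_fst_quantile()].
#'
#' @param panel1,panel2 [haplotype_panel()] objects over the same sites.
#' @param n1,n2 Optional haplotype counts to downsample to.
#' @param seed Optional seed for the downsampling.
#' @return A tibble with one row per site: `pos`, `count1`, `size1`,
#'   `count2`, `size2`, `num`, `den`, `fst`.
#' @export
panel_site_fst <- function(panel1, panel2, n1 = NULL, n2 = NULL,
                           seed = NULL) {
  if (!identical(panel1$pos, panel2$pos)) {
    abort("panels must share the same site positions")
  }
  with_seed_if(seed, {
    h1 <- panel1$haps
    h2 <- panel2$haps
    if (!is.null(n1)) h1 <- h1[sample(nrow(h1), n1), , drop = FALSE]
    if (!is.null(n2)) h2 <- h2[sample(nrow(h2), n2), , drop = FALSE]
    c1 <- colSums(h1 == 1L, na.rm = TRUE)
    s1 <- colSums(!is.na(h1))
    c2 <- colSums(h2 == 1L, na.rm = TRUE)
    s2 <- colSums(!is.na(h2))
    usable <- s1 >= 2 & s2 >= 2
    f <- site_fst(c1[usable], s1[usable], c2[usable], s2[usable])
    tibble(pos = panel1$pos[usable], count1 = c1[usable], size1 = s1[usable],
           count2 = c2[usable], size2 = s2[usable],
           num = f$num, den = f$den, fst = f$fst)
  })
}

window_site_mask <- function(pos, window) {
  pos >= window[1] & pos <= window[2]
}

#' Full-window Fst (ratio of averages)
#'
#' Window-level Hudson Fst using all variable sites in the window: the sum
#' of per-site numerators divided by the sum of per-site denominators.
#' Ratio-of-averages weighting is standard practice and is stable for
#' low-frequency sites. Returns NA when the window holds no variable site.
#'
#' @param panel1,panel2 [haplotype_panel()] objects over the same sites.
#' @param window Length-2 numeric `(start, end)` in bp, inclusive.
#' @return A single Fst value (or NA).
#' @export
window_fst_full <- function(panel1, panel2, window) {
  s <- panel_site_fst(panel1, panel2)
  s <- s[window_site_mask(s$pos, window) & s$den > 0, ]
  if (nrow(s) == 0) return(NA_real_)
  sum(s$num) / sum(s$den)
}

#' Maximum per-SNP Fst within a window
#'
#' The maximum defined per-site Fst value over variable sites in the
#' window; NA when no site is variable.
#'
#' @inheritParams window_fst_full
#' @return A single Fst value (or NA).
#' @export
window_fst_maxsnp <- function(panel1, panel2, window) {
  s <- panel_site_fst(panel1, panel2)
  s <- s[window_site_mask(s$pos, window) & !is.na(s$fst), ]
  if (nrow(s) == 0) return(NA_real_)
  max(s$fst)
}

#' Comparative haplotype identity between two populations
#'
#' For every haplotype pair within a population, finds the longest run of
#' sites in the window at which the pair is identical and measures its span
#' in bp (first to last site of the run; a single-site run spans the
#' midpoints to its flanking sites; sites missing in either haplotype break
#' no run but contribute no length). The population's identity score is the
#' mean of these maximal spans over pairs; the statistic is the ratio
#' `I_pop1 / I_pop2`, with population 1 conventionally the putatively
#' selected (non-ancestral-range) population. Values far above 1 indicate
#' unusually long shared haplotypes in population 1, as expected under a
#' local sweep. Pairs with more than `max_missing` of the window's sites
#' unusable are dropped from the mean.
#'
#' @inheritParams window_fst_full
#' @param max_missing Maximum tolerated missing fraction per pair
#'   (default 0.5).
#' @return A one-row tibble: `i_pop1`, `i_pop2`, `chi_md` (`Inf` with
#'   `undefined = TRUE` when `i_pop2` is zero).
#' @export
window_chi_md <- function(panel1, panel2, window, max_missing = 0.5) {
  i1 <- pop_identity_score(panel1, window, max_missing)
  i2 <- pop_identity_score(panel2, window, max_missing)
  if (is.na(i1) || is.na(i2)) {
    return(tibble(i_pop1 = i1, i_pop2 = i2, chi_md = NA_real_,
                  undefined = TRUE))
  }
  if (i2 == 0) {
    return(tibble(i_pop1 = i1, i_pop2 = i2, chi_md = Inf, undefined = TRUE))
  }
  tibble(i_pop1 = i1, i_pop2 = i2, chi_md = i1 / i2, undefined = FALSE)
}

pop_identity_score <- function(panel, window, max_missing = 0.5) {
  keep <- window_site_mask(panel$pos, window)
  if (sum(keep) < 1) return(NA_real_)
  if (nrow(panel$haps) < 2) abort("need at least 2 haplotypes per population")
  spans <- pair_identity_spans(panel$haps[, keep, drop = FALSE],
                               panel$pos[keep], max_missing)
  if (all(is.na(spans))) return(NA_real_)
  mean(spans, na.rm = TRUE)
}

#' Windowed population-genetic differentiation statistics
#'
#' Computes full-window Fst, maximum-SNP Fst and comparative haplotype
#' identity for every window, then adds per-arm quantile ranks and top-
#' quantile outlier flags via [arm_outliers()].
#'
#' @param panel1,panel2 [haplotype_panel()] objects over the same sites;
#'   population 1 is the putatively selected population.
#' @param windows Tibble with columns `window`, `arm`, `start`, `end`
#'   (bp, inclusive).
#' @param top_q Upper tail quantile for outlier calls (default 0.01).
#' @param max_missing Per-pair missing tolerance for the identity statistic.
#' @return A `popgen_stats` tibble: one row per window with `fst_fullwin`,
#'   `fst_maxsnp`, `chi_md`, per-arm quantile ranks (`*_q`), per-statistic
#'   outlier flags and the combined `outlier` flag.
#' @export
popgen_window_stats <- function(panel1, panel2, windows, top_q = 0.01,
                                max_missing = 0.5) {
  check_columns(windows, c("window", "arm", "start", "end"), "windows")
  sites <- panel_site_fst(panel1, panel2)
  res <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    win <- c(windows$start[i], windows$end[i])
    s <- sites[window_site_mask(sites$pos, win) & sites$den > 0, ]
    full <- if (nrow(s) == 0) NA_real_ else sum(s$num) / sum(s$den)
    maxsnp <- if (nrow(s) == 0) NA_real_ else max(s$fst, na.rm = TRUE)
    chi <- window_chi_md(panel1, panel2, win, max_missing)
    tibble(window = windows$window[i], arm = windows$arm[i],
           start = windows$start[i], end = windows$end[i],
           n_sites = nrow(s), fst_fullwin = full, fst_maxsnp = maxsnp,
           chi_md = chi$chi_md)
  })
  out <- arm_outliers(res, q = top_q)
  class(out) <- c("popgen_stats", class(out))
  out
}

#' Per-arm top-quantile outlier flags for window statistics
#'
#' For each statistic and chromosome arm, computes the empirical quantile
#' rank of every window (proportion of windows on the arm with a value at
#' or below it) and flags windows whose value is at or above the `1 - q`
#' empirical quantile. With all values tied, every window reaches the
#' quantile and all are flagged. A window is an outlier window when flagged
#' for any statistic.
#'
#' @param stats Tibble with columns `arm` and the statistic columns.
#' @param q Upper tail mass (default 0.01, i.e. top 1 percent).
#' @param statistics Statistic columns to rank.
#' @return `stats` with added `<stat>_q` quantile-rank columns,
#'   `<stat>_outlier` flags, and a combined `outlier` column.
#' @export
arm_outliers <- function(stats, q = 0.01,
                         statistics = c("fst_fullwin", "fst_maxsnp",
                                        "chi_md")) {
  statistics <- intersect(statistics, names(stats))
  arms <- unique(stats$arm)
  for (a in arms) {
    if (sum(stats$arm == a) < 100) {
      warn(sprintf("arm %s has fewer than 100 windows; quantiles are coarse", a))
      break
    }
  }
  out <- stats
  for (st in statistics) {
    qcol <- paste0(st, "_q")
    ocol <- paste0(st, "_outlier")
    out[[qcol]] <- NA_real_
    out[[ocol]] <- NA
    for (a in arms) {
      rows <- which(out$arm == a)
      v <- out[[st]][rows]
      ok <- !is.na(v)
      if (!any(ok)) next
      vf <- v[ok]
      has_inf <- is.infinite(vf)
      qr <- rep(NA_real_, length(v))
      qr[ok] <- ecdf(vf)(vf)
      thr <- if (all(has_inf)) Inf else
        quantile(vf[!has_inf], 1 - q, type = 7, names = FALSE)
      out[[qcol]][rows] <- qr
      out[[ocol]][rows][ok] <- vf >= thr | has_inf
    }
  }
  flag_cols <- paste0(statistics, "_outlier")
  out$outlier <- rowSums(as.matrix(out[flag_cols]) == TRUE,
                         na.rm = TRUE) > 0
  out
}

#' Plot windowed differentiation statistics along an arm
#'
#' @param object A `popgen_stats` tibble from [popgen_window_stats()].
#' @param ... Unused.
#' @return A ggplot of -log10 per-arm quantile ranks per statistic, with
#'   outlier windows highlighted.
#' @export
#' @method autoplot popgen_stats
autoplot.popgen_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("arm", "start", "end", "fst_fullwin_q",
                        "fst_maxsnp_q", "chi_md_q")],
    cols = tidyr::ends_with("_q"),
    names_to = "statistic", values_to = "qrank"
  )
  long$mid <- (long$start + long$end) / 2 / 1e6
  long$neglogq <- -log10(pmax(1 - long$qrank, 1e-4))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$neglogq,
                                     colour = .data$statistic)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$arm),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10] * " (1 - arm quantile)")) +
    ggplot2::theme_minimal()
}
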