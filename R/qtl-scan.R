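#' Construct an ancestry-genotype panel
#'
#' Bundles a RIL-by-window matrix of parental ancestry dosages (0, 1 or 2
#' copies of the reference parent's ancestry, NA allowed) with window
#' coordinates. Windows must be ordered and non-overlapping within an arm.
#'
#' @param geno Integer matrix, RILs in rows (rownames = strain ids), windows
#'   in columns; values in \{0, 1, 2\} or NA.
#' @param windows Tibble with columns `window` (matching `colnames(geno)`),
#'   `arm`, `start`, `end` (bp).
#' @return An object of class `ancestry_panel`.
#' @export
ancestry_panel <- function(geno, windows) {
  check_columns(windows, c("window", "arm", "start", "end"), "windows")
  if (ncol(geno) != nrow(windows)) {
    abort("geno must have one column per window")
  }
  if (is.null(colnames(geno))) colnames(geno) <- windows$window
  if (!identical(colnames(geno), as.character(windows$window))) {
    abort("colnames(geno) must match windows$window, in order")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L, 2L))) {
    abort("ancestry dosages must be 0, 1, 2 or NA")
  }
  bad <- windows %>%
    group_by(.data$arm) %>%
    summarise(unsorted = any(diff(.data$start) < 0) ||
                any(head(.data$end, -1) > tail(.data$start, -1)),
              .groups = "drop")
  if (any(bad$unsorted)) {
    abort("windows must be sorted and non-overlapping within each arm")
  }
  structure(list(geno = geno, windows = as_tibble(windows)),
            class = "ancestry_panel")
}

#' @export
print.ancestry_panel <- function(x, ...) {
  cat(sprintf("<ancestry_panel> %d RILs x %d windows on %d arm(s)\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$windows$arm))))
  invisible(x)
}

#' @export
dim.ancestry_panel <- function(x) dim(x$geno)

#' Mask windows with skewed panel-wide ancestry
#'
#' A window is masked when the RIL panel-wide ancestry proportion of either
#' parent exceeds `max_prop` (i.e. mean dosage / 2 strictly above `max_prop`
#' or strictly below `1 - max_prop`). Windows at exactly the boundary are
#' kept. Such windows carry little mapping information and can distort
#' single-window regression.
#'
#' @param panel An [ancestry_panel()].
#' @param max_prop Maximum tolerated ancestry proportion (default 0.90).
#' @return A tibble with columns `window`, `arm`, `ancestry_prop`, `masked`.
#' @export
mask_skewed_windows <- function(panel, max_prop = 0.90) {
  prop <- colMeans(panel$geno, na.rm = TRUE) / 2
  masked <- prop > max_prop | prop < 1 - max_prop
  if (all(masked)) abort("all windows are masked; nothing to scan")
  tibble(window = panel$windows$window, arm = panel$windows$arm,
         ancestry_prop = unname(prop), masked = unname(masked))
}

#' Additive single-QTL LOD scan over ancestry windows
#'
#' At every unmasked window, regresses the trait on ancestry dosage
#' (intercept + additive slope, ordinary least squares) and reports
#' `LOD = (n/2) * log10(RSS0 / RSS1)`, where RSS0 is the intercept-only
#' residual sum of squares -- equivalently `-(n/2) * log10(1 - R^2)`. RILs
#' with a missing dosage or trait value are dropped pairwise per window.
#' Windows with a single genotype class present get LOD 0 with a warning.
#'
#' @param panel An [ancestry_panel()].
#' @param y Trait values: either a numeric vector named by strain id (or
#'   aligned to `rownames(panel$geno)`), or a data frame with columns
#'   `strain_id` and `value`.
#' @param mask Optional output of [mask_skewed_windows()]; if supplied,
#'   masked windows carry `lod = NA`.
#' @return A `lod_profile` tibble: `window`, `arm`, `start`, `end`, `lod`,
#'   `n_used`, `masked`, with the trait vector and any threshold stored in
#'   attributes.
#' @export
lod_scan <- function(panel, y, mask = NULL) {
  y <- align_trait(panel, y)
  G <- panel$geno
  lods <- lod_scan_matrix(G, matrix(y, ncol = 1))
  lod <- unname(lods$lod[, 1])
  single_class <- unname(lods$single_class[, 1])
  if (any(single_class)) {
    warn(sprintf("%d window(s) had a single genotype class; LOD set to 0",
                 sum(single_class)))
  }
  masked <- if (is.null(mask)) rep(FALSE, ncol(G)) else mask$masked
  lod[masked] <- NA_real_
  out <- tibble(
    window = panel$windows$window,
    arm = panel$windows$arm,
    start = panel$windows$start,
    end = panel$windows$end,
    lod = lod,
    n_used = unname(lods$n_used[, 1]),
    masked = masked
  )
  class(out) <- c("lod_profile", class(out))
  attr(out, "trait") <- y
  out
}

# Core scan: LOD for each column of Y against each column of G.
# Returns list(lod, n_used, single_class), each windows x phenotypes.
# Complete data goes through one BLAS crossprod; data with NAs falls back to
# pairwise-complete correlations.
lod_scan_matrix <- function(G, Y) {
  n <- nrow(G)
  if (!anyNA(G) && !anyNA(Y)) {
    sdg <- apply(G, 2, sd)
    single <- sdg == 0
    Gs <- G
    Gs[, !single] <- scale(G[, !single, drop = FALSE])
    Gs[, single] <- 0
    Ys <- scale(Y)
    sdy <- attr(Ys, "scaled:scale")
    Ys[, sdy == 0] <- 0
    r <- crossprod(Gs, Ys) / (n - 1)
    r2 <- pmin(r^2, 1)
    lod <- -(n / 2) * log10(1 - r2)
    lod[single, ] <- 0
    lod[, sdy == 0] <- 0
    list(lod = lod, n_used = matrix(n, ncol(G), ncol(Y)),
         single_class = matrix(single, ncol(G), ncol(Y)))
  } else {
    lod <- matrix(0, ncol(G), ncol(Y))
    n_used <- matrix(0L, ncol(G), ncol(Y))
    single <- matrix(FALSE, ncol(G), ncol(Y))
    for (k in seq_len(ncol(Y))) {
      yk <- Y[, k]
      for (j in seq_len(ncol(G))) {
        g <- G[, j]
        ok <- !is.na(g) & !is.na(yk)
        m <- sum(ok)
        n_used[j, k] <- m
        if (m >= 2 && sd(g[ok]) == 0) single[j, k] <- TRUE
        if (m < 3 || sd(g[ok]) == 0 || sd(yk[ok]) == 0) next
        r <- cor(g[ok], yk[ok])
        lod[j, k] <- -(m / 2) * log10(max(1 - r^2, .Machine$double.xmin))
      }
    }
    list(lod = lod, n_used = n_used, single_class = single)
  }
}

align_trait <- function(panel, y) {
  rils <- rownames(panel$geno)
  if (is.data.frame(y)) {
    check_columns(y, c("strain_id", "value"), "trait data frame")
    v <- y$value[match(rils, y$strain_id)]
    return(v)
  }
  if (!is.null(names(y)) && !is.null(rils)) {
    return(unname(y[rils]))
  }
  if (length(y) != nrow(panel$geno)) {
    abort("trait vector length must equal the number of RILs")
  }
  as.numeric(y)
}

#' Permutation-based genome-wide LOD threshold
#'
#' Shuffles the per-RIL trait values across RILs, reruns the full scan, and
#' records the genome-wide maximum LOD of each permutation. The threshold is
#' the `1 - alpha` empirical quantile of the maxima; the genome-wide p-value
#' of an observed peak is the proportion of permutation maxima at or above
#' it. All chromosome arms are scanned jointly, so a single threshold
#' controls genome-wide multiple testing for the trait.
#'
#' @param panel An [ancestry_panel()].
#' @param y Trait values (see [lod_scan()]).
#' @param n_perm Number of permutations (default 10000). Below 100 a warning
#'   about threshold instability is emitted.
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Optional integer seed.
#' @param mask Optional [mask_skewed_windows()] output; masked windows are
#'   excluded from the maxima.
#' @return A list with `threshold`, the vector of permutation `maxima`, and
#'   `p_fun(peak_lod)` mapping an observed peak LOD to a genome-wide
#'   p-value.
#' @export
perm_threshold <- function(panel, y, n_perm = 10000, alpha = 0.05,
                           seed = NULL, mask = NULL) {
  if (n_perm < 100) warn("n_perm < 100: permutation threshold is unstable")
  y <- align_trait(panel, y)
  G <- panel$geno
  keep <- if (is.null(mask)) rep(TRUE, ncol(G)) else !mask$masked
  ok <- !is.na(y)
  Gk <- G[ok, keep, drop = FALSE]
  yk <- y[ok]
  maxima <- with_seed_if(seed, {
    Y <- replicate(n_perm, sample(yk))
    block <- 1000L  # bound the crossprod workspace
    out <- numeric(n_perm)
    for (s in seq(1, n_perm, by = block)) {
      e <- min(s + block - 1, n_perm)
      lods <- lod_scan_matrix(Gk, Y[, s:e, drop = FALSE])$lod
      out[s:e] <- apply(lods, 2, max)
    }
    out
  })
  threshold <- unname(quantile(maxima, 1 - alpha, type = 7))
  list(
    threshold = threshold,
    maxima = maxima,
    alpha = alpha,
    p_fun = function(peak_lod) {
      vapply(peak_lod, function(l) mean(maxima >= l), numeric(1))
    }
  )
}

#' QTL effect size as the proportion of the parental difference explained
#'
#' Fits the additive slope of the trait on ancestry dosage at one window and
#' reports `|2 * beta| / |parent_a - parent_b|`: the fitted difference
#' between the two homozygous ancestry classes as a fraction of the observed
#' parental strain difference. The signed direction of the fitted contrast
#' is reported separately. Estimates for traits with several linked QTLs can
#' be inflated by linkage.
#'
#' @param dosage Ancestry dosages at the window (0/1/2, NA allowed).
#' @param y Trait values aligned to `dosage`.
#' @param parent_a,parent_b Trait values of the two parental strains
#'   (must differ); `parent_a` is the parent whose ancestry `dosage` counts.
#' @return A one-row tibble: `beta` (slope per dosage unit), `effect`
#'   (proportion of parental difference), `direction` (sign of the
#'   homozygote contrast relative to `parent_a - parent_b`), `n`.
#' @export
qtl_effect_size <- function(dosage, y, parent_a, parent_b) {
  delta <- parent_a - parent_b
  if (delta == 0) abort("parental trait values must differ")
  ok <- !is.na(dosage) & !is.na(y)
  d <- dosage[ok]
  yy <- y[ok]
  if (sd(d) == 0) abort("dosage has a single genotype class")
  beta <- cov(d, yy) / var(d)
  tibble(
    beta = beta,
    effect = abs(2 * beta) / abs(delta),
    direction = sign(2 * beta) * sign(delta),
    n = sum(ok)
  )
}

#' @export
#' @method tidy lod_profile
tidy.lod_profile <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lod_profile")
  attr(out, "trait") <- NULL
  attr(out, "threshold") <- NULL
  out
}

#' @export
#' @method glance lod_profile
glance.lod_profile <- function(x, threshold = attr(x, "threshold"), ...) {
  tibble(
    n_windows = nrow(x),
    n_masked = sum(x$masked),
    max_lod = max(x$lod, na.rm = TRUE),
    peak_window = x$window[which.max(x$lod)],
    threshold = if (is.null(threshold)) NA_real_ else threshold,
    n_significant = if (is.null(threshold)) NA_integer_ else
      sum(x$lod >= threshold, na.rm = TRUE)
  )
}

#' Plot a LOD profile along the genome
#'
#' @param object A `lod_profile` from [lod_scan()].
#' @param threshold Optional genome-wide LOD threshold drawn as a dashed
#'   line.
#' @param ... Unused.
#' @return A ggplot object: LOD against genomic position, faceted by arm.
#' @export
#' @method autoplot lod_profile
autoplot.lod_profile <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  df$mid <- (df$start + df$end) / 2 / 1e6
  p <- ggplot2::ggplot(df[!df$masked, ],
                       ggplot2::aes(x = .data$mid, y = .data$lod,
                                    colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$arm),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "LOD") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
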