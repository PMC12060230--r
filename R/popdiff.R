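#' Two-sample Mann-Whitney test
#'
#' Computes the Mann-Whitney U statistic for the first sample and a
#' two-sided p-value. When there are no ties and both groups are at or below
#' `exact_max_n`, the p-value is exact (doubled smaller tail of the null U
#' distribution, capped at 1). Otherwise ties are handled by mid-ranks and a
#' normal approximation with continuity correction and tie-corrected
#' variance is used, matching standard two-sample Wilcoxon behaviour.
#'
#' @param a,b Numeric vectors of trait values for the two groups (nonempty).
#' @param exact_max_n Largest group size for which the exact null
#'   distribution is used (default 50).
#' @return A one-row tibble with columns `u`, `p`, `method`
#'   (`"exact"` or `"normal"`), `n_a`, `n_b`.
#' @export
mw_test <- function(a, b, exact_max_n = 50) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("both groups must be nonempty")
  }
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && max(n_a, n_b) <= exact_max_n) {
    p <- mw_exact_p(u, n_a, n_b)
    method <- "exact"
  } else {
    p <- mw_normal_p(u, n_a, n_b, r)
    method <- "normal"
  }
  tibble(u = u, p = p, method = method, n_a = n_a, n_b = n_b)
}

# Exact two-sided p: doubled smaller tail of the null U distribution.
mw_exact_p <- function(u, n_a, n_b) {
  p <- if (u > n_a * n_b / 2) {
    pwilcox(u - 1, n_a, n_b, lower.tail = FALSE)
  } else {
    pwilcox(u, n_a, n_b)
  }
  min(2 * p, 1)
}

# Normal approximation with continuity correction and tie correction,
# given the mid-ranks of the pooled sample.
mw_normal_p <- function(u, n_a, n_b, r) {
  n <- n_a + n_b
  nties <- table(r)
  z <- u - n_a * n_b / 2
  sigma <- sqrt((n_a * n_b / 12) *
                  ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
  if (sigma == 0) return(1)  # all values tied
  z <- (z - sign(z) * 0.5) / sigma
  min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
}

# Exact p lookup table for all U values at fixed group sizes (no ties).
mw_exact_p_table <- function(n_a, n_b) {
  vapply(0:(n_a * n_b), mw_exact_p, numeric(1), n_a = n_a, n_b = n_b)
}

#' Family-wise min-p permutation correction for population trait comparisons
#'
#' Tests every trait for a population difference with a Mann-Whitney test,
#' then corrects for testing the whole trait family with a min-p
#' (Westfall-Young style) permutation procedure: in each permutation the
#' strain labels are reshuffled once, the same relabelling is applied to all
#' traits (preserving trait-trait correlations), the raw Mann-Whitney
#' p-value is recomputed per trait, and the minimum p across traits is
#' recorded. The corrected false-positive rate of a trait is the proportion
#' of permutations whose minimum p is at or below that trait's empirical raw
#' p -- the chance of seeing at least one p-value that small anywhere in the
#' family under no true difference.
#'
#' @param table Strain trait table with a `cohort` column holding exactly
#'   two population labels (see [strain_trait_means()]).
#' @param populations Length-2 character vector naming the two cohorts; the
#'   first is treated as group 1. Default: the two cohort values in order of
#'   appearance.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive If `TRUE`, enumerate all distinct label assignments
#'   instead of sampling (`n_perm` is ignored); feasible for small panels.
#' @param shared If `TRUE` (default) one relabelling per permutation is
#'   shared by all traits (min-p procedure); if `FALSE` each trait is
#'   permuted independently.
#' @param add_one If `TRUE`, report corrected rates as (b+1)/(n+1) instead of
#'   the plain proportion b/n. Default `FALSE` (a plain proportion, which can
#'   be zero).
#' @param traits Trait columns to include; default all numeric columns.
#'   Traits with missing cells are dropped from the family with a warning.
#' @return A tibble with one row per trait: `trait`, `u`, `p_raw`, `fpr`
#'   (corrected family-wise false-positive rate), group means and sizes.
#'   The permutation minimum-p distribution is attached as attribute
#'   `"min_p"`, and the number of permutations as `"n_perm"`.
#' @export
familywise_fpr <- function(table, populations = NULL, n_perm = 10000,
                           seed = NULL, exhaustive = FALSE, shared = TRUE,
                           add_one = FALSE, traits = NULL) {
  check_columns(table, "cohort", "strain trait table")
  if (is.null(populations)) {
    populations <- unique(as.character(table$cohort))
  }
  if (length(populations) != 2) {
    abort("exactly two population labels are required")
  }
  table <- table[table$cohort %in% populations, , drop = FALSE]
  if (is.null(traits)) {
    traits <- setdiff(names(table), c("strain_id", "cohort"))
    traits <- traits[vapply(table[traits], is.numeric, logical(1))]
  }
  m <- as.matrix(table[traits])
  has_na <- colnames(m)[colSums(is.na(m)) > 0]
  if (length(has_na) > 0) {
    warn(sprintf("dropping trait(s) with missing cells from the family: %s",
                 paste(has_na, collapse = ", ")))
    m <- m[, setdiff(colnames(m), has_na), drop = FALSE]
  }
  if (ncol(m) == 0) abort("no complete traits to test")
  grp1 <- table$cohort == populations[1]
  n1 <- sum(grp1)
  n2 <- sum(!grp1)
  if (n1 < 1 || n2 < 1) abort("each population needs at least one strain")
  n <- n1 + n2

  # Per-trait machinery reused by the empirical test and every permutation:
  # mid-ranks are invariant under relabelling, so compute them once.
  ranks <- apply(m, 2, rank)
  tied <- apply(m, 2, function(v) any(duplicated(v)))
  exact_tbl <- if (any(!tied)) mw_exact_p_table(n1, n2) else NULL
  sigma <- vapply(seq_len(ncol(m)), function(j) {
    nt <- table(ranks[, j])
    sqrt((n1 * n2 / 12) * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1))))
  }, numeric(1))

  p_from_idx <- function(idx) {
    u <- colSums(ranks[idx, , drop = FALSE]) - n1 * (n1 + 1) / 2
    p <- numeric(length(u))
    if (any(!tied)) p[!tied] <- exact_tbl[u[!tied] + 1]
    if (any(tied)) {
      z <- u[tied] - n1 * n2 / 2
      s <- sigma[tied]
      zz <- ifelse(s == 0, 0, (z - sign(z) * 0.5) / s)
      pt <- 2 * pnorm(-abs(zz))
      pt[s == 0] <- 1
      p[tied] <- pmin(pt, 1)
    }
    p
  }

  idx_obs <- which(grp1)
  p_obs <- p_from_idx(idx_obs)
  u_obs <- colSums(ranks[idx_obs, , drop = FALSE]) - n1 * (n1 + 1) / 2

  if (exhaustive && !shared) {
    abort("exhaustive enumeration is only available with shared = TRUE")
  }
  min_p <- with_seed_if(seed, {
    if (exhaustive) {
      sets <- combn(n, n1)
      apply(sets, 2, function(idx) min(p_from_idx(idx)))
    } else {
      vapply(seq_len(n_perm), function(k) {
        if (shared) {
          min(p_from_idx(sample.int(n, n1)))
        } else {
          min(vapply(seq_len(ncol(m)), function(j) {
            p_from_idx(sample.int(n, n1))[j]
          }, numeric(1)))
        }
      }, numeric(1))
    }
  })

  denom <- length(min_p)
  fpr <- vapply(p_obs, function(p) sum(min_p <= p), numeric(1))
  fpr <- if (add_one) (fpr + 1) / (denom + 1) else fpr / denom

  out <- tibble(
    trait = colnames(m),
    u = u_obs,
    p_raw = p_obs,
    fpr = fpr,
    mean_1 = colMeans(m[grp1, , drop = FALSE]),
    mean_2 = colMeans(m[!grp1, , drop = FALSE]),
    n_1 = n1,
    n_2 = n2
  )
  attr(out, "min_p") <- min_p
  attr(out, "n_perm") <- denom
  attr(out, "populations") <- populations
  out
}

#' Qst: quantitative trait differentiation between two populations
#'
#' Method-of-moments one-way random-effects decomposition of strain trait
#' means grouped by population, with the standard unbalanced-design
#' correction for unequal strain counts. Qst is the proportion of variance
#' between populations: `V_b / (V_b + V_w)` for panels of fully inbred
#' strains, where the among-strain variance within populations already
#' absorbs the conventional factor of two on additive variance; the outbred
#' form `V_b / (V_b + 2 V_w)` is available via `form`. Negative
#' between-population variance estimates are truncated to zero.
#'
#' @param values Numeric vector of strain trait means.
#' @param population Population label per strain (two levels, >= 2 strains
#'   each).
#' @param form `"inbred"` (default) or `"outbred"`.
#' @return A one-row tibble: `v_between`, `v_within`, `qst`, `n_1`, `n_2`.
#' @export
qst <- function(values, population, form = c("inbred", "outbred")) {
  form <- match.arg(form)
  ok <- !is.na(values) & !is.na(population)
  values <- values[ok]
  population <- as.character(population)[ok]
  pops <- unique(population)
  if (length(pops) != 2) abort("exactly two populations are required")
  ni <- table(population)[pops]
  if (any(ni < 2)) abort("each population needs at least two strains")
  k <- 2
  N <- sum(ni)
  grand <- mean(values)
  group_means <- vapply(pops, function(p) mean(values[population == p]),
                        numeric(1))
  ss_between <- sum(ni * (group_means - grand)^2)
  ss_within <- sum((values - group_means[population])^2)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  v_b <- max(0, (ms_between - ms_within) / n0)
  v_w <- ms_within
  denom <- if (form == "inbred") v_b + v_w else v_b + 2 * v_w
  q <- if (denom == 0) NA_real_ else v_b / denom
  tibble(v_between = v_b, v_within = v_w, qst = q,
         n_1 = unname(ni[1]), n_2 = unname(ni[2]), form = form)
}

#' Percentile of a Qst value within a per-SNP Fst distribution
#'
#' Places an observed Qst within an empirical distribution of per-SNP Fst
#' values: the percentile is `100 * (# Fst values < qst) / N`. A Qst in the
#' upper tail of the neutral Fst distribution is the classic signature of
#' geographically variable directional selection on the trait.
#'
#' @param q A Qst value (see [qst()]).
#' @param fst_values Numeric vector of per-SNP Fst values (NA dropped;
#'   must be nonempty). Typically produced by [site_fst()] on allele counts
#'   downsampled to match the phenotyped strain numbers.
#' @return Percentile in \[0, 100\].
#' @export
qst_fst_quantile <- function(q, fst_values) {
  fst_values <- fst_values[!is.na(fst_values)]
  if (length(fst_values) == 0) abort("empty Fst distribution")
  100 * sum(fst_values < q) / length(fst_values)
}
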