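#' Default chromosome-arm layout for simulated panels
#'
#' Five major arms with approximate D. melanogaster lengths and 100 ancestry
#' windows per arm (500 windows genome-wide).
#'
#' @param n_windows Windows per arm.
#' @return A tibble with columns `arm`, `length_bp`, `n_windows`.
#' @export
sim_arms_default <- function(n_windows = 100) {
  tibble(
    arm = c("X", "2L", "2R", "3L", "3R"),
    length_bp = c(22.4e6, 23.0e6, 21.1e6, 24.5e6, 27.9e6),
    n_windows = n_windows
  )
}

#' Simulate a RIL ancestry-genotype panel
#'
#' Emulates the ancestry mosaic of a recombinant inbred panel derived from a
#' two-strain cross: per RIL and arm, ancestry breakpoints are drawn as a
#' Poisson process whose rate reflects `intercross_generations` of
#' recombination (expected tract length `1 / (g * c)` with `c` the per-bp
#' recombination rate, i.e. megabase-scale tracts after 12 generations),
#' tract ancestries alternate from a fair random start, and residual
#' heterozygosity after inbreeding is applied per tract at rate
#' `0.5^inbreed_generations`. Windows take the dosage of the tract overlying
#' their midpoint. Optionally, listed windows are forced to a skewed
#' panel-wide ancestry to exercise window masking.
#'
#' @param n_ril Number of RILs (default 305).
#' @param arms Arm layout (see [sim_arms_default()]).
#' @param intercross_generations Generations of interbreeding before
#'   inbreeding (default 12).
#' @param inbreed_generations Generations of inbreeding (default 5).
#' @param recomb_cm_per_mb Recombination rate (default 2 cM/Mb).
#' @param skewed_windows Optional integer indices (into the genome-wide
#'   window order) to force to skewed ancestry.
#' @param skew_prop Forced panel ancestry proportion for skewed windows
#'   (default 0.97).
#' @param seed Optional integer seed; the generator is a pure function of
#'   its arguments and the seed.
#' @return An [ancestry_panel()]; ground truth (heterozygosity rate, forced
#'   windows) is in attribute `"truth"`.
#' @export
sim_ril_panel <- function(n_ril = 305, arms = sim_arms_default(),
                          intercross_generations = 12,
                          inbreed_generations = 5,
                          recomb_cm_per_mb = 2,
                          skewed_windows = NULL, skew_prop = 0.97,
                          seed = NULL) {
  if (sum(arms$n_windows) == 0) abort("zero windows requested")
  windows <- purrr::map_dfr(seq_len(nrow(arms)), function(i) {
    w <- arms$length_bp[i] / arms$n_windows[i]
    k <- seq_len(arms$n_windows[i])
    tibble(window = sprintf("%s_%03d", arms$arm[i], k),
           arm = arms$arm[i], start = (k - 1) * w, end = k * w)
  })
  mid <- (windows$start + windows$end) / 2
  het_rate <- 0.5^inbreed_generations
  rate_per_bp <- intercross_generations * recomb_cm_per_mb / 100 / 1e6
  geno <- with_seed_if(seed, {
    g <- matrix(NA_integer_, n_ril, nrow(windows))
    for (a in seq_len(nrow(arms))) {
      cols <- which(windows$arm == arms$arm[a])
      L <- arms$length_bp[a]
      for (r in seq_len(n_ril)) {
        n_bp <- rpois(1, rate_per_bp * L)
        bounds <- c(0, sort(runif(n_bp, 0, L)), L)
        n_tracts <- length(bounds) - 1
        first <- rbinom(1, 1, 0.5)
        anc <- (first + seq_len(n_tracts) - 1) %% 2  # alternating ancestry
        het <- rbinom(n_tracts, 1, het_rate) == 1
        dos <- ifelse(het, 1L, 2L * anc)
        tract_of <- findInterval(mid[cols], bounds,
                                 rightmost.closed = TRUE)
        g[r, cols] <- dos[tract_of]
      }
    }
    if (!is.null(skewed_windows)) {
      for (j in skewed_windows) {
        forced <- rbinom(n_ril, 1, skew_prop)
        g[, j] <- ifelse(forced == 1, 2L, 0L)
      }
    }
    g
  })
  rownames(geno) <- sprintf("RIL_%04d", seq_len(n_ril))
  panel <- ancestry_panel(geno, windows)
  attr(panel, "truth") <- list(het_rate = het_rate,
                               skewed_windows = skewed_windows,
                               skew_prop = skew_prop)
  panel
}

#' Simulate RIL trait values with planted QTLs
#'
#' Builds strain trait values over a simulated ancestry panel: each strain's
#' genetic value is the parental midpoint plus the sum over planted QTLs of
#' `beta * (dosage - 1)`, where the homozygote contrast `2 * beta` equals
#' `effect_frac` times the parental strain difference. Strain means add
#' Gaussian strain-level noise; the mapped trait value is the mean of
#' `n_reps` replicates, each adding Gaussian replicate noise (so the
#' effective noise standard deviation is
#' `sqrt(strain_sd^2 + rep_sd^2 / n_reps)`).
#'
#' @param panel An [ancestry_panel()].
#' @param qtl Tibble with columns `window` (window id or genome-wide index)
#'   and `effect_frac` (homozygote contrast as a fraction of the parental
#'   difference).
#' @param parent_a,parent_b Parental strain trait values (`parent_a` is the
#'   parent whose ancestry the dosage counts).
#' @param n_reps Replicates per strain (default 19).
#' @param rep_sd Replicate noise SD (default 0.15).
#' @param strain_sd Strain-level (non-QTL) noise SD (default 0.02).
#' @param heavy_tails If `TRUE`, replicate noise is drawn from a scaled t(3)
#'   instead of a Gaussian.
#' @param seed Optional integer seed.
#' @return A list: `traits` (tibble `strain_id`, `value`), `replicates`
#'   (tibble `strain_id`, `replicate_id`, `value`), `truth` (planted betas,
#'   window indices, parental values).
#' @export
sim_ril_traits <- function(panel, qtl, parent_a, parent_b, n_reps = 19,
                           rep_sd = 0.15, strain_sd = 0.02,
                           heavy_tails = FALSE, seed = NULL) {
  idx <- if (is.numeric(qtl$window)) {
    as.integer(qtl$window)
  } else {
    match(as.character(qtl$window), panel$windows$window)
  }
  if (any(is.na(idx)) || any(idx < 1 | idx > ncol(panel$geno))) {
    abort("QTL window absent from the panel")
  }
  delta <- parent_a - parent_b
  beta <- qtl$effect_frac * delta / 2
  n <- nrow(panel$geno)
  with_seed_if(seed, {
    D <- panel$geno[, idx, drop = FALSE]
    D[is.na(D)] <- 1L  # midpoint for the rare missing dosage
    genetic <- (parent_a + parent_b) / 2 + as.numeric((D - 1L) %*% beta)
    strain_mean <- genetic + rnorm(n, 0, strain_sd)
    noise <- if (heavy_tails) {
      matrix(stats::rt(n * n_reps, df = 3) / sqrt(3) * rep_sd, n, n_reps)
    } else {
      matrix(rnorm(n * n_reps, 0, rep_sd), n, n_reps)
    }
    reps <- strain_mean + noise
    traits <- tibble(strain_id = rownames(panel$geno),
                     value = rowMeans(reps))
    replicates <- tibble(
      strain_id = rep(rownames(panel$geno), times = n_reps),
      replicate_id = rep(sprintf("rep_%02d", seq_len(n_reps)), each = n),
      value = as.numeric(reps)
    )
    list(traits = traits, replicates = replicates,
         truth = list(qtl_idx = idx, beta = beta, parent_a = parent_a,
                      parent_b = parent_b, delta = delta,
                      genetic = genetic))
  })
}

#' Simulate a strain trait table for two populations
#'
#' Draws strain trait means from a multivariate normal with a configurable
#' trait correlation structure, then shifts population 1 by `delta` per
#' trait. With `delta = 0` this is the null generator used to calibrate the
#' family-wise permutation correction.
#'
#' @param n1,n2 Strains in populations 1 and 2 (defaults 10 and 7).
#' @param n_traits Number of traits (default 37).
#' @param delta Population shift, scalar or per-trait vector (default 0).
#' @param between_sd Between-strain SD per trait (default 1).
#' @param cor_structure `"ar1"` (default), `"exchangeable"` or
#'   `"identity"`; ignored when `cor_mat` is given.
#' @param cor_rho Correlation parameter (default 0.5).
#' @param cor_mat Optional explicit trait correlation matrix; repaired to
#'   the nearest positive-definite correlation (eigenvalue clipping) with a
#'   warning if needed.
#' @param cohorts Population labels (default `c("FR", "ZI")`).
#' @param seed Optional integer seed.
#' @return A strain trait table: `strain_id`, `cohort`, `trait_01` ...
#' @export
sim_population_panel <- function(n1 = 10, n2 = 7, n_traits = 37, delta = 0,
                                 between_sd = 1,
                                 cor_structure = c("ar1", "exchangeable",
                                                   "identity"),
                                 cor_rho = 0.5, cor_mat = NULL,
                                 cohorts = c("FR", "ZI"), seed = NULL) {
  cor_structure <- match.arg(cor_structure)
  if (is.null(cor_mat)) {
    idx <- seq_len(n_traits)
    cor_mat <- switch(cor_structure,
      ar1 = cor_rho^abs(outer(idx, idx, "-")),
      exchangeable = matrix(cor_rho, n_traits, n_traits) +
        diag(1 - cor_rho, n_traits),
      identity = diag(n_traits)
    )
  } else {
    cor_mat <- repair_correlation(cor_mat)
  }
  delta <- rep_len(delta, n_traits)
  sigma <- (between_sd^2) * cor_mat
  with_seed_if(seed, {
    m <- MASS::mvrnorm(n1 + n2, mu = rep(0, n_traits), Sigma = sigma)
    m[seq_len(n1), ] <- m[seq_len(n1), , drop = FALSE] +
      matrix(delta, n1, n_traits, byrow = TRUE)
    colnames(m) <- sprintf("trait_%02d", seq_len(n_traits))
    dplyr::bind_cols(
      tibble(strain_id = sprintf("S_%02d", seq_len(n1 + n2)),
             cohort = rep(cohorts, c(n1, n2))),
      as_tibble(m)
    )
  })
}

# Nearest-positive-definite repair by eigenvalue clipping, rescaled to a
# unit diagonal.
repair_correlation <- function(m, eps = 1e-8) {
  ev <- eigen(m, symmetric = TRUE)
  if (all(ev$values > eps)) return(m)
  warn("correlation matrix is not positive definite; applying eigenvalue clipping")
  vals <- pmax(ev$values, eps)
  r <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  d <- sqrt(diag(r))
  r / tcrossprod(d)
}

#' Simulate a pair of diverged haplotype panels
#'
#' Draws biallelic SNP haplotypes for two populations under the
#' Balding-Nichols model: each site's ancestral frequency is uniform on
#' `maf_range` and population frequencies are Beta-distributed around it
#' with divergence parameter `fst` (with `fst = 0` the populations share
#' the ancestral frequency exactly). Optionally plants a local sweep in
#' population 1: within the sweep window, haplotypes are replaced by copies
#' of one template with per-site copying-error rate `sweep_fidelity`.
#'
#' @param n1,n2 Haplotypes per population (defaults 20).
#' @param n_win Number of windows (default 200).
#' @param sites_per_window SNPs per window (default 40).
#' @param window_bp Window width in bp (default 10000).
#' @param fst Balding-Nichols divergence parameter (default 0.2).
#' @param maf_range Ancestral frequency range (default `c(0.05, 0.95)`).
#' @param sweep_window Optional window index to sweep in population 1.
#' @param sweep_fidelity Per-site mutation rate of sweep copies
#'   (default 0.02).
#' @param missing_rate Per-genotype missing rate (default 0).
#' @param arm Arm label (default `"2L"`).
#' @param seed Optional integer seed.
#' @return A list: `pop1`, `pop2` ([haplotype_panel()]s), `windows` tibble,
#'   `truth` (ancestral frequencies, sweep window).
#' @export
sim_haplotypes <- function(n1 = 20, n2 = 20, n_win = 200,
                           sites_per_window = 40, window_bp = 10000,
                           fst = 0.2, maf_range = c(0.05, 0.95),
                           sweep_window = NULL, sweep_fidelity = 0.02,
                           missing_rate = 0, arm = "2L", seed = NULL) {
  S <- n_win * sites_per_window
  windows <- tibble(
    window = sprintf("%s_w%03d", arm, seq_len(n_win)),
    arm = arm,
    start = (seq_len(n_win) - 1) * window_bp + 1,
    end = seq_len(n_win) * window_bp
  )
  with_seed_if(seed, {
    pos <- sort(unlist(lapply(seq_len(n_win), function(i) {
      sort(sample(seq(windows$start[i], windows$end[i]), sites_per_window))
    })))
    p_anc <- runif(S, maf_range[1], maf_range[2])
    pop_freq <- function(p) {
      if (fst == 0) return(p)
      rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    }
    p1 <- pop_freq(p_anc)
    p2 <- pop_freq(p_anc)
    h1 <- matrix(rbinom(n1 * S, 1, rep(p1, each = n1)), n1, S)
    h2 <- matrix(rbinom(n2 * S, 1, rep(p2, each = n2)), n2, S)
    if (!is.null(sweep_window)) {
      in_sweep <- pos >= windows$start[sweep_window] &
        pos <= windows$end[sweep_window]
      template <- h1[1, in_sweep]
      for (r in seq_len(n1)) {
        flip <- rbinom(sum(in_sweep), 1, sweep_fidelity) == 1
        h1[r, in_sweep] <- ifelse(flip, 1L - template, template)
      }
    }
    if (missing_rate > 0) {
      h1[matrix(rbinom(n1 * S, 1, missing_rate) == 1, n1, S)] <- NA_integer_
      h2[matrix(rbinom(n2 * S, 1, missing_rate) == 1, n2, S)] <- NA_integer_
    }
    list(
      pop1 = haplotype_panel(h1, pos, arm),
      pop2 = haplotype_panel(h2, pos, arm),
      windows = windows,
      truth = list(p_anc = p_anc, p1 = p1, p2 = p2,
                   sweep_window = sweep_window)
    )
  })
}

#' Simulate non-overlapping gene models with planted list memberships
#'
#' Lays out non-overlapping genes along one arm, each with 1-10 exons
#' (0-based half-open coordinates) and Bernoulli coding flags (the first
#' and last exon keep a coding core so every gene has at least one coding
#' exon), and plants memberships in named candidate lists.
#'
#' @param n_genes Number of genes (default 30).
#' @param arm Arm label (default `"3R"`).
#' @param arm_length Arm length in bp (default 1e6).
#' @param lists Named integer vector: how many genes to sample into each
#'   candidate list (e.g. `c(courtship = 5)`).
#' @param seed Optional integer seed.
#' @return An exon tibble as from [read_gene_models()]; planted list
#'   memberships are in attribute `"truth"`.
#' @export
sim_gene_models <- function(n_genes = 30, arm = "3R", arm_length = 1e6,
                            lists = c(), seed = NULL) {
  if (n_genes == 0) {
    out <- tibble(gene_id = character(), symbol = character(),
                  arm = character(), strand = character(),
                  start = numeric(), end = numeric(), coding = logical())
    attr(out, "truth") <- list(memberships = list())
    return(out)
  }
  with_seed_if(seed, {
    slot <- arm_length / n_genes
    exons <- purrr::map_dfr(seq_len(n_genes), function(i) {
      gid <- sprintf("gene_%03d", i)
      lo <- (i - 1) * slot + slot * 0.1
      hi <- i * slot - slot * 0.1
      k <- sample(1:10, 1)
      cuts <- sort(runif(2 * k, lo, hi))
      starts <- cuts[seq(1, 2 * k, 2)]
      ends <- cuts[seq(2, 2 * k, 2)]
      ok <- ends > starts
      starts <- starts[ok]
      ends <- ends[ok]
      if (length(starts) == 0) { starts <- lo; ends <- hi }
      coding <- rbinom(length(starts), 1, 0.7) == 1
      coding[1] <- TRUE
      tibble(gene_id = gid, symbol = gid, arm = arm,
             strand = sample(c("+", "-"), 1),
             start = floor(starts), end = ceiling(ends), coding = coding)
    })
    gene_ids <- unique(exons$gene_id)
    memberships <- lapply(lists, function(k) {
      sample(gene_ids, min(k, length(gene_ids)))
    })
    names(memberships) <- names(lists)
    attr(exons, "truth") <- list(memberships = memberships)
    exons
  })
}

#' Simulate recording-level song data with planted filter violations
#'
#' Expands a strain table into replicate recording rows: every trait cell
#' gets Gaussian replicate noise, quality fields (`song_seconds_per_min`,
#' `sine_seconds_total`) are drawn in the retained range, and a requested
#' number of disjoint recordings is planted to violate the low-song and
#' high-sine filter rules. Optionally zeroes a fraction of trait cells to
#' exercise per-trait zero exclusion.
#'
#' @param strain_table Tibble `strain_id`, `cohort`, plus numeric trait
#'   columns (e.g. from [sim_population_panel()]).
#' @param n_reps Replicates per strain (default 5).
#' @param rep_sd Replicate noise SD (default 0.1).
#' @param n_low_song,n_high_sine Planted counts of filter-violating
#'   recordings (disjoint; default 0).
#' @param zero_rate Fraction of trait cells set to zero (default 0).
#' @param min_song,max_sine Filter thresholds used to place violations.
#' @param seed Optional integer seed.
#' @return A recordings tibble; planted violation row ids are in attribute
#'   `"truth"`.
#' @export
sim_recordings <- function(strain_table, n_reps = 5, rep_sd = 0.1,
                           n_low_song = 0, n_high_sine = 0, zero_rate = 0,
                           min_song = 1, max_sine = 55, seed = NULL) {
  traits <- setdiff(names(strain_table), c("strain_id", "cohort"))
  traits <- traits[vapply(strain_table[traits], is.numeric, logical(1))]
  n_strain <- nrow(strain_table)
  n_rec <- n_strain * n_reps
  if (n_low_song + n_high_sine > n_rec) {
    abort("more planted violations than recordings")
  }
  with_seed_if(seed, {
    rec <- strain_table[rep(seq_len(n_strain), each = n_reps),
                        c("strain_id", "cohort")]
    rec$replicate_id <- rep(sprintf("rep_%02d", seq_len(n_reps)), n_strain)
    rec$song_seconds_per_min <- runif(n_rec, min_song + 1, min_song + 20)
    rec$sine_seconds_total <- runif(n_rec, 5, max_sine - 5)
    viol <- sample(n_rec, n_low_song + n_high_sine)
    low <- head(viol, n_low_song)
    high <- tail(viol, n_high_sine)
    rec$song_seconds_per_min[low] <- runif(n_low_song, 0, min_song * 0.9)
    rec$sine_seconds_total[high] <- runif(n_high_sine, max_sine * 1.1,
                                          max_sine * 2)
    for (tr in traits) {
      v <- rep(strain_table[[tr]], each = n_reps) + rnorm(n_rec, 0, rep_sd)
      if (zero_rate > 0) v[rbinom(n_rec, 1, zero_rate) == 1] <- 0
      rec[[tr]] <- v
    }
    rec <- as_tibble(rec)
    attr(rec, "truth") <- list(low_song_rows = low, high_sine_rows = high)
    rec
  })
}
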