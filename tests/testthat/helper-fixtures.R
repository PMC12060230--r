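# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A LOD profile tibble laid out as consecutive 10-bp windows on one or more
# arms, for exercising the peak/CI algorithm directly.
make_profile <- function(lod, masked = rep(FALSE, length(lod)),
                         arm = rep("3R", length(lod)), width = 10) {
  n <- length(lod)
  start <- numeric(n)
  for (a in unique(arm)) {
    i <- which(arm == a)
    start[i] <- (seq_along(i) - 1) * width
  }
  tibble::tibble(
    window = sprintf("w%02d", seq_len(n)),
    arm = arm, start = start, end = start + width,
    lod = ifelse(masked, NA_real_, lod), masked = masked
  )
}

# A small ancestry panel with explicit dosages (RIL x window).
make_panel <- function(geno, arm = "2L", width = 10) {
  n_win <- ncol(geno)
  windows <- tibble::tibble(
    window = sprintf("w%02d", seq_len(n_win)),
    arm = arm,
    start = (seq_len(n_win) - 1) * width,
    end = seq_len(n_win) * width
  )
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("RIL_%03d", seq_len(nrow(geno)))
  }
  colnames(geno) <- windows$window
  songqtl::ancestry_panel(geno, windows)
}

# Independent Mann-Whitney oracle: exact two-sided p by full enumeration of
# all C(n, n_a) group labelings (doubled smaller tail, capped at 1).
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(n, n_a)
  u_all <- apply(sets, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Independent per-window LOD oracle via explicit OLS residual sums of
# squares.
lm_lod_oracle <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]
  y <- y[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (length(unique(g)) < 2) return(0)
  fit <- stats::lm(y ~ g)
  rss1 <- sum(stats::resid(fit)^2)
  (n / 2) * log10(rss0 / rss1)
}
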