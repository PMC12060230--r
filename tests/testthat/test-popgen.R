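test_that("per-site Hudson Fst matches hand-evaluated arithmetic", {
  # p1 = 0.8 (n=10), p2 = 0.2 (n=10):
  # num = 0.36 - 2 * (0.16/9), den = 0.64 + 0.04
  f <- site_fst(8, 10, 2, 10)
  expect_equal(f$num, 0.36 - 2 * 0.16 / 9, tolerance = 1e-12)
  expect_equal(f$den, 0.68, tolerance = 1e-12)
  expect_equal(f$fst, (0.36 - 2 * 0.16 / 9) / 0.68, tolerance = 1e-12)
  # fixed difference
  expect_equal(site_fst(10, 10, 0, 10)$fst, 1)
  # monomorphic same allele in both: undefined
  expect_true(is.na(site_fst(0, 10, 0, 10)$fst))
  # equal frequencies at large n: near zero (small negatives allowed)
  expect_equal(site_fst(500, 1000, 500, 1000)$fst, 0, tolerance = 2e-3)
  expect_error(site_fst(3, 1, 2, 10), ">= 2")
})

test_that("window Fst summaries match brute-force site sums", {
  sim <- sim_haplotypes(n1 = 12, n2 = 14, n_win = 3, sites_per_window = 20,
                        fst = 0.15, seed = 121)
  win <- c(sim$windows$start[2], sim$windows$end[2])
  full <- window_fst_full(sim$pop1, sim$pop2, win)
  maxsnp <- window_fst_maxsnp(sim$pop1, sim$pop2, win)

  # independent per-site oracle from raw allele counts
  in_win <- sim$pop1$pos >= win[1] & sim$pop1$pos <= win[2]
  num <- den <- fst <- numeric(0)
  for (s in which(in_win)) {
    p1 <- mean(sim$pop1$haps[, s])
    p2 <- mean(sim$pop2$haps[, s])
    n1 <- nrow(sim$pop1$haps)
    n2 <- nrow(sim$pop2$haps)
    nm <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    dn <- p1 * (1 - p2) + p2 * (1 - p1)
    if (dn > 0) {
      num <- c(num, nm); den <- c(den, dn); fst <- c(fst, nm / dn)
    }
  }
  expect_equal(full, sum(num) / sum(den), tolerance = 1e-12)
  expect_equal(maxsnp, max(fst), tolerance = 1e-12)
  expect_gte(maxsnp, max(fst) - 1e-12)  # max over per-site values exactly

  # single-SNP window equals the site statistic; fixed difference gives 1
  one <- haplotype_panel(matrix(c(1L, 1L, 1L), 3, 1), 50)
  zero <- haplotype_panel(matrix(c(0L, 0L, 0L), 3, 1), 50)
  expect_equal(window_fst_full(one, zero, c(0, 100)), 1)
  expect_equal(window_fst_maxsnp(one, zero, c(0, 100)), 1)
})

test_that("comparative haplotype identity follows the run-span accounting", {
  # identical pairs in both populations: ratio 1
  pos <- 0:100
  all_same <- haplotype_panel(matrix(0L, 2, 101), pos)
  res <- window_chi_md(all_same, all_same, c(0, 100))
  expect_equal(res$chi_md, 1)

  # pop2's pair differs at the midpoint: its best run spans 49 bp vs 100
  h2 <- matrix(0L, 2, 101)
  h2[2, 51] <- 1L
  broken <- haplotype_panel(h2, pos)
  res2 <- window_chi_md(all_same, broken, c(0, 100))
  expect_equal(res2$i_pop1, 100)
  expect_equal(res2$i_pop2, 49)
  expect_equal(res2$chi_md, 100 / 49)  # ~2: sweep-like elevation

  # reciprocal ratios multiply to one when both are finite
  rev <- window_chi_md(broken, all_same, c(0, 100))
  expect_equal(res2$chi_md * rev$chi_md, 1, tolerance = 1e-12)

  # no identity anywhere in pop2 -> infinite sentinel with flag
  opp <- haplotype_panel(rbind(rep(0L, 101), rep(1L, 101)), pos)
  res3 <- window_chi_md(all_same, opp, c(0, 100))
  expect_true(is.infinite(res3$chi_md))
  expect_true(res3$undefined)
})

test_that("identity statistic: missing sites, order and label invariance", {
  set.seed(122)
  pos <- sort(sample(1:5000, 60))
  h <- matrix(rbinom(8 * 60, 1, 0.5), 8, 60)
  p1 <- haplotype_panel(h, pos)
  p2 <- haplotype_panel(matrix(rbinom(8 * 60, 1, 0.5), 8, 60), pos)
  win <- c(1, 5000)
  base <- window_chi_md(p1, p2, win)

  # haplotype order invariance
  perm <- haplotype_panel(h[sample(8), ], pos)
  expect_equal(window_chi_md(perm, p2, win)$chi_md, base$chi_md)

  # global allele swap at every site preserves identity patterns
  swapped <- haplotype_panel(1L - h, pos)
  expect_equal(window_chi_md(swapped, p2, win)$chi_md, base$chi_md)

  # a missing site breaks no run: pair identical elsewhere keeps full span
  hm <- matrix(0L, 2, 5)
  hm[1, 3] <- NA_integer_
  pm <- haplotype_panel(hm, c(10, 20, 30, 40, 50))
  expect_equal(songqtl:::pop_identity_score(pm, c(0, 60)), 40)

  # fully missing pairs are dropped under the missing tolerance
  hd <- rbind(rep(0L, 5), rep(NA_integer_, 5), rep(0L, 5))
  pd <- haplotype_panel(hd, c(10, 20, 30, 40, 50))
  expect_equal(songqtl:::pop_identity_score(pd, c(0, 60)), 40)
})

test_that("arm outliers flag the top quantile per statistic", {
  set.seed(123)
  stats <- tibble::tibble(
    window = sprintf("w%04d", 1:1000), arm = "3R",
    start = (1:1000) * 10, end = (1:1000) * 10 + 10,
    fst_fullwin = sample(seq(0.001, 1, length.out = 1000)),
    fst_maxsnp = runif(1000),
    chi_md = rlnorm(1000)
  )
  out <- arm_outliers(stats, q = 0.01)
  # distinct values: exactly the top 10 of 1000 are flagged
  expect_equal(sum(out$fst_fullwin_outlier), 10)
  expect_equal(which(out$fst_fullwin_outlier),
               which(rank(stats$fst_fullwin) > 990))
  # brute-force sort oracle for the other statistics
  for (st in c("fst_maxsnp", "chi_md")) {
    thr <- quantile(stats[[st]], 0.99, type = 7)
    expect_equal(out[[paste0(st, "_outlier")]], stats[[st]] >= thr)
  }
  expect_equal(out$outlier,
               out$fst_fullwin_outlier | out$fst_maxsnp_outlier |
                 out$chi_md_outlier)
  # all-equal degenerate: every window reaches the quantile
  tied <- stats
  tied$fst_fullwin <- 0.5
  out2 <- arm_outliers(tied, q = 0.01)
  expect_true(all(out2$fst_fullwin_outlier))
})

test_that("window stats pipeline is invariant to haplotype order", {
  sim <- sim_haplotypes(n1 = 10, n2 = 10, n_win = 5, sites_per_window = 15,
                        fst = 0.2, seed = 124)
  s1 <- suppressWarnings(
    popgen_window_stats(sim$pop1, sim$pop2, sim$windows))
  shuf <- haplotype_panel(sim$pop1$haps[sample(10), ], sim$pop1$pos,
                          sim$pop1$arm)
  s2 <- suppressWarnings(popgen_window_stats(shuf, sim$pop2, sim$windows))
  expect_equal(s1$fst_fullwin, s2$fst_fullwin)
  expect_equal(s1$fst_maxsnp, s2$fst_maxsnp)
  expect_equal(s1$chi_md, s2$chi_md)
})
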