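test_that("generators are pure functions of their seed", {
  p1 <- sim_ril_panel(n_ril = 30, arms = sim_arms_default(20), seed = 141)
  p2 <- sim_ril_panel(n_ril = 30, arms = sim_arms_default(20), seed = 141)
  expect_identical(p1$geno, p2$geno)

  h1 <- sim_haplotypes(n_win = 4, sites_per_window = 10, seed = 142)
  h2 <- sim_haplotypes(n_win = 4, sites_per_window = 10, seed = 142)
  expect_identical(h1$pop1$haps, h2$pop1$haps)

  s1 <- sim_population_panel(seed = 143)
  s2 <- sim_population_panel(seed = 143)
  expect_identical(s1, s2)

  g1 <- sim_gene_models(seed = 144)
  g2 <- sim_gene_models(seed = 144)
  expect_identical(as.data.frame(g1), as.data.frame(g2), ignore_attr = TRUE)
})

test_that("ancestry panel has balanced dosage and megabase-scale tracts", {
  panel <- sim_ril_panel(n_ril = 305, seed = 145)
  means <- colMeans(panel$geno)
  # each window's mean dosage is ~1 (50:50 ancestry); with per-RIL dosage
  # variance ~1 the SE at n = 305 is ~0.057
  expect_equal(mean(means), 1, tolerance = 0.02)
  expect_true(all(abs(means - 1) < 6 * 0.057))
  # dosages are valid and mostly homozygous (residual heterozygosity
  # ~0.5^5)
  expect_true(all(panel$geno %in% 0:2))
  expect_lt(mean(panel$geno == 1), 0.08)
  # adjacent windows share ancestry far more often than distant ones
  # (megabase tracts over ~230-kb windows)
  same_adj <- mean(panel$geno[, 1:99] == panel$geno[, 2:100])
  expect_gt(same_adj, 0.85)
})

test_that("unlimited inbreeding removes residual heterozygosity", {
  panel <- sim_ril_panel(n_ril = 50, arms = sim_arms_default(20),
                         inbreed_generations = 60, seed = 146)
  expect_equal(sum(panel$geno == 1), 0)
})

test_that("trait generator plants QTLs with the requested contrast", {
  panel <- sim_ril_panel(n_ril = 40, arms = sim_arms_default(10), seed = 147)
  # zero effect, zero noise: all strains identical at the parental midpoint
  flat <- sim_ril_traits(panel, tibble::tibble(window = 3, effect_frac = 0),
                         parent_a = 1, parent_b = 3, rep_sd = 0,
                         strain_sd = 0, seed = 1)
  expect_true(all(flat$traits$value == 2))
  # single QTL, no noise: trait collinear with dosage, scan peaks there
  qtl <- sim_ril_traits(panel, tibble::tibble(window = 27, effect_frac = 0.5),
                        parent_a = 1, parent_b = 3, rep_sd = 0,
                        strain_sd = 0, seed = 2)
  expect_equal(cor(qtl$traits$value, panel$geno[, 27]), -1)  # parent_a lower
  prof <- lod_scan(panel, qtl$traits$value)
  expect_equal(prof$lod[27], max(prof$lod))
  # the homozygote contrast matches the planted fraction of the gap
  by_class <- tapply(qtl$traits$value, panel$geno[, 27], mean)
  expect_equal(unname(by_class["2"] - by_class["0"]), 0.5 * (1 - 3))
  expect_error(
    sim_ril_traits(panel, tibble::tibble(window = 999, effect_frac = 0.4),
                   parent_a = 1, parent_b = 3),
    "absent"
  )
})

test_that("population panel honours shift, correlation and repair", {
  null <- sim_population_panel(delta = 0, seed = 148)
  expect_equal(dim(null), c(17, 39))
  expect_equal(as.vector(table(null$cohort)[c("FR", "ZI")]), c(10L, 7L))
  # large shift with identity correlation separates the cohorts
  shifted <- sim_population_panel(n_traits = 2, delta = 50,
                                  cor_structure = "identity", seed = 149)
  expect_true(min(shifted$trait_01[shifted$cohort == "FR"]) >
                max(shifted$trait_01[shifted$cohort == "ZI"]))
  # complete separation of 10 vs 7 reaches the exact two-sided floor
  p <- mw_test(shifted$trait_01[shifted$cohort == "FR"],
               shifted$trait_01[shifted$cohort == "ZI"])$p
  expect_equal(p, 2 / choose(17, 10))
  # a non-positive-definite correlation matrix is repaired with a warning
  bad <- matrix(0.99, 3, 3); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_warning(sim_population_panel(n_traits = 3, cor_mat = bad,
                                      seed = 150),
                 "positive definite")
})

test_that("haplotype generator matches its divergence parameter", {
  # F = 0: the two populations share site frequencies exactly
  h0 <- sim_haplotypes(n1 = 50, n2 = 50, n_win = 40, sites_per_window = 20,
                       fst = 0, seed = 151)
  sf0 <- panel_site_fst(h0$pop1, h0$pop2)
  expect_equal(mean(sf0$fst, na.rm = TRUE), 0, tolerance = 0.01)
  # positions strictly increasing, alleles binary
  expect_true(all(diff(h0$pop1$pos) > 0))
  # planted sweep elevates identity in the sweep window
  hs <- sim_haplotypes(n_win = 20, sites_per_window = 30,
                       sweep_window = 10, sweep_fidelity = 0.01,
                       seed = 152)
  stats <- suppressWarnings(
    popgen_window_stats(hs$pop1, hs$pop2, hs$windows))
  expect_equal(which.max(stats$chi_md), 10)
})

test_that("gene generator produces non-overlapping genes and empty sets", {
  genes <- sim_gene_models(n_genes = 20, seed = 153)
  expect_true(all(genes$end > genes$start))
  spans <- dplyr::summarise(dplyr::group_by(genes, gene_id),
                            lo = min(start), hi = max(end))
  spans <- spans[order(spans$lo), ]
  expect_true(all(utils::head(spans$hi, -1) <= utils::tail(spans$lo, -1)))
  # every gene keeps at least one coding exon
  expect_true(all(tapply(genes$coding, genes$gene_id, any)))
  empty <- sim_gene_models(n_genes = 0)
  expect_equal(nrow(empty), 0)
})
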