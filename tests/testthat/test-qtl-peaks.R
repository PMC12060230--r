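# Hand-traced LOD landscapes exercising every branch of the peak/CI
# algorithm: run detection, valley merging, inclusive vs restrictive
# intervals, and extension through masked windows.

test_that("significant runs are maximal contiguous stretches", {
  prof <- make_profile(c(4, 6, 4, 5, 7, 4, 2, 1))
  runs <- significant_regions(prof, threshold = 3.5)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start_idx, runs$end_idx), c(1, 6))
  expect_equal(runs$max_lod, 7)
  expect_equal(runs$peak_idx, 5)

  # nothing above threshold
  expect_equal(nrow(significant_regions(prof, threshold = 10)), 0)

  # a sub-threshold window splits two maximal runs
  prof2 <- make_profile(c(5, 1, 7))
  runs2 <- significant_regions(prof2, threshold = 4.5)
  expect_equal(nrow(runs2), 2)

  # runs never span different chromosomes
  prof3 <- make_profile(c(5, 5, 5, 5), arm = c("2R", "2R", "3L", "3L"))
  runs3 <- significant_regions(prof3, threshold = 4)
  expect_equal(nrow(runs3), 2)
  # ... but do span the centromere between arms of one chromosome
  prof4 <- make_profile(c(5, 5, 5, 5), arm = c("2L", "2L", "2R", "2R"))
  expect_equal(nrow(significant_regions(prof4, threshold = 4)), 1)
  expect_equal(nrow(significant_regions(prof4, threshold = 4,
                                        adjacency = "arm")), 2)
})

test_that("valley merging fires exactly when the shorter peak's support reaches it", {
  # peaks 5 and 7 with a valley of 4: 4 > 5 - 1.5, merged
  prof <- make_profile(c(5, 4, 7))
  runs <- significant_regions(prof, threshold = 4.5)
  expect_equal(nrow(runs), 2)
  merged <- merge_regions(runs, prof)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start_idx, merged$end_idx), c(1, 3))
  expect_equal(merged$max_lod, 7)

  # valley of 3: 3 <= 5 - 1.5, kept apart
  prof2 <- make_profile(c(5, 3, 7))
  runs2 <- significant_regions(prof2, threshold = 4.5)
  expect_equal(nrow(merge_regions(runs2, prof2)), 2)

  # single run is unchanged; merging is idempotent
  runs1 <- significant_regions(make_profile(c(4, 6, 4, 5, 7, 4)), 3.5)
  expect_equal(merge_regions(runs1, make_profile(c(4, 6, 4, 5, 7, 4))), runs1)
  m2 <- merge_regions(merged, prof)
  expect_equal(m2, merged)
})

test_that("merging iterates to a fixed point along a chain of peaks", {
  # three peaks whose valleys (4.6 and 5.2) both sit inside the shorter
  # neighbour's 1.5-LOD support, collapsing the chain into one region
  lod <- c(5.5, 4.6, 6, 5.2, 7)
  prof <- make_profile(lod)
  runs <- significant_regions(prof, threshold = 5.4)
  expect_equal(nrow(runs), 3)
  merged <- merge_regions(runs, prof)
  expect_equal(nrow(merged), 1)
  expect_true(nrow(merged) <= nrow(runs))
})

test_that("inclusive and restrictive CIs follow the 1.5-LOD qualification", {
  # ragged region: qualifying windows (LOD > 7 - 1.5) are 2 and 5 only
  prof <- make_profile(c(4, 6, 4, 5, 7, 4, 2, 1))
  runs <- significant_regions(prof, threshold = 3.5)
  ci <- confidence_intervals(runs[1, ], prof)
  expect_equal(c(ci$inclusive$start_idx, ci$inclusive$end_idx), c(2, 5))
  expect_equal(ci$inclusive$start, prof$start[2])
  expect_equal(ci$inclusive$end, prof$end[5])
  expect_equal(nrow(ci$restrictive), 2)
  expect_equal(ci$restrictive$start_idx, c(2, 5))
  expect_equal(ci$restrictive$end_idx, c(2, 5))

  # monotone peak: only the windows above max - 1.5 qualify, contiguously
  prof2 <- make_profile(c(4, 5, 6, 7))
  runs2 <- significant_regions(prof2, threshold = 3.5)
  ci2 <- confidence_intervals(runs2[1, ], prof2)
  expect_equal(c(ci2$inclusive$start_idx, ci2$inclusive$end_idx), c(3, 4))
  expect_equal(nrow(ci2$restrictive), 1)
  expect_equal(c(ci2$restrictive$start_idx, ci2$restrictive$end_idx), c(3, 4))

  # flat region: every window qualifies
  prof3 <- make_profile(rep(5, 4))
  runs3 <- significant_regions(prof3, threshold = 3.5)
  ci3 <- confidence_intervals(runs3[1, ], prof3)
  expect_equal(c(ci3$inclusive$start_idx, ci3$inclusive$end_idx), c(1, 4))
  expect_equal(nrow(ci3$restrictive), 1)
})

test_that("CIs extend through masked windows and stop at a failing window", {
  # windows: [6, 7] significant; 3 masked windows; then a failing window
  lod <- c(6, 7, NA, NA, NA, 4, 4)
  masked <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
  prof <- make_profile(lod, masked)
  runs <- significant_regions(prof, threshold = 5)
  ci <- confidence_intervals(runs[1, ], prof)
  expect_equal(c(ci$inclusive$start_idx, ci$inclusive$end_idx), c(1, 2))
  ext <- extend_through_masked(ci, runs[1, ], prof)
  # masked stretch is bridged; window 6 (LOD 4 <= 5.5) ends the CI and is
  # excluded, so the inclusive CI runs through the last masked window
  expect_equal(c(ext$inclusive$start_idx, ext$inclusive$end_idx), c(1, 5))

  # no masked neighbour: CI unchanged
  prof2 <- make_profile(c(6, 7, 4))
  runs2 <- significant_regions(prof2, threshold = 5)
  ci2 <- confidence_intervals(runs2[1, ], prof2)
  expect_identical(extend_through_masked(ci2, runs2[1, ], prof2), ci2)

  # qualifying window beyond the stretch: included, extension continues
  lod3 <- c(6, 7, NA, 6.2, 6.1, 4)
  masked3 <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  prof3 <- make_profile(lod3, masked3)
  runs3 <- significant_regions(prof3, threshold = 5)
  ci3 <- confidence_intervals(runs3[1, ], prof3)
  ext3 <- extend_through_masked(ci3, runs3[1, ], prof3)
  expect_equal(c(ext3$inclusive$start_idx, ext3$inclusive$end_idx), c(1, 5))
  # the bridged masked window does not break the restrictive run
  expect_equal(nrow(ext3$restrictive), 1)

  # masked stretch running to the chromosome end extends with a warning
  lod4 <- c(6, 7, NA, NA)
  masked4 <- c(FALSE, FALSE, TRUE, TRUE)
  prof4 <- make_profile(lod4, masked4)
  runs4 <- significant_regions(prof4, threshold = 5)
  ci4 <- confidence_intervals(runs4[1, ], prof4)
  expect_warning(ext4 <- extend_through_masked(ci4, runs4[1, ], prof4),
                 "end")
  expect_equal(ext4$inclusive$end_idx, 4)
})

test_that("full region pipeline reports sorted regions with valid CIs", {
  set.seed(101)
  lod <- c(runif(10, 0, 2), 4, 6, 4, 5, 7, 4, runif(10, 0, 2),
           5.5, 5.8, runif(4, 0, 2))
  prof <- make_profile(lod)
  regions <- find_qtl_regions(prof, threshold = 3.5,
                              p_fun = function(l) 0.123 * (l < 100))
  expect_equal(nrow(regions), 2)
  expect_true(all(diff(regions$inclusive_start) > 0))
  for (i in seq_len(nrow(regions))) {
    seg <- regions$restrictive[[i]]
    expect_true(all(seg$start >= regions$inclusive_start[i]))
    expect_true(all(seg$end <= regions$inclusive_end[i]))
    expect_true(all(diff(seg$start_idx) > 0))
    # the peak window lies inside a restrictive segment
    expect_true(any(regions$peak_idx[i] >= seg$start_idx &
                      regions$peak_idx[i] <= seg$end_idx))
  }
  expect_equal(regions$genomewide_p, c(0.123, 0.123))

  # BED export is sorted, 0-based half-open, and covers both CI flavours
  path <- withr::local_tempfile(fileext = ".bed")
  bed <- write_regions_bed(regions, prof, path, which = "restrictive")
  expect_true(all(diff(bed$start) > 0 | diff(as.integer(factor(bed$chrom))) != 0))
  lines <- readLines(path)
  expect_equal(length(lines), sum(vapply(regions$restrictive, nrow,
                                         integer(1))))
})

test_that("ties at the maximum resolve to the leftmost window", {
  prof <- make_profile(c(4, 7, 5, 7, 4))
  runs <- significant_regions(prof, threshold = 3.5)
  expect_equal(runs$peak_idx, 2)
})
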