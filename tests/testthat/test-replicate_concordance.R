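test_that("IUT venn counts equal brute-force per-base classification", {
  tr <- target_regions("chrT", 0L, 100L)
  set.seed(17)
  for (rep in 1:5) {
    bits <- matrix(runif(300) < 0.6, ncol = 3)
    masks <- lapply(1:3, function(i) toy_mask(bits[, i], tr))
    res <- iut(masks)
    # brute force: tally membership patterns base by base
    pat <- apply(bits, 1, function(b) paste(as.integer(b), collapse = ""))
    brute <- table(factor(pat, levels = c("100", "010", "110", "001",
                                          "101", "011", "111")))
    expect_equal(unname(res$venn), as.integer(brute)[c(1:7)])
    expect_equal(res$intersection, sum(bits[, 1] & bits[, 2] & bits[, 3]))
    expect_equal(res$union, sum(bits[, 1] | bits[, 2] | bits[, 3]))
    # conservation identities
    expect_equal(sum(res$venn), res$union)
    expect_equal(res$variable, res$union - res$intersection)
    expect_equal(sum(res$fractions), 100)
  }
})

test_that("identical masks give zero variable fraction; mismatches error", {
  tr <- target_regions("chrT", 0L, 50L)
  m <- toy_mask(rep(c(TRUE, FALSE), 25), tr)
  res <- iut(list(m, m, m))
  expect_equal(res$variable, 0L)
  expect_equal(res$intersection, res$union)

  m1 <- toy_mask(rep(TRUE, 50), tr, t = 1)
  expect_error(iut(list(m, m, m1)), "threshold")
  tr2 <- target_regions("chrT", 0L, 60L)
  m2 <- toy_mask(rep(TRUE, 60), tr2)
  expect_error(iut(list(m, m, m2)), "target spaces")
})

test_that("two-proportion test matches the hand-computed 2x2 chi-square oracle", {
  eq <- two_proportion_test(5, 10, 50, 100, continuity = FALSE)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  grid <- expand.grid(x1 = c(0, 2, 5, 9), n1 = c(10, 25),
                      x2 = c(1, 4, 9), n2 = c(10, 40),
                      corr = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- two_proportion_test(g$x1, g$n1, g$x2, g$n2, continuity = g$corr)
    want <- chisq_2x2_oracle(g$x1, g$n1, g$x2, g$n2, continuity = g$corr)
    expect_lt(abs(got$p_value - want$p_value), 1e-10)
    expect_lt(abs(got$statistic - want$statistic), 1e-10)
    # symmetry under group swap
    swap <- two_proportion_test(g$x2, g$n2, g$x1, g$n1, continuity = g$corr)
    expect_equal(got$p_value, swap$p_value)
  }
  expect_error(two_proportion_test(0, 0, 1, 10), "positive")
})

test_that("aggregation sums depths and is linear in mean depth", {
  tr <- target_regions("chrT", 0L, 1L)
  ps <- Map(function(d, r) toy_profile(d, tr, "S1", r),
            c(10L, 20L, 30L), c("R1", "R2", "R3"))
  expect_equal(aggregate_profiles(ps)$depth, 60L)

  one <- toy_profile(7L, toy_targets(2L))
  agg1 <- aggregate_profiles(list(one))
  expect_equal(agg1$depth, one$depth)
  expect_equal(agg1$replicate_id, "aggregate")

  set.seed(23)
  tr2 <- toy_targets(8L, width = 40L)
  reps <- lapply(1:3, function(i)
    toy_profile(rpois(tr2$total_bases, 15 * i), tr2, "S1", paste0("R", i)))
  expect_equal(mean_target_depth(aggregate_profiles(reps)),
               sum(vapply(reps, mean_target_depth, numeric(1))))

  other <- toy_profile(5L, tr2, "S2", "R1")
  expect_error(aggregate_profiles(c(reps, list(other))), "mixed samples")
})

test_that("recovered bases are the aggregate mask minus the replicate intersection", {
  tr <- target_regions("chrT", 0L, 1L)
  reps <- Map(function(d, r) toy_profile(d, tr, "S1", r),
              c(19L, 19L, 19L), c("R1", "R2", "R3"))
  agg <- aggregate_profiles(reps)
  rmask <- lapply(reps, coverage_mask, t = 20)
  rec <- recovered_mask(coverage_mask(agg, 20), rmask)
  expect_true(rec$mask)  # 57x aggregate recovers the base all replicates missed

  covered <- Map(function(d, r) toy_profile(d, tr, "S1", r),
                 c(25L, 30L, 21L), c("R1", "R2", "R3"))
  rec2 <- recovered_mask(coverage_mask(aggregate_profiles(covered), 20),
                         lapply(covered, coverage_mask, t = 20))
  expect_false(rec2$mask)

  set.seed(19)
  tr3 <- toy_targets(6L, width = 30L)
  reps3 <- lapply(1:3, function(i)
    toy_profile(rpois(tr3$total_bases, 10), tr3, "S1", paste0("R", i)))
  agg3 <- aggregate_profiles(reps3)
  rec3 <- recovered_mask(coverage_mask(agg3, 20),
                         lapply(reps3, coverage_mask, t = 20))
  brute <- agg3$depth >= 20 &
    !(reps3[[1]]$depth >= 20 & reps3[[2]]$depth >= 20 & reps3[[3]]$depth >= 20)
  expect_equal(rec3$mask, brute)
  # recovered set is inside the aggregate mask, disjoint from the intersection
  expect_true(all(!rec3$mask | agg3$depth >= 20))
  expect_error(recovered_mask(coverage_mask(agg3, 10),
                              lapply(reps3, coverage_mask, t = 20)),
               "threshold")
})

test_that("segments are maximal runs that never span target gaps", {
  tr <- target_regions("chrT", 0L, 4L)
  segs <- segments_from_mask(toy_mask(c(TRUE, TRUE, FALSE, TRUE), tr))
  expect_equal(segs$segments$start, c(0L, 3L))
  expect_equal(segs$segments$end, c(2L, 4L))
  expect_equal(segs$segments$length, c(2L, 1L))

  expect_equal(segments_from_mask(toy_mask(rep(FALSE, 4), tr))$n_segments, 0L)

  # a run of TRUEs across two adjacent-in-flat-space targets must split
  tr2 <- toy_targets(2L, width = 3L, gap = 5L)
  segs2 <- segments_from_mask(toy_mask(rep(TRUE, 6), tr2))
  expect_equal(segs2$n_segments, 2L)
  expect_equal(segs2$segments$length, c(3L, 3L))

  set.seed(29)
  tr3 <- toy_targets(5L, width = 20L)
  bits <- runif(tr3$total_bases) < 0.5
  segs3 <- segments_from_mask(toy_mask(bits, tr3))
  # brute-force run-length scan within each target interval
  brute <- unlist(lapply(0:4, function(i) {
    r <- rle(bits[(i * 20 + 1):((i + 1) * 20)])
    r$lengths[r$values]
  }))
  expect_equal(segs3$segments$length, as.integer(brute))
  expect_equal(segs3$total_bases, sum(bits))
})

test_that("segment length distribution recovers an exact power law", {
  lengths <- rep(c(1, 2, 4, 8, 16), times = c(256, 64, 16, 4, 1))
  pl <- segment_length_distribution(lengths)
  expect_equal(pl$slope, -2, tolerance = 1e-6)
  expect_gt(pl$r_squared, 1 - 1e-10)
  expect_equal(pl$n_singletons, 256L)

  pl2 <- segment_length_distribution(c(1, 1, 1, 1, 2, 2))
  expect_equal(pl2$freq$count, c(4L, 2L))
  expect_equal(pl2$mean_length, 8 / 6)

  # single distinct length: histogram returned, slope undefined
  pl3 <- segment_length_distribution(rep(5, 10))
  expect_true(is.na(pl3$slope))
  expect_equal(pl3$freq$count, 10L)
})

test_that("segment-exon intersection counts segments once and overlaps per base", {
  exons <- target_regions("chrT", 50L, 60L)
  seg100 <- structure(list(segments = data.frame(chrom = "chrT", start = 0L,
                                                 end = 100L, length = 100L),
                           n_segments = 1L, total_bases = 100L),
                      class = "SegmentSet")
  ov <- intersect_segments_exons(seg100, exons, min_len = 50)
  expect_equal(ov$n_overlapping_segments, 1L)
  expect_equal(ov$overlapped_coding_bases, 10L)

  # boundary: a segment of exactly min_len is excluded (strictly greater)
  seg50 <- structure(list(segments = data.frame(chrom = "chrT", start = 0L,
                                                end = 50L, length = 50L),
                          n_segments = 1L, total_bases = 50L),
                     class = "SegmentSet")
  ov50 <- intersect_segments_exons(seg50, exons, min_len = 50)
  expect_equal(ov50$n_overlapping_segments, 0L)

  set.seed(37)
  tr <- toy_targets(6L, width = 120L, gap = 30L)
  bits <- runif(tr$total_bases) < 0.7
  segs <- segments_from_mask(toy_mask(bits, tr))
  sel <- seq(1, nrow(tr$regions), by = 2)
  ex <- target_regions(tr$regions$chrom[sel],
                       tr$regions$start[sel] + 10L,
                       tr$regions$end[sel] - 10L)
  got <- intersect_segments_exons(segs, ex, min_len = 3)
  # brute force per base
  expos <- paste0(target_positions(ex)$chrom, ":", target_positions(ex)$pos)
  keep <- segs$segments[segs$segments$length > 3, ]
  per_seg <- vapply(seq_len(nrow(keep)), function(i)
    sum(paste0(keep$chrom[i], ":", keep$start[i]:(keep$end[i] - 1)) %in% expos),
    numeric(1))
  expect_equal(got$overlapped_coding_bases, sum(per_seg))
  expect_equal(got$n_overlapping_segments, sum(per_seg > 0))
})
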