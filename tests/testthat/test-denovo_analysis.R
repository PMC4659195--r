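test_that("Mendelian consistency matches gamete enumeration over all 27 triples", {
  gts <- c("hom_ref", "het", "hom_alt")
  alleles <- list(hom_ref = c(0, 0), het = c(0, 1), hom_alt = c(1, 1))
  n_bad <- 0L
  for (child in gts) for (father in gts) for (mother in gts) {
    # independent oracle: enumerate transmitted gametes
    ok <- FALSE
    for (fa in alleles[[father]]) for (ma in alleles[[mother]])
      if (all(sort(c(fa, ma)) == sort(alleles[[child]]))) ok <- TRUE
    expect_identical(unname(mendelian_consistent(child, father, mother)), ok)
    if (!ok) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 12L)

  expect_false(mendelian_consistent("het", "hom_ref", "hom_ref"))
  expect_true(all(mendelian_consistent(gts, "het", "het")))
  expect_error(mendelian_consistent("no_call", "het", "het"), "no_call")
})

test_that("trio enumeration covers children of two in-pedigree parents", {
  ped <- default_pedigree()
  trios <- enumerate_trios(ped)
  expect_equal(sort(trios$child), c("C1", "C2", "G1"))
  founders <- pedigree(data.frame(id = c("A", "B"), father = NA, mother = NA,
                                  sex = 1:2))
  expect_equal(nrow(enumerate_trios(founders)), 0L)
})

test_that("detect_dnm recovers injected mutations exactly on clean data", {
  p <- sim_params(seed = 6, n_targets = 60L, target_length_mean = 150,
                  het_density = 2, de_novo_rate = 5)
  tt <- simulate_targets(p)
  ped <- default_pedigree()
  truth <- simulate_pedigree_truth(tt, ped, p)
  trios <- enumerate_trios(ped)
  calls <- calls_from_truth(truth, ped$individuals$id, depth = 100L)

  for (i in seq_len(nrow(trios))) {
    child <- trios$child[i]
    dnm <- detect_dnm(calls, trios[i, ], min_depth = 10)
    td <- truth$dnm[truth$dnm$child == child, ]
    expect_equal(sort(dnm$pos), sort(td$pos))
    # monotone in the depth filter (here trivially equal)
    dnm20 <- detect_dnm(calls, trios[i, ], min_depth = 20)
    expect_true(all(paste(dnm20$chrom, dnm20$pos) %in% paste(dnm$chrom, dnm$pos)))
  }

  # no injected DNMs and clean calls: zero candidates
  p0 <- sim_params(seed = 6, n_targets = 60L, het_density = 2, de_novo_rate = 0)
  t0 <- simulate_targets(p0)
  truth0 <- simulate_pedigree_truth(t0, ped, p0)
  calls0 <- calls_from_truth(truth0, ped$individuals$id)
  for (i in seq_len(nrow(trios)))
    expect_equal(nrow(detect_dnm(calls0, trios[i, ], min_depth = 10)), 0L)

  expect_error(detect_dnm(calls[calls$sample != "F1", ], trios[1, ]),
               "trio member F1")
})

test_that("depth and confidence filters gate DNM candidacy", {
  row1 <- function(sample, genotype, depth) {
    data.frame(chrom = "chrT", pos = 0L, ref = "A", alt = "G",
               sample = sample, replicate = "aggregate",
               genotype = genotype, depth = depth, quality = 50,
               stringsAsFactors = FALSE)
  }
  mk <- function(child_depth, child_gt = "het") {
    genotype_table(rbind(row1("K", child_gt, child_depth),
                         row1("D", "hom_ref", 40L),
                         row1("M", "hom_ref", 40L)))
  }
  trio <- data.frame(child = "K", father = "D", mother = "M")
  expect_equal(nrow(detect_dnm(mk(40L), trio, min_depth = 20)), 1L)
  # child below the depth floor: unevaluable, not a candidate
  res <- detect_dnm(mk(12L), trio, min_depth = 20)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_unevaluable"), 1L)
  # no_call in a member: unevaluable
  res2 <- detect_dnm(mk(40L, child_gt = "no_call"), trio, min_depth = 20)
  expect_equal(nrow(res2), 0L)
  expect_equal(attr(res2, "n_unevaluable"), 1L)
})

test_that("replicate/aggregate DNM concordance matches brute-force set comparison", {
  mkdnm <- function(pos) data.frame(chrom = "chrT", pos = pos)
  reps <- list(R1 = mkdnm(c(1L, 5L, 9L)), R2 = mkdnm(c(1L, 5L)),
               R3 = mkdnm(c(1L, 5L, 9L)))
  agg <- mkdnm(c(1L, 9L, 40L))
  cc <- dnm_concordance(reps, agg)
  tab <- cc$table[order(cc$table$pos), ]
  expect_equal(tab$pos, c(1L, 5L, 9L, 40L))
  expect_equal(tab$support, c(3L, 3L, 2L, 0L))
  expect_equal(tab$in_aggregate, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(cc$summary$concordant, 1L)   # pos 1: all replicates + aggregate
  expect_equal(cc$summary$aggregate_only, 1L)  # pos 40
  expect_equal(cc$summary$replicate_only, 1L)  # pos 5

  set.seed(55)
  reps2 <- lapply(1:3, function(i) mkdnm(sort(sample.int(30, 8))))
  names(reps2) <- paste0("R", 1:3)
  agg2 <- mkdnm(sort(sample.int(30, 8)))
  cc2 <- dnm_concordance(reps2, agg2)
  for (j in seq_len(nrow(cc2$table))) {
    pos <- cc2$table$pos[j]
    expect_equal(cc2$table$support[j],
                 sum(vapply(reps2, function(r) pos %in% r$pos, logical(1))))
    expect_equal(cc2$table$in_aggregate[j], pos %in% agg2$pos)
  }
})

test_that("aggregate mode finds DNMs that straddling replicate depths miss", {
  # child het site with replicate depths below the call floor but an
  # aggregate comfortably above it
  rows <- do.call(rbind, lapply(c("K", "D", "M"), function(id) {
    do.call(rbind, lapply(c("R1", "R2", "R3", "aggregate"), function(r) {
      depth <- if (r == "aggregate") 24L else 8L
      gt <- if (depth < 10) "no_call" else if (id == "K") "het" else "hom_ref"
      data.frame(chrom = "chrT", pos = 0L, ref = "A", alt = "G", sample = id,
                 replicate = r, genotype = gt, depth = depth, quality = 30,
                 stringsAsFactors = FALSE)
    }))
  }))
  calls <- genotype_table(rows)
  trio <- data.frame(child = "K", father = "D", mother = "M")
  agg <- detect_dnm(calls, trio, min_depth = 10, mode = "aggregate")
  expect_equal(nrow(agg), 1L)
  for (r in paste0("R", 1:3))
    expect_equal(nrow(detect_dnm(calls, trio, min_depth = 10, mode = r)), 0L)
})
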