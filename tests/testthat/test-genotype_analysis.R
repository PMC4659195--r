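test_that("genotype caller matches a direct three-term posterior computation", {
  # overwhelming reference evidence: log10 posterior odds of ~8.9,
  # far above any call threshold
  hr <- call_genotype(30L, 0L, error_rate = 0.01, min_call_depth = 10)
  expect_equal(hr$genotype, "hom_ref")
  expect_gt(hr$quality, 5)
  expect_equal(hr$quality,
               log10(dbinom(0, 30, 0.01) / dbinom(0, 30, 0.5)),
               tolerance = 1e-12)

  # symmetric evidence
  het <- call_genotype(15L, 15L, error_rate = 0.01)
  expect_equal(het$genotype, "het")

  # (8, 2) against an explicit Bayes computation
  got <- call_genotype(8L, 2L, error_rate = 0.01, min_call_depth = 10,
                       quality_threshold = 0)
  lik <- dbinom(2, 10, c(0.01, 0.5, 0.99)) / 3
  post <- lik / sum(lik)
  ord <- order(post, decreasing = TRUE)
  expect_equal(got$genotype, c("hom_ref", "het", "hom_alt")[ord[1]])
  expect_equal(got$quality, log10(post[ord[1]] / post[ord[2]]),
               tolerance = 1e-12)

  # thresholds produce no_call
  expect_equal(call_genotype(4L, 4L, min_call_depth = 10)$genotype, "no_call")
  expect_equal(call_genotype(6L, 4L, min_call_depth = 10,
                             quality_threshold = 50)$genotype, "no_call")
  expect_equal(call_genotype(0L, 0L)$genotype, "no_call")
  expect_error(call_genotype(5L, 5L, error_rate = 0.6), "error_rate")
  expect_error(call_genotype(5L, 5L, error_rate = 0), "error_rate")
})

test_that("caller recovers simulated truth exactly at high depth and zero error", {
  p <- sim_params(seed = 14, n_targets = 100L, target_length_mean = 150,
                  het_density = 3, de_novo_rate = 2, base_error_rate = 0,
                  per_target_sdlog = 0, target_failure_rate = 0,
                  efficiency_sdlog = 0, mean_depth = 80,
                  library_scale_range = c(1, 1))
  tt <- simulate_targets(p)
  ped <- default_pedigree()
  truth <- simulate_pedigree_truth(tt, ped, p)
  for (id in c("F1", "C1", "G1")) {
    pr <- simulate_replicate_depth(tt, p, "R1", sample_id = id)
    cnt <- simulate_allele_counts(truth, pr, p)
    calls <- call_genotype_table(cnt, error_rate = 0.005)
    deep <- calls$depth >= 30
    expect_true(all(calls$genotype[deep] == truth$genotypes[deep, id]))
  }
})

test_that("position binning uses the minimum depth across replicates", {
  tr <- target_regions("chrT", 0L, 3L)
  reps <- Map(function(d, r) depth_profile(tr, d, "S1", r),
              list(c(12L, 9L, 35L), c(15L, 100L, 31L), c(40L, 100L, 30L)),
              c("R1", "R2", "R3"))
  b <- bin_positions(reps)
  expect_equal(as.character(b$bin), c("10-19x", NA, ">=30x"))
  expect_equal(as.integer(b$counts), c(1L, 0L, 1L))

  set.seed(44)
  tr2 <- toy_targets(10L, width = 25L)
  reps2 <- lapply(1:3, function(i)
    toy_profile(rpois(tr2$total_bases, 25), tr2, "S1", paste0("R", i)))
  b2 <- bin_positions(reps2)
  mind <- pmin(reps2[[1]]$depth, reps2[[2]]$depth, reps2[[3]]$depth)
  expect_equal(as.integer(b2$counts),
               c(sum(mind >= 10 & mind < 20), sum(mind >= 20 & mind < 30),
                 sum(mind >= 30)))
  expect_error(bin_positions(reps2[1]), "at least 2")
})

test_that("discordance tallies disagreeing confident calls per depth bin", {
  tr <- target_regions("chrT", 0L, 100L)
  reps <- lapply(1:3, function(i) toy_profile(15L, tr, "S1", paste0("R", i)))
  bins <- bin_positions(reps)

  site <- function(pos, genos, quality = 20) {
    do.call(rbind, lapply(1:3, function(i)
      data.frame(chrom = "chrT", pos = pos, ref = "A", alt = "G",
                 sample = "S1", replicate = paste0("R", i),
                 genotype = genos[i], depth = 15L, quality = quality)))
  }
  calls <- genotype_table(rbind(
    site(0L, c("het", "het", "het")),
    site(1L, c("het", "hom_ref", "het")),     # discordant
    site(2L, c("het", "no_call", "het")),     # excluded
    site(3L, c("hom_alt", "het", "hom_ref")), # discordant
    site(4L, c("hom_ref", "hom_ref", "hom_ref"))))
  d <- discordance(calls, bins)
  low <- d$summary[d$summary$bin == "10-19x", ]
  expect_equal(low$discordant, 2L)
  expect_equal(low$positions_evaluated, 99L)  # 100 binned minus 1 no_call site
  expect_equal(low$rate, 2 / 99)
  expect_equal(sort(d$sites$pos), c(1L, 3L))
  expect_equal(d$summary$discordant[d$summary$bin != "10-19x"], c(0L, 0L))

  # all-identical calls give zero discordance everywhere
  ident <- genotype_table(rbind(site(0L, rep("het", 3)),
                                site(1L, rep("hom_alt", 3))))
  d0 <- discordance(ident, bins)
  expect_true(all(d0$summary$discordant == 0L))

  pooled <- combine_discordance(list(d, d0))
  expect_equal(pooled$summary$positions_evaluated,
               d$summary$positions_evaluated + d0$summary$positions_evaluated)
  expect_equal(pooled$summary$discordant, d$summary$discordant)
})

test_that("discordant sites classify against truth genotypes", {
  p <- sim_params(seed = 3, n_targets = 30L, het_density = 2)
  tt <- simulate_targets(p)
  ped <- default_pedigree()
  truth <- simulate_pedigree_truth(tt, ped, p)

  s1 <- truth$sites[1:2, ]
  g1 <- truth$genotypes[1:2, "F1"]
  sites <- data.frame(
    sample = c("F1", "F1", "F1"),
    chrom = c(s1$chrom, "chrZ"), pos = c(s1$pos, 99999L),
    genotypes = c(if (g1[1] == "het") "het,hom_ref,het" else "het,hom_ref,hom_ref",
                  "het,het,hom_alt", "het,hom_ref,het"),
    stringsAsFactors = FALSE)
  cl <- classify_discordances(sites, truth, evaluated_positions = 1e6)
  expect_equal(unname(cl$tallies[["unvalidated"]]), 1L)
  expect_equal(sum(cl$tallies[c("het", "hom_ref", "hom_alt")]), 2)
  # a truth-het with a non-het call is a missed het
  if (g1[1] == "het") expect_gte(cl$missed_het, 1L)
  expect_equal(cl$missed_het_rate, cl$missed_het / 1e6)
})

test_that("discordance is concentrated in, and decreases with, depth bins", {
  # low-depth regime chosen to make heterozygote dropout observable:
  # Poisson(13) depths put most positions in the 10-19x bin, where an
  # all-reference sampling of a het site yields a confident wrong call
  p <- sim_params(seed = 77, n_targets = 300L, target_length_mean = 200,
                  het_density = 20, de_novo_rate = 0, base_error_rate = 0.01,
                  per_target_sdlog = 0, target_failure_rate = 0,
                  efficiency_sdlog = 0, mean_depth = 13,
                  library_scale_range = c(1, 1), dispersion = Inf)
  tt <- simulate_targets(p)
  ped <- pedigree(data.frame(id = c("A", "B"), father = NA, mother = NA,
                             sex = 1:2))
  truth <- simulate_pedigree_truth(tt, ped, p)
  summaries <- lapply(c("A", "B"), function(id) {
    reps <- lapply(paste0("R", 1:3), function(r)
      simulate_replicate_depth(tt, p, r, sample_id = id))
    counts <- do.call(rbind, lapply(reps, function(pr)
      simulate_allele_counts(truth, pr, p)))
    calls <- call_genotype_table(counts, error_rate = 0.01,
                                 min_call_depth = p$min_call_depth,
                                 quality_threshold = p$call_quality_threshold)
    discordance(calls, bin_positions(reps))
  })
  pooled <- combine_discordance(summaries)
  occupied <- pooled$summary$positions_evaluated > 0
  rates <- pooled$summary$rate[occupied]
  expect_gt(sum(pooled$summary$discordant), 0)  # the regime produces events
  expect_true(all(diff(rates) <= 1e-12))        # non-increasing with depth
})
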