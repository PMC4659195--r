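# Shared fixture builders; everything is generated in code.

# small deterministic target space: n intervals of given width on chrT
toy_targets <- function(n = 5L, width = 20L, gap = 10L) {
  start <- (seq_len(n) - 1L) * (width + gap)
  target_regions(rep("chrT", n), start, start + width)
}

# depth profile with explicit depths (recycled) over toy targets
toy_profile <- function(depths, targets = toy_targets(),
                        sample_id = "S1", replicate_id = "R1") {
  depth_profile(targets, rep_len(depths, targets$total_bases),
                sample_id, replicate_id)
}

# coverage mask built directly from a logical vector
toy_mask <- function(bits, targets, t = 20L) {
  structure(list(threshold = as.integer(t), mask = as.logical(bits),
                 covered_count = sum(bits), targets = targets),
            class = "CoverageMask")
}

# independent 2x2 chi-square oracle for the two-proportion test
chisq_2x2_oracle <- function(x1, n1, x2, n2, continuity = TRUE) {
  obs <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  corr <- if (continuity) pmin(0.5, abs(obs - exp)) else 0
  stat <- sum((abs(obs - exp) - corr)^2 / exp)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# genotype table assembled from truth genotypes at uniform depth/quality,
# bypassing the caller (for de novo tests that need exact calls)
calls_from_truth <- function(truth, sample_ids, depth = 100L,
                             replicate = "aggregate", quality = 99) {
  rows <- do.call(rbind, lapply(sample_ids, function(id) {
    data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
               ref = truth$sites$ref, alt = truth$sites$alt,
               sample = id, replicate = replicate,
               genotype = truth$genotypes[, id],
               depth = depth, quality = quality,
               stringsAsFactors = FALSE)
  }))
  genotype_table(rows)
}
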