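#' Bayesian genotype call from biallelic allele counts
#'
#' Three-genotype binomial Bayes caller: the alternate-allele count given
#' depth is binomial with success probability eps (hom_ref), 1/2 (het) or
#' 1 - eps (hom_alt), where eps is the per-base miscall rate; posteriors
#' combine these likelihoods with the supplied prior.  The call is the
#' posterior mode and its quality is the log10 ratio of the best to the
#' second-best posterior.  Calls below the depth or quality floor are
#' reported as `no_call`.
#'
#' @param ref_count,alt_count non-negative integer vectors of Q20-quality
#'   reference and alternate read counts.
#' @param error_rate per-base miscall probability eps, in (0, 0.5).
#' @param priors genotype prior (hom_ref, het, hom_alt); normalized
#'   internally; default flat.
#' @param min_call_depth minimum depth for a confident call.
#' @param quality_threshold minimum quality for a confident call.
#' @return data.frame with `genotype`, `quality` (log10 posterior odds),
#'   `depth`, `ref_count`, `alt_count`; one row per input site.
#' @export
call_genotype <- function(ref_count, alt_count, error_rate = 0.01,
                          priors = c(1, 1, 1) / 3, min_call_depth = 10L,
                          quality_threshold = 2) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  if (length(priors) != 3L || any(priors <= 0))
    stop("priors must be 3 positive weights (hom_ref, het, hom_alt)")
  if (length(ref_count) != length(alt_count))
    stop("ref_count and alt_count must have equal length")
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("allele counts must be non-negative")
  priors <- priors / sum(priors)
  n <- length(alt_count)
  d <- ref_count + alt_count
  p_alt <- c(error_rate, 0.5, 1 - error_rate)
  ll <- matrix(0, nrow = n, ncol = 3L)
  for (j in 1:3)
    ll[, j] <- stats::dbinom(alt_count, d, p_alt[j], log = TRUE) + log(priors[j])
  best <- max.col(ll, ties.method = "first")
  best_ll <- ll[cbind(seq_len(n), best)]
  ll[cbind(seq_len(n), best)] <- -Inf
  second_ll <- ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
  quality <- (best_ll - second_ll) / log(10)
  genotype <- c("hom_ref", "het", "hom_alt")[best]
  genotype[d < min_call_depth | quality < quality_threshold] <- "no_call"
  data.frame(genotype = genotype, quality = pmax(quality, 0), depth = d,
             ref_count = ref_count, alt_count = alt_count,
             stringsAsFactors = FALSE)
}

#' Call genotypes for a whole allele-count table
#'
#' Vectorized [call_genotype()] over an allele-count table (as produced by
#' [simulate_allele_counts()] or [read_allele_counts()]).
#'
#' @param counts allele-count data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `replicate`, `ref_count`, `alt_count`.
#' @inheritParams call_genotype
#' @return a [genotype_table()].
#' @export
call_genotype_table <- function(counts, error_rate = 0.01,
                                priors = c(1, 1, 1) / 3, min_call_depth = 10L,
                                quality_threshold = 2) {
  calls <- call_genotype(counts$ref_count, counts$alt_count,
                         error_rate = error_rate, priors = priors,
                         min_call_depth = min_call_depth,
                         quality_threshold = quality_threshold)
  genotype_table(data.frame(chrom = counts$chrom, pos = counts$pos,
                            ref = counts$ref, alt = counts$alt,
                            sample = counts$sample,
                            replicate = counts$replicate,
                            genotype = calls$genotype,
                            depth = calls$depth, quality = calls$quality,
                            stringsAsFactors = FALSE))
}

DEPTH_BIN_LABELS <- c("10-19x", "20-29x", ">=30x")

#' Assign target positions to depth bins across replicates
#'
#' Each position's binning depth is the minimum (default) or mean depth
#' across the replicates; positions below the lowest break (10x) are
#' excluded (`NA`).  The minimum is the conservative statistic: every
#' replicate then meets the bin's depth floor.
#'
#' @param profiles list of >= 2 replicate [depth_profile()]s of one
#'   individual over the same targets.
#' @param breaks lower bin edges (default `c(10, 20, 30)` giving 10-19x,
#'   20-29x, >=30x).
#' @param stat `"min"` or `"mean"` binning depth across replicates.
#' @return a `DepthBins`: list with `targets`, `bin` (factor over the
#'   flattened target space, `NA` = excluded), and `counts` (positions per
#'   bin).
#' @export
bin_positions <- function(profiles, breaks = c(10L, 20L, 30L),
                          stat = c("min", "mean")) {
  stat <- match.arg(stat)
  if (length(profiles) < 2L)
    stop("binning requires at least 2 replicates")
  t0 <- profiles[[1L]]$targets
  if (!all(vapply(profiles, function(p) same_targets(p$targets, t0), logical(1))))
    stop("profiles are defined over different target spaces")
  depths <- lapply(profiles, `[[`, "depth")
  bd <- if (stat == "min") do.call(pmin, depths)
        else Reduce(`+`, depths) / length(depths)
  labels <- c(paste0(breaks[-length(breaks)], "-", breaks[-1L] - 1L, "x"),
              paste0(">=", breaks[length(breaks)], "x"))
  bin <- cut(bd, c(breaks, Inf), right = FALSE, labels = labels)
  structure(list(targets = t0, bin = bin, counts = table(bin)),
            class = "DepthBins")
}

#' Depth-binned genotype discordance between technical replicates
#'
#' A site is discordant when its (confident) genotype calls differ between
#' replicates of the same individual.  Sites where any replicate is
#' `no_call`, or where a replicate lacks a call, are excluded from both
#' numerator and denominator; all remaining binned positions count as
#' evaluated (positions absent from the call table carry identical implied
#' hom_ref calls in every replicate).
#'
#' @param calls a [genotype_table()] for one individual's replicates.
#' @param bins a [bin_positions()] object for the same individual.
#' @return a `DiscordanceSummary`: list with `sample_id`, `summary`
#'   (data.frame `bin`, `positions_evaluated`, `discordant`, `rate`) and
#'   `sites` (data.frame of discordant sites with the per-replicate
#'   genotype string).
#' @export
discordance <- function(calls, bins) {
  stopifnot(inherits(bins, "DepthBins"))
  sid <- unique(calls$sample)
  if (length(sid) != 1L)
    stop("discordance is per-individual; got samples: ",
         paste(sid, collapse = ", "))
  n_rep <- length(unique(calls$replicate))
  if (n_rep < 2L) stop("discordance requires >= 2 replicates")

  dt <- data.table::as.data.table(calls)
  data.table::setorder(dt, chrom, pos, replicate)
  site <- dt[, list(n = .N,
                    any_nocall = any(genotype == "no_call"),
                    discordant = data.table::uniqueN(genotype) > 1L,
                    genotypes = paste(genotype, collapse = ",")),
             by = c("chrom", "pos")]
  site$bin <- bins$bin[target_index(bins$targets, site$chrom, site$pos)]
  site$excluded <- site$any_nocall | site$n < n_rep

  labels <- levels(bins$bin)
  excl <- table(factor(site$bin[site$excluded], levels = labels))
  disc <- site[!site$excluded & site$discordant & !is.na(site$bin), ]
  disc_n <- table(factor(disc$bin, levels = labels))
  evaluated <- as.integer(bins$counts) - as.integer(excl)
  summary <- data.frame(bin = labels,
                        positions_evaluated = evaluated,
                        discordant = as.integer(disc_n),
                        rate = ifelse(evaluated > 0,
                                      as.integer(disc_n) / evaluated, NA_real_),
                        row.names = NULL)
  sites <- data.frame(sample = rep(sid, nrow(disc)),
                      chrom = disc$chrom, pos = disc$pos,
                      bin = as.character(disc$bin),
                      genotypes = disc$genotypes, stringsAsFactors = FALSE)
  structure(list(sample_id = sid, summary = summary, sites = sites),
            class = "DiscordanceSummary")
}

#' @export
print.DiscordanceSummary <- function(x, ...) {
  cat("Genotype discordance for", x$sample_id, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s %d discordant / %d evaluated (%.1f x 10^-6)\n",
                s$bin[i], s$discordant[i], s$positions_evaluated[i],
                1e6 * s$rate[i]))
  invisible(x)
}

#' Pool per-individual discordance summaries
#'
#' Sums evaluated and discordant counts across individuals (the study-wide
#' tally) and recomputes per-bin rates.
#'
#' @param summaries list of [discordance()] results.
#' @return a `DiscordanceSummary` with `sample_id = "all"`.
#' @export
combine_discordance <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  s0 <- summaries[[1L]]$summary
  evaluated <- Reduce(`+`, lapply(summaries, function(s) s$summary$positions_evaluated))
  disc <- Reduce(`+`, lapply(summaries, function(s) s$summary$discordant))
  sites <- do.call(rbind, lapply(summaries, `[[`, "sites"))
  structure(list(sample_id = "all",
                 summary = data.frame(bin = s0$bin,
                                      positions_evaluated = evaluated,
                                      discordant = disc,
                                      rate = ifelse(evaluated > 0,
                                                    disc / evaluated, NA_real_),
                                      row.names = NULL),
                 sites = sites),
            class = "DiscordanceSummary")
}

#' Classify discordant sites against truth genotypes
#'
#' Labels each discordant site by its ground-truth genotype (the synthetic
#' stand-in for orthogonal validation sequencing) and derives the
#' missed-heterozygote and false-heterozygote event counts.
#'
#' @param sites discordant-site data.frame from [discordance()] /
#'   [combine_discordance()] (columns `sample`, `chrom`, `pos`,
#'   `genotypes`).
#' @param truth a `TruthSet` from [simulate_pedigree_truth()].
#' @param evaluated_positions denominator for the missed-het rate (total
#'   positions evaluated in the bins contributing discordant sites);
#'   `NULL` leaves the rate `NA`.
#' @return list with `tallies` (counts by truth genotype, plus
#'   `unvalidated` for sites absent from truth), `percentages` (of
#'   validated sites), `missed_het`, `false_het`, and `missed_het_rate`.
#' @export
classify_discordances <- function(sites, truth, evaluated_positions = NULL) {
  stopifnot(inherits(truth, "TruthSet"))
  key_truth <- paste(truth$sites$chrom, truth$sites$pos)
  i <- match(paste(sites$chrom, sites$pos), key_truth)
  truth_gt <- rep(NA_character_, nrow(sites))
  found <- !is.na(i)
  if (any(found))
    truth_gt[found] <- truth$genotypes[cbind(i[found],
                                             match(sites$sample[found],
                                                   colnames(truth$genotypes)))]
  calls <- strsplit(sites$genotypes, ",", fixed = TRUE)
  missed_het <- sum(truth_gt == "het" &
                    vapply(calls, function(g) any(g != "het"), logical(1)),
                    na.rm = TRUE)
  false_het <- sum(truth_gt %in% c("hom_ref", "hom_alt") &
                   vapply(calls, function(g) any(g == "het"), logical(1)))
  tallies <- c(table(factor(truth_gt, levels = c("het", "hom_ref", "hom_alt"))),
               unvalidated = sum(!found))
  validated <- sum(tallies[c("het", "hom_ref", "hom_alt")])
  percentages <- if (validated > 0)
    round(100 * tallies[c("het", "hom_ref", "hom_alt")] / validated)
  else tallies[c("het", "hom_ref", "hom_alt")] * NA_real_
  list(tallies = tallies, percentages = percentages,
       missed_het = missed_het, false_het = false_het,
       missed_het_rate = if (is.null(evaluated_positions)) NA_real_
                         else missed_het / evaluated_positions)
}
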