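#' Intersection-union analysis of three replicate coverage masks
#'
#' Classifies every target base by its membership triple across the three
#' replicates' coverage masks in one pass, so the seven Venn region counts
#' sum to the union by construction.  The "variable" bases -- covered in at
#' least one but not all three replicates -- quantify the stochastic
#' component of capture.
#'
#' @param masks list of exactly 3 [coverage_mask()] objects at the same
#'   threshold over the same target space.
#' @return an `IUTResult`: list with `threshold`, `total_bases`, `venn`
#'   (named counts of the 7 non-empty regions, names like `"R1"`, `"R1R2"`,
#'   `"R1R2R3"`), `intersection`, `union`, `variable`, and `fractions`
#'   (percent of total bases: `intersection`, `variable`, `uncovered`).
#' @export
iut <- function(masks) {
  if (length(masks) != 3L || !all(vapply(masks, inherits, logical(1), "CoverageMask")))
    stop("iut requires a list of exactly 3 CoverageMask objects")
  t <- unique(vapply(masks, `[[`, integer(1), "threshold"))
  if (length(t) != 1L)
    stop("masks have mismatched thresholds: ", paste(t, collapse = ", "))
  t0 <- masks[[1L]]$targets
  if (!all(vapply(masks, function(m) same_targets(m$targets, t0), logical(1))))
    stop("masks are defined over different target spaces")
  code <- masks[[1L]]$mask + 2L * masks[[2L]]$mask + 4L * masks[[3L]]$mask
  venn <- tabulate(code[code > 0L], nbins = 7L)
  names(venn) <- c("R1", "R2", "R1R2", "R3", "R1R3", "R2R3", "R1R2R3")
  N <- t0$total_bases
  U <- sum(venn)
  I <- venn[["R1R2R3"]]
  structure(c(list(threshold = t, total_bases = N, venn = venn,
                   intersection = I, union = U, variable = U - I),
              list(fractions = iut_fractions(I, U, N))),
            class = "IUTResult")
}

#' IUT fractions from intersection/union counts
#'
#' Computes the headline intersection-union percentages from base counts --
#' useful for re-deriving published figures from their printed counts as
#' well as inside [iut()].
#'
#' @param intersection bases covered in all three replicates.
#' @param union bases covered in at least one replicate.
#' @param total total targeted bases (the denominator).
#' @return named numeric vector (percent): `intersection`, `variable`
#'   (union minus intersection), `uncovered` (off the union).
#' @export
iut_fractions <- function(intersection, union, total) {
  if (intersection > union || union > total)
    stop("need intersection <= union <= total")
  c(intersection = 100 * intersection / total,
    variable = 100 * (union - intersection) / total,
    uncovered = 100 * (total - union) / total)
}

#' @export
print.IUTResult <- function(x, ...) {
  cat(sprintf("IUT at >=%dx over %d bases\n", x$threshold, x$total_bases))
  cat(sprintf("  intersection %d (%.1f%%), variable %d (%.1f%%), uncovered %d (%.1f%%)\n",
              x$intersection, x$fractions[["intersection"]],
              x$variable, x$fractions[["variable"]],
              x$total_bases - x$union, x$fractions[["uncovered"]]))
  invisible(x)
}

#' Two independent proportion test
#'
#' Chi-square test that two binomial proportions are equal (the classic
#' 2x2 test of `prop.test`), optionally with Yates continuity correction;
#' two-sided p-value.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param continuity apply Yates continuity correction (default `TRUE`,
#'   matching `prop.test`).
#' @return a `ProportionTestResult`: list with the counts, `statistic`
#'   (chi-square), `p_value`, `estimate` (the two proportions) and
#'   `continuity`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("need 0 <= x <= n in both groups")
  pt <- suppressWarnings(
    stats::prop.test(x = c(x1, x2), n = c(n1, n2), correct = continuity))
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                 statistic = unname(pt$statistic),
                 p_value = pt$p.value,
                 estimate = unname(pt$estimate),
                 continuity = continuity),
            class = "ProportionTestResult")
}

#' @export
print.ProportionTestResult <- function(x, ...) {
  cat(sprintf("two-proportion test: %d/%d vs %d/%d, X2 = %.4g, p = %.2g%s\n",
              x$x1, x$n1, x$x2, x$n2, x$statistic, x$p_value,
              if (x$continuity) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Aggregate technical replicates into one depth profile
#'
#' Per-base sum of the replicate depths -- the in-silico equivalent of
#' merging the replicate alignments of one individual.
#'
#' @param profiles list of [depth_profile()] objects from the same sample
#'   over the same target space.
#' @return a [depth_profile()] with `replicate_id = "aggregate"`.
#' @export
aggregate_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  sid <- unique(vapply(profiles, `[[`, character(1), "sample_id"))
  if (length(sid) != 1L)
    stop("cannot aggregate profiles from mixed samples: ",
         paste(sid, collapse = ", "))
  t0 <- profiles[[1L]]$targets
  if (!all(vapply(profiles, function(p) same_targets(p$targets, t0), logical(1))))
    stop("profiles are defined over different target spaces")
  depth <- Reduce(`+`, lapply(profiles, `[[`, "depth"))
  depth_profile(t0, depth, sid, "aggregate")
}

#' Bases recovered by aggregation
#'
#' A base is "recovered" when the aggregate reaches the threshold but the
#' three replicates do not all reach it, i.e. aggregate-covered bases
#' outside the replicate intersection.  With `baseline = "union"` the
#' comparison set is the replicate union instead.
#'
#' @param aggregate_mask [coverage_mask()] of the aggregate profile.
#' @param replicate_masks list of 3 replicate [coverage_mask()]s at the
#'   same threshold.
#' @param baseline `"intersection"` (default) or `"union"`.
#' @return a `CoverageMask` whose `mask` flags the recovered bases.
#' @export
recovered_mask <- function(aggregate_mask, replicate_masks,
                           baseline = c("intersection", "union")) {
  baseline <- match.arg(baseline)
  all_masks <- c(list(aggregate_mask), replicate_masks)
  t <- unique(vapply(all_masks, `[[`, integer(1), "threshold"))
  if (length(t) != 1L)
    stop("threshold mismatch between aggregate and replicate masks")
  t0 <- aggregate_mask$targets
  if (!all(vapply(all_masks, function(m) same_targets(m$targets, t0), logical(1))))
    stop("masks are defined over different target spaces")
  op <- if (baseline == "intersection") `&` else `|`
  base <- Reduce(op, lapply(replicate_masks, `[[`, "mask"))
  m <- aggregate_mask$mask & !base
  structure(list(threshold = t, mask = m, covered_count = sum(m),
                 targets = t0),
            class = "CoverageMask")
}

#' Maximal covered segments of a mask
#'
#' Extracts the maximal runs of consecutive `TRUE` bases; runs never span
#' the gap between two target intervals, so each segment lies inside a
#' single interval.
#'
#' @param mask a [coverage_mask()] (or any object with `mask` and
#'   `targets`).
#' @return a `SegmentSet`: list with `segments` (data.frame `chrom`,
#'   `start`, `end` 0-based half-open, `length`), `n_segments` and
#'   `total_bases`.
#' @export
segments_from_mask <- function(mask) {
  m <- mask$mask
  targets <- mask$targets
  reg <- targets$regions
  N <- length(m)
  if (!any(m)) {
    seg <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer())
    return(structure(list(segments = seg, n_segments = 0L, total_bases = 0L),
                     class = "SegmentSet"))
  }
  region_id <- rep.int(seq_len(nrow(reg)), reg$width)
  brk <- region_id[-N] != region_id[-1L]          # boundary after base i
  run_start <- m & c(TRUE, !m[-N] | brk)
  run_end <- m & c(!m[-1L] | brk, TRUE)
  s <- which(run_start)
  e <- which(run_end)
  r <- findInterval(s - 1L, reg$offset)
  seg <- data.frame(chrom = reg$chrom[r],
                    start = reg$start[r] + (s - 1L - reg$offset[r]),
                    end = reg$start[r] + (e - 1L - reg$offset[r]) + 1L,
                    stringsAsFactors = FALSE)
  seg$length <- seg$end - seg$start
  structure(list(segments = seg, n_segments = nrow(seg),
                 total_bases = sum(seg$length)),
            class = "SegmentSet")
}

#' @export
print.SegmentSet <- function(x, ...) {
  cat(sprintf("SegmentSet: %d segments, %d bases, mean length %.1f\n",
              x$n_segments, x$total_bases,
              if (x$n_segments) x$total_bases / x$n_segments else NA_real_))
  invisible(x)
}

#' Segment length-frequency distribution and log-log power-law fit
#'
#' Tallies segment lengths and fits an ordinary least-squares line to
#' (log length, log frequency) over lengths with nonzero frequency -- the
#' standard descriptive check that recovered-segment sizes follow a
#' power law.
#'
#' @param x a `SegmentSet` or a numeric vector of segment lengths.
#' @return a `PowerLawSummary`: list with `freq` (data.frame `length`,
#'   `count`), `mean_length`, `n_singletons` (count at length 1), `slope`,
#'   `r_squared` (both `NA` with fewer than 2 distinct lengths).
#' @export
segment_length_distribution <- function(x) {
  lengths <- if (inherits(x, "SegmentSet")) x$segments$length else as.numeric(x)
  if (!length(lengths))
    return(structure(list(freq = data.frame(length = integer(), count = integer()),
                          mean_length = NA_real_, n_singletons = 0L,
                          slope = NA_real_, r_squared = NA_real_),
                     class = "PowerLawSummary"))
  tab <- table(lengths)
  freq <- data.frame(length = as.numeric(names(tab)), count = as.integer(tab))
  slope <- r2 <- NA_real_
  if (nrow(freq) >= 2L) {
    fit <- stats::lm(log(count) ~ log(length), data = freq)
    slope <- unname(stats::coef(fit)[2L])
    # exact power-law inputs produce a perfect fit; that is fine here
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  ones <- freq$count[freq$length == 1]
  structure(list(freq = freq, mean_length = mean(lengths),
                 n_singletons = if (length(ones)) ones else 0L,
                 slope = slope, r_squared = r2),
            class = "PowerLawSummary")
}

#' @export
print.PowerLawSummary <- function(x, ...) {
  cat(sprintf("segment lengths: mean %.1f, %d singleton(s), log-log slope %.3f (r2 %.3f)\n",
              x$mean_length, x$n_singletons, x$slope, x$r_squared))
  invisible(x)
}

#' Intersect long recovered segments with coding exons
#'
#' Keeps segments strictly longer than `min_len`, then overlaps them with
#' the (merged) exon intervals.  A segment counts once if it overlaps at
#' least one exon base; the base tally sums each segment's exon overlap.
#'
#' @param segments a `SegmentSet`.
#' @param exons a [target_regions()] object of coding exons.
#' @param min_len length cutoff; only segments with `length > min_len` are
#'   considered (default 50).
#' @return list with `n_overlapping_segments` and `overlapped_coding_bases`.
#' @export
intersect_segments_exons <- function(segments, exons, min_len = 50L) {
  stopifnot(inherits(segments, "SegmentSet"), inherits(exons, "TargetRegions"))
  seg <- segments$segments[segments$segments$length > min_len, , drop = FALSE]
  n_overlapping <- 0L
  bases <- 0L
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    e <- exons$regions[exons$regions$chrom == ch, , drop = FALSE]
    if (!nrow(e)) next
    ir_s <- IRanges::IRanges(s$start + 1L, s$end)
    ir_e <- IRanges::IRanges(e$start + 1L, e$end)
    ov <- IRanges::findOverlaps(ir_s, ir_e)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- pmin(IRanges::end(ir_s)[qh], IRanges::end(ir_e)[sh]) -
         pmax(IRanges::start(ir_s)[qh], IRanges::start(ir_e)[sh]) + 1L
    n_overlapping <- n_overlapping + length(unique(qh))
    bases <- bases + sum(w)
  }
  list(n_overlapping_segments = n_overlapping,
       overlapped_coding_bases = bases)
}
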