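#' Mean per-base depth over the target space
#'
#' @param profile a [depth_profile()] object.
#' @return mean depth in x units (total aligned target bases / target size).
#' @export
mean_target_depth <- function(profile) {
  stopifnot(inherits(profile, "DepthProfile"))
  if (profile$targets$total_bases == 0L) stop("empty target space")
  sum(as.numeric(profile$depth)) / profile$targets$total_bases
}

#' Coverage mask at a depth threshold
#'
#' A target base is covered at threshold `t` when its depth is `>= t`
#' (inclusive boundary).
#'
#' @param profile a [depth_profile()] object.
#' @param t integer threshold >= 1.
#' @return a `CoverageMask`: list with `threshold`, logical `mask` in
#'   flattened target order, `covered_count` and `targets`.
#' @export
coverage_mask <- function(profile, t) {
  stopifnot(inherits(profile, "DepthProfile"))
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("threshold must be an integer >= 1")
  m <- profile$depth >= t
  structure(list(threshold = t, mask = m, covered_count = sum(m),
                 targets = profile$targets),
            class = "CoverageMask")
}

#' @export
print.CoverageMask <- function(x, ...) {
  cat(sprintf("CoverageMask >=%dx: %d / %d bases (%.1f%%)\n", x$threshold,
              x$covered_count, x$targets$total_bases,
              100 * x$covered_count / x$targets$total_bases))
  invisible(x)
}

#' Percent of target bases covered at each threshold
#'
#' @param profile a [depth_profile()] object.
#' @param thresholds integer vector of depth thresholds (>= 1).
#' @return named numeric vector of percentages (full precision; report
#'   renderers round to one decimal).
#' @export
percent_target_at <- function(profile, thresholds = c(1L, 10L, 20L)) {
  stopifnot(all(thresholds >= 1))
  out <- vapply(thresholds,
                function(t) 100 * mean(profile$depth >= t), numeric(1))
  names(out) <- paste0(">=", thresholds, "x")
  out
}

#' Replicate-group coverage summary
#'
#' Per-replicate mean target depth and percent-covered at each threshold,
#' with the across-replicate mean and sample standard deviation (n - 1
#' denominator) of the percentages, rounded to one decimal.
#'
#' @param profiles list of >= 2 [depth_profile()] objects over the same
#'   targets (the technical replicates of one individual).
#' @param thresholds integer vector of depth thresholds.
#' @return a `CoverageSummary`: list with `sample_id`, `per_replicate`
#'   (data.frame of mean depth and unrounded percentages) and `summary`
#'   (data.frame `threshold`, `mean_pct`, `sd_pct`).
#' @export
replicate_summary <- function(profiles, thresholds = c(1L, 10L, 20L)) {
  if (length(profiles) < 2L)
    stop("dispersion undefined with fewer than 2 replicates")
  t0 <- profiles[[1L]]$targets
  if (!all(vapply(profiles, function(p) same_targets(p$targets, t0), logical(1))))
    stop("replicate profiles are defined over different target spaces")
  pct <- t(vapply(profiles, percent_target_at, numeric(length(thresholds)),
                  thresholds = thresholds))
  per_rep <- data.frame(
    replicate = vapply(profiles, `[[`, character(1), "replicate_id"),
    mean_depth = vapply(profiles, mean_target_depth, numeric(1)))
  per_rep <- cbind(per_rep, as.data.frame(pct))
  structure(list(sample_id = profiles[[1L]]$sample_id,
                 per_replicate = per_rep,
                 summary = summarize_percentages(pct, thresholds)),
            class = "CoverageSummary")
}

#' Across-replicate mean and SD of coverage percentages
#'
#' The dispersion is the sample standard deviation of the replicate
#' percentages (n - 1 denominator); published per-threshold "mean +/- SE"
#' tables of three replicates print this quantity.
#'
#' @param pct matrix of percentages, replicates in rows, thresholds in
#'   columns.
#' @param thresholds optional threshold labels.
#' @return data.frame `threshold`, `mean_pct`, `sd_pct` (one decimal).
#' @export
summarize_percentages <- function(pct, thresholds = NULL) {
  pct <- as.matrix(pct)
  if (nrow(pct) < 2L)
    stop("dispersion undefined with fewer than 2 replicates")
  if (is.null(thresholds))
    thresholds <- if (!is.null(colnames(pct))) colnames(pct)
                  else seq_len(ncol(pct))
  data.frame(threshold = as.character(thresholds),
             mean_pct = round(colMeans(pct), 1),
             sd_pct = round(apply(pct, 2L, stats::sd), 1),
             row.names = NULL)
}

#' @export
print.CoverageSummary <- function(x, ...) {
  cat("CoverageSummary for", x$sample_id, "\n")
  print(x$per_replicate, digits = 4)
  with(x$summary,
       cat(paste(sprintf("  %s: %.1f +/- %.1f", threshold, mean_pct, sd_pct),
                 collapse = "\n"), "\n"))
  invisible(x)
}

#' Normalized per-base depth histogram
#'
#' @param profile a [depth_profile()] object.
#' @param binwidth width of depth bins (default 1 = one bin per depth value).
#' @return data.frame `depth` (bin lower edge), `count`, `density`; the
#'   densities sum to 1; empty bins are dropped.
#' @export
depth_density <- function(profile, binwidth = 1L) {
  stopifnot(inherits(profile, "DepthProfile"), binwidth >= 1L)
  bin <- (profile$depth %/% binwidth) * binwidth
  tab <- table(bin)
  data.frame(depth = as.integer(names(tab)),
             count = as.integer(tab),
             density = as.integer(tab) / length(profile$depth),
             row.names = NULL)
}

#' Loess saturation trend of coverage versus input data
#'
#' Fits the locally weighted polynomial regression (degree 2, default span
#' 0.75) used to describe percent-target-covered as a function of total
#' aligned bases, with a pointwise 95% confidence band.
#'
#' @param x predictor (total bases aligned to target, e.g. in Gb).
#' @param y response (percent target covered at a threshold).
#' @param span loess span alpha controlling the regression neighbourhood.
#' @return a `LoessFit`: list with `x`, `y`, `fitted`, `lower`, `upper`,
#'   `span`, `smoother` (description of the smoother family) and `model`
#'   (the underlying [stats::loess()] fit).
#' @export
loess_trend <- function(x, y, span = 0.75) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("loess trend needs at least 4 points")
  fit <- tryCatch(
    stats::loess(y ~ x, span = span, degree = 2,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) stop("loess fit failed: ", conditionMessage(e)))
  pr <- stats::predict(fit, se = TRUE)
  tcrit <- stats::qt(0.975, pr$df)
  structure(list(x = x, y = y, fitted = as.numeric(pr$fit),
                 lower = as.numeric(pr$fit - tcrit * pr$se.fit),
                 upper = as.numeric(pr$fit + tcrit * pr$se.fit),
                 span = span,
                 smoother = "loess (local quadratic, gaussian family)",
                 model = fit),
            class = "LoessFit")
}
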