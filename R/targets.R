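#' Build a merged, sorted set of target regions
#'
#' Constructs the target space over which all per-base coverage analysis is
#' defined.  Intervals use 0-based half-open coordinates (BED convention).
#' Overlapping or book-ended intervals are merged -- capture kits ship
#' overlapping probes, so overlap is expected input, not an error.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open interval bounds.
#' @return A `TargetRegions` object: a list with `regions` (data.frame of
#'   `chrom`, `start`, `end`, `width`, `offset`, sorted by chromosome then
#'   start, non-overlapping) and `total_bases` (sum of widths).  `offset` is
#'   the cumulative number of bases preceding each interval in the flattened
#'   target space; every per-base vector in the package (depths, masks) is
#'   addressed in that flattened order.
#' @examples
#' tr <- target_regions(c("chr1", "chr1"), c(0L, 50L), c(100L, 150L))
#' tr$total_bases  # 150: the two overlapping intervals merge
#' @export
target_regions <- function(chrom, start, end) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (length(chrom) == 0L)
    stop("at least one interval is required")
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end))
    stop("interval bounds must be integers")
  if (any(start < 0L))
    stop("negative interval start")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) at input row ", bad[1L])

  pieces <- lapply(split(seq_along(chrom), chrom), function(i) {
    r <- IRanges::reduce(IRanges::IRanges(start = start[i] + 1L, end = end[i]))
    data.frame(chrom = chrom[i[1L]],
               start = IRanges::start(r) - 1L,
               end   = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, pieces[order(names(pieces))])
  rownames(regions) <- NULL
  regions$width <- regions$end - regions$start
  regions$offset <- cumsum(c(0L, regions$width[-nrow(regions)]))
  structure(list(regions = regions, total_bases = sum(regions$width)),
            class = "TargetRegions")
}

#' @export
print.TargetRegions <- function(x, ...) {
  cat("TargetRegions:", nrow(x$regions), "intervals on",
      length(unique(x$regions$chrom)), "chromosome(s),",
      x$total_bases, "bases\n")
  invisible(x)
}

#' Test whether two target spaces are identical
#' @noRd
same_targets <- function(a, b) {
  a$total_bases == b$total_bases &&
    nrow(a$regions) == nrow(b$regions) &&
    all(a$regions$chrom == b$regions$chrom) &&
    all(a$regions$start == b$regions$start) &&
    all(a$regions$end == b$regions$end)
}

#' Flat index of genomic positions within the target space
#'
#' Maps `(chrom, pos)` pairs (0-based) to 1-based indices into the flattened
#' per-base vector over the targets; positions outside every interval map to
#' `NA`.
#'
#' @param targets a [target_regions()] object.
#' @param chrom,pos vectors of equal length.
#' @return integer vector of indices (NA where off-target).
#' @export
target_index <- function(targets, chrom, pos) {
  reg <- targets$regions
  pos <- as.integer(pos)
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    q <- which(chrom == ch)
    r <- which(reg$chrom == ch)
    if (!length(r)) next
    j <- findInterval(pos[q], reg$start[r])
    ok <- j >= 1L
    ok[ok] <- pos[q][ok] < reg$end[r][j[ok]]
    jj <- r[j[ok]]
    idx[q[ok]] <- reg$offset[jj] + (pos[q][ok] - reg$start[jj]) + 1L
  }
  idx
}

#' Genomic coordinates of flat target-space indices
#'
#' Inverse of [target_index()].
#'
#' @param targets a [target_regions()] object.
#' @param idx 1-based flat indices.
#' @return data.frame with `chrom` and 0-based `pos`.
#' @export
target_coords <- function(targets, idx) {
  reg <- targets$regions
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > targets$total_bases))
    stop("flat index out of range")
  r <- findInterval(idx - 1L, reg$offset)
  data.frame(chrom = reg$chrom[r],
             pos = reg$start[r] + (idx - 1L - reg$offset[r]),
             stringsAsFactors = FALSE)
}

#' Enumerate every base of the target space
#'
#' @param targets a [target_regions()] object.
#' @return data.frame with one row per target base (`chrom`, 0-based `pos`),
#'   in flattened order.
#' @export
target_positions <- function(targets) {
  reg <- targets$regions
  data.frame(chrom = rep(reg$chrom, reg$width),
             pos = sequence(reg$width, from = reg$start),
             stringsAsFactors = FALSE)
}

#' Read a BED file of target (or exon) intervals
#'
#' Reads a 3+ column BED file (0-based half-open), merges overlapping and
#' book-ended intervals, and returns the resulting target space.  Lines
#' starting with `#`, `track` or `browser` are ignored.
#'
#' @param path path to a BED file.
#' @return a [target_regions()] object.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  ln <- which(keep)
  if (!length(ln))
    stop("no intervals found in BED file: ", path)
  fields <- strsplit(lines[ln], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", ln[which(nf < 3L)[1L]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", ln[bad[1L]], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) on BED line ", ln[bad[1L]])
  target_regions(chrom, start, end)
}

#' Write intervals to a BED file
#'
#' @param x a `TargetRegions` or `SegmentSet` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- if (inherits(x, "TargetRegions")) x$regions else x$segments
  data.table::fwrite(df[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}
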