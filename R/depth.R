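#' Per-base depth profile over the target space
#'
#' A `DepthProfile` holds the Q20-filtered per-base sequencing depth of one
#' technical replicate (or of the aggregate of several) at every base of the
#' target space, stored as a dense integer vector in flattened target order.
#'
#' @param targets a [target_regions()] object.
#' @param depth integer vector of length `targets$total_bases`, depths >= 0.
#' @param sample_id individual identifier.
#' @param replicate_id replicate label (e.g. `"R1"`), or `"aggregate"`.
#' @return a `DepthProfile` object.
#' @export
depth_profile <- function(targets, depth, sample_id, replicate_id) {
  stopifnot(inherits(targets, "TargetRegions"))
  depth <- as.integer(round(depth))
  if (length(depth) != targets$total_bases)
    stop("depth vector length (", length(depth),
         ") does not match target space (", targets$total_bases, " bases)")
  if (anyNA(depth) || any(depth < 0L))
    stop("depths must be non-negative integers")
  structure(list(sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id),
                 targets = targets,
                 depth = depth),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile %s/%s: %d bases, mean depth %.1fx\n",
              x$sample_id, x$replicate_id, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Read a samtools-depth-style table into a depth profile
#'
#' The file is a headerless TSV of `chrom`, 1-based `position`, integer
#' `depth` (the format `samtools depth` emits).  Positions are converted to
#' the package's 0-based convention; target bases absent from the file get
#' depth 0.
#'
#' @param path path to the TSV.
#' @param targets a [target_regions()] object the profile is defined over.
#' @param sample_id,replicate_id labels recorded on the profile.
#' @param strict if `TRUE`, a position outside the targets is an error;
#'   otherwise it is dropped with a warning.
#' @return a [depth_profile()] object.
#' @export
read_depth_table <- function(path, targets, sample_id = "sample",
                             replicate_id = "R1", strict = FALSE) {
  depth <- integer(targets$total_bases)
  if (file.info(path)$size > 0) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "pos", "depth"),
                            colClasses = list(character = 1))
    if (anyNA(dt$depth) || any(dt$depth < 0))
      stop("negative or missing depth value in ", path)
    idx <- target_index(targets, dt$chrom, dt$pos - 1L)
    if (anyNA(idx)) {
      msg <- sprintf("%d position(s) in %s fall outside the target regions",
                     sum(is.na(idx)), path)
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
      dt <- dt[!is.na(idx)]
      idx <- idx[!is.na(idx)]
    }
    depth[idx] <- as.integer(dt$depth)
  }
  depth_profile(targets, depth, sample_id, replicate_id)
}

#' Write a depth profile as a samtools-depth-style table
#'
#' Emits every target base (zeros included, 1-based positions) so that files
#' written from the same target space are row-aligned and directly
#' comparable.
#'
#' @param profile a [depth_profile()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path) {
  coords <- target_positions(profile$targets)
  data.table::fwrite(
    data.table::data.table(chrom = coords$chrom,
                           pos = coords$pos + 1L,
                           depth = profile$depth),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}
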