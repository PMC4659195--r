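GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "no_call")

#' Validate a per-site, per-sample-replicate genotype table
#'
#' The table is the package's VCF-lite container: one row per
#' (site, sample, replicate) with columns `chrom`, `pos` (0-based), `ref`,
#' `alt`, `sample`, `replicate`, `genotype` (one of `hom_ref`, `het`,
#' `hom_alt`, `no_call`), `depth` and `quality`.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame with class `GenotypeTable`.
#' @export
genotype_table <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "sample", "replicate",
           "genotype", "depth", "quality")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- !(df$genotype %in% GENOTYPE_LEVELS)
  if (any(bad))
    stop("unknown genotype token '", df$genotype[bad][1L], "'")
  if (any(df$depth < 0) || any(df$quality < 0))
    stop("depth and quality must be non-negative")
  key <- paste(df$chrom, df$pos, df$sample, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (site, sample, replicate) row: ", key[duplicated(key)][1L])
  df <- as.data.frame(df)[, req]
  class(df) <- c("GenotypeTable", "data.frame")
  df
}

gt_header <- "#chrom\tpos\tref\talt\tsample\treplicate\tgenotype\tdepth\tquality"

#' Read a VCF-lite genotype table
#'
#' Tab-separated with header line
#' `#chrom pos ref alt sample replicate genotype depth quality`;
#' positions are 1-based on disk and converted to 0-based internally.
#'
#' @param path path to the file.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#chrom"))
    stop("not a genotype table (missing '#chrom' header): ", path)
  cols <- c("chrom", "pos", "ref", "alt", "sample", "replicate",
            "genotype", "depth", "quality")
  n_lines <- length(readLines(path))
  if (n_lines < 2L) {
    df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), sample = character(),
                     replicate = character(), genotype = character(),
                     depth = integer(), quality = numeric())
    return(genotype_table(df))
  }
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t",
                          col.names = cols, colClasses = list(character = 1))
  dt$pos <- as.integer(dt$pos) - 1L
  genotype_table(as.data.frame(dt))
}

#' Write a VCF-lite genotype table
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  table <- genotype_table(table)
  out <- as.data.frame(table)
  out$pos <- out$pos + 1L
  writeLines(gt_header, path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

counts_header <- "#chrom\tpos\tref\talt\tsample\treplicate\tref_count\talt_count\tdepth"

#' Read / write per-site allele-count tables
#'
#' Same layout as the genotype table but with `ref_count`, `alt_count`,
#' `depth` in place of the call columns.  These are the Q20-equivalent
#' pileup counts the genotype caller consumes.
#'
#' @param path path to the file.
#' @return data.frame with 0-based `pos`.
#' @export
read_allele_counts <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#chrom"))
    stop("not an allele-count table (missing '#chrom' header): ", path)
  cols <- c("chrom", "pos", "ref", "alt", "sample", "replicate",
            "ref_count", "alt_count", "depth")
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t",
                          col.names = cols, colClasses = list(character = 1))
  dt$pos <- as.integer(dt$pos) - 1L
  if (any(dt$ref_count < 0) || any(dt$alt_count < 0))
    stop("negative allele count in ", path)
  if (any(dt$ref_count + dt$alt_count > dt$depth))
    stop("ref_count + alt_count exceeds depth in ", path)
  as.data.frame(dt)
}

#' @param counts data.frame as returned by [read_allele_counts()] or
#'   [simulate_allele_counts()].
#' @rdname read_allele_counts
#' @export
write_allele_counts <- function(counts, path) {
  out <- as.data.frame(counts)[, c("chrom", "pos", "ref", "alt", "sample",
                                   "replicate", "ref_count", "alt_count",
                                   "depth")]
  out$pos <- out$pos + 1L
  writeLines(counts_header, path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
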