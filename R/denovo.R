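# Precomputed Mendelian consistency over ordered (child, father, mother)
# genotype triples, built by allele-transmission enumeration at load time.
.genotype_alleles <- list(hom_ref = c(0L, 0L), het = c(0L, 1L),
                          hom_alt = c(1L, 1L))
.mendel_ok <- local({
  gts <- names(.genotype_alleles)
  arr <- array(FALSE, dim = c(3L, 3L, 3L), dimnames = list(gts, gts, gts))
  for (child in gts) for (father in gts) for (mother in gts) {
    ca <- sort(.genotype_alleles[[child]])
    ok <- FALSE
    for (fa in .genotype_alleles[[father]])
      for (ma in .genotype_alleles[[mother]])
        if (identical(sort(c(fa, ma)), ca)) ok <- TRUE
    arr[child, father, mother] <- ok
  }
  arr
})

#' Mendelian consistency of a biallelic genotype triple
#'
#' `TRUE` when the child genotype can be assembled from one allele of each
#' parent.  Vectorized; all inputs must be confident genotypes
#' (`hom_ref`, `het`, `hom_alt`) -- filter `no_call`s first.
#'
#' @param child,father,mother character vectors of genotypes.
#' @return logical vector.
#' @examples
#' mendelian_consistent("het", "hom_ref", "hom_ref")  # FALSE: DNM candidate
#' @export
mendelian_consistent <- function(child, father, mother) {
  gts <- names(.genotype_alleles)
  if (!all(c(child, father, mother) %in% gts))
    stop("genotypes must be one of ", paste(gts, collapse = ", "),
         " (no_call must be filtered before the Mendelian check)")
  .mendel_ok[cbind(child, father, mother)]
}

#' Enumerate trios of a pedigree
#'
#' One trio per child whose father and mother are both present, in
#' deterministic (child-id) order.
#'
#' @param ped a [pedigree()] object.
#' @return data.frame `child`, `father`, `mother`.
#' @export
enumerate_trios <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  ped$trios
}

#' Detect de novo mutation candidates in one trio
#'
#' Flags sites where all three trio members have confident genotype calls
#' at depth `>= min_depth` (in the chosen replicate or aggregate data) and
#' the genotype triple violates Mendelian inheritance.
#'
#' @param calls a [genotype_table()] containing the three trio members.
#' @param trio one-row data.frame (or list) with `child`, `father`,
#'   `mother`.
#' @param min_depth depth floor applied to all three members.
#' @param mode replicate id to use (e.g. `"R1"`) or `"aggregate"`.
#' @return data.frame of DNM candidates (`chrom`, `pos`, member genotypes
#'   and depths, `min_member_depth`, `depth_bin`, `mode`), with attributes
#'   `n_unevaluable` (sites failing the depth/confidence filter in >= 1
#'   member) and `n_tested`.
#' @export
detect_dnm <- function(calls, trio, min_depth = 10L,
                       mode = "aggregate") {
  members <- c(child = trio$child[[1L]], father = trio$father[[1L]],
               mother = trio$mother[[1L]])
  dt <- calls[calls$replicate == mode & calls$sample %in% members, ,
              drop = FALSE]
  for (m in members)
    if (!any(dt$sample == m))
      stop("no '", mode, "' genotype calls for trio member ", m)

  wide <- NULL
  for (role in names(members)) {
    mm <- dt[dt$sample == members[[role]],
             c("chrom", "pos", "genotype", "depth")]
    names(mm)[3:4] <- paste0(c("gt_", "depth_"), role)
    wide <- if (is.null(wide)) mm else merge(wide, mm, by = c("chrom", "pos"))
  }
  md <- pmin(wide$depth_child, wide$depth_father, wide$depth_mother)
  confident <- wide$gt_child != "no_call" & wide$gt_father != "no_call" &
    wide$gt_mother != "no_call"
  usable <- confident & md >= min_depth
  tested <- wide[usable, , drop = FALSE]
  viol <- !mendelian_consistent(tested$gt_child, tested$gt_father,
                                tested$gt_mother)
  out <- tested[viol, , drop = FALSE]
  out$min_member_depth <- md[usable][viol]
  out$depth_bin <- as.character(cut(out$min_member_depth,
                                    c(10, 20, 30, Inf), right = FALSE,
                                    labels = DEPTH_BIN_LABELS))
  out$child <- rep(members[["child"]], nrow(out))
  out$mode <- rep(mode, nrow(out))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unevaluable") <- sum(!usable)
  attr(out, "n_tested") <- nrow(tested)
  out
}

#' Replicate/aggregate concordance of de novo calls
#'
#' Tabulates, per candidate site, how many technical replicates support the
#' call and whether the aggregate data calls it, then summarizes
#' fully-concordant, aggregate-only and replicate-only sites.
#'
#' @param replicate_calls named list of [detect_dnm()] results, one per
#'   replicate.
#' @param aggregate_calls [detect_dnm()] result for the aggregate data.
#' @return list with `table` (per-site `chrom`, `pos`, `support` in 0..R,
#'   `in_aggregate`) and `summary` (`n_sites`, `concordant`,
#'   `aggregate_only`, `replicate_only`).
#' @export
dnm_concordance <- function(replicate_calls, aggregate_calls) {
  key <- function(df) if (nrow(df)) paste(df$chrom, df$pos) else character()
  rep_keys <- lapply(replicate_calls, key)
  agg_key <- key(aggregate_calls)
  all_keys <- sort(unique(c(unlist(rep_keys), agg_key)))
  membership <- matrix(vapply(rep_keys, function(k) all_keys %in% k,
                              logical(length(all_keys))),
                       nrow = length(all_keys))
  support <- rowSums(membership)
  in_agg <- all_keys %in% agg_key
  parts <- strsplit(all_keys, " ", fixed = TRUE)
  tab <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
                    support = as.integer(support),
                    in_aggregate = in_agg, stringsAsFactors = FALSE)
  list(table = tab,
       summary = list(n_sites = nrow(tab),
                      concordant = sum(tab$support == length(replicate_calls) &
                                         tab$in_aggregate),
                      aggregate_only = sum(tab$support == 0L & tab$in_aggregate),
                      replicate_only = sum(tab$support > 0L & !tab$in_aggregate)))
}
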