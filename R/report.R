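#' Render pipeline results as a plain-text report
#'
#' Purely presentational: formats the numeric stage outputs of
#' [run_pipeline()] in the layout of a replicate-exome study report --
#' per-individual coverage block (replicates, mean +/- SD, aggregate),
#' intersection-union block, per-bin discordance block (rates in units of
#' 10^-6) and the de novo block.  No quantity is computed here beyond
#' rounding.
#'
#' @param results the list returned by [run_pipeline()].
#' @return character vector of report lines, invisibly printed with
#'   `cat()` when interactive use is wanted.
#' @export
render_report <- function(results) {
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))

  add("# Replicate exome analysis (seed %d)", results$seed)
  add("")
  add("## Coverage by individual")
  for (id in names(results$coverage)) {
    cv <- results$coverage[[id]]
    add("")
    add("### %s", id)
    pr <- cv$replicates$per_replicate
    thr <- names(pr)[-(1:2)]
    add("| sample | mean depth | %s |", paste(thr, collapse = " | "))
    add("|---|---|%s|", paste(rep("---", length(thr)), collapse = "|"))
    for (i in seq_len(nrow(pr)))
      add("| %s | %.0fx | %s |", pr$replicate[i], pr$mean_depth[i],
          paste(sprintf("%.1f", unlist(pr[i, thr])), collapse = " | "))
    s <- cv$replicates$summary
    add("| Mean +/- SD | | %s |",
        paste(sprintf("%.1f +/- %.1f", s$mean_pct, s$sd_pct), collapse = " | "))
    agg <- cv$aggregate
    add("| Aggregate | %.0fx | %s |", agg$mean_depth,
        paste(sprintf("%.1f", unlist(agg[thr])), collapse = " | "))
  }

  add("")
  add("## Intersection-union analysis")
  for (id in names(results$concordance)) {
    cc <- results$concordance[[id]]
    for (r in cc$iut)
      add("- %s at >=%dx: intersection %d (%.1f%%), variable %d (%.1f%%), uncovered %.1f%% of %d bases",
          id, r$threshold, r$intersection, r$fractions[["intersection"]],
          r$variable, r$fractions[["variable"]],
          r$fractions[["uncovered"]], r$total_bases)
    add("  recovered by aggregation: %d bases in %d segments (mean %.1f bp); %d segments > threshold overlap %d coding bases; p = %.1g",
        cc$recovered$covered_count, cc$segments$n_segments,
        cc$length_distribution$mean_length,
        cc$coding_overlap$n_overlapping_segments,
        cc$coding_overlap$overlapped_coding_bases,
        cc$stochastic_test$p_value)
  }

  add("")
  add("## Genotype discordance (all individuals pooled)")
  gs <- results$genotype$pooled$summary
  for (i in seq_len(nrow(gs)))
    add("- %s: %d discordant / %d evaluated (%.1f x 10^-6)", gs$bin[i],
        gs$discordant[i], gs$positions_evaluated[i], 1e6 * gs$rate[i])
  cl <- results$genotype$classification
  add("- truth classification of discordant sites: het %d (%.0f%%), hom_ref %d (%.0f%%), hom_alt %d (%.0f%%), unvalidated %d",
      cl$tallies[["het"]], cl$percentages[["het"]],
      cl$tallies[["hom_ref"]], cl$percentages[["hom_ref"]],
      cl$tallies[["hom_alt"]], cl$percentages[["hom_alt"]],
      cl$tallies[["unvalidated"]])
  add("- missed heterozygotes: %d (rate %.2f x 10^-6); false heterozygotes: %d",
      cl$missed_het, 1e6 * cl$missed_het_rate, cl$false_het)

  add("")
  add("## De novo mutations")
  for (child in names(results$denovo$per_trio)) {
    tr <- results$denovo$per_trio[[child]]
    for (d in setdiff(names(tr), "trio")) {
      x <- tr[[d]]
      repn <- vapply(x$replicates, nrow, integer(1))
      add("- trio %s at >=%sx: replicates %s (mean %.1f +/- %.1f), aggregate %d; concordant %d, aggregate-only %d, replicate-only %d",
          child, sub("^d", "", d),
          paste(repn, collapse = "/"), mean(repn), stats::sd(repn),
          nrow(x$aggregate), x$concordance$summary$concordant,
          x$concordance$summary$aggregate_only,
          x$concordance$summary$replicate_only)
    }
  }
  rec <- results$denovo$recall_aggregate
  add("- aggregate DNM recall vs truth: %s",
      paste(sprintf("%s %.0f%%", names(rec), 100 * rec), collapse = ", "))
  out
}
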