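#' Run the full replicate-exome analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> coverage -> concordance -> genotype -> denovo
#' and writes every stage artifact plus a manifest under `out_dir`.  The
#' run is fully deterministic given the seed: rerunning with the same
#' configuration reproduces every numeric output byte for byte.
#'
#' @param config a list (or path to a YAML file) with any of:
#'   `seed` (default 1), `out_dir` (default `tempfile("exorep_run")`),
#'   `params` (list of [sim_params()] overrides), `thresholds` (coverage
#'   thresholds, default `c(1, 10, 20)`), `iut_thresholds` (default
#'   `c(20, 1)`), `min_seg_len` (default 50), `dnm_min_depth` (default
#'   `c(10, 20)`), `caller_error_rate` (default 0.01, the Q20 floor),
#'   `write_inputs` (default TRUE), `quiet` (default FALSE).
#' @return (invisibly) the results list: `coverage`, `concordance`,
#'   `genotype`, `denovo`, `seed`, `params`, `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, out_dir = tempfile("exorep_run"), params = list(),
         thresholds = c(1L, 10L, 20L), iut_thresholds = c(20L, 1L),
         min_seg_len = 50L, dnm_min_depth = c(10L, 20L),
         caller_error_rate = 0.01, write_inputs = TRUE, quiet = FALSE),
    config)
  if (any(diff(cfg$thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!cfg$quiet) message(...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say(sprintf("[exorep] stage %-12s %6.2fs", name, timings[[name]]))
    res
  }

  ds <- stage("simulate", {
    params <- do.call(sim_params, c(list(seed = cfg$seed), cfg$params))
    simulate_dataset(params)
  })
  ids <- ds$pedigree$individuals$id
  rep_ids <- names(ds$profiles[[1L]])

  if (cfg$write_inputs) stage("write_inputs", {
    inp <- file.path(cfg$out_dir, "inputs")
    dir.create(inp, showWarnings = FALSE)
    write_bed(ds$targets, file.path(inp, "targets.bed"))
    write_bed(ds$exons, file.path(inp, "exons.bed"))
    write_pedigree(ds$pedigree, file.path(inp, "pedigree.ped"))
    for (id in ids) for (r in rep_ids)
      write_depth_table(ds$profiles[[id]][[r]],
                        file.path(inp, sprintf("depth_%s_%s.tsv", id, r)))
    write_allele_counts(ds$counts, file.path(inp, "allele_counts.tsv"))
    utils::write.table(ds$truth$dnm, file.path(inp, "truth_dnm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })

  aggregates <- lapply(ds$profiles, aggregate_profiles)

  coverage <- stage("coverage", {
    lapply(stats::setNames(ids, ids), function(id) {
      rs <- replicate_summary(ds$profiles[[id]], cfg$thresholds)
      agg <- aggregates[[id]]
      list(replicates = rs,
           aggregate = c(list(mean_depth = mean_target_depth(agg)),
                         as.list(percent_target_at(agg, cfg$thresholds))))
    })
  })

  concordance <- stage("concordance", {
    lapply(stats::setNames(ids, ids), function(id) {
      reps <- ds$profiles[[id]]
      per_t <- lapply(stats::setNames(cfg$iut_thresholds,
                                      paste0("t", cfg$iut_thresholds)),
                      function(t) iut(lapply(reps, coverage_mask, t = t)))
      t_main <- cfg$iut_thresholds[1L]
      rmasks <- lapply(reps, coverage_mask, t = t_main)
      amask <- coverage_mask(aggregates[[id]], t_main)
      rec <- recovered_mask(amask, rmasks)
      segs <- segments_from_mask(rec)
      main <- per_t[[1L]]
      list(iut = per_t,
           stochastic_test = two_proportion_test(main$intersection,
                                                 main$total_bases,
                                                 main$union, main$total_bases),
           recovered = rec, segments = segs,
           length_distribution = segment_length_distribution(segs),
           coding_overlap = intersect_segments_exons(segs, ds$exons,
                                                     cfg$min_seg_len))
    })
  })

  genotype <- stage("genotype", {
    p <- ds$params
    calls <- call_genotype_table(ds$counts, error_rate = cfg$caller_error_rate,
                                 min_call_depth = p$min_call_depth,
                                 quality_threshold = p$call_quality_threshold)
    agg_counts <- stats::aggregate(
      cbind(ref_count, alt_count, depth) ~ chrom + pos + ref + alt + sample,
      data = ds$counts, FUN = sum)
    agg_counts$replicate <- "aggregate"
    agg_calls <- call_genotype_table(agg_counts,
                                     error_rate = cfg$caller_error_rate,
                                     min_call_depth = p$min_call_depth,
                                     quality_threshold = p$call_quality_threshold)
    bins <- lapply(stats::setNames(ids, ids),
                   function(id) bin_positions(ds$profiles[[id]]))
    per_ind <- lapply(stats::setNames(ids, ids), function(id)
      discordance(calls[calls$sample == id, ], bins[[id]]))
    pooled <- combine_discordance(per_ind)
    low_bins <- pooled$summary$positions_evaluated[
      pooled$summary$bin %in% c("10-19x", "20-29x")]
    classified <- classify_discordances(pooled$sites, ds$truth,
                                        evaluated_positions = sum(low_bins))
    list(calls = calls, aggregate_calls = agg_calls, bins = bins,
         per_individual = per_ind, pooled = pooled,
         classification = classified)
  })

  denovo <- stage("denovo", {
    trios <- enumerate_trios(ds$pedigree)
    all_calls <- genotype_table(rbind(as.data.frame(genotype$calls),
                                      as.data.frame(genotype$aggregate_calls)))
    per_trio <- lapply(seq_len(nrow(trios)), function(i) {
      trio <- trios[i, ]
      per_depth <- lapply(stats::setNames(cfg$dnm_min_depth,
                                          paste0("d", cfg$dnm_min_depth)),
                          function(md) {
        rep_dnm <- lapply(stats::setNames(rep_ids, rep_ids), function(r)
          detect_dnm(all_calls, trio, min_depth = md, mode = r))
        agg_dnm <- detect_dnm(all_calls, trio, min_depth = md,
                              mode = "aggregate")
        list(replicates = rep_dnm, aggregate = agg_dnm,
             concordance = dnm_concordance(rep_dnm, agg_dnm))
      })
      c(list(trio = trio), per_depth)
    })
    names(per_trio) <- trios$child

    # aggregate-mode recall over depth-qualified truth sites: an injected
    # DNM inside an uncapturable target is undetectable by any caller and
    # does not belong in the denominator
    truth_dnm <- ds$truth$dnm
    md0 <- cfg$dnm_min_depth[1L]
    agg_depth <- function(id, idx) aggregates[[id]]$depth[idx]
    recall <- vapply(seq_len(nrow(trios)), function(i) {
      child <- trios$child[i]
      td <- truth_dnm[truth_dnm$child == child, , drop = FALSE]
      if (!nrow(td)) return(NA_real_)
      qualified <- agg_depth(child, td$index) >= md0 &
        agg_depth(trios$father[i], td$index) >= md0 &
        agg_depth(trios$mother[i], td$index) >= md0
      if (!any(qualified)) return(NA_real_)
      agg <- per_trio[[child]][[paste0("d", md0)]]$aggregate
      found <- paste(td$chrom, td$pos)[qualified] %in% paste(agg$chrom, agg$pos)
      mean(found)
    }, numeric(1))
    list(trios = trios, per_trio = per_trio,
         recall_aggregate = stats::setNames(recall, trios$child))
  })

  results <- list(seed = cfg$seed, params = ds$params, coverage = coverage,
                  concordance = concordance, genotype = genotype,
                  denovo = denovo, out_dir = cfg$out_dir)

  stage("write_results", {
    jsonlite::write_json(results_json(results),
                         file.path(cfg$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(package = "exorep",
                     version = as.character(utils::packageVersion("exorep")),
                     seed = cfg$seed,
                     config = cfg[c("thresholds", "iut_thresholds",
                                    "min_seg_len", "dnm_min_depth",
                                    "caller_error_rate")],
                     params = unclass(ds$params),
                     inputs = if (cfg$write_inputs)
                       list.files(file.path(cfg$out_dir, "inputs"))
                     else character(),
                     stage_seconds = timings)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(NULL)
  })

  invisible(results)
}

# Machine-readable projection of the results list (numeric stage outputs
# only; every figure in the rendered report comes from these fields).
results_json <- function(results) {
  ids <- names(results$coverage)
  list(
    seed = results$seed,
    coverage = lapply(results$coverage, function(cv) {
      list(per_replicate = cv$replicates$per_replicate,
           summary = cv$replicates$summary,
           aggregate = cv$aggregate)
    }),
    concordance = lapply(results$concordance, function(cc) {
      list(iut = lapply(cc$iut, function(r)
        list(threshold = r$threshold, total_bases = r$total_bases,
             venn = as.list(r$venn), intersection = r$intersection,
             union = r$union, variable = r$variable,
             fractions = as.list(r$fractions))),
        stochastic_test_p = cc$stochastic_test$p_value,
        recovered_bases = cc$recovered$covered_count,
        n_segments = cc$segments$n_segments,
        mean_segment_length = cc$length_distribution$mean_length,
        n_singletons = cc$length_distribution$n_singletons,
        power_law_slope = cc$length_distribution$slope,
        coding_overlap = cc$coding_overlap)
    }),
    genotype = list(
      pooled = results$genotype$pooled$summary,
      classification = list(
        tallies = as.list(results$genotype$classification$tallies),
        percentages = as.list(results$genotype$classification$percentages),
        missed_het = results$genotype$classification$missed_het,
        false_het = results$genotype$classification$false_het,
        missed_het_rate = results$genotype$classification$missed_het_rate)),
    denovo = list(
      recall_aggregate = as.list(results$denovo$recall_aggregate),
      per_trio = lapply(results$denovo$per_trio, function(tr) {
        depths <- setdiff(names(tr), "trio")
        stats::setNames(lapply(depths, function(d) {
          list(replicate_counts = vapply(tr[[d]]$replicates, nrow, integer(1)),
               aggregate_count = nrow(tr[[d]]$aggregate),
               concordance = tr[[d]]$concordance$summary)
        }), depths)
      }))
  )
}
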