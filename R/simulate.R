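#' Simulation parameters for the synthetic replicate-exome study
#'
#' Houses every knob of the generator.  Defaults emulate the study design
#' the analysis is built for: ~10^5 bases of exon-sized capture targets,
#' three technical replicates per individual with replicate mean depths in
#' the 48-86x range, log-normal per-target capture efficiency, negative
#' binomial (overdispersed) per-base depth, founder heterozygosity near the
#' human exome rate, and a handful of injected de novo mutations per child.
#'
#' @param seed master seed; every stochastic draw in the generator is a
#'   deterministic function of it (plus sample/replicate labels).
#' @param n_targets number of capture target intervals.
#' @param target_length_mean mean target length in bases (Poisson lengths).
#' @param per_target_sdlog sdlog of the log-normal per-target capture
#'   efficiency component shared by every library (probe quality, GC --
#'   the between-target heterogeneity all replicates see alike); meanlog
#'   is chosen so the mean multiplier is 1.  0 disables it.
#' @param target_failure_rate fraction of targets that are essentially
#'   uncapturable in every library (shared efficiency scaled by 0.01),
#'   emulating the few percent of targeted bases real kits never cover.
#' @param efficiency_sdlog sdlog of the replicate-specific log-normal
#'   efficiency jitter, redrawn per (target, replicate) -- the
#'   library-preparation stochasticity that makes whole targets rise or
#'   fall between captures.  0 disables it.
#' @param mean_depth global mean per-base depth (x units) at library scale 1.
#' @param library_scale_range range of the uniform draw of each replicate's
#'   library-size multiplier; the default maps `mean_depth` to 48-86x
#'   realized replicate means.
#' @param dispersion negative binomial size parameter k for per-base depth;
#'   `Inf` gives the Poisson limit.
#' @param het_density expected heterozygous sites per kb in each founder.
#' @param base_error_rate probability a sequenced base is miscalled.
#' @param de_novo_rate expected de novo mutations injected per child over
#'   the whole target space.
#' @param min_call_depth minimum depth for a confident genotype call.
#' @param call_quality_threshold minimum log10 posterior-odds quality for a
#'   confident call.
#' @param n_replicates technical replicates per individual.
#' @return a `SimulationParams` list.
#' @export
sim_params <- function(seed = 1L,
                       n_targets = 400L,
                       target_length_mean = 250,
                       per_target_sdlog = 0.5,
                       target_failure_rate = 0.03,
                       efficiency_sdlog = 0.15,
                       mean_depth = 67,
                       library_scale_range = c(48, 86) / 67,
                       dispersion = 30,
                       het_density = 0.8,
                       base_error_rate = 0.005,
                       de_novo_rate = 5,
                       min_call_depth = 10L,
                       call_quality_threshold = 2,
                       n_replicates = 3L) {
  p <- list(seed = as.integer(seed), n_targets = as.integer(n_targets),
            target_length_mean = target_length_mean,
            per_target_sdlog = per_target_sdlog,
            target_failure_rate = target_failure_rate,
            efficiency_sdlog = efficiency_sdlog, mean_depth = mean_depth,
            library_scale_range = library_scale_range,
            dispersion = dispersion, het_density = het_density,
            base_error_rate = base_error_rate, de_novo_rate = de_novo_rate,
            min_call_depth = as.integer(min_call_depth),
            call_quality_threshold = call_quality_threshold,
            n_replicates = as.integer(n_replicates))
  stopifnot(p$n_targets >= 1L, p$target_length_mean > 0,
            p$per_target_sdlog >= 0,
            p$target_failure_rate >= 0, p$target_failure_rate <= 1,
            p$efficiency_sdlog >= 0, p$mean_depth >= 0,
            all(p$library_scale_range > 0), p$dispersion > 0,
            p$het_density >= 0,
            p$base_error_rate >= 0, p$base_error_rate <= 1,
            p$de_novo_rate >= 0, p$n_replicates >= 1L)
  structure(p, class = "SimulationParams")
}

# Deterministic substream seed from the master seed plus string labels,
# kept below 2^31 so it is a valid R integer seed.
substream_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(lab)) h <- (h * 131 + k) %% 2147483647
  as.integer((h * 97 + as.numeric(seed) * 7919 + 1) %% 2147483647)
}

#' Simulate capture target intervals
#'
#' Lays `n_targets` exon-sized intervals left to right on one synthetic
#' chromosome (`chrS`), with Poisson lengths around `target_length_mean`
#' and positive inter-target gaps, so intervals never overlap.
#'
#' @param params a [sim_params()] object.
#' @return a [target_regions()] object.
#' @export
simulate_targets <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  withr::with_seed(substream_seed(params$seed, "targets"), {
    len <- pmax(1L, stats::rpois(params$n_targets, params$target_length_mean))
    gap <- stats::rpois(params$n_targets, 200) + 50L
    start <- cumsum(gap) + cumsum(c(0L, len[-params$n_targets]))
    target_regions(rep("chrS", params$n_targets), start, start + len)
  })
}

# Shared per-target efficiency component: one draw per target, identical
# for every sample and replicate (probe quality is a property of the kit).
# A `target_failure_rate` fraction of targets is scaled by 0.01,
# emulating regions the kit never captures.
target_efficiencies <- function(targets, params) {
  withr::with_seed(substream_seed(params$seed, "target_efficiency"), {
    nt <- nrow(targets$regions)
    eff <- stats::rlnorm(nt, meanlog = -params$per_target_sdlog^2 / 2,
                         sdlog = params$per_target_sdlog)
    failed <- stats::runif(nt) < params$target_failure_rate
    eff[failed] <- eff[failed] * 0.01
    eff
  })
}

#' Simulate one replicate's per-base capture depth
#'
#' The per-base expected depth factorizes into the three scales of
#' variability replicate exome data shows: a per-target efficiency
#' component shared by all libraries (between-target heterogeneity plus a
#' small fraction of uncapturable targets), a replicate-specific
#' per-target jitter redrawn for every library preparation (the
#' stochastics the intersection-union analysis measures), and a
#' replicate-wide library-size multiplier.  Per-base depth is negative
#' binomial around `mean_depth * library_scale * shared_eff * jitter`
#' with dispersion `k` (Poisson when `k = Inf`).  Deterministic given
#' `(seed, sample_id, replicate_id)`.
#'
#' @param targets a [target_regions()] object.
#' @param params a [sim_params()] object.
#' @param replicate_id replicate label (part of the random substream).
#' @param sample_id individual label (part of the random substream).
#' @param library_scale optional fixed library-size multiplier; drawn
#'   uniformly from `params$library_scale_range` when `NULL`.
#' @return a [depth_profile()] object.
#' @export
simulate_replicate_depth <- function(targets, params, replicate_id,
                                     sample_id = "S1", library_scale = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  shared <- target_efficiencies(targets, params)
  withr::with_seed(substream_seed(params$seed, "depth", sample_id, replicate_id), {
    nt <- nrow(targets$regions)
    jitter <- stats::rlnorm(nt, meanlog = -params$efficiency_sdlog^2 / 2,
                            sdlog = params$efficiency_sdlog)
    if (is.null(library_scale))
      library_scale <- stats::runif(1, params$library_scale_range[1L],
                                    params$library_scale_range[2L])
    mu <- rep(params$mean_depth * library_scale * shared * jitter,
              targets$regions$width)
    d <- if (is.infinite(params$dispersion)) stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), mu = mu, size = params$dispersion)
    depth_profile(targets, d, sample_id, replicate_id)
  })
}

#' Simulate ground-truth pedigree genotypes with injected de novo mutations
#'
#' Founders receive heterozygous sites at `het_density` per kb (uniformly
#' placed, hom_ref elsewhere); non-founders inherit one allele from each
#' parent uniformly at random, in generation order.  De novo mutations are
#' injected per child at fresh positions where both parents are necessarily
#' hom_ref, recorded in the returned DNM list, and are transmissible to the
#' child's own descendants.  Deterministic given the seed.
#'
#' @param targets a [target_regions()] object.
#' @param ped a [pedigree()] object.
#' @param params a [sim_params()] object.
#' @return a `TruthSet`: list with `sites` (data.frame `chrom`, `pos`,
#'   `index`, `ref`, `alt`), `genotypes` (sites x individuals character
#'   matrix), and `dnm` (data.frame `child`, `chrom`, `pos`, `index`).
#' @export
simulate_pedigree_truth <- function(targets, ped, params) {
  stopifnot(inherits(params, "SimulationParams"), inherits(ped, "Pedigree"))
  withr::with_seed(substream_seed(params$seed, "truth"), {
    N <- targets$total_bases
    ind <- ped$individuals
    founders <- ind$id[is.na(ind$father) & is.na(ind$mother)]

    founder_sites <- lapply(founders, function(f) {
      k <- stats::rpois(1L, params$het_density * N / 1000)
      sort(sample.int(N, min(k, N)))
    })
    names(founder_sites) <- founders
    het_sites <- sort(unique(unlist(founder_sites)))

    children <- ind$id[order(ind$generation, ind$id)]
    children <- children[!(children %in% founders)]
    used <- het_sites
    dnm_sites <- lapply(children, function(ch) {
      k <- stats::rpois(1L, params$de_novo_rate)
      avail <- setdiff(seq_len(N), used)
      s <- sort(sample(avail, min(k, length(avail))))
      used <<- c(used, s)
      s
    })
    names(dnm_sites) <- children

    sites <- sort(unique(used))
    ns <- length(sites)
    G <- matrix("hom_ref", nrow = ns, ncol = nrow(ind),
                dimnames = list(NULL, ind$id))
    for (f in founders)
      G[match(founder_sites[[f]], sites), f] <- "het"

    transmit <- function(geno) {
      # one allele drawn from each parent genotype: 0 = ref, 1 = alt
      a <- integer(length(geno))
      a[geno == "hom_alt"] <- 1L
      is_het <- geno == "het"
      a[is_het] <- stats::rbinom(sum(is_het), 1L, 0.5)
      a
    }
    for (ch in children) {
      fa <- ind$father[ind$id == ch]
      mo <- ind$mother[ind$id == ch]
      n_alt <- (if (is.na(fa)) integer(ns) else transmit(G[, fa])) +
               (if (is.na(mo)) integer(ns) else transmit(G[, mo]))
      G[, ch] <- c("hom_ref", "het", "hom_alt")[n_alt + 1L]
      G[match(dnm_sites[[ch]], sites), ch] <- "het"
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, ns, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    coords <- target_coords(targets, sites)
    dnm <- do.call(rbind, lapply(children, function(ch) {
      if (!length(dnm_sites[[ch]])) return(NULL)
      cc <- target_coords(targets, dnm_sites[[ch]])
      data.frame(child = ch, chrom = cc$chrom, pos = cc$pos,
                 index = dnm_sites[[ch]], stringsAsFactors = FALSE)
    }))
    if (is.null(dnm))
      dnm <- data.frame(child = character(), chrom = character(),
                        pos = integer(), index = integer())
    structure(list(sites = data.frame(chrom = coords$chrom, pos = coords$pos,
                                      index = sites, ref = ref, alt = unname(alt),
                                      stringsAsFactors = FALSE),
                   genotypes = G, dnm = dnm),
              class = "TruthSet")
  })
}

#' Simulate Q20-filtered allele counts at truth sites for one replicate
#'
#' At each truth site, the site depth is taken from the replicate's depth
#' profile and alternate-allele reads are drawn by genotype: heterozygous
#' sites binomial(depth, 1/2), homozygous sites all-ref or all-alt; every
#' read is then independently miscalled (ref and alt swap) with probability
#' `base_error_rate`.
#'
#' @param truth a [simulate_pedigree_truth()] object.
#' @param profile the [depth_profile()] of one (sample, replicate).
#' @param params a [sim_params()] object.
#' @return data.frame of per-site counts (`chrom`, 0-based `pos`, `ref`,
#'   `alt`, `sample`, `replicate`, `ref_count`, `alt_count`, `depth`).
#' @export
simulate_allele_counts <- function(truth, profile, params) {
  stopifnot(inherits(truth, "TruthSet"), inherits(profile, "DepthProfile"))
  withr::with_seed(
    substream_seed(params$seed, "counts", profile$sample_id, profile$replicate_id), {
    d <- profile$depth[truth$sites$index]
    g <- truth$genotypes[, profile$sample_id]
    eps <- params$base_error_rate
    true_alt <- integer(length(d))
    is_het <- g == "het"
    true_alt[is_het] <- stats::rbinom(sum(is_het), d[is_het], 0.5)
    true_alt[g == "hom_alt"] <- d[g == "hom_alt"]
    alt <- stats::rbinom(length(d), true_alt, 1 - eps) +
           stats::rbinom(length(d), d - true_alt, eps)
    data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
               ref = truth$sites$ref, alt = truth$sites$alt,
               sample = profile$sample_id, replicate = profile$replicate_id,
               ref_count = d - alt, alt_count = alt, depth = d,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete replicate-exome study data set
#'
#' Convenience wrapper generating targets, a coding-exon subset (every
#' second target), ground-truth pedigree genotypes, per-replicate depth
#' profiles for every individual, and allele counts for every
#' (individual, replicate).
#'
#' @param params a [sim_params()] object.
#' @param ped a [pedigree()] object; defaults to the six-member,
#'   three-generation study family.
#' @return list with `params`, `pedigree`, `targets`, `exons`, `truth`,
#'   `profiles` (nested list `[[individual]][[replicate]]`), and `counts`
#'   (one data.frame over all individuals and replicates).
#' @export
simulate_dataset <- function(params = sim_params(), ped = default_pedigree()) {
  targets <- simulate_targets(params)
  reg <- targets$regions
  sel <- seq(1L, nrow(reg), by = 2L)
  exons <- target_regions(reg$chrom[sel], reg$start[sel], reg$end[sel])
  truth <- simulate_pedigree_truth(targets, ped, params)
  rep_ids <- paste0("R", seq_len(params$n_replicates))
  profiles <- lapply(ped$individuals$id, function(id) {
    pr <- lapply(rep_ids, function(r)
      simulate_replicate_depth(targets, params, r, sample_id = id))
    names(pr) <- rep_ids
    pr
  })
  names(profiles) <- ped$individuals$id
  counts <- do.call(rbind, lapply(unlist(profiles, recursive = FALSE),
                                  function(p) simulate_allele_counts(truth, p, params)))
  rownames(counts) <- NULL
  list(params = params, pedigree = ped, targets = targets, exons = exons,
       truth = truth, profiles = profiles, counts = counts)
}
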