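---
title: "Quantifying stochastic variability between technical-replicate exome captures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stochastic variability between technical-replicate exome captures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exorep)
```

## The problem

Whole-exome sequencing reports are usually summarized as "percent of
targeted bases covered at >= t x".  That summary hides a question that
matters in diagnostic settings: if the capture were repeated from the same
DNA, would the *same* bases reach the threshold again?  Independent
library preparations of one sample differ not just in total yield but in
*which* targets capture well, so a base that is genotypeable (>= 20x) in
one library may be silent in the next.  `exorep` quantifies that
stochastic component from per-base depth tables of replicate libraries,
shows how much of it aggregation of replicates repairs, and propagates the
consequences to genotype discordance and trio de novo (DNM) detection.

## The core quantities

For three replicate coverage masks $R_1, R_2, R_3$ at threshold $t$ over
$N$ targeted bases, the package computes the full 7-region Venn
classification per base, and from it

* the **intersection** $I = |R_1 \cap R_2 \cap R_3|$ -- bases reliably
  covered in every library;
* the **union** $U = |R_1 \cup R_2 \cup R_3|$;
* the **variable** set $V = U - I$ -- bases whose coverage is a property
  of the library draw, not of the kit.  $V/N$ is the headline measure of
  capture stochasticity.

Classification is done in one per-base pass (membership triples), so
$\sum \text{venn} = U$ and $I + V = U$ hold by construction and are
asserted on every run.  Differences between coverage proportions are
tested with the standard two-independent-proportion chi-square
(`prop.test`, Yates-corrected by default); an independent hand-computed
2x2 oracle backs it in the test suite.

**Aggregation.** Summing the three replicates' per-base depths emulates
merging their alignments.  Because aggregate depth is the sum, the
aggregate mask dominates every replicate mask at every threshold -- an
exact inequality the tests assert.  Bases reaching $t$ in the aggregate
but not in the replicate intersection are **recovered**; maximal runs of
recovered bases (never spanning a target gap) are extracted, their
length-frequency distribution is fit by least squares on the log-log
scale (the conventional power-law check), and runs longer than 50 bp are
intersected with coding exons.  The recovered-baseline is configurable
(`intersection`, the default, or `union`).

**Genotype discordance.** A three-genotype binomial Bayes caller stands
in for pipeline callers: alternate-read counts are binomial with success
probability $\varepsilon$, $1/2$ or $1-\varepsilon$ under hom-ref, het
and hom-alt, the call is the posterior mode, and its quality is the
log10 ratio of best to second-best posterior.  Calls below a depth or
quality floor are `no_call`.  Positions are binned by the *minimum*
depth across replicates (10-19x, 20-29x, >= 30x; below 10x excluded) --
the conservative choice guaranteeing every replicate meets the bin
floor; `bin_positions(stat = "mean")` gives the alternative.  A site is
discordant when confident calls differ between replicates; sites with
any `no_call` are excluded from numerator and denominator, since an
absent call cannot disagree.  Discordant sites are classified against
ground truth into missed heterozygotes and false heterozygotes.

**De novo detection.** Trios are enumerated from the PED pedigree; a
site is a DNM candidate when all three members have confident calls at
depth >= the chosen floor and the genotype triple cannot be assembled
from one transmitted allele per parent.  Exactly 12 of the 27 ordered
biallelic triples are inconsistent, verified against a gamete-enumeration
oracle.  Candidates are compared across replicates and aggregate data
(support count 0-3, aggregate-only, replicate-only).

## What the generator emulates

The emulated study design is 6 individuals in a 3-generation family,
3 independent captures each.  The generator reproduces the statistical
structure that design exhibits, with all knobs in `sim_params()`:

* **Targets**: 400 exon-sized intervals (Poisson lengths, mean 250 bp,
  ~1e5 bases) on one synthetic chromosome.  This problem size keeps a
  full 18-library study under a few seconds; all structural results are
  size-independent.
* **Three scales of depth variability**:
  1. a per-target log-normal efficiency shared by *every* library
     (sdlog 0.5), plus a 3% fraction of uncapturable targets (efficiency
     x 0.01) -- the heterogeneity all replicates see alike, which is why
     even deep aggregates cover only ~97% of targets at >= 1x rather
     than 100%;
  2. a per-(target, replicate) log-normal jitter (sdlog 0.15) -- the
     library-preparation stochasticity that the intersection-union
     analysis measures;
  3. a per-replicate library-size multiplier drawn so replicate mean
     depths span 48-86x, the range the study design reports, with the
     aggregate at roughly three times a replicate.
  Per-base depth is negative binomial (dispersion k = 30; `Inf` gives
  the Poisson limit used by the closed-form coverage checks).
  These values were calibrated once against the published per-replicate
  and aggregate coverage ranges; under them the synthetic study lands at
  5-11% variable bases at >= 20x versus ~2% at >= 1x, replicate >= 20x
  coverage of 88-96% and aggregate ~97% -- the same ordering and
  magnitudes as the real study.
* **Genotypes**: founders receive heterozygous sites at 0.8/kb (near the
  human exome rate); children inherit one allele per parent uniformly;
  de novo mutations (5 expected per child, deliberately generous so the
  trio machinery is exercised at 1e5 bases) are injected on
  double-hom-ref backgrounds -- the class a trio test flags most
  cleanly -- and are transmissible to the next generation.
* **Reads**: per-site alternate counts are binomial by genotype, with
  every read independently miscalled at `base_error_rate` (0.5%,
  consistent with a Q20-filtered pileup).

Every draw is a deterministic function of the master seed plus
sample/replicate labels, so any subset of the data can be regenerated
independently and reruns are byte-identical.

What the generator does **not** emulate: spatial correlation of depth
along a target (real coverage rises and falls smoothly across an exon,
so real recovered segments average ~50 bp while synthetic ones are a few
bases), GC-content and mappability structure, indels, multi-allelic
sites, and read-level artifacts such as mis-mapping.  Consequently,
passing tests demonstrate the correctness of the set algebra, callers
and statistics, and the direction and rough magnitude of the
replicate-vs-aggregate effects -- not the exact segment-length or
validation-category figures of real data, which depend on those
unmodelled features.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; BED is native,
  `samtools depth`-style TSV (1-based) and the VCF-lite tables are
  converted at the boundary.  Depth tables are written dense (zeros
  included) so set operations never need missing-data semantics.
* Overlapping BED inputs are merged, not rejected: capture kits ship
  overlapping probes.  The BED-derived base total is the single
  denominator for all fractions.
* Dispersion in replicate coverage summaries is the sample SD (n-1) of
  the three percentages, printed to one decimal; published tables of
  this kind label the column "SE" but print the SD, and the SD is what
  three replicate percentages such as 83.5/87.4/89.4 -> 86.8 +/- 3.0
  reproduce.
* The loess saturation trend uses `stats::loess` with span 0.75 and
  local quadratics (`surface = "direct"`), with a pointwise t-based 95%
  band.  Acceptance is via reproduction of straight lines and the
  span-smoothness ordering, since no coefficients are published for
  such fits.
* The caller's quality threshold defaults to 2 (posterior odds 100:1)
  with a 10x depth floor; at eps = 1%, 10 clean reference reads are just
  confidently callable, which anchors the 10-19x bin as the
  discordance-prone regime.
* Genotype priors are flat by default: the analysis runs at known
  variant sites, where a population prior would only shift the
  low-depth no_call boundary.
* The p-value reported for the stochasticity contrast tests the
  intersection proportion against the union proportion of the same
  individual; which two proportions the original analysis compared is
  not identifiable from its text, so the package exposes the test for
  arbitrary count pairs rather than chasing a specific printed p.
* At the default 1e5-base problem size the expected number of
  inter-replicate discordant genotype calls is below one (the published
  per-bin rates are a few per million positions), so the pipeline's
  discordance block legitimately reports zeros; the test suite
  demonstrates the discordance machinery and its depth-monotonicity in
  a dedicated low-depth regime (Poisson 13x depths, het density 20/kb)
  where heterozygote dropout is observable.
* DNM recall is reported over *depth-qualified* injected sites (all
  three members >= 10x in aggregate): a mutation injected into an
  uncapturable target is undetectable by any caller and does not belong
  in the denominator.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(list(seed = 1, out_dir = "exorep_run"))
cat(render_report(res), sep = "\n")
```

The run writes `results.json` (machine-readable stage outputs),
`manifest.json` (parameters, seed, versions, timings) and all simulated
inputs (BED/PED/TSV) under `out_dir`; `render_report()` formats the same
numbers -- it computes nothing new.  See the README for the numbers a
seed-1 run prints and `scripts/acceptance.R` for the scripted
reproduction of the headline quantities.

## Known limitations

Beyond the generator simplifications above: the package ingests depth
tables, not BAMs (alignment, duplicate marking and base-quality
filtering are upstream concerns); the caller is a stand-in, not a
reimplementation of any production caller; Mendelian checks are
autosomal-biallelic only; and the two-proportion test on tens of
millions of bases is, as in any study of this design, so overpowered
that its p-values are descriptive rather than decisive.
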