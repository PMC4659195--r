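# exorep

Technical-replicate exome coverage concordance and trio de novo analysis.

## Why

A single exome capture is a random draw: independent library
preparations from the same DNA differ not only in yield but in *which*
targeted bases reach a usable depth. For anyone interpreting exomes
clinically — or designing how many libraries to prepare — the question is
how much of "percent of target at ≥20x" is a stable property of the kit
and how much is per-library chance, and how much of the chance component
merging replicate data repairs. `exorep` answers that from plain
per-base depth tables (the `samtools depth` format), a BED of targets,
and a PED pedigree, and ships a pedigree-aware simulator so the whole
analysis runs and is tested end to end without any external data.

## What it computes

For three replicate coverage masks R1, R2, R3 at threshold *t* over *N*
targeted bases:

- the per-base Venn classification, intersection *I* = |R1 ∩ R2 ∩ R3|,
  union *U*, and the **variable fraction** (U − I)/N — the stochastic
  component of capture — with a two-independent-proportion chi-square
  (Yates-corrected `prop.test`) for contrasts;
- aggregate profiles (per-base sums), the bases **recovered** by
  aggregation (aggregate ≥ t but outside the replicate intersection),
  their maximal segments, the log–log least-squares slope of the
  segment-length distribution, and the intersection of >50 bp segments
  with coding exons;
- coverage summaries per replicate and aggregate (mean target depth,
  percent ≥ t, across-replicate mean ± SD) and loess saturation trends
  (span 0.75) with 95% bands;
- genotypes from allele counts via a three-genotype binomial Bayes
  caller (posterior-mode call, log10 posterior-odds quality), per-base
  depth bins (10–19x / 20–29x / ≥30x by minimum replicate depth), the
  inter-replicate **genotype discordance rate** per bin, and truth-based
  classification of discordant sites (missed / false heterozygotes);
- trio **de novo candidates** as Mendelian-inheritance violations
  (12 of the 27 ordered genotype triples) at 10x and 20x floors, with
  replicate/aggregate concordance and recall against the simulator's
  injected-mutation truth set.

## A worked example

```r
library(exorep)
res <- run_pipeline(list(seed = 1, out_dir = "exorep_run"))
cat(render_report(res), sep = "\n")
```

The default configuration simulates the study design the package
targets: a six-member three-generation family, three capture libraries
per individual over ~1e5 targeted bases, replicate mean depths in the
48–86x range. The seed-1 report starts:

```
### F1
| sample | mean depth | >=1x | >=10x | >=20x |
|---|---|---|---|---|
| R1 | 61x | 98.3 | 96.8 | 93.5 |
| R2 | 49x | 98.1 | 96.6 | 90.0 |
| R3 | 81x | 98.6 | 97.0 | 95.9 |
| Mean +/- SD | | 98.3 +/- 0.2 | 96.8 +/- 0.2 | 93.1 +/- 3.0 |
| Aggregate | 191x | 99.4 | 97.0 | 97.0 |

## Intersection-union analysis
- F1 at >=20x: intersection 87586 (87.6%), variable 9068 (9.1%), uncovered 3.3% of 99948 bases
- F1 at >=1x: intersection 97251 (97.3%), variable 2120 (2.1%), uncovered 0.6% of 99948 bases
```

Read: each single library leaves 4–10% of the target below the
genotyping threshold, and 9.1% of targeted bases flip in or out of
≥20x between libraries of the *same* DNA, versus only 2.1% at ≥1x —
coverage stochasticity lives at the usable-depth threshold, not at
bare detectability. Merging the three libraries lifts ≥20x coverage to
97.0%, above every individual replicate. Downstream, the de novo block
shows the same effect on variant interpretation:

```
- trio G1 at >=20x: replicates 2/2/3 (mean 2.3 +/- 0.6), aggregate 4; concordant 2, aggregate-only 1, replicate-only 0
- aggregate DNM recall vs truth: C1 100%, C2 100%, G1 100%
```

an injected mutation missed by replicates at the 20x floor is found in
the aggregate data, and every depth-qualified injected mutation is
recovered.

`run_pipeline()` writes the simulated inputs (BED / PED / depth TSVs /
allele counts), `results.json` with every stage's numeric outputs, and a
`manifest.json` (seed, parameters, versions, timings); `render_report()`
only formats `results.json` content. Reruns with the same seed are
byte-identical. Every step is also available as a standalone function
(`read_bed()`, `coverage_mask()`, `iut()`, `aggregate_profiles()`,
`segments_from_mask()`, `call_genotype()`, `bin_positions()`,
`discordance()`, `detect_dnm()`, ...) for use on real depth tables.

The methods vignette
(`vignettes/replicate-exome-concordance.Rmd`) documents the model, the
generator's calibration and its limits, and the numerical choices.

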