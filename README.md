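# svjunctions

Analysis of structural variant (SV) breakpoint junctions from
single-molecule hybrid-capture sequencing of common fragile sites (CFSs),
for researchers studying replication-stress-induced genome instability and
DSB repair pathway choice.

Large transcribed CFS genes acquire de novo deletions (and rarer
duplications/inversions) under replication stress. Deep capture sequencing
resolves each SV to a breakpoint junction whose local structure — shared
microhomology, blunt joint, or de novo insertion — is a fingerprint of the
repair mechanism. Theta-mediated end joining (TMEJ) leaves a
2 bp-peaked microhomology distribution and short insertions copied from
templates near the breakpoints, bounded by priming and resolving
microhomologies. This package implements the full downstream analysis and a
synthetic cohort generator that plants junctions with known truth so every
stage is verifiable without sequencing data.

## The model

Each junction carries two breakpoints (the last aligned base on each side)
in reference and molecule coordinates. With `a` and `b` the molecule
positions of the two junction-proximal aligned bases, the breakpoint
**offset** is `b − a − 1`: microhomology `< 0`, blunt `= 0`, insertion
`> 0`. The main quantitative machinery is:

* **Filtering** — junctions kept only when unique to one molecule in one
  sample, supported by ≥ 3 read pairs, mapq ≥ 30/one and ≥ 20/both sides,
  on-target within an 800 kb padded span, and inside per-type size windows
  (DEL/DUP 10 kb–1.2 Mb, INV ≥ 50 kb).
* **Coverage** — `Σ max(len − 40, 0) / target length` over ≥ 3-read-pair,
  non-SV, on-target molecules; **SV frequency** = junction count /
  fold-coverage.
* **Template search** — exact-match scan of the insertion ± flanking
  microhomologies (≥ 7 query bases, ≥ 1 flank base per side) over 2
  breakpoints × 2 strands × 500 bp per side = 4 kb; maximal flank
  extension; classes foldback/palindrome, cross-junction,
  strand-switching, expansion by strand and retained/lost placement.
* **Enrichment** — random matches arise at Poisson rate
  `mu = 4000 / 4^n`; the per-size template yield is tested against
  `Binomial(nSearched, 1 − e^(−mu))` (upper tail).
* **Frequency comparison** — negative-binomial GLM
  `nSvs ~ group + batch + offset(log(coverage))`, Wald p-value on the
  group coefficient (log SV-frequency ratio), Poisson fallback when the
  overdispersed fit fails; p ≤ 0.01 convention.

## Worked example

```r
library(svjunctions)

cfg <- sim_config(seed = 42, meanCoverage = 20, nSamplesPerGroup = 6,
                  svRatePerHaplotype = c(A = 0.2, B = 1.0))
sim <- simulate_cohort(cfg)
out <- run_pipeline(sim$reference, sim$targets, sim$molecules, sim$calls,
                    sim$samples, outDir = "svj_out")
#> filter: 143 calls in, 135 kept, 8 rejected
#> coverage: 241.9 fold over 1 target(s)
#> templates: 39 insertion junctions searched

out$comparisonTable
#>   groupRef groupAlt logRateRatio    se rateRatio   pValue         modelUsed
#> 1        A        B         1.49 0.218      4.44 8.31e-12 negative_binomial

junction_profile(out$kept)
#> Junction profile over 135 junctions:
#>   mean microhomology (non-insertion junctions): 2.646 bp
#>   fraction with 2-15 bp insertions: 0.2148
```

The cohort planted a 5-fold SV-rate difference (0.2 vs 1.0 SVs per covered
haplotype); the fitted rate ratio is 4.44 with Wald p ≈ 10⁻¹¹. The
junction profile reflects the TMEJ-mode defaults: ~2.6 bp mean
microhomology among non-insertion junctions and ~21% of junctions carrying
a 2–15 bp insertion. `out$templates`, `out$enrichment`, and `out$pileup`
hold the per-SV template calls, the per-insertion-size enrichment tests,
and the template-position pileup; everything is also written as TSV under
`svj_out/` together with a machine-readable `run_summary.json`.

A thin command-line wrapper with `simulate | filter | coverage |
characterize | templates | enrich | compare | report` subcommands is
provided at `inst/scripts/svjunctions-cli.R`.

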