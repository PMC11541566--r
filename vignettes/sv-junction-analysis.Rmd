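---
title: "Analyzing SV breakpoint junctions from single-molecule capture sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing SV breakpoint junctions from single-molecule capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svjunctions)
```

## The problem

Common fragile sites (CFSs) — typically very large transcribed genes — break
under replication stress and acquire kilobase-to-megabase de novo structural
variants (SVs), predominantly deletions. Hybrid-capture sequencing of CFS
genes at high depth, with reads aggregated into unique source DNA molecules,
detects these SVs as breakpoint junctions at base-pair resolution. The
repair mechanism leaves a signature at the junction: theta-mediated end
joining (TMEJ) produces junctions with short (peak 2 bp) microhomologies and
a substantial minority of short de novo insertions that are often copied
from templates within tens of bases of the breakpoints, bounded by priming
and resolving microhomologies.

`svjunctions` implements the downstream analysis of such data: molecule-level
SV filtering, adjusted coverage, junction characterization, insertion-template
discovery and classification, template-enrichment statistics, and an
overdispersed count model for comparing SV frequency between experimental
groups. A synthetic-cohort generator plants junctions with known mechanism
truth so every stage is testable without sequencing data.

## The junction model

Each junction is described by two breakpoints, the last aligned base nearest
the junction on each side, recorded in two coordinate systems: the reference
genome and the SV-containing molecule. With `a` the molecule index of the
first segment's last aligned base and `b` that of the second segment's first
aligned base, the breakpoint **offset** is `b - a - 1`:

* offset `< 0`: **microhomology** — the same `-offset` molecule bases align
  to both reference breakpoints;
* offset `= 0`: **blunt** joint;
* offset `> 0`: **de novo insertion** of the intervening bases.

The distance between the two reference breakpoint positions defines the SV
size. Because aligners place shiftable junctions arbitrarily,
`canonicalize_offset()` extends both alignments to the first mismatch so
that the reported microhomology is maximal; this is idempotent, never
shortens a microhomology, and never converts a microhomology into an
insertion. The package stores everything on the reference forward ("top")
strand; transcription orientation of the captured gene is applied only when
reporting (`orient_to_transcription()` toggles a flag that swaps breakpoint
side labels — template strand labels are invariant under the flip, because
molecule and reference reverse-complement together).

## Filtering and coverage

De novo SVs that arose during the experimental window are expected in a
single molecule of a single sample. `filter_svs()` applies, in a fixed
order so rejection reasons are reproducible: uniqueness of the junction
across molecules and samples; at least 3 supporting read pairs (chimeric
PCR artifacts typically have one); mapping quality at least 30 on one side
and 20 on both; at least one breakpoint in an unpadded capture target with
both inside the 800 kb padded span; and per-type size windows (deletions
and duplications 10 kb – 1.2 Mb; inversions at least 50 kb, excluding the
small-inversion artifact class of transposase libraries).

Coverage weights samples by their ability to report junctions: molecules
with fewer than 3 read pairs are excluded, 2 × 20 bp of unalignable
terminal bases are subtracted from each remaining molecule, and the summed
adjusted lengths of on-target molecules are divided by the unpadded target
length (`compute_coverage()`). SV-carrying molecules are set aside — their
outer span covers the rearranged interval, not sequenced bases. SV
frequency is then junction count divided by fold-coverage, approximating
the fraction of sequenced target haplotypes carrying a de novo SV.
`breakpoint_density()` aggregates breakpoints in 5 kb bins and reports
coverage-normalized density only on bins with at least 500-fold adjusted
coverage (masked bins are `NA`, never zero; we use the adjusted rather than
raw track, a choice the source conventions leave open).

## Insertion-template discovery

Inserted bases plus their flanking microhomologies may identify a local
template. The query takes the inserted bases as they appear in the molecule
plus enough flanking bases for at least seven total and at least one per
side: 1 bp insertions get 3 flank bases per side, 4 bp get 2, 5 bp or more
get 1 (odd totals split by ceiling, so 2–3 bp insertions also get 3/2 per
side). `scan_templates()` searches for exact matches on both strands within
500 bp on each side of both breakpoints (4 kb in total), extends every
match's flanks to the first mismatch, and `select_template()` prefers the
longest extended span, then the smallest distance to the junction, with a
deterministic final tie-break (breakpoint 1, top strand, leftmost).

Classes follow strand and placement relative to retained/lost sequence
(defined for deletions; for duplications and inversions the same geometry
is reported with a low-confidence flag): **foldback** (bottom strand,
retained; subclassified **palindrome** when the extended template equals
its own reverse complement — an explicit operational stand-in for the
narrative palindrome definition), **cross-junction** (top strand,
retained), **strand-switching** (bottom strand, at least partly lost), and
**expansion** (top strand, crossing the breakpoint from retained into lost,
the geometry of a direct repeat expanded by one unit). Windows are measured
from canonicalized breakpoints.

## Statistics

**Template enrichment.** An n-base query matches a random 4 kb search space
at Poisson rate `mu = 4000 / 4^n`, so a junction yields at least one random
match with probability `1 - exp(-mu)`. Treating each searched junction of a
given insertion size as a Bernoulli trial, `enrichment_test()` reports the
upper binomial tail of the observed template yield; p < 0.05 is taken as
evidence for genuine local templating. The initial query length (not the
extended span) enters the rate, matching the quantity in the formula.

**Junction profiles.** `junction_profile()` reports the mean microhomology
of junctions without insertions (blunt joints count as zero) and the
fraction of all junctions with 2–15 bp insertions — two axes that separate
TMEJ-proficient from TMEJ-deficient repair.

**SV frequency comparison.** Counts are modeled as an overdispersed Poisson
via the negative binomial: `nSvs ~ group + batch + offset(log(coverage))`
(`MASS::glm.nb`), so the group coefficient is the log SV-frequency ratio.
The two-sided Wald p-value on that coefficient is reported, with p ≤ 0.01
as the conventional significance threshold. If the overdispersed fit fails
(non-convergence, or dispersion implying variance/mean below 1 + 1e-6) the
model refits as plain Poisson and is flagged `poisson_fallback`. A batch
perfectly confounded with group is dropped with a warning; batch contrasts
use the alphabetically first level as reference; no pseudocounts are ever
added, so zero-count groups propagate their instability with a warning.

A calibration note: with estimated dispersion the Wald test is slightly
liberal in small cohorts (in our null simulations, ~4% rejections at
nominal 1% with 6 samples per group) and essentially exact by 20 samples
per group. The calibration tests therefore simulate 20 samples per group;
the strict p ≤ 0.01 convention mitigates the small-cohort liberality in
practice.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, directly at the molecule/call level (no reads are simulated — the
generator stands in for the upstream capture pipeline whose output schema
it emits). Per sample, source molecules of 300–600 bp are placed in the
target until the configured mean adjusted coverage is reached; read-pair
counts follow a truncated geometric with ≥ 3 for ~96% of molecules so the
support filter sees both passing and failing records; SV counts are
negative binomial with mean = group rate × sample coverage and shape
`dispersionTheta`.

Every junction is **planted**: the reference is locally edited so the
requested structure is genuinely and maximally present — microhomology
bases really match both flanks with mismatches immediately beyond, and
templated insertions really occur at their recorded coordinates with
extension stopping exactly at the planted priming/resolving
microhomologies. Each plant is verified by a characterize/canonicalize
round-trip and retried with fresh draws if an edit would create a longer
accidental homology. This makes oracle tests exact: the analysis must
recover truth coordinates, not merely statistics. Junction neighbourhoods
are kept disjoint, and SVs are planted in a globally shuffled sample order
so that placement failures in a crowded target are exchangeable across
samples rather than biasing the samples generated last.

Defaults were chosen once to reproduce the empirical junction summaries of
replication-stress CFS deletions and are fully configurable: mechanism mix
62% microhomology / 12% blunt / 26% insertion with microhomology lengths
peaking at 2 bp; half of deletion insertions templated, with class weights
foldback 0.45, cross-junction 0.30, expansion 0.20, strand-switching 0.05
(strand-switching is described only as "rarer", so its weight is small and
configurable); template distances peaked under 20 bp; priming/resolving
microhomologies peaked at 2–3 bp; SV sizes log-normal with 200 kb median
truncated to 10 kb – 1.2 Mb; one 400 kb target (capture probes target the
central few hundred kb of CFS genes) padded by 800 kb in a 4 Mb genome.
The `POLQ_KO` mode emulates TMEJ-deficient repair: the microhomology peak
shifts to 1 bp and insertions of 3 bp or more nearly vanish; `NHEJ_like`
gives blunt-heavy, short-microhomology junctions. The default mean
coverage (100-fold) and the cohort sizes used in tests are desk-scale
choices — real experiments run ~20× deeper — chosen so the full suite
completes in minutes while leaving every rate estimable.

Planting constraints worth knowing: priming/resolving lengths are drawn
conditioned on being at least the query flank size (otherwise the plant
would be undiscoverable by construction); retained-side template distances
are at least the priming length + 2 so the template cannot overlap the
junction's own flank bases; templated insertions are planted only at
deletion junctions, where the class geometry is defined. Truth records for
expansion plants store the query-match coordinates (the extended span
absorbs additional repeat units by design).

## What passing tests do and do not show

The generator produces i.i.d. uniform reference sequence and exactly
planted junctions. Real genomes have repeats, homopolymers, and mappability
structure that raise the random template-match floor and can create
ambiguous multi-template hits; real pipelines also mis-place a fraction of
breakpoints in ways canonicalization cannot always repair. Passing the
planted-truth suites therefore demonstrates the correctness of the
algorithms under their stated definitions, not the biological error rate on
real data. The enrichment statistic in particular inherits the
uniform-composition assumption of its `4^-n` match rate; on real sequence
the observed random line should be taken from matched shuffled controls.

## Numerical and degenerate-input choices

Probability vectors must sum to 1 within 1e-9. All randomness derives from
one seed through R's Mersenne-Twister with pinned normal/sample kinds, so
cohort output is byte-identical per config. Homology extension treats any
non-ACGT base as a universal mismatch. Empty call sets produce explicit
empty-profile markers rather than zeros; coverage-masked density bins are
`NA`, never zero. Selection ties are broken deterministically as described
above. `filter_svs` records only the first failing rule per call, in the
documented order.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, meanCoverage = 20, nSamplesPerGroup = 4,
                  svRatePerHaplotype = c(A = 0.2, B = 1.0))
sim <- simulate_cohort(cfg)
out <- run_pipeline(sim$reference, sim$targets, sim$molecules, sim$calls,
                    sim$samples, outDir = "svj_out")
out$comparisonTable
junction_profile(out$kept)
head(out$enrichment)
```

The pipeline writes kept/rejected calls, coverage and density tracks, the
per-SV template table, per-size enrichment, per-sample profiles, frequency
comparisons, and a machine-readable run summary with per-stage counts so
filter conservation is auditable from the outputs alone.
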