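---
title: "Modelling droplet-based target enrichment: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling droplet-based target enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesasim)
```

## The workflow being modelled

Droplet-based target enrichment isolates intact, high-molecular-weight
genomic DNA fragments (~52 kb) in millions of emulsion droplets that each
carry a TaqMan PCR reaction. A droplet fluoresces only if one of its
fragments fully contains the ~100 bp assay amplicon — both primer sites must
sit on the same molecule. Fluorescent droplets are deflected into a
collection channel; their DNA is pooled, the dU-containing identification
amplicons are destroyed enzymatically, the pool is whole-genome amplified,
and 50-bp reads are sequenced. Because a positive droplet contributes its
whole fragment, each ~100 bp assay buys tens of kb of enriched flanking
sequence.

`mesasim` implements each stage as a seeded operation on explicit data
structures, plus the closed-form expectations that the simulation must
reproduce. The analytic layer is deliberately idealized (no merging, no WGA
dispersion, no false sorts); it serves as a design tool and as the oracle in
the package's simulation-equivalence tests.

## The stochastic model, stage by stage

**Fragmentation.** Each genome copy is tiled independently by a renewal
process of fragment lengths (fixed, or normal truncated at `min_len`). The
tiling phase of every copy is uniformly random, so breakpoints are
independent across copies — the stationary picture of physical shearing.
This matters: with a common phase, every copy would contribute the *same*
amplicon-containing fragment and the coverage peak around a probe would not
average to the triangular kernel below. A `phase = "zero"` option anchors
the tiling for didactic, deterministic examples. Total fragment bases equal
`n_copies × G` exactly; the boundary fragments of each copy are truncated.

**Encapsulation.** Per-droplet occupancy is Poisson: target and background
counts are drawn independently as `Pois(λ_t)` and `Pois(λ_b)`, which is
equivalent to drawing total occupancy `Pois(λ_t + λ_b)` with multinomial
type labels. Fragments are sampled from the pool without replacement when it
is large enough, and with replacement otherwise (recorded in the result), so
a desk-scale fragment pool can feed millions of droplets. A droplet is
TaqMan-positive iff it holds a fragment fully containing an amplicon
(boundary-touching fragments cannot amplify) and its PCR did not fail
(`pcr_failure_rate`). The positive fraction follows the digital-PCR law
`1 − e^{−λ_t}`.

**Fluorescence, merging, sorting.** Amplitudes are class-conditional
normals; PCR-failed positives draw from the negative class. A fraction
`merge_rate` of droplets is merged with an independently drawn partner
droplet (emulsion instability): the merged droplet carries both content
loads, twice the width, and the larger amplitude. A merged
negative-plus-positive droplet passes the gate and drags extra background
into the pool — the mechanism that keeps sorted purity below 100%. Note the
observable "merged fraction *of sorted* droplets" exceeds `merge_rate`,
because merging doubles a droplet's chance of containing a target. Sorting
collects droplets passing the amplitude threshold and width gate, plus
gate-negative droplets at `false_sort_rate`. The sorted-droplet purity (the
fraction of collected droplets truly containing a target) has the closed
form `p / (p + (1 − p) f)`; `calibrate_false_sort_rate()` inverts it, which
is how the pipeline reproduces a measured post-sort purity (e.g. 2.3% of
droplets positive before sorting, 87.6% after) when the instrument's
false-sort rate is not known directly.

**Amplicon removal and WGA.** Each collected fluorescing droplet contributes
`amplicon_copies` molecules of its ~100 bp amplicon; `remove_amplicons()`
scales them by a residual fraction (default 0 — complete enzymatic removal).
Multiple-displacement amplification is modelled abstractly as a per-fragment
integer copy number: lognormal with log-sd `σ_wga`, rescaled to mean 1,
rounded, floored at 1. This reproduces the two downstream signatures that
matter — duplicate reads and less uniform coverage — without modelling
polymerase kinetics.

**Sequencing.** Reads carry their true coordinates; there is no aligner, so
alignment rates and mapping artifacts are out of scope (FASTQ export exists
for users who want to run one). Molecules are sampled proportional to
`copies × (length − read_len + 1)`, i.e. uniformly over valid start
positions, so per-base coverage is proportional to molecule copy number.
Strands are uniform; per-base substitution errors are i.i.d. Planted
homozygous variants appear on every read, heterozygous ones on each read
independently with probability 1/2.

## The coverage kernel and fold enrichment

A fragment of fixed length `L` that covers the probe point covers the point
at distance `d` with probability `K(d) = max(0, 1 − |d|/L)`: the mean
coverage profile around a probe is a triangle of base `2L` whose full width
at half maximum is exactly `L`. The amplicon is treated as a point — the
error is `O(amplicon/L) ≈ 0.2%`. For a fragment-length distribution the
kernel is the length-biased mixture of triangles (longer fragments are more
likely to cover the probe).

Averaging the kernel over a probe-centered window of size `s` and dividing
by the genome-wide mean depth gives, for `s ≤ 2L`,

$$\mathrm{fold}(s) = \frac{G\,(s - s^2/4L)}{n\, s\,(1+\lambda_b)\,L}
  + \frac{\lambda_b}{1+\lambda_b},$$

saturating to `G/(n s (1+λ_b)) + λ_b/(1+λ_b)` for `s ≥ 2L` (continuous at
`s = 2L`). The factor `n` is the number of loci sharing one sorted pool:
each collected droplet carries a target for a given locus with probability
`1/n`. Two unit conventions are worth stating explicitly: *purity* is
defined over molecule counts while *fold enrichment* is defined over base
coverage; for a single fragment-length model the conversion factor `L`
cancels, which is why the two layers can cross-check each other. The
genome-wide mean in the denominator *includes* the target regions — the
paper-style alternative of excluding them would raise folds slightly; the
inclusive choice is conservative and simpler. These formulas are upper-bound
design tools: WGA dispersion, merged droplets, and false sorts all push the
realized fold below them, so measured folds from full pipeline runs are not
expected to reach the ideal values.

## Estimating fragment size from the coverage peak (FWHM)

`fwhm_fragment_size()` subtracts a baseline (genome-wide mean depth by
default), finds the profile maximum near the probe, and walks outward to the
first half-maximum crossing on each side with linear interpolation. Raw
per-base profiles from realistic runs carry sharp spikes (duplicate stacks,
WGA copy bursts) that defeat the half-maximum search, so the profile is
box-smoothed over 5 kb by default. A box of width `w` widens a triangular
peak's FWHM by exactly `w/4`; the estimator subtracts that bias, so on an
exact triangle the smoothed estimate is unbiased. The correction is
triangle-specific, which is the right model here; `smooth_w = NULL` gives
the raw profile for dense, low-noise data. Degenerate inputs error
explicitly: a flat profile has no peak (detected with a small tolerance
against floating-point residue), and a peak clipped at a chromosome end
reports which side lacks a crossing.

## Window statistics and the variant filter

Sliding windows default to 20 kb with a 2-kb step; tail windows shorter than
`w` are dropped, not rescaled (their count is recorded). The background
threshold is mean + 3×SD of window means with the sample (n−1) standard
deviation. The specificity scan reports windows at or above the minimum
coverage `X` in one track but below it in the other, merged into maximal
runs; `X = 56` is the configured default, and scaled-down runs should scale
`X` with their mean depth. Coverage uniformity uses at-or-above (`≥ d`)
counting by default, with a strict `> d` toggle.

The SNP caller is deliberately minimal: candidates need ≥ 2 reads supporting
one alternate base (ties broken alphabetically), quality is the phred-scaled
binomial tail `−10·log10 P[X ≥ alt | Bin(depth, ε)]` (capped at 10⁴ to avoid
log-underflow infinities), and a call PASSes only with depth ≥ 10, quality
≥ 10, and an allele fraction supporting a genotype (het in [0.2, 0.8],
hom-alt ≥ 0.8). Duplicates — reads sharing chromosome, start and strand —
are removed first, keeping a deterministic representative (sorted by
sequence as the final key), which makes calling invariant to read order.
What matters scientifically is the filter pair and the enrichment effect on
callable positions, not caller sophistication; quality values are not meant
to agree numerically with any production caller's genotype-likelihood model.

## Study conditions in the presets and their rationale

| Parameter | Default | Why |
|---|---|---|
| fragment length | 52,400 ± 5,706 bp, min 200 | encapsulated high-molecular-weight DNA scale |
| `λ_t` | 0.013085 | loading that yields a 1.3% positive-droplet rate |
| `λ_b` | `λ_t·(G/L − n)/n` | whole-genome DNA composition at the same dilution |
| droplet count | 10⁵ (desk), 2×10⁴ (test) | desk-scale stand-in for millions of droplets |
| `merge_rate` | 0.02 | emulsion-instability scale observed in sorted pools |
| `false_sort_rate` | calibrated to 87.6% sorted purity | measured observable; instrument rate unknown |
| `σ_wga` | 1 | MDA-scale copy dispersion (CV ≈ 1.3) |
| reads | 6×10⁵ × 50 bp (desk) | ~5× genome mean; locus peaks clear the 56× scan threshold |
| windows | 20 kb / 2 kb step | coverage-averaging scale for ~52 kb fragments |
| probe windows | 50–200 kb | the enrichment footprint of one fragment length |
| variant filters | depth ≥ 10, qual ≥ 10 | the hard filter pair under study |

The synthetic genome (5 Mb + 1 Mb chromosomes, 5 loci ≥ 200 kb apart,
i.i.d. uniform bases, planted SNPs at 10⁻³/bp) is a scaled stand-in for a
targeted region of a human chromosome. It emulates what the statistics need
— locus geometry, fragment-scale coverage structure, truth variants — and
nothing else: no repeats, GC structure, gene annotation, mappability, or
library-preparation sequence bias. Consequently, passing tests demonstrate
the internal consistency of the statistics and the simulator, not
performance on real sequencing data, where alignment artifacts and
transposase insertion bias add background structure this generator does not
produce.

## Problem sizes and numerical choices

The test suite runs paired pipeline instances at the "test" preset (2.5 Mb
genome, 2×10⁴ droplets, 1.5×10⁵ reads) and simulation-vs-analytics
equivalence at 10⁵ droplets on a 5 Mb genome over 20 seeds — sizes chosen so
the whole suite completes in minutes on one CPU while keeping Monte-Carlo
standard errors small enough for 3-SE comparisons to be informative.
Stochastic checks compare against independent oracles (binomial/Poisson
moments, brute-force per-base counting, hand algebra) at 3 standard errors;
exact checks (coverage conservation, window re-summation) use equality or
1e-9. Every stochastic stage derives a named substream from one global seed
(`substream_seed()`), so a stage can be re-run in isolation and a whole run
is bit-identical under a fixed configuration.

## Known limitations

- No aligner, no mapping ambiguity; alignment-rate style metrics are out of
  scope by design.
- PCR inside droplets is binary (fluoresce or fail); amplification
  efficiency and TaqMan chemistry are not modelled.
- WGA is a copy-number abstraction; chimera formation and branch artifacts
  of displacement amplification are absent.
- The caller handles biallelic SNVs only — no indels, no multi-allelic
  sites.
- `λ` values are back-calculated from observable positive fractions; actual
  genome-equivalents per droplet in any given experiment are not separately
  identifiable from those observables.
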