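---
title: "Calling and comparing promoter-super-enhancer interactomes from capture Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing promoter-super-enhancer interactomes from capture Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sehub)
library(data.table)
```

## The problem

Promoter-capture Hi-C (PCHi-C) enriches Hi-C libraries for ligation
products involving baited, promoter-containing restriction fragments,
yielding a sparse table of contact counts between each bait and the
other-end fragments of its chromosome. Super-enhancers (SEs) — stitched
clusters of enhancer peaks with exceptionally high ranked H3K27ac
density — are of particular interest because their promoter contacts can
span very large genomic distances and rewire between pluripotent cell
states. This package implements the statistics for that analysis: SE
calling, a negative-binomial background for fragment-level contacts, a
composite test over the fragments of a whole SE, control-region
construction, long-range classification, and cross-state comparison. A
synthetic-data generator with known ground truth underpins all testing.

All coordinates are 0-based half-open throughout; strand is ignored
(TSS positions are explicit inputs). Fragment ids are integers in genome
order, so a bait's genomic neighbours are `id ± 1` on its chromosome.

## SE calling

Enhancer peaks within `stitch_distance = 12500` bp of each other
(single-linkage over consecutive gaps) are stitched; peaks fully inside
a `tss_exclusion = 2000` bp window around a TSS are removed first —
partial overlappers are kept, following ROSE. Each stitched region is
scored by `treatment/treatment_library − input/input_library` summed
over constituent peaks and floored at zero. Regions are ranked by
density; with both rank and density rescaled to `[0, 1]`, the SE
threshold is the density at the first point (scanning from the low end)
where the forward-difference slope reaches 1. If the slope equals 1
exactly over a run of points (a perfectly linear stretch), the
highest-density point of the run is taken, which is the conservative
choice — a degenerate, perfectly linear curve yields zero SEs, as does a
constant curve (with a warning). Comparison tiers are taken from the
same ranking: the `tier_size` highest-density regions, the `tier_size`
highest-density regions below the SE threshold ("normal" enhancers), and
the `tier_size` lowest-ranked regions with positive density ("low"
enhancers; zero-density regions are indistinguishable from background
and are excluded).

## The contact background model

The expected count of a cis bait-fragment pair at midpoint distance `d`
is

```
mu(i, j) = f(d_ij) * s_i * s_j * m
```

* `f(d)`: mean count in ~20 log-spaced distance bins, evaluated at each
  bin's geometric-centre distance and linearly interpolated in log-log
  space (flat extrapolation beyond the outer bin centres; empty bins are
  merged into their neighbour). The bin mean is the moment estimator of
  the NB mean; a geometric mean of counts would be degenerate at zero
  counts, which dominate sparse capture data.
* `s_i`, `s_j`: multiplicative bait and other-end factors absorbing
  capture-efficiency variation, fitted by iterative proportional scaling
  of row/column totals (up to 200 iterations, stopping when the largest
  log-factor change falls below `1e-3` — a 0.1% factor error, far below
  sampling noise; non-convergence is an error), normalised to geometric
  mean 1 with the scale absorbed into `m`.
* `r`: negative-binomial dispersion (`var = mu + mu^2/r`), maximum
  likelihood over all pairs, including the zero pairs reconstructed by
  enumerating the full cis pair universe within `max_distance`
  (excluding each bait's own and adjacent fragments, the usual
  proximity-artifact exclusion).

**Outlier hold-out.** Genuine interactions would otherwise inflate the
factors of their other-end fragments — severely so when several enriched
baits contact the same small region, because the inflated factor then
hides the very signal that caused it. After the first fit, pairs whose
*leave-one-bait-out* p-value (own count removed from the other-end
total before forming the factor) falls below `outlier_p = 1e-4` are held
out and everything but the decay curve is refitted; this repeats until
the held-out set stabilises (≤ 6 passes). Final scoring uses the plain
fitted factors: held-out pairs are therefore scored against a background
that already excludes them, while retained (null) pairs keep the mildly
conservative correlation between their own count and their expected
value. Using leave-one-out expectations at scoring time as well was
rejected: it makes the expected value an independent noisy estimate,
and the convexity of the NB tail in its mean then visibly inflates the
null fraction of small p-values.

Replicates are combined before fitting: counts are scaled by library
size (mean total over replicates divided by the replicate's total),
summed per pair, and rounded. Note that the dispersion of a sum of `k`
i.i.d. NB replicates is `k·r`, so the fitted `r` on pooled data is
expected to be about `n_replicates` times the per-replicate value.

## Per-fragment and composite tests

The one-tailed p-value of an observed count is the inclusive upper NB
tail `P(X >= N_obs)` with mean `N_exp` and dispersion `r`; `N_obs = 0`
gives `p = 1`. For a composite promoter-SE test, constituent fragments
are all fragments overlapping the SE span minus the bait and its two
immediate neighbours ("adjacent fragments" is read as exactly the two
genomic neighbours); observed and expected counts are summed over
constituents and the same NB tail is applied with the fitted dispersion.
The NB-with-summed-mean null treats the sum of NB variables as NB with
the same `r`; this follows the stated procedure and is slightly
conservative (the true variance of the sum is smaller than
`M + M²/r` at fixed total mean), which the Monte-Carlo oracle in the
test suite quantifies. Pairs whose constituent set is empty (bait inside
or adjacent to the region) are skipped and logged, not errors; only cis
pairs are tested, and SEs overlapping any baited fragment are filtered
out before testing so bait-to-bait signal is not misread as
promoter-enhancer contact.

P-values are weighted by `w(d) = (1 + d/3e5)^-0.4`, normalised to mean 1
over the tested set (weighting redistributes stringency across distance
without changing the average), clamped at 1 after division, and
transformed to `score = max(0, -ln(weighted p))`. A score of 5 —
weighted p ≈ 6.7e-3 — is the high-confidence threshold. Because the
weights average 1, the null rate of score ≥ 5 calls is about 0.5-0.7%
of tested pairs; comparative statistics must therefore rest on designs
where true signal dominates this floor. Per-fragment calls additionally
support the replicate-consensus rule: combined score ≥ 5, or combined
score in [4, 5) with one own replicate above 5 and every replicate of
every other cell state at or below 5.

## Control regions

Three constructions, all deterministic given a seed:

* **Shuffle.** Each SE is re-placed uniformly within its chromosome,
  keeping its length, rejecting placements overlapping previously placed
  controls — and, by default, the source SEs themselves, which keeps the
  control set signal-free (configurable).
* **Size-extension.** Each "normal"/"low" enhancer seed is assigned to
  an SE by a random bijection and extended symmetrically from the
  midpoint of the fragment containing the seed's midpoint until it
  matches the SE length; candidates sharing a fragment with any SE (or
  running off the chromosome) are discarded and replaced from the pool.
* **Distance match.** For each significant promoter-SE contact, a
  control of identical span and identical constituent-fragment count is
  placed at the same bait distance within a ±5% band, trying candidate
  midpoints on both sides of the bait in random order (random order
  keeps accepted distances unbiased inside the band); contacts with no
  valid placement are skipped and logged.

## Distances and long-range classes

Distance is `|(a+b)/2 − (c+d)/2|` between the interval midpoints —
bait fragment to region span for composite contacts. Long-range
interactions (LRIs) are contacts with distance strictly greater than
800 kb; the threshold may instead be derived as the type-7 empirical
quantile exceeded by a chosen fraction (default 25%) of contacts. SEs
with at least one significant contact are classed short-only, long-only
or both; hub statistics bin per-SE promoter counts (1, 2-5, 6-10, ≥ 11)
and per-promoter SE counts.

## Comparative statistics

LRI-proportion differences between states use Pearson's chi-square of
independence without continuity correction (the tables of interest have
hundreds of counts, where the correction is immaterial; it is exposed as
an argument). P-values are Benjamini-Hochberg adjusted within each
analysis family. Rank comparisons of expression use the two-sided
Mann-Whitney U test, exact by enumeration when both groups have ≤ 8
untied values, otherwise the normal approximation with tie correction;
two all-tied groups give p = 1. TF binding classifies each contact end
as bound iff a peak overlaps the bait fragment (bait end) or any
constituent fragment (other end), giving four exclusive categories.

## The synthetic-data generator

The generator emulates the statistical structure of a PCHi-C study,
not its sequence content:

* **Genome.** Shifted-geometric fragment lengths (mean 4 kb, the
  HindIII scale; minimum 200 bp); baits sampled uniformly; TSSs at bait
  fragment midpoints.
* **Enhancer landscape.** Clusters of 1-5 peaks with intra-cluster gaps
  below 12.5 kb and > 30 kb between clusters, clear of TSS windows, so
  stitching reconstitutes exactly the generated clusters. Cluster
  signal is log-normal; `n_true_se` designated clusters are amplified by
  `se_signal_scale × Pareto(signal_tail_exponent)` — a heavy tail with a
  hard floor. The floor makes the truth identifiable: on a scale-free
  continuum no inflection rule can match an arbitrary cutoff, so truth
  is defined by design (designation), not by thresholding a realisation.
  A heavier tail makes SE signal stochastically larger; it does not
  change how many true SEs exist.
* **Contacts.** `count ~ NB(mean = decay_scale · (d/100kb)^-alpha · s_i
  · s_j, dispersion r)` over the enumerated cis pairs; log-normal
  factors (sdlog 0.25) mimic capture-efficiency variation; replicates
  are i.i.d. A pure power-law decay (rather than a piecewise fit) keeps
  closed-form oracles available. Planted promoter-SE contacts multiply
  the mean by `fold_enrichment` (default 8× — a free simulation
  parameter chosen to represent a strong regulatory contact; no
  published effect size exists for it) for all bait x SE-fragment pairs,
  with per-state long-range fractions (defaults 25% and 7%) and at most
  `max_planted_per_se` planted baits per SE, keeping hubs small relative
  to the bait pool covering a region — dense planting at desk scale
  would make enrichment and capture efficiency unidentifiable in a way
  genome-scale data are not.
* **Binding and expression.** A "NANOG-like" factor binds SEs holding a
  planted long-range contact with probability 0.86 and other SEs at
  0.58 (rates implied by published binding tables), baits at 0.35, plus
  scattered noise peaks; binding is drawn per region, so states sharing
  an SE see consistent occupancy. Expression is normal on the log2
  scale with a +1 uplift at promoters holding a planted contact.

What the generator does **not** emulate: mappability and GC artifacts,
copy-number variation, trans contacts, the read level (FASTQ), and
CHiCAGO's technical-noise component (the null here is purely Brownian
NB, matching the composite test being validated). Passing tests
therefore demonstrate the statistical machinery under the stated model,
not robustness to those artifacts.

## Study designs used by the test suite

The simulation-based checks each fix one experimental design and vary
seeds:

* *Calibration* (uniformity of null p-values): one 20 Mb chromosome,
  280 baits, contacts to 1.6 Mb at depth 400 (mean count at 100 kb),
  `alpha = 0.8`, `r = 8`, one replicate — about 180,000 pairs with means
  of roughly 50-900. The depth is chosen so the discrete NB null is
  near-continuous: the inclusive tail p-value is super-uniform by
  construction, and at shallow depth the attainable fraction below 0.05
  is far from nominal for purely arithmetic reasons, which would make a
  uniformity check meaningless. The fraction is evaluated on a 10,000
  pair subsample against the exact binomial 99% interval.
* *Parameter recovery*: ~96,000 null pairs (one replicate), decay slope
  within ±0.1 and dispersion within ±20%.
* *Power*: 8 Mb chromosome, 40 baits, depth 30, ten planted contacts at
  8×; sensitivity among planted contacts with summed expected count ≥ 5,
  aggregated over 50 seeds.
* *Rewiring*: 40 Mb chromosome, 180 baits, 8 kb fragments, depth 15,
  60 true SEs, 140 planted contacts per state (≤ 3 per SE), long
  fractions 25% vs 7%; twenty seeds for the contrast and twenty for an
  equal-fraction null arm.

These sizes keep the full suite within a desktop-scale run while leaving
each check statistically meaningful; the vignette states them as the
package's chosen designs.

## Known limitations

* The background has no technical-noise component; counts from
  re-ligation or mapping artifacts would be read as signal. Upstream
  filtering is assumed.
* The composite null's NB-with-summed-mean approximation is
  conservative for many-fragment regions.
* The score ≥ 5 rule is a fixed operating point, not an FDR guarantee;
  its null call rate is ~0.5% of tested pairs, which matters whenever
  the true-signal density is low.
* Other-end factors are per-fragment; on very sparse data they are
  noisy, and the calibration of extreme tail p-values degrades
  accordingly.
```{r session}
sessionInfo()
```
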