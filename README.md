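# sehub

Promoter-capture Hi-C (PCHi-C) measures physical contacts between baited
promoter-containing restriction fragments and the rest of the genome at
single-fragment resolution. `sehub` implements the downstream statistics
needed to map which gene promoters are wired to **super-enhancers (SEs)**,
how far those contacts reach, and how the wiring changes between cell
states (e.g. naive versus primed pluripotency, or wild-type versus
knockout cells). It is aimed at computational biologists analysing
fragment-level capture Hi-C count tables together with H3K27ac ChIP-seq
peaks, TF peaks and expression tables.

## What it computes

* **SE calling (ROSE-style).** H3K27ac peaks within 12.5 kb are stitched
  (peaks fully inside a 2 kb TSS exclusion window are dropped first),
  stitched regions are scored by input-subtracted, library-normalised
  signal, ranked, and thresholded at the point where the tangent slope of
  the rank/density curve (both axes scaled to [0, 1]) first reaches 1;
  regions above the threshold are SEs. Comparison tiers (top-ranked SEs,
  "normal" and "low" enhancers) are selected from the same ranking.

* **Background model.** The expected ("Brownian") count of a cis
  bait-fragment pair is `f(d) · s_i · s_j · m`: a distance-decay curve
  estimated in log-spaced bins, multiplicative bait and other-end
  capture factors fitted by iterative proportional scaling (with
  iterative hold-out of outlying pairs so real interactions do not
  inflate the background), and a negative-binomial dispersion `r`
  (`var = mu + mu²/r`) fitted by maximum likelihood.

* **Composite SE interaction test.** For a promoter-SE pair, all
  restriction fragments overlapping the SE are concatenated (excluding
  the bait and its adjacent fragments); the observed count is the total
  across constituents and the expected count is the sum of per-fragment
  expectations. The one-tailed p-value is the upper NB tail
  `P(X >= N_obs)` at mean `N_exp` and the fitted dispersion; p-values
  are distance-weighted, converted to scores `-ln(weighted p)`, and
  calls use the CHiCAGO-style threshold **score ≥ 5** (with a ≥ 4
  replicate-rescue rule for per-fragment calls).

* **Controls.** Within-chromosome shuffles (length- and
  chromosome-preserving, non-overlapping), enhancer regions size-extended
  from fragment midpoints to match assigned SE lengths, and controls
  matched for fragment count and bait distance (±5%).

* **Long-range interactions (LRIs).** Distance is
  `|(a+b)/2 − (c+d)/2|` between interval midpoints; contacts spanning
  **> 800 kb** are long-range (the threshold can also be derived as the
  quantile exceeded by a chosen fraction of contacts). Per-SE engagement
  classes (short-only / long-only / both), hub statistics, chi-square
  tests of LRI proportions between states with Benjamini-Hochberg
  adjustment, TF-binding classification of interaction ends, and
  Mann-Whitney expression comparisons complete the comparative layer.

* **Synthetic data.** A fully specified generator produces fragment
  maps, heavy-tailed enhancer landscapes with designated true SEs,
  NB-distributed distance-decaying contact counts with planted
  promoter-SE contacts (configurable fold enrichment and per-state
  long-range fractions), TF peaks co-occupying planted long-range
  contacts, and expression uplifted at contacted promoters — so every
  stage is testable against known ground truth.

## Worked example

```r
library(sehub)

cfg <- pipeline_config(
  seed = 3,
  sim = sim_config(chrom_sizes = c(chr1 = 1.2e7, chr2 = 8e6), n_baits = 70,
                   n_enhancer_peaks = 240, n_true_se = 10, n_planted = 16,
                   max_distance = 2e6, decay_scale = 25, n_replicates = 2),
  se = se_config(tier_size = 12))
res <- run_full_pipeline(cfg, "run1")

sum(res$se$called$is_SE)
#> [1] 10
res$per_cell_type$escLike$background
#> <chic_background> 20 decay bins (log-log slope -0.99), 70 bait / 5023
#> other-end factors, dispersion r = 23.26, scale m = 0.904
res$comparison$lri_fraction
#>    escLike    epiLike
#> 0.25000000 0.05882353
```

The ten planted true SEs all clear the ranked-density inflection; the
fitted decay slope recovers the simulated power law (−1), and the
dispersion fitted on the pooled replicates exceeds the per-replicate
value of 8, as expected when two independent NB replicates are summed
(the sum of two i.i.d. NB(mu, r) variables has dispersion 2r; factor
fitting absorbs a little more). Among significant promoter-SE contacts,
25% span > 800 kb in the "escLike" state versus ~6% in the "epiLike"
state, recovering the planted long-range rewiring. `run1/` contains every stage table
(`stitched_enhancers.tsv`, `composite_<state>.tsv`, `regions.bed`, the
synthetic inputs under `data/`) plus `manifest.json` with seeds and the
config hash; re-running with the same config reproduces the tables
byte-for-byte.

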