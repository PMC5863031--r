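# Shared study configurations for the simulation-based checks.
# Each is a fixed experimental design (genome scale, sequencing depth,
# planted-signal density); seeds vary per test.

# Deeply sequenced null: counts large enough that the discrete NB null is
# near-continuous, making the p-value uniformity check meaningful.
calibration_config <- function(seed) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 2e7), n_baits = 280,
             n_enhancer_peaks = 60, n_true_se = 5, n_planted = 0,
             max_distance = 1.6e6, decay_scale = 400, decay_exponent = 0.8,
             dispersion = 8, n_replicates = 1)
}

# Parameter-recovery design: ~1e5 cis pairs, moderate depth.
recovery_config <- function(seed) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 2e7), n_baits = 100,
             n_enhancer_peaks = 60, n_true_se = 5, n_planted = 0,
             max_distance = 2e6, decay_scale = 40, decay_exponent = 1.0,
             dispersion = 8, n_replicates = 1)
}

# Power design: planted promoter-SE contacts at the default 8x enrichment.
power_config <- function(seed) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 8e6), n_baits = 40,
             n_enhancer_peaks = 150, n_true_se = 8, n_planted = 10,
             max_distance = 2e6, decay_scale = 30, dispersion = 8,
             n_replicates = 1, lri_fraction = c(escLike = 0.25, epiLike = 0.07))
}

# Two-cell-state rewiring design: planted long-range fractions per state.
lri_config_sim <- function(seed, fractions = c(escLike = 0.25, epiLike = 0.07)) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 4e7), n_baits = 180,
             n_enhancer_peaks = 800, n_true_se = 60, n_planted = 140,
             max_planted_per_se = 3, max_distance = 2e6,
             mean_fragment_length = 8000, decay_scale = 15, dispersion = 8,
             n_replicates = 1, lri_fraction = fractions)
}

# Run one cell state of an LRI experiment: fit, composite-call over the
# true SEs, classify ranges; returns the significant set and truth.
run_lri_cell_type <- function(ds, ct) {
  regions <- ds$truth$clusters[is_true_se == TRUE,
                               .(region_id = cluster, chrom, start, end,
                                 source_label = "SE")]
  bait_ids <- data.table::as.data.table(ds$fragmap)[is_bait == TRUE, id]
  cc <- ds$contacts[[ct]]$rep1
  bg <- fit_background(cc, ds$fragmap, max_distance = ds$config$max_distance)
  comp <- classify_range(call_composite_interactions(bait_ids, regions, cc,
                                                     bg, ds$fragmap))
  list(comp = comp, sig = comp[significant == TRUE],
       planted = ds$truth$planted[cell_type == ct])
}

# Landscape-only simulation + ROSE calling; returns called and true SE sets.
run_se_calling <- function(seed) {
  cfg <- sim_config(seed = seed, chrom_sizes = c(chr1 = 2e7), n_baits = 60,
                    n_enhancer_peaks = 600, n_true_se = 20, n_planted = 0)
  fm <- simulate_genome(cfg)
  peaks <- simulate_enhancer_landscape(cfg, fm)
  st <- stitch_peaks(peaks, simulated_tss(fm)[, .(chrom, pos)], se_config())
  sc <- score_stitched(st, library_sizes = attr(peaks, "library_sizes"))
  called <- call_super_enhancers(sc)
  list(called = called, truth = attr(peaks, "truth"))
}

# Jaccard between called SE regions and true SE cluster spans, matching
# by genomic overlap.
se_jaccard <- function(called, truth) {
  called_se <- called[is_SE == TRUE]
  true_se <- truth[is_true_se == TRUE]
  if (!nrow(called_se) && !nrow(true_se)) return(1)
  if (!nrow(called_se) || !nrow(true_se)) return(0)
  ov <- find_overlaps(called_se[, .(chrom, start, end)],
                      true_se[, .(chrom, start, end)])
  inter <- length(unique(ov$query))
  extra_true <- nrow(true_se) - length(unique(ov$subject))
  inter / (nrow(called_se) + extra_true)
}
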