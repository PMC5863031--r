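small_cfg <- function(seed = 1) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 6e6, chr2 = 4e6), n_baits = 30,
             n_enhancer_peaks = 90, n_true_se = 6, n_planted = 6,
             max_distance = 1.5e6, decay_scale = 30, dispersion = 8,
             n_replicates = 2)
}

test_that("the generator is fully deterministic given its config", {
  d1 <- simulate_dataset(small_cfg())
  d2 <- simulate_dataset(small_cfg())
  expect_identical(d1$fragmap, d2$fragmap)
  expect_identical(d1$enhancer_peaks, d2$enhancer_peaks)
  expect_identical(d1$contacts, d2$contacts)
  expect_identical(d1$tf_peaks, d2$tf_peaks)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth$planted, d2$truth$planted)
  # a different seed changes realisations
  d3 <- simulate_dataset(small_cfg(seed = 2))
  expect_false(identical(d1$contacts, d3$contacts))
})

test_that("simulated genomes have the expected fragment statistics", {
  cfg <- sim_config(seed = 5, chrom_sizes = c(chr1 = 1e7),
                    mean_fragment_length = 4000, n_baits = 10)
  fm <- simulate_genome(cfg)
  expect_silent(validate_fragment_map(fm))
  # mean 4 kb on 10 Mb: ~2500 fragments, sd ~ sqrt(2500) * cv(length) ~ 50
  expect_lt(abs(nrow(fm) - 2500), 150)
  expect_equal(sum(fm$is_bait), 10L)

  # boundary: every fragment baited
  cfg2 <- sim_config(seed = 5, chrom_sizes = c(chr1 = 1e5),
                     mean_fragment_length = 5000, n_baits = 1)
  fm2 <- simulate_genome(cfg2)
  cfg2$n_baits <- nrow(fm2)
  fm3 <- simulate_genome(cfg2)
  expect_true(all(fm3$is_bait))
  cfg2$n_baits <- nrow(fm2) + 1000
  expect_error(simulate_genome(cfg2), "exceeds fragment count")
})

test_that("enhancer landscapes separate designated SEs and respect stitching", {
  cfg <- small_cfg()
  fm <- simulate_genome(cfg)
  pk <- simulate_enhancer_landscape(cfg, fm)
  truth <- attr(pk, "truth")
  expect_equal(sum(truth$is_true_se), cfg$n_true_se)
  # stitching at 12.5 kb reconstitutes exactly the generated clusters
  st <- stitch_peaks(pk, simulated_tss(fm)[, .(chrom, pos)], se_config())
  expect_equal(nrow(st), nrow(truth))
  # determinism of peak coordinates
  pk2 <- simulate_enhancer_landscape(cfg, fm)
  expect_identical(pk$start, pk2$start)
  # heavier amplification tail gives stochastically larger top signal
  med_max <- function(expo) {
    median(vapply(1:12, function(s) {
      c2 <- small_cfg(seed = 100 + s); c2$signal_tail_exponent <- expo
      p <- simulate_enhancer_landscape(c2, fm)
      max(p$treatment - p$input)
    }, numeric(1)))
  }
  expect_gt(med_max(0.8), med_max(3))
})

test_that("null contact counts follow the configured NB distance decay", {
  cfg <- sim_config(seed = 11, chrom_sizes = c(chr1 = 1.2e7), n_baits = 60,
                    n_enhancer_peaks = 30, n_true_se = 3, n_planted = 0,
                    max_distance = 2e6, decay_scale = 30, decay_exponent = 1,
                    dispersion = 8, n_replicates = 1)
  fm <- simulate_genome(cfg)
  ct <- simulate_contacts(cfg, fm, NULL)
  cc <- ct[[1]]$rep1
  expect_true(all(cc$count > 0))          # sparse: zeros dropped
  tf <- attr(ct, "factors")
  pairs <- enumerate_cis_pairs(fm, 2e6)
  pairs <- merge(pairs, cc, by = c("bait_id", "oe_id"), all.x = TRUE)
  pairs[is.na(count), count := 0]
  # log-log regression of binned means on distance recovers -alpha
  pairs[, bin := cut(log(distance), 15)]
  bm <- pairs[, .(m = mean(count), d = exp(mean(log(distance)))), by = bin][m > 0]
  slope <- coef(lm(log(m) ~ log(d), bm))[2]
  expect_lt(abs(slope - (-1)), 0.1)
  # variance/mean consistent with NB dispersion: Pearson-type moment on true mu
  mu <- 30 * (pairs$distance / 1e5)^(-1) *
    tf$s_bait[as.character(pairs$bait_id)] * tf$s_oe[as.character(pairs$oe_id)]
  inv_r <- mean(((pairs$count - mu)^2 - mu) / mu^2)
  expect_lt(abs(inv_r - 1 / 8), 0.03)
})

test_that("planted contacts are cis, capped, and fold-enriched", {
  ds <- simulate_dataset(small_cfg())
  pl <- ds$truth$planted
  fm <- data.table::as.data.table(ds$fragmap)
  expect_true(all(fm$chrom[match(pl$bait_id, fm$id)] == pl$chrom))
  expect_true(all(pl[, .N, by = .(cell_type, cluster)]$N <=
                    small_cfg()$max_planted_per_se))
  # planted pairs carry visibly more counts than the background mean
  cc <- ds$contacts$escLike$rep1
  p1 <- ds$truth$planted[cell_type == "escLike"][1]
  frs <- fm[chrom == p1$chrom & start < p1$end & end > p1$start, id]
  obs <- cc[bait_id == p1$bait_id & oe_id %in% frs, sum(count)]
  mu_null <- sum(30 * (abs((fm[id == p1$bait_id, (start + end) / 2]) -
                             fm[id %in% frs, (start + end) / 2]) / 1e5)^(-1))
  expect_gt(obs, 2 * mu_null)  # 8x enrichment minus factor noise
  # a planted trans pair is rejected
  bad <- data.table::copy(pl[1])[, chrom := setdiff(names(small_cfg()$chrom_sizes),
                                                    chrom)[1]]
  expect_error(simulate_contacts(small_cfg(), ds$fragmap, bad), "trans")
})

test_that("fold_enrichment = 1 reproduces the pure null", {
  cfg <- small_cfg()
  ds_null <- simulate_contacts(cfg, simulate_genome(cfg), NULL)
  pl <- plant_contacts(cfg, simulate_genome(cfg),
                       attr(simulate_enhancer_landscape(cfg, simulate_genome(cfg)),
                            "truth"))
  pl[, fold := 1]
  ds_flat <- simulate_contacts(cfg, simulate_genome(cfg), pl)
  expect_identical(ds_null$escLike$rep1, ds_flat$escLike$rep1)
})

test_that("binding and expression carry the planted structure", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  expect_true(nrow(ds$tf_peaks) > 0)
  expect_equal(names(ds$expression), c("gene", "escLike", "epiLike"))
  # determinism
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$tf_peaks, ds2$tf_peaks)
  # with certain co-occupancy every long-planted SE end is bound
  cfg3 <- small_cfg(); cfg3$tf_cooccupancy_prob <- 1; cfg3$tf_base_rate <- 0
  fm <- simulate_genome(cfg3)
  pk <- simulate_enhancer_landscape(cfg3, fm)
  truth <- attr(pk, "truth")
  pl <- plant_contacts(cfg3, fm, truth)
  be <- simulate_binding_and_expression(cfg3, fm, truth, pl)
  long_se <- truth[cluster %in% pl[true_long == TRUE, cluster]]
  if (nrow(long_se)) {
    ov <- find_overlaps(long_se[, .(chrom, start, end)],
                        be$tf_peaks[, .(chrom, start, end)])
    expect_equal(length(unique(ov$query)), nrow(long_se))
  }
  # expression uplift at contacted promoters
  cfg4 <- small_cfg(); cfg4$expr_uplift_log2 <- 5
  ds4 <- simulate_dataset(cfg4)
  pl4 <- ds4$truth$planted[cell_type == "escLike"]
  fm4 <- data.table::as.data.table(ds4$fragmap)
  contacted <- fm4[id %in% pl4$bait_id, genes]
  others <- setdiff(ds4$expression$gene, contacted)
  expect_gt(mean(ds4$expression[gene %in% contacted, escLike]),
            mean(ds4$expression[gene %in% others, escLike]) + 2)
})

test_that("datasets write to disk in the documented dialects", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg())
  write_synthetic_dataset(ds, dir)
  fm <- read_fragment_map(file.path(dir, "fragments.tsv"))
  expect_equal(nrow(fm), nrow(ds$fragmap))
  bm <- read_baitmap(file.path(dir, "baitmap.tsv"))
  expect_equal(nrow(bm), sum(ds$fragmap$is_bait))
  cc <- read_contacts(file.path(dir, "contacts_escLike_rep1.tsv"))
  expect_equal(cc, ds$contacts$escLike$rep1[, .(bait_id, oe_id, count)])
  expect_true(file.exists(file.path(dir, "truth", "planted.tsv")))
})
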