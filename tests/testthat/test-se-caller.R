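mk_peaks <- function(starts, ends, chrom = "chr1", treatment = 100, input = 10) {
  genomic_intervals(chrom, starts, ends,
                    name = paste0("p", seq_along(starts)),
                    treatment = rep_len(treatment, length(starts)),
                    input = rep_len(input, length(starts)))
}

test_that("peaks within the stitch distance merge; beyond it they do not", {
  pk <- mk_peaks(c(100, 5000), c(200, 5100))   # gap 4800 <= 12500
  st <- stitch_peaks(pk, tss = NULL)
  expect_equal(nrow(st), 1L)
  expect_equal(c(st$start, st$end), c(100, 5100))

  pk2 <- mk_peaks(c(100, 20300), c(200, 20400)) # gap 20100 > 12500
  expect_equal(nrow(stitch_peaks(pk2, tss = NULL)), 2L)

  # chained single-linkage: consecutive gaps each <= 12.5 kb merge the chain
  pk3 <- mk_peaks(c(0, 10000, 20000, 45000), c(500, 10500, 20500, 45500))
  st3 <- stitch_peaks(pk3, tss = NULL)
  expect_equal(nrow(st3), 2L)
  expect_equal(st3$n_peaks, c(3L, 1L))
})

test_that("peaks fully inside a TSS exclusion window are removed first", {
  pk <- mk_peaks(c(900, 8000), c(1100, 8300))
  tss <- data.table::data.table(chrom = "chr1", pos = 1000)
  st <- stitch_peaks(pk, tss = tss)
  expect_equal(nrow(st), 1L)
  expect_equal(st$start, 8000)
  # a peak only partially overlapping the window is kept
  pk2 <- mk_peaks(1500, 3500)
  expect_equal(nrow(stitch_peaks(pk2, tss = tss)), 1L)
})

test_that("stitching is idempotent and order-invariant", {
  set.seed(3)
  n <- 80
  s <- sort(sample(1e6, n)) ; pk <- mk_peaks(s, s + sample(300, n))
  st <- stitch_peaks(pk, tss = NULL)
  # stitched regions are pairwise separated by more than the stitch distance
  gaps <- st[order(chrom, start), start[-1] - end[-.N], by = chrom]$V1
  expect_true(all(gaps > 12500))
  # stitching the stitched spans changes nothing
  st2 <- stitch_peaks(st[, .(chrom, start, end, treatment = 1, input = 0)], tss = NULL)
  expect_equal(st2[, .(chrom, start, end)], st[, .(chrom, start, end)])
  # input order invariance
  stsh <- stitch_peaks(pk[sample(nrow(pk))], tss = NULL)
  expect_equal(stsh[, .(chrom, start, end)], st[, .(chrom, start, end)])
})

test_that("stitched regions score by library-normalised input subtraction", {
  pk <- mk_peaks(c(100, 30000), c(200, 30100), treatment = c(100, 70), input = c(20, 70))
  st <- stitch_peaks(pk, tss = NULL)
  sc <- score_stitched(st, library_sizes = c(treatment = 1, input = 1))
  expect_equal(sc$density, c(80, 0))       # input == treatment floors at 0
  # additivity over constituents
  pk2 <- mk_peaks(c(0, 2000), c(1000, 3000), treatment = c(60, 40), input = c(10, 10))
  sc2 <- score_stitched(stitch_peaks(pk2, tss = NULL),
                        library_sizes = c(treatment = 2, input = 1))
  expect_equal(sc2$density, (60 + 40) / 2 - (10 + 10) / 1)
  # missing signal errors with the region named
  pk3 <- mk_peaks(100, 200); pk3$treatment <- NA_real_
  expect_error(score_stitched(stitch_peaks(pk3, tss = NULL)), "chr1:100-200")
})

test_that("the inflection threshold isolates the heavy tail", {
  reg <- data.table::data.table(region_id = 1:5, chrom = "chr1",
                                start = (0:4) * 1e5, end = (0:4) * 1e5 + 1e4,
                                density = c(1, 1, 1, 1, 50))
  called <- call_super_enhancers(reg)
  expect_equal(called[is_SE == TRUE, density], 50)
  expect_equal(sum(called$is_SE), 1L)
  expect_equal(sort(called$rank_), 1:5)

  # perfectly linear curve: slope is exactly 1 everywhere -> zero SEs
  lin <- data.table::copy(reg)[, density := 1:5]
  expect_equal(sum(call_super_enhancers(lin)$is_SE), 0L)

  # all equal densities: zero SEs with a warning
  flat <- data.table::copy(reg)[, density := 7]
  expect_warning(out <- call_super_enhancers(flat), "equal")
  expect_equal(sum(out$is_SE), 0L)

  # order invariance
  shuf <- reg[c(3, 5, 1, 4, 2)]
  expect_equal(sort(call_super_enhancers(shuf)[is_SE == TRUE, region_id]),
               sort(called[is_SE == TRUE, region_id]))

  # monotonicity: raising a density never demotes it
  set.seed(9)
  base <- data.table::data.table(region_id = 1:40, chrom = "chr1",
                                 start = (1:40) * 1e5, end = (1:40) * 1e5 + 1e4,
                                 density = c(rlnorm(36, 0, 0.3), 40, 55, 70, 90))
  c0 <- call_super_enhancers(base)
  for (k in c0[is_SE == TRUE, region_id]) {
    up <- data.table::copy(base)[region_id == k, density := density * 2]
    expect_true(call_super_enhancers(up)[region_id == k, is_SE])
  }
})

test_that("enhancer tiers are disjoint and sized as configured", {
  set.seed(4)
  n <- 750
  reg <- data.table::data.table(region_id = 1:n, chrom = "chr1",
                                start = (1:n) * 2e4, end = (1:n) * 2e4 + 1e4,
                                density = c(rlnorm(n - 20, 0, 0.5), rlnorm(20, 4, 0.3)))
  called <- call_super_enhancers(reg)
  tiers <- select_enhancer_tiers(called, se_config(tier_size = 250))
  expect_equal(vapply(tiers, nrow, integer(1)),
               c(SE_top = 250L, NE = 250L, LE = 250L))
  ids <- lapply(tiers, `[[`, "region_id")
  expect_equal(length(intersect(ids$SE_top, ids$NE)), 0L)
  expect_equal(length(intersect(ids$SE_top, ids$LE)), 0L)
  expect_equal(length(intersect(ids$NE, ids$LE)), 0L)
  expect_true(all(tiers$NE$is_SE == FALSE))
  expect_true(all(tiers$LE$density > 0))

  t1 <- select_enhancer_tiers(called, se_config(tier_size = 1))
  expect_equal(t1$SE_top$density, max(called$density))
  expect_equal(t1$NE$density, called[is_SE == FALSE, max(density)])
  expect_error(select_enhancer_tiers(called, se_config(tier_size = 300)),
               "900")
})

test_that("called SEs recover the designated landscape truth", {
  jc <- vapply(1:3, function(s) {
    r <- run_se_calling(s)
    se_jaccard(r$called, r$truth)
  }, numeric(1))
  expect_gte(mean(jc), 0.9)
})
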