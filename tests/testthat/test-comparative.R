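test_that("interactome comparison partitions gene sets exactly", {
  cmp <- compare_interactomes(list(wt = c("A", "B", "C"), ko = c("B", "C", "D")))
  expect_setequal(cmp$shared, c("B", "C"))
  expect_setequal(cmp$specific$wt, "A")
  expect_setequal(cmp$specific$ko, "D")
  expect_equal(length(cmp$shared) + sum(lengths(cmp$specific)),
               length(cmp$union))
  same <- compare_interactomes(list(a = c("X", "Y"), b = c("Y", "X")))
  expect_equal(lengths(same$specific), c(a = 0L, b = 0L))
})

test_that("chi-square of independence matches the closed form", {
  flat <- chisq_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  # hand-computed Pearson statistic on a published-scale binding table
  m <- matrix(c(284, 46, 574, 414), 2, 2, byrow = TRUE)
  res <- chisq_independence(m)
  exp_m <- outer(rowSums(m), colSums(m)) / sum(m)
  stat_hand <- sum((m - exp_m)^2 / exp_m)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(res$p.value, pchisq(stat_hand, 1, lower.tail = FALSE))
  expect_lt(res$p.value, 1e-15)
  # symmetry under transposition
  expect_equal(chisq_independence(t(m))$statistic, res$statistic)
  expect_error(chisq_independence(matrix(c(0, 0, 5, 7), 2, 2)), "marginal")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), "TRUE")
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 0.1)
  expect_equal(rs$p, brute_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2))$p, 1)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(rank_sum_test(a, b)$p, rank_sum_test(b, a)$p)
  # exact route agrees with enumeration on a random small case
  set.seed(12)
  x <- sample(100, 5); y <- sample(100, 4) + 0.5
  expect_equal(rank_sum_test(x, y)$p, brute_ranksum_p(x, y), tolerance = 1e-9)
})

test_that("interaction ends classify into four exclusive binding categories", {
  fm <- build_fragment_map(c(chr1 = 50000), list(chr1 = seq(5000, 45000, 5000)),
                           baits = list(`1` = "gA", `3` = "gB"))
  it <- data.table::data.table(
    bait_id = c(1L, 3L, 1L, 3L),
    region_id = 1:4,
    constituents = list(c(7L, 8L), c(7L, 8L), 9L, 9L))
  bait_peak <- genomic_intervals("chr1", 100, 300)       # on fragment 1 only
  oe_peak <- genomic_intervals("chr1", 31000, 32000)     # on fragment 7
  ann <- annotate_peak_binding(it, fm, rbind(bait_peak, oe_peak))
  expect_equal(as.character(ann$category),
               c("both", "OE-only", "bait-only", "neither"))
  expect_equal(sum(table(ann$category)), nrow(it))
})

test_that("TF long-vs-short enrichment is detected at planted rates", {
  # direct construction at published-scale group sizes: 330 long, 988 short
  run_once <- function(seed, p_long, p_short) {
    set.seed(seed)
    tab <- matrix(c(rbinom(1, 330, p_long), 330 - (b1 <- rbinom(1, 330, p_long)),
                    rbinom(1, 988, p_short), 988 - (b2 <- rbinom(1, 988, p_short))),
                  2, 2, byrow = TRUE)
    tab[1, 1] <- b1; tab[1, 2] <- 330 - b1
    tab[2, 1] <- b2; tab[2, 2] <- 988 - b2
    chisq_independence(tab)$p.value
  }
  p_enr <- vapply(1:40, run_once, 0, p_long = 0.86, p_short = 0.58)
  expect_gte(mean(bh_adjust(p_enr) < 0.01), 0.95)
  p_null <- vapply(41:140, run_once, 0, p_long = 0.6, p_short = 0.6)
  expect_lte(mean(p_null < 0.05), 0.10)

  # the pipeline surface produces per-TF tables with BH across the family
  ds <- simulate_dataset(power_config(55))
  bids <- data.table::as.data.table(ds$fragmap)[is_bait == TRUE, id]
  it <- data.table::data.table(
    bait_id = rep(bids[1:10], 2),
    region_id = 1:20,
    constituents = as.list(sample(data.table::as.data.table(ds$fragmap)$id, 20)),
    distance = c(runif(10, 1e5, 7e5), runif(10, 9e5, 1.9e6)))
  it <- classify_range(it)
  out <- suppressWarnings(
    tf_enrichment_long_vs_short(it, ds$fragmap,
                                list(nanog = ds$tf_peaks,
                                     empty = ds$tf_peaks[0])))
  expect_equal(nrow(out), 2L)
  expect_true(is.na(out[tf == "empty", p]))
  expect_equal(out[tf == "nanog", long_bound + long_unbound], 10)
})

test_that("promoter skip counts match a brute-force TSS scan", {
  tss <- data.table::data.table(chrom = "chr1",
                                pos = c(5e5, 1e6, 1.5e6, 2e6, 2.5e6, 3e6, 3.5e6),
                                gene = paste0("g", 1:7))
  bait <- genomic_intervals("chr1", 1e5, 1.05e5)
  region <- genomic_intervals("chr1", 3.3e6, 3.4e6)
  expect_equal(promoter_skip_count(bait, region, tss), 6L)  # g1..g6 strictly between
  # adjacent features skip nothing
  expect_equal(promoter_skip_count(genomic_intervals("chr1", 4.9e5, 5.2e5),
                                   genomic_intervals("chr1", 5.2e5, 6e5), tss), 0L)
  expect_error(promoter_skip_count(bait, genomic_intervals("chr2", 1, 2), tss),
               "trans")
  # random-instance oracle
  set.seed(3)
  for (i in 1:20) {
    t2 <- data.table::data.table(chrom = "chr1", pos = sort(sample(1e6, 15)),
                                 gene = paste0("g", 1:15))
    b <- sort(sample(1e6, 2)); r <- sort(sample(1e6, 2))
    bait2 <- genomic_intervals("chr1", b[1], b[2] + 1)
    reg2 <- genomic_intervals("chr1", r[1], r[2] + 1)
    lo <- min(bait2$end, reg2$end); hi <- max(bait2$start, reg2$start)
    expected <- if (bait2$start < reg2$start)
      sum(t2$pos > bait2$end & t2$pos < reg2$start)
    else sum(t2$pos > reg2$end & t2$pos < bait2$start)
    expect_equal(promoter_skip_count(bait2, reg2, t2), expected)
  }
})

test_that("hub statistics bin SEs and promoters as published", {
  it <- data.table::data.table(
    region_id = c(rep(1, 3), rep(2, 1), rep(3, 12), rep(4, 7)),
    bait_id = c(101:103, 101, 201:212, 301:307),
    significant = TRUE)
  h <- hub_statistics(it)
  expect_equal(as.vector(h$se_hist), c(1, 1, 1, 1))  # 1, 3, 7, 12 promoters
  expect_equal(sum(h$se_hist), length(unique(it$region_id)))
  expect_equal(h$per_promoter[bait_id == 101, n_ses], 2L)
  expect_equal(sum(h$promoter_hist), length(unique(it$bait_id)))
})
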