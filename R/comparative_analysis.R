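#' Compare SE-interacting gene sets across conditions
#'
#' Exact set arithmetic on the per-condition sets of genes whose
#' promoters significantly contact a region class: genes shared by all
#' conditions, and genes specific to each (absent from every other
#' condition).
#'
#' @param target_genes_by_condition named list (>= 2 conditions) of
#'   character vectors of gene symbols.
#' @return list with `shared`, `specific` (named list), `union`, and
#'   `counts`.
#' @export
compare_interactomes <- function(target_genes_by_condition) {
  stopifnot(length(target_genes_by_condition) >= 2,
            !is.null(names(target_genes_by_condition)))
  sets <- lapply(target_genes_by_condition, unique)
  shared <- Reduce(intersect, sets)
  specific <- lapply(seq_along(sets), function(i)
    setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE)))
  names(specific) <- names(sets)
  uni <- unique(unlist(sets, use.names = FALSE))
  list(shared = shared, specific = specific, union = uni,
       counts = c(shared = length(shared),
                  vapply(specific, length, integer(1)),
                  union = length(uni)))
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' No continuity correction (the tables this pipeline tests have large
#' counts, where the correction is immaterial); df = 1, upper-tail p.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p.value`, `expected`, `table`.
#' @export
chisq_independence <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (sum(m) <= 0) stop("chisq_independence: empty table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chisq_independence: a zero marginal makes the test undefined")
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       expected = ht$expected, table = m)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; output
#' order matches input order.
#'
#' @param pvals p-values in `(0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  p.adjust(pvals, method = "BH")
}

#' Classify interaction ends by TF binding
#'
#' The bait end is bound iff a peak overlaps the bait fragment; the other
#' end is bound iff a peak overlaps any constituent fragment of the
#' composite region. Categories are exhaustive and exclusive:
#' `bait-only`, `OE-only`, `both`, `neither`.
#'
#' @param interactions composite interactions with `bait_id` and a
#'   `constituents` list column.
#' @param fragmap a `fragment_map`.
#' @param bait_peaks,oe_peaks `data.table(chrom, start, end)` peak sets
#'   used for the bait and other-end calls (typically the same TF).
#' @return `interactions` with logical `bait_bound`, `oe_bound` and a
#'   `category` factor.
#' @export
annotate_peak_binding <- function(interactions, fragmap, bait_peaks, oe_peaks = bait_peaks) {
  it <- copy(as.data.table(interactions))
  fm <- as.data.table(fragmap)
  bound_frags <- function(peaks) {
    if (is.null(peaks) || !nrow(peaks)) return(integer())
    unique(find_overlaps(peaks, fm[, .(chrom, start, end, id)])$subject)
  }
  bf <- bound_frags(bait_peaks); of <- bound_frags(oe_peaks)
  it[, `:=`(bait_bound = bait_id %in% bf,
            oe_bound = vapply(constituents, function(k) any(k %in% of), TRUE))]
  it[, category := factor(fifelse(bait_bound & oe_bound, "both",
                          fifelse(bait_bound, "bait-only",
                          fifelse(oe_bound, "OE-only", "neither"))),
                          levels = c("bait-only", "OE-only", "both", "neither"))]
  it[]
}

#' TF enrichment at long- versus short-range interactions
#'
#' Per TF: a 2x2 table of (long, short) x (bound at either end, unbound),
#' Pearson chi-square, and BH adjustment across the TF family.
#'
#' @param interactions classified composite interactions (`range_class`,
#'   `bait_id`, `constituents`).
#' @param fragmap a `fragment_map`.
#' @param peak_sets named list of TF peak tables.
#' @return `data.table(tf, long_bound, long_unbound, short_bound,
#'   short_unbound, statistic, p, p_adj)`; TFs with zero peaks get `NA`
#'   statistics and a warning.
#' @export
tf_enrichment_long_vs_short <- function(interactions, fragmap, peak_sets) {
  it <- as.data.table(interactions)
  stopifnot("range_class" %in% names(it))
  if (!any(it$range_class == "long") || !any(it$range_class == "short"))
    stop("tf_enrichment_long_vs_short: need both long and short interactions")
  rows <- lapply(names(peak_sets), function(tf) {
    pk <- peak_sets[[tf]]
    if (is.null(pk) || !nrow(pk)) {
      warning("TF '", tf, "' has zero peaks; test skipped")
      return(data.table(tf = tf, long_bound = 0L, long_unbound = sum(it$range_class == "long"),
                        short_bound = 0L, short_unbound = sum(it$range_class == "short"),
                        statistic = NA_real_, p = NA_real_))
    }
    ann <- annotate_peak_binding(it, fragmap, pk, pk)
    ann[, bound := bait_bound | oe_bound]
    tab <- ann[, table(factor(range_class, c("long", "short")),
                       factor(bound, c(TRUE, FALSE)))]
    res <- tryCatch(chisq_independence(tab),
                    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    data.table(tf = tf, long_bound = tab[1, 1], long_unbound = tab[1, 2],
               short_bound = tab[2, 1], short_unbound = tab[2, 2],
               statistic = res$statistic, p = res$p.value)
  })
  out <- rbindlist(rows)
  out[, p_adj := NA_real_]
  ok <- !is.na(out$p)
  if (any(ok)) out[ok, p_adj := bh_adjust(p[ok])]
  out[]
}

#' Two-sided Mann-Whitney U rank-sum test
#'
#' Exact enumeration when both groups have `<= exact_max` values and no
#' ties; normal approximation with tie correction otherwise. Two groups
#' of entirely identical values give `p = 1`.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param exact_max largest group size for exact enumeration (default 8).
#' @return list with `U` and `p`.
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 8) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  vals <- c(group_a, group_b)
  if (length(unique(vals)) == 1L)
    return(list(U = length(group_a) * length(group_b) / 2, p = 1))
  exact <- length(group_a) <= exact_max && length(group_b) <= exact_max &&
    !anyDuplicated(vals)
  ht <- suppressWarnings(wilcox.test(group_a, group_b, alternative = "two.sided",
                                     exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Count promoters skipped by an interaction
#'
#' The number of distinct genes whose TSS lies strictly between the bait
#' fragment and the composite region span.
#'
#' @param bait one-row bait fragment (`chrom`, `start`, `end`).
#' @param region one-row region span (`chrom`, `start`, `end`).
#' @param tss `data.table(chrom, pos, gene)`.
#' @return integer count.
#' @export
promoter_skip_count <- function(bait, region, tss) {
  if (bait$chrom[1] != region$chrom[1])
    stop("promoter_skip_count: trans pair")
  if (bait$start[1] < region$start[1]) {
    lo <- bait$end[1]; hi <- region$start[1]
  } else {
    lo <- region$end[1]; hi <- bait$start[1]
  }
  if (hi <= lo) return(0L)
  length(unique(tss[chrom == bait$chrom[1] & pos > lo & pos < hi, gene]))
}

#' Hub statistics of the SE interactome
#'
#' Per SE: the number of distinct interacting promoters; per promoter:
#' the number of distinct interacting SEs; both binned as 1, 2-5, 6-10,
#' >= 11.
#'
#' @param interactions significant composite interactions with
#'   `region_id` and `bait_id`.
#' @param breaks,labels histogram bins.
#' @return list with `per_se` and `per_promoter` count tables plus the
#'   binned histograms `se_hist`, `promoter_hist`.
#' @export
hub_statistics <- function(interactions,
                           breaks = c(0, 1, 5, 10, Inf),
                           labels = c("1", "2-5", "6-10", ">=11")) {
  it <- as.data.table(interactions)
  if ("significant" %in% names(it)) it <- it[significant == TRUE]
  per_se <- it[, .(n_promoters = uniqueN(bait_id)), by = region_id]
  per_prom <- it[, .(n_ses = uniqueN(region_id)), by = bait_id]
  list(per_se = per_se, per_promoter = per_prom,
       se_hist = table(cut(per_se$n_promoters, breaks, labels)),
       promoter_hist = table(cut(per_prom$n_ses, breaks, labels)))
}
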