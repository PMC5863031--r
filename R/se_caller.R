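#' Super-enhancer caller configuration
#'
#' Defaults follow the ROSE convention: enhancer peaks within 12.5 kb of
#' each other are stitched into one region, peaks fully inside a 2 kb TSS
#' exclusion zone are dropped first, and comparison tiers hold 250 regions
#' each.
#'
#' @param stitch_distance maximum gap (bp) between consecutive peaks that
#'   are merged into one stitched region.
#' @param tss_exclusion half-width (bp) of the TSS exclusion window; a peak
#'   fully contained in `[tss - w, tss + w]` is removed before stitching.
#' @param tier_size number of regions per enhancer tier.
#' @return a list of class `se_config`.
#' @export
se_config <- function(stitch_distance = 12500, tss_exclusion = 2000, tier_size = 250) {
  stopifnot(stitch_distance >= 0, tss_exclusion >= 0, tier_size >= 1)
  structure(list(stitch_distance = stitch_distance, tss_exclusion = tss_exclusion,
                 tier_size = tier_size), class = "se_config")
}

#' Stitch enhancer peaks into candidate regions
#'
#' Single-linkage chaining: two peaks end up in the same stitched region
#' iff every gap along the chain of consecutive peaks between them is
#' `<= stitch_distance` (gap = next peak's start minus previous peak's
#' end). Peaks fully contained in a TSS exclusion window are removed
#' before stitching.
#'
#' @param peaks intervals with optional `name`; extra columns (e.g.
#'   `treatment`, `input`) are carried through per constituent.
#' @param tss `data.table(chrom, pos)` of transcription start sites (or
#'   `NULL` to skip exclusion).
#' @param config an [se_config()].
#' @return `data.table(region_id, chrom, start, end, n_peaks,
#'   constituents)` where `constituents` is a list column of input row
#'   indices; attribute `peaks` holds the retained, sorted peaks with
#'   their region assignment.
#' @export
stitch_peaks <- function(peaks, tss = NULL, config = se_config()) {
  validate_intervals(peaks, "peaks")
  pk <- as.data.table(peaks)
  pk[, peak_id := .I]
  if (!is.null(tss) && nrow(tss)) {
    w <- config$tss_exclusion
    win <- data.table(chrom = tss$chrom, start = pmax(0, tss$pos - w), end = tss$pos + w)
    ov <- find_overlaps(pk, win)
    if (nrow(ov)) {
      contained <- ov[pk$start[query] >= win$start[subject] &
                      pk$end[query] <= win$end[subject], unique(query)]
      if (length(contained)) pk <- pk[-contained]
    }
  }
  if (!nrow(pk)) {
    return(data.table(region_id = integer(), chrom = character(), start = numeric(),
                      end = numeric(), n_peaks = integer(), constituents = list()))
  }
  setorder(pk, chrom, start, end)
  pk[, cluster := cumsum(c(1, (start[-1] - cummax(end)[-.N]) > config$stitch_distance)),
     by = chrom]
  regions <- pk[, .(start = min(start), end = max(end), n_peaks = .N,
                    constituents = list(peak_id)), by = .(chrom, cluster)]
  setorder(regions, chrom, start)
  regions[, region_id := .I]
  out <- regions[, .(region_id, chrom, start, end, n_peaks, constituents)]
  setattr(out, "peaks", pk)
  out[]
}

#' Score stitched regions by input-subtracted signal density
#'
#' Density = sum over constituent peaks of
#' `treatment / treatment_library - input / input_library`, floored at 0.
#'
#' @param regions output of [stitch_peaks()] (must carry its `peaks`
#'   attribute, or pass `peaks` explicitly).
#' @param peaks peak table with numeric `treatment` and `input` columns
#'   aligned with the constituent indices of `regions`.
#' @param library_sizes named numeric vector `c(treatment=, input=)`.
#' @return `regions` with a `density` column added.
#' @export
score_stitched <- function(regions, peaks = attr(regions, "peaks"),
                           library_sizes = c(treatment = 1, input = 1)) {
  if (is.null(peaks)) stop("score_stitched: no peak table supplied")
  stopifnot(all(c("treatment", "input") %in% names(peaks)))
  pk <- as.data.table(peaks)
  if (is.null(pk$peak_id)) pk[, peak_id := .I]
  dens <- vapply(seq_len(nrow(regions)), function(i) {
    ids <- regions$constituents[[i]]
    rows <- pk[match(ids, peak_id)]
    if (anyNA(rows$treatment) || anyNA(rows$input))
      stop(sprintf("score_stitched: missing signal over region %s:%d-%d",
                   regions$chrom[i], as.integer(regions$start[i]), as.integer(regions$end[i])))
    sum(rows$treatment) / library_sizes[["treatment"]] -
      sum(rows$input) / library_sizes[["input"]]
  }, numeric(1))
  out <- copy(regions)
  out[, density := pmax(0, dens)]
  setattr(out, "peaks", attr(regions, "peaks"))
  out[]
}

## internal: slope-1 inflection threshold on the rank/density curve,
## both axes rescaled to [0,1]; scanning from the low-density end.
.inflection_threshold <- function(density) {
  n <- length(density)
  d <- sort(density)
  if (d[n] - d[1] <= 0) return(NA_real_)
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (d - d[1]) / (d[n] - d[1])
  slope <- diff(ys) / diff(xs)
  hit <- which(slope >= 1)
  if (!length(hit)) return(d[n])            # cannot happen: mean slope is 1
  i <- hit[1]
  # ties: slope exactly 1 over a run -> take the highest-density point of it
  if (abs(slope[i] - 1) < 1e-12) {
    j <- i
    while (j < n - 1 && abs(slope[j + 1] - 1) < 1e-12) j <- j + 1
    i <- j + 1
  }
  d[i]
}

#' Call super-enhancers at the ranked-density inflection point
#'
#' Regions are ranked by density; with both the rank axis and the density
#' axis rescaled to `[0, 1]`, the threshold is the density at the point
#' where the tangent slope of the scaled curve first reaches 1 (scanning
#' from the low end). Regions with density strictly above the threshold
#' are super-enhancers.
#'
#' @param regions scored regions (from [score_stitched()]) with `density`.
#' @return `regions` with `rank_` (1 = highest density), `is_SE`, and an
#'   `se_threshold` attribute. If all densities are equal, zero SEs are
#'   called and a warning is issued.
#' @export
call_super_enhancers <- function(regions) {
  stopifnot("density" %in% names(regions))
  if (nrow(regions) < 3) stop("call_super_enhancers: need >= 3 scored regions")
  out <- copy(regions)
  thr <- .inflection_threshold(out$density)
  if (is.na(thr)) {
    warning("all densities equal; zero super-enhancers called")
    out[, is_SE := FALSE]
    thr <- out$density[1]
  } else {
    out[, is_SE := density > thr]
  }
  out[, rank_ := frank(-density, ties.method = "first")]
  setattr(out, "se_threshold", thr)
  setattr(out, "peaks", attr(regions, "peaks"))
  out[]
}

#' Select the three enhancer comparison tiers
#'
#' `SE_top`: the `tier_size` regions with highest density (a subset of the
#' SEs on a typical landscape); `NE` ("normal" enhancers): the `tier_size`
#' highest-density regions below the SE threshold; `LE` ("low"
#' enhancers): the `tier_size` lowest-density regions with density > 0.
#' Tiers are disjoint by construction.
#'
#' @param regions output of [call_super_enhancers()].
#' @param config an [se_config()].
#' @return named list of three `data.table`s (`SE_top`, `NE`, `LE`).
#' @export
select_enhancer_tiers <- function(regions, config = se_config()) {
  k <- config$tier_size
  pos <- regions[density > 0]
  if (nrow(pos) < 3 * k)
    stop(sprintf("select_enhancer_tiers: need >= %d regions with density > 0, have %d",
                 3 * k, nrow(pos)))
  desc <- pos[order(-density)]
  se_top <- desc[seq_len(k)]
  below <- desc[!(is_SE) & !(region_id %in% se_top$region_id)]
  if (nrow(below) < k) stop("select_enhancer_tiers: fewer than tier_size regions below the SE threshold")
  ne <- below[seq_len(k)]
  asc <- pos[order(density)]
  asc <- asc[!(region_id %in% c(se_top$region_id, ne$region_id))]
  if (nrow(asc) < k) stop("select_enhancer_tiers: insufficient low-density regions")
  le <- asc[seq_len(k)]
  list(SE_top = se_top, NE = ne, LE = le)
}
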