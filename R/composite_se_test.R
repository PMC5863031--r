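#' Concatenate the restriction fragments of a multi-fragment region
#'
#' For a bait-region test, the composite "other end" is the set of
#' fragments overlapping the region span, minus the bait fragment itself
#' and its two immediate genomic neighbours (standard proximity-artifact
#' exclusion). A pair whose constituent set comes out empty is skipped by
#' the caller, not an error.
#'
#' @param region one-row data.frame with `chrom`, `start`, `end` (and
#'   optionally `region_id`, `source_label`).
#' @param fragmap a `fragment_map`.
#' @param bait_id bait fragment id (must be cis with the region; trans
#'   pairs are the caller's responsibility to skip).
#' @return list with `region_id`, `chrom`, `start`, `end`, `constituents`
#'   (integer fragment ids), `empty` flag.
#' @export
concatenate_fragments <- function(region, fragmap, bait_id) {
  fm <- as.data.table(fragmap)
  bait <- fm[id == bait_id]
  if (!nrow(bait)) stop("concatenate_fragments: unknown bait fragment ", bait_id)
  if (bait$chrom != region$chrom[1])
    stop("concatenate_fragments: bait and region on different chromosomes")
  ov <- fm[chrom == region$chrom[1] & start < region$end[1] & end > region$start[1], id]
  if (!length(ov)) stop(sprintf("concatenate_fragments: region %s:%d-%d overlaps no fragment",
                                region$chrom[1], as.integer(region$start[1]),
                                as.integer(region$end[1])))
  ## fragment ids are genome-ordered, so the bait's genomic neighbours on
  ## its chromosome are id +/- 1 (when they exist on the same chromosome)
  excl <- fm[chrom == bait$chrom & abs(id - bait_id) <= 1, id]
  keep <- setdiff(ov, excl)
  list(region_id = if (!is.null(region$region_id)) region$region_id[1] else NA_integer_,
       chrom = region$chrom[1], start = region$start[1], end = region$end[1],
       constituents = keep, empty = length(keep) == 0L)
}

#' Composite negative-binomial test for one bait-region pair
#'
#' The observed count is the total count between the bait and any
#' constituent fragment of the region; the expected count is the sum of
#' the per-fragment expected background counts. The null is
#' `NB(mean = N_exp_sum, dispersion = r)` with the model's fitted
#' dispersion, tested one-tailed (upper, inclusive). Distance is measured
#' bait midpoint to region-span midpoint.
#'
#' @param bait_id bait fragment id.
#' @param comp output of [concatenate_fragments()].
#' @param contacts pooled `data.table(bait_id, oe_id, count)`.
#' @param background a `chic_background`.
#' @param fragmap a `fragment_map`.
#' @return one-row `data.table(bait_id, region_id, n_frag, N_obs, N_exp,
#'   p, distance)`, or `NULL` for an empty constituent set.
#' @export
composite_pvalue <- function(bait_id, comp, contacts, background, fragmap) {
  if (comp$empty) return(NULL)
  fm <- as.data.table(fragmap)
  bait <- fm[id == bait_id]
  cons <- fm[id %in% comp$constituents]
  ct <- as.data.table(contacts)
  b <- bait_id
  obs <- ct[bait_id == b & oe_id %in% comp$constituents, sum(count)]
  d_frag <- abs((bait$start + bait$end) / 2 - (cons$start + cons$end) / 2)
  exp_sum <- sum(expected_count(background, rep(bait_id, nrow(cons)), cons$id, d_frag))
  dist <- abs((bait$start + bait$end) / 2 - (comp$start + comp$end) / 2)
  data.table(bait_id = bait_id, region_id = comp$region_id,
             n_frag = length(comp$constituents),
             N_obs = obs, N_exp = exp_sum,
             p = interaction_pvalue(obs, exp_sum, background$r),
             distance = dist)
}

#' Call composite bait-region interactions
#'
#' Tests every cis bait x region pair within the background model's
#' distance range; p-values are distance-weighted and converted to scores
#' (weights normalised to mean 1 over the tested pairs); pairs with score
#' `>= score_threshold` are significant. Pairs whose constituent set is
#' empty (bait inside or adjacent to the region) are skipped and listed
#' in the `skipped` attribute.
#'
#' @param bait_ids integer vector of bait fragment ids to test.
#' @param regions `data.table(region_id, chrom, start, end[,
#'   source_label])` of composite regions (SE / NE / LE / CTRL).
#' @param contacts pooled `data.table(bait_id, oe_id, count)`.
#' @param background a `chic_background`.
#' @param fragmap a `fragment_map`.
#' @param score_threshold significance cutoff (default 5).
#' @param d0,beta weighting parameters (see [distance_weight()]).
#' @return `data.table(region_id, bait_id, source_label, n_frag, N_obs,
#'   N_exp, p, score, distance, significant, constituents)`, sorted by
#'   region then bait; skipped pairs in `attr(, "skipped")`.
#' @export
call_composite_interactions <- function(bait_ids, regions, contacts, background,
                                        fragmap, score_threshold = 5,
                                        d0 = 3e5, beta = 0.4) {
  fm <- as.data.table(fragmap)
  rg <- as.data.table(regions)
  if (is.null(rg$region_id)) rg[, region_id := .I]
  if (is.null(rg$source_label)) rg[, source_label := "region"]
  ct <- as.data.table(contacts)
  baits <- fm[id %in% bait_ids]
  setkey(fm, chrom)

  rows <- list()
  skipped <- list()
  k <- 0L
  for (ri in seq_len(nrow(rg))) {
    frags_chr <- fm[.(rg$chrom[ri]), nomatch = NULL]
    ov_rows <- frags_chr[start < rg$end[ri] & end > rg$start[ri]]
    ov <- ov_rows$id
    r_mid <- (rg$start[ri] + rg$end[ri]) / 2
    cis_baits <- baits[chrom == rg$chrom[ri]]
    if (!nrow(cis_baits) || !length(ov)) next
    b_mid <- (cis_baits$start + cis_baits$end) / 2
    dist <- abs(b_mid - r_mid)
    in_range <- dist <= background$max_distance
    if (!any(in_range)) next
    cis_baits <- cis_baits[in_range]; b_mid <- b_mid[in_range]; dist <- dist[in_range]

    ## observed: per-bait, per-fragment counts into the region
    sub <- ct[oe_id %in% ov]
    obs_tab <- if (nrow(sub)) sub[, .(tot = sum(count)), keyby = bait_id] else NULL

    ## per-bait expected over constituents, with bait +/- 1 excluded
    f_mid <- (ov_rows$start + ov_rows$end) / 2
    for (bi in seq_len(nrow(cis_baits))) {
      b_id <- cis_baits$id[bi]
      excl <- abs(ov - b_id) <= 1
      keep <- ov[!excl]
      if (!length(keep)) {
        skipped[[length(skipped) + 1L]] <-
          data.table(region_id = rg$region_id[ri], bait_id = b_id,
                     reason = "no constituent fragments after bait/adjacent exclusion")
        next
      }
      d_frag <- abs(b_mid[bi] - f_mid[!excl])
      obs <- if (is.null(obs_tab)) 0 else {
        tot <- obs_tab[.(b_id), tot]
        if (is.na(tot)) 0 else if (any(excl)) {
          drop <- ct[bait_id == b_id & oe_id %in% ov[excl], sum(count)]
          tot - drop
        } else tot
      }
      exp_sum <- sum(expected_count(background, rep(b_id, length(keep)), keep, d_frag))
      k <- k + 1L
      rows[[k]] <- data.table(region_id = rg$region_id[ri], bait_id = b_id,
                              source_label = rg$source_label[ri],
                              n_frag = length(keep), N_obs = obs, N_exp = exp_sum,
                              distance = dist[bi], constituents = list(keep))
    }
  }
  if (k == 0L) {
    out <- data.table(region_id = integer(), bait_id = integer(),
                      source_label = character(), n_frag = integer(),
                      N_obs = numeric(), N_exp = numeric(), p = numeric(),
                      score = numeric(), distance = numeric(),
                      significant = logical(), constituents = list())
  } else {
    out <- rbindlist(rows[seq_len(k)])
    out[, p := interaction_pvalue(N_obs, N_exp, background$r)]
    ws <- weight_and_score(out$p, out$distance, d0 = d0, beta = beta)
    out[, score := ws$score]
    out[, significant := score >= score_threshold]
    setorder(out, region_id, bait_id)
    setcolorder(out, c("region_id", "bait_id", "source_label", "n_frag", "N_obs",
                       "N_exp", "p", "score", "distance", "significant", "constituents"))
  }
  setattr(out, "skipped",
          if (length(skipped)) rbindlist(skipped)
          else data.table(region_id = integer(), bait_id = integer(), reason = character()))
  out[]
}

#' Drop regions overlapping any baited fragment
#'
#' Promoter-overlapping regions are excluded before composite testing, so
#' that bait-to-bait proximity signal does not masquerade as a
#' promoter-enhancer contact.
#'
#' @param regions composite regions (`chrom`, `start`, `end`).
#' @param fragmap a `fragment_map` with bait flags.
#' @return the subset of `regions` overlapping no baited fragment.
#' @export
filter_regions_overlapping_baits <- function(regions, fragmap) {
  baited <- as.data.table(fragmap)[is_bait == TRUE]
  if (!nrow(baited) || !nrow(regions)) return(regions)
  ov <- find_overlaps(regions, baited[, .(chrom, start, end)])
  if (!nrow(ov)) return(regions)
  regions[-unique(ov$query)]
}
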