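## Control-region construction: shuffled, size-matched (extended), and
## fragment-size + distance-matched controls for composite testing.

.overlaps_any <- function(start, end, starts, ends) {
  any(start < ends & end > starts)
}

#' Shuffle regions within their chromosomes
#'
#' Each control keeps the chromosome and exact length of its source
#' region and gets a uniform random start; placements are resampled until
#' no two controls overlap (and, by default, none overlaps a source
#' region). Deterministic given `seed`.
#'
#' @param ses `data.table(chrom, start, end[, region_id])` of regions to
#'   shuffle (typically the called SEs).
#' @param chrom_sizes named numeric vector.
#' @param seed integer RNG seed.
#' @param max_tries placement attempts per region before giving up.
#' @param avoid_sources also reject placements overlapping the source
#'   regions themselves (keeps the control set signal-free).
#' @return `data.table(chrom, start, end, se_id, mode)`.
#' @export
shuffle_within_chromosome <- function(ses, chrom_sizes, seed = 1L,
                                      max_tries = 1000L, avoid_sources = TRUE) {
  se <- as.data.table(ses)
  if (is.null(se$region_id)) se[, region_id := .I]
  bad <- se[, .(tot = sum(end - start)), by = chrom][tot >= chrom_sizes[chrom]]
  if (nrow(bad)) stop("shuffle_within_chromosome: regions on ", bad$chrom[1],
                      " exceed the chromosome size")
  set.seed(seed)
  out <- vector("list", nrow(se))
  placed <- split(se[0], se$chrom[0])  # per-chrom accumulators
  placed_start <- list(); placed_end <- list()
  for (i in seq_len(nrow(se))) {
    cn <- se$chrom[i]; len <- se$end[i] - se$start[i]
    size <- chrom_sizes[[cn]]
    ps <- placed_start[[cn]] %||% numeric()
    pe <- placed_end[[cn]] %||% numeric()
    if (avoid_sources) {
      src <- se[chrom == cn]
      ps0 <- c(ps, src$start); pe0 <- c(pe, src$end)
    } else { ps0 <- ps; pe0 <- pe }
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- floor(runif(1, 0, size - len))
      if (!.overlaps_any(s, s + len, ps0, pe0)) { ok <- TRUE; break }
    }
    if (!ok) stop("shuffle_within_chromosome: no non-overlapping placement on ", cn,
                  " after ", max_tries, " tries; use fewer or shorter regions")
    placed_start[[cn]] <- c(ps, s); placed_end[[cn]] <- c(pe, s + len)
    out[[i]] <- data.table(chrom = cn, start = s, end = s + len,
                           se_id = se$region_id[i], mode = "shuffle")
  }
  rbindlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Size-extend seed regions to match assigned SEs
#'
#' Each seed region (an NE or LE enhancer) is assigned to an SE at random
#' (a bijection over the SE set) and extended symmetrically from the
#' midpoint of the fragment containing the seed region's midpoint until
#' its length equals the assigned SE's length. Extended regions sharing
#' any fragment with any SE (or running off the chromosome) are discarded
#' and replaced from the remaining seed pool.
#'
#' @param seed_regions `data.table(chrom, start, end[, region_id])`
#'   candidate seeds; need at least as many as SEs.
#' @param ses `data.table(chrom, start, end[, region_id])` the SE set.
#' @param fragmap a `fragment_map`.
#' @param seed integer RNG seed.
#' @return `data.table(chrom, start, end, se_id, seed_id, mode)` with one
#'   control per SE; the control length multiset equals the SE length
#'   multiset.
#' @export
extend_to_size_match <- function(seed_regions, ses, fragmap, seed = 1L) {
  sr <- as.data.table(seed_regions); se <- as.data.table(ses)
  if (is.null(sr$region_id)) sr[, region_id := .I]
  if (is.null(se$region_id)) se[, region_id := .I]
  if (nrow(sr) < nrow(se))
    stop("extend_to_size_match: need at least as many seed regions (",
         nrow(sr), ") as SEs (", nrow(se), ")")
  fm <- as.data.table(fragmap)
  cs <- fm_chrom_sizes(fragmap)
  ## fragments touched by any SE (shared-fragment exclusion)
  se_frag <- find_overlaps(se, fm[, .(chrom, start, end, id)])$subject
  set.seed(seed)
  pool <- sample(nrow(sr))          # random order of seed candidates
  assign_se <- sample(nrow(se))     # random bijection SE <- candidate stream
  out <- vector("list", nrow(se))
  nxt <- 1L
  for (j in seq_along(assign_se)) {
    se_row <- se[assign_se[j]]
    len <- se_row$end - se_row$start
    repeat {
      if (nxt > length(pool))
        stop("extend_to_size_match: seed-region pool exhausted before all SEs were matched")
      cand <- sr[pool[nxt]]; nxt <- nxt + 1L
      cmid <- (cand$start + cand$end) / 2
      frag <- fm[chrom == cand$chrom & start <= cmid & end > cmid]
      if (!nrow(frag)) next
      fmid <- (frag$start + frag$end) / 2
      s <- fmid - floor(len / 2); e <- s + len
      if (s < 0 || e > cs[[cand$chrom]]) next
      cand_frags <- fm[chrom == cand$chrom & start < e & end > s, id]
      if (length(intersect(cand_frags, se_frag))) next
      out[[j]] <- data.table(chrom = cand$chrom, start = s, end = e,
                             se_id = se_row$region_id, seed_id = cand$region_id,
                             mode = "size-extend")
      break
    }
  }
  rbindlist(out)
}

#' Distance- and fragment-size-matched control interactions
#'
#' For each promoter-region interaction, places a control region with the
#' same span and the same number of constituent fragments at the same
#' bait distance (within `+/- tol`), trying both sides of the bait
#' (reflecting to the other side when one exits the chromosome) over a
#' grid of candidate midpoints. Interactions with no valid placement are
#' skipped and listed in the `skipped` attribute.
#'
#' @param interactions `data.table` with `bait_id`, `region_id`, `n_frag`,
#'   `distance`, and region `chrom`, `start`, `end` columns (as produced
#'   by joining [call_composite_interactions()] output to its regions).
#' @param fragmap a `fragment_map`.
#' @param seed integer RNG seed (side order randomisation).
#' @param tol relative distance tolerance (default 0.05).
#' @param n_grid candidate midpoints per side.
#' @return `data.table(bait_id, se_id, chrom, start, end, distance, mode)`.
#' @export
distance_matched_controls <- function(interactions, fragmap, seed = 1L,
                                      tol = 0.05, n_grid = 41L) {
  it <- as.data.table(interactions)
  if (!nrow(it)) stop("distance_matched_controls: empty interaction set")
  fm <- as.data.table(fragmap)
  cs <- fm_chrom_sizes(fragmap)
  frag_chr <- split(fm[order(start)], by = "chrom")
  set.seed(seed)
  out <- vector("list", nrow(it)); skipped <- list()
  for (i in seq_len(nrow(it))) {
    row <- it[i]
    bait <- fm[id == row$bait_id]
    b_mid <- (bait$start + bait$end) / 2
    span <- row$end - row$start
    frags_chr <- frag_chr[[row$chrom]]
    found <- NULL
    ## candidate midpoints on both sides, in random order (keeps the
    ## accepted distances unbiased within the tolerance band)
    band <- tol * (1 - 1e-9)   # strictly inside +/- tol despite rounding
    mids <- c(b_mid + seq(row$distance * (1 - band), row$distance * (1 + band),
                          length.out = n_grid),
              b_mid - seq(row$distance * (1 - band), row$distance * (1 + band),
                          length.out = n_grid))
    for (m in sample(mids)) {
      s <- m - span / 2; e <- s + span
      if (s < 0 || e > cs[[row$chrom]]) next
      if (s < row$end && e > row$start) next        # don't sit on the source region
      lo <- findInterval(s, frags_chr$start); if (lo < 1) lo <- 1
      hi <- findInterval(e - 1e-9, frags_chr$start)
      ids <- frags_chr$id[lo:hi]
      nf <- sum(abs(ids - row$bait_id) > 1)
      if (nf == row$n_frag) { found <- c(m, s, e); break }
    }
    if (is.null(found)) {
      skipped[[length(skipped) + 1L]] <-
        data.table(bait_id = row$bait_id, se_id = row$region_id,
                   reason = "no fragment-count-matched placement within distance tolerance")
      next
    }
    out[[i]] <- data.table(bait_id = row$bait_id, se_id = row$region_id,
                           chrom = row$chrom, start = found[2], end = found[3],
                           distance = abs(found[1] - b_mid), mode = "distance-match")
  }
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  setattr(res, "skipped",
          if (length(skipped)) rbindlist(skipped)
          else data.table(bait_id = integer(), se_id = integer(), reason = character()))
  res[]
}
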