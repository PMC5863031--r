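#' Long-range interaction (LRI) configuration
#'
#' @param threshold fixed distance threshold in bp (default 800 kb):
#'   interactions strictly above it are long-range.
#' @param derive_fraction fraction used when deriving the threshold from
#'   data (default 0.25, i.e. the threshold exceeded by a quarter of
#'   interactions).
#' @return a list of class `lri_config`.
#' @export
lri_config <- function(threshold = 8e5, derive_fraction = 0.25) {
  stopifnot(threshold > 0, derive_fraction > 0, derive_fraction < 1)
  structure(list(threshold = threshold, derive_fraction = derive_fraction),
            class = "lri_config")
}

#' Midpoint distance between two intervals
#'
#' `distance = |(a + b)/2 - (c + d)/2|` for intervals `(a, b)` and
#' `(c, d)` on the same chromosome. Vectorised; symmetric and
#' translation-invariant.
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (recycled
#'   row-wise).
#' @return numeric distances in bp; errors on a trans pair.
#' @export
interaction_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ac <- rep_len(a$chrom, n); bc <- rep_len(b$chrom, n)
  if (any(ac != bc)) stop("interaction_distance: trans pair at row ",
                          which(ac != bc)[1])
  abs(rep_len((a$start + a$end) / 2, n) - rep_len((b$start + b$end) / 2, n))
}

#' Derive the LRI distance threshold from observed distances
#'
#' The empirical `1 - fraction` quantile (linear interpolation, type 7)
#' of the distance vector: the distance exceeded by about `fraction` of
#' interactions.
#'
#' @param distances numeric vector (bp); at least 4 values.
#' @param fraction upper-tail fraction (default 0.25).
#' @return threshold in bp.
#' @export
derive_lri_threshold <- function(distances, fraction = 0.25) {
  stopifnot(length(distances) >= 4, fraction > 0, fraction < 1)
  unname(quantile(distances, probs = 1 - fraction, type = 7, names = FALSE))
}

#' Classify interactions as long- or short-range
#'
#' Long iff `distance > threshold` (strictly); a distance exactly at the
#' threshold is short.
#'
#' @param interactions `data.table` with a `distance` column.
#' @param config an [lri_config()] (or numeric threshold).
#' @return `interactions` with a `range_class` factor (`"short"`,
#'   `"long"`).
#' @export
classify_range <- function(interactions, config = lri_config()) {
  thr <- if (is.numeric(config)) config else config$threshold
  out <- copy(as.data.table(interactions))
  out[, range_class := factor(ifelse(distance > thr, "long", "short"),
                              levels = c("short", "long"))]
  out[]
}

#' Per-region engagement classes
#'
#' Each region with at least one significant interaction is classed by
#' the range labels of its significant interactions: `short-only`,
#' `long-only`, or `both`. Regions with no significant interaction are
#' excluded.
#'
#' @param interactions classified interactions with `region_id`,
#'   `range_class`, and `significant`.
#' @return `data.table(region_id, class)` plus a `proportions` attribute
#'   (named fractions over the interacting regions).
#' @export
classify_se_engagement <- function(interactions) {
  sig <- as.data.table(interactions)[significant == TRUE]
  if (!nrow(sig)) return(data.table(region_id = integer(), class = character()))
  cls <- sig[, .(
    class = {
      has_l <- any(range_class == "long"); has_s <- any(range_class == "short")
      if (has_l && has_s) "both" else if (has_l) "long-only" else "short-only"
    }), by = region_id]
  props <- prop.table(table(factor(cls$class, c("short-only", "long-only", "both"))))
  setattr(cls, "proportions", props)
  cls[]
}
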