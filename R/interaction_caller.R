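#' Enumerate testable cis bait-fragment pairs
#'
#' All (bait fragment, other-end fragment) pairs on the same chromosome
#' with midpoint distance `<= max_distance`, excluding the bait itself and
#' its `exclude_adjacent` immediate genomic neighbours on each side
#' (re-ligation / proximity artifacts). These are the pairs over which
#' the background is fitted and p-values computed; pairs absent from a
#' sparse contact table have observed count 0.
#'
#' @param fragmap a `fragment_map` with bait flags.
#' @param max_distance maximum midpoint distance (bp).
#' @param exclude_adjacent number of neighbouring fragments per side to
#'   drop (default 1).
#' @return `data.table(bait_id, oe_id, distance)`.
#' @export
enumerate_cis_pairs <- function(fragmap, max_distance = 5e6, exclude_adjacent = 1L) {
  fm <- as.data.table(fragmap)
  fm[, mid := (start + end) / 2]
  baits <- fm[is_bait == TRUE]
  if (!nrow(baits)) stop("enumerate_cis_pairs: fragment map has no baits")
  pieces <- lapply(split(seq_len(nrow(baits)), baits$chrom), function(ix) {
    b <- baits[ix]
    frags <- fm[chrom == b$chrom[1]]
    cj <- CJ(bi = seq_len(nrow(b)), fi = seq_len(nrow(frags)))
    dt <- data.table(bait_id = b$id[cj$bi], oe_id = frags$id[cj$fi],
                     distance = abs(b$mid[cj$bi] - frags$mid[cj$fi]))
    dt <- dt[abs(oe_id - bait_id) > exclude_adjacent & distance <= max_distance]
    dt
  })
  out <- rbindlist(pieces)
  setorder(out, bait_id, oe_id)
  out[]
}

#' Pool replicate contact tables
#'
#' Counts are library-size scaled (each replicate multiplied by the mean
#' total over replicates divided by its own total), summed per fragment
#' pair, and rounded to integers.
#'
#' @param reps list of `data.table(bait_id, oe_id, count)`.
#' @return pooled `data.table(bait_id, oe_id, count)`.
#' @export
pool_replicates <- function(reps) {
  stopifnot(length(reps) >= 1)
  totals <- vapply(reps, function(r) sum(r$count), numeric(1))
  target <- mean(totals)
  scaled <- lapply(seq_along(reps), function(i) {
    r <- copy(as.data.table(reps[[i]]))
    r[, count := count * target / totals[i]]
    r
  })
  pooled <- rbindlist(scaled)[, .(count = round(sum(count))), by = .(bait_id, oe_id)]
  pooled[count > 0][order(bait_id, oe_id)]
}

#' Fit the negative-binomial distance-decay background
#'
#' The expected ("Brownian") count of a cis bait-fragment pair is
#' `f(d) * s_i * s_j * m`: a distance-decay curve `f` estimated as the
#' mean count in log-spaced distance bins (evaluated at each bin's
#' geometric-centre distance and linearly interpolated in log-log space),
#' multiplicative bait and other-end factors `s_i`, `s_j` fitted by
#' iterative proportional scaling of row/column totals, a global scale
#' `m`, and a negative-binomial dispersion `r` fitted by maximum
#' likelihood on the full pair set (`variance = mu + mu^2 / r`).
#'
#' @param contacts pooled `data.table(bait_id, oe_id, count)` (zeros may
#'   be omitted).
#' @param fragmap a `fragment_map` with bait flags.
#' @param max_distance,exclude_adjacent pair universe, as in
#'   [enumerate_cis_pairs()].
#' @param n_bins number of log-spaced distance bins.
#' @param max_iter,tol iterative-scaling controls.
#' @param outlier_p pairs with a first-pass p-value below this are held
#'   out and the factors, scale and dispersion refitted without them, so
#'   genuine interaction signal does not leak into the background
#'   (set to 0 to disable the second pass).
#' @return an object of class `chic_background`.
#' @export
fit_background <- function(contacts, fragmap, max_distance = 5e6,
                           exclude_adjacent = 1L, n_bins = 20L,
                           max_iter = 200L, tol = 1e-3, outlier_p = 1e-4) {
  pairs <- enumerate_cis_pairs(fragmap, max_distance, exclude_adjacent)
  if (nrow(pairs) < 1000) stop("fit_background: need >= 1000 cis pairs, have ", nrow(pairs))
  pairs <- merge(pairs, as.data.table(contacts)[, .(bait_id, oe_id, count)],
                 by = c("bait_id", "oe_id"), all.x = TRUE)
  pairs[is.na(count), count := 0]

  ## distance-decay curve: mean count per log-spaced bin
  rng <- range(pairs$distance)
  breaks <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  breaks[length(breaks)] <- rng[2] + 1
  pairs[, d_bin := findInterval(distance, breaks, rightmost.closed = TRUE)]
  bins <- pairs[, .(mean_count = mean(count), d_centre = exp(mean(log(distance))),
                    n = .N), by = d_bin][order(d_centre)]
  ## merge empty/zero bins into their left neighbour
  while (any(bins$mean_count <= 0) && nrow(bins) > 2) {
    i <- which(bins$mean_count <= 0)[1]
    j <- if (i == 1) 2 else i - 1
    tot <- bins$n[i] + bins$n[j]
    bins$mean_count[j] <- (bins$mean_count[i] * bins$n[i] + bins$mean_count[j] * bins$n[j]) / tot
    bins$d_centre[j] <- exp((log(bins$d_centre[i]) * bins$n[i] +
                             log(bins$d_centre[j]) * bins$n[j]) / tot)
    bins$n[j] <- tot
    bins <- bins[-i]
  }
  if (any(bins$mean_count <= 0)) stop("fit_background: no usable distance bins")
  decay <- data.table(log_d = log(bins$d_centre), log_f = log(bins$mean_count))
  f_of_d <- function(d) exp(approx(decay$log_d, decay$log_f, xout = log(d), rule = 2)$y)

  pairs[, f_d := f_of_d(distance)]

  ## iterative proportional scaling of bait / other-end factors, then
  ## global scale and ML dispersion, on a subset of the pairs
  fit_pass <- function(px, s_j_init = NULL) {
    bait_lev <- sort(unique(px$bait_id)); oe_lev <- sort(unique(px$oe_id))
    bi_idx <- match(px$bait_id, bait_lev); oj_idx <- match(px$oe_id, oe_lev)
    obs_i <- as.vector(rowsum(px$count, bi_idx))
    obs_j <- as.vector(rowsum(px$count, oj_idx))
    f_d <- px$f_d
    s_i <- rep(1, length(bait_lev))
    s_j <- if (is.null(s_j_init)) rep(1, length(oe_lev)) else {
      v <- s_j_init[as.character(oe_lev)]; v[is.na(v)] <- 1; unname(v)
    }
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      s_i <- pmax(obs_i / pmax(as.vector(rowsum(f_d * s_j[oj_idx], bi_idx)), 1e-12), 1e-6)
      new_j <- pmax(obs_j / pmax(as.vector(rowsum(f_d * s_i[bi_idx], oj_idx)), 1e-12), 1e-6)
      delta <- max(abs(log(new_j) - log(s_j)))
      s_j <- new_j
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop("fit_background: factor scaling did not converge after ", max_iter, " iterations")
    gm_i <- exp(mean(log(s_i))); gm_j <- exp(mean(log(s_j)))
    s_i <- s_i / gm_i; s_j <- s_j / gm_j
    base <- f_d * s_i[bi_idx] * s_j[oj_idx]
    m <- sum(px$count) / sum(base)
    mu <- base * m
    nll <- function(log_r) -sum(dnbinom(px$count, size = exp(log_r), mu = mu, log = TRUE))
    r <- exp(optimize(nll, c(log(1e-2), log(1e4)))$minimum)
    list(s_bait = setNames(s_i, bait_lev), s_oe = setNames(s_j, oe_lev),
         m = m, r = r, mu = mu)
  }

  ## other-end totals over a kept subset, for leave-one-bait-out factors
  oe_totals <- function(fit, px) {
    si <- fit$s_bait[as.character(px$bait_id)]; si[is.na(si)] <- 1
    base <- px$f_d * si * fit$m
    lev <- sort(unique(px$oe_id))
    gi <- match(px$oe_id, lev)
    list(obs = setNames(as.vector(rowsum(px$count, gi)), lev),
         den = setNames(as.vector(rowsum(base, gi)), lev))
  }

  ## expected counts with the pair's own contribution removed from its
  ## other-end factor (kept pairs only; held-out pairs use the plain
  ## factor, which already excludes them)
  mu_loo_all <- function(fit, px, keep) {
    si <- fit$s_bait[as.character(px$bait_id)]; si[is.na(si)] <- 1
    sj <- fit$s_oe[as.character(px$oe_id)]; sj[is.na(sj)] <- 1
    base <- px$f_d * si * fit$m
    tot <- oe_totals(fit, px[keep])
    obs_j <- tot$obs[as.character(px$oe_id)]
    den_j <- tot$den[as.character(px$oe_id)]
    s_loo <- (obs_j - px$count) / (den_j - base)
    use <- keep & is.finite(s_loo) & (den_j - base) > 0 & s_loo > 0
    mu <- base * ifelse(use, s_loo, sj)
    pmax(mu, 1e-12)
  }

  fit <- fit_pass(pairs)
  keep <- rep(TRUE, nrow(pairs))
  if (outlier_p > 0) {
    ## iterative outlier trimming: hold out pairs the current fit flags
    ## as signal (on leave-one-out expected counts, so a pair cannot
    ## shelter behind its own inflation of the factor) and refit, until
    ## the held-out set stabilises
    for (pass in 1:6) {
      pv <- interaction_pvalue(pairs$count, mu_loo_all(fit, pairs, keep), fit$r)
      new_keep <- pv >= outlier_p
      if (all(new_keep == keep) || sum(new_keep) < 1000) break
      keep <- new_keep
      fit <- fit_pass(pairs[keep], s_j_init = fit$s_oe)
    }
  }

  tot <- oe_totals(fit, pairs[keep])
  heldout <- pairs[!keep, paste(bait_id, oe_id)]
  structure(list(decay = decay, s_bait = fit$s_bait, s_oe = fit$s_oe,
                 r = fit$r, m = fit$m,
                 oe_obs = tot$obs, oe_den = tot$den,
                 heldout = heldout,
                 max_distance = max_distance, exclude_adjacent = exclude_adjacent),
            class = "chic_background")
}

#' @export
print.chic_background <- function(x, ...) {
  slope <- with(x$decay, stats::coef(stats::lm(log_f ~ log_d))[2])
  cat(sprintf("<chic_background> %d decay bins (log-log slope %.2f), %d bait / %d other-end factors, dispersion r = %.2f, scale m = %.3f\n",
              nrow(x$decay), slope, length(x$s_bait), length(x$s_oe), x$r, x$m))
  invisible(x)
}

#' Expected background counts under a fitted model
#'
#' @param background a `chic_background`.
#' @param bait_id,oe_id fragment ids (factors default to 1 for fragments
#'   unseen during fitting).
#' @param distance midpoint distances (bp).
#' @return numeric vector of expected counts.
#' @export
expected_count <- function(background, bait_id, oe_id, distance) {
  f <- exp(approx(background$decay$log_d, background$decay$log_f,
                  xout = log(pmax(distance, 1)), rule = 2)$y)
  si <- background$s_bait[as.character(bait_id)]; si[is.na(si)] <- 1
  sj <- background$s_oe[as.character(oe_id)]; sj[is.na(sj)] <- 1
  unname(f * si * sj * background$m)
}

#' Leave-one-bait-out expected counts
#'
#' Like [expected_count()], but the other-end factor is recomputed with
#' the tested pair's own observed count removed from the other-end total
#' (and its base expectation from the denominator), so a genuinely
#' enriched pair cannot inflate its own expected value. Pairs that the
#' background fit held out as outliers use the plain factor, which
#' already excludes them.
#'
#' @param background a `chic_background` from [fit_background()].
#' @param bait_id,oe_id fragment ids.
#' @param distance midpoint distances (bp).
#' @param n_obs the observed counts of the same pairs, as used in the
#'   fit.
#' @return numeric vector of expected counts (strictly positive).
#' @export
expected_count_loo <- function(background, bait_id, oe_id, distance, n_obs) {
  f <- exp(approx(background$decay$log_d, background$decay$log_f,
                  xout = log(pmax(distance, 1)), rule = 2)$y)
  si <- background$s_bait[as.character(bait_id)]; si[is.na(si)] <- 1
  sj <- background$s_oe[as.character(oe_id)]; sj[is.na(sj)] <- 1
  base <- f * si * background$m
  obs_j <- background$oe_obs[as.character(oe_id)]
  den_j <- background$oe_den[as.character(oe_id)]
  held <- paste(bait_id, oe_id) %in% background$heldout
  s_loo <- (obs_j - n_obs) / (den_j - base)
  use <- !held & is.finite(s_loo) & (den_j - base) > 0 & s_loo > 0
  unname(pmax(base * ifelse(use, s_loo, sj), 1e-12))
}

#' One-tailed negative-binomial interaction p-value
#'
#' `p = P(X >= N_obs)` for `X ~ NB(mean = N_exp, dispersion = r)`
#' (variance `N_exp + N_exp^2 / r`), inclusive of the observed value;
#' `N_obs = 0` gives `p = 1`.
#'
#' @param n_obs observed counts (non-negative integers).
#' @param n_exp expected counts (> 0).
#' @param r dispersion (> 0); the Poisson limit is `r -> Inf`.
#' @return p-values, vectorised over the inputs.
#' @export
interaction_pvalue <- function(n_obs, n_exp, r) {
  if (any(n_exp <= 0)) stop("interaction_pvalue: N_exp must be > 0")
  if (any(r <= 0)) stop("interaction_pvalue: dispersion r must be > 0")
  if (any(n_obs < 0)) stop("interaction_pvalue: N_obs must be >= 0")
  ifelse(n_obs == 0, 1,
         pnbinom(n_obs - 1, size = r, mu = n_exp, lower.tail = FALSE))
}

#' Distance weight for p-values
#'
#' `w(d) = (1 + d / d0)^(-beta)`, monotone non-increasing in distance.
#' When `normalize = TRUE` the weights are rescaled to mean 1 over the
#' supplied vector (the set of tested pairs), so that weighting is a pure
#' redistribution of stringency across distances.
#'
#' @param distance distances (bp).
#' @param d0 scale (bp), default 300 kb.
#' @param beta decay exponent, default 0.4.
#' @param normalize rescale to mean 1 over `distance`.
#' @return numeric weights.
#' @export
distance_weight <- function(distance, d0 = 3e5, beta = 0.4, normalize = TRUE) {
  w <- (1 + distance / d0)^(-beta)
  if (normalize) w <- w / mean(w)
  w
}

#' Weight a p-value by distance and convert to a score
#'
#' `weighted p = min(1, p / w(distance))`; `score = max(0, -ln(weighted
#' p))`. A score of 5 therefore corresponds to a weighted p of
#' `exp(-5) ~ 6.7e-3`; scores `>= 5` are high-confidence calls. The score
#' is monotone decreasing in p at fixed distance, and non-increasing in
#' distance at fixed p.
#'
#' @param p p-values in `(0, 1]`.
#' @param distance distances (bp), same length.
#' @param weights optional explicit weights (overrides the default weight
#'   function; e.g. `1` for unweighted scores).
#' @param d0,beta,normalize passed to [distance_weight()].
#' @return `data.table(weight, weighted_p, score)`.
#' @export
weight_and_score <- function(p, distance, weights = NULL, d0 = 3e5, beta = 0.4,
                             normalize = TRUE) {
  stopifnot(all(p > 0 & p <= 1))
  w <- if (is.null(weights)) distance_weight(distance, d0, beta, normalize)
       else rep_len(weights, length(p))
  wp <- pmin(1, p / w)
  wp[p == 1] <- 1   # a p of exactly 1 carries no evidence at any distance
  data.table(weight = w, weighted_p = wp, score = pmax(0, -log(wp)))
}

#' Per-fragment interaction calling
#'
#' Scores every testable cis bait-fragment pair against a fitted
#' background: observed count, expected count, one-tailed NB p-value,
#' distance-weighted score.
#'
#' @param contacts pooled `data.table(bait_id, oe_id, count)`.
#' @param fragmap a `fragment_map`.
#' @param background a `chic_background` from [fit_background()].
#' @param d0,beta weighting parameters (see [distance_weight()]).
#' @return `data.table(bait_id, oe_id, distance, N_obs, N_exp, p, score)`.
#' @export
call_interactions <- function(contacts, fragmap, background, d0 = 3e5, beta = 0.4) {
  pairs <- enumerate_cis_pairs(fragmap, background$max_distance,
                               background$exclude_adjacent)
  pairs <- merge(pairs, as.data.table(contacts)[, .(bait_id, oe_id, count)],
                 by = c("bait_id", "oe_id"), all.x = TRUE)
  pairs[is.na(count), count := 0]
  pairs[, N_obs := count][, count := NULL]
  pairs[, N_exp := expected_count(background, bait_id, oe_id, distance)]
  pairs[, p := interaction_pvalue(N_obs, N_exp, background$r)]
  ws <- weight_and_score(pairs$p, pairs$distance, d0 = d0, beta = beta)
  pairs[, score := ws$score]
  pairs[]
}

#' Replicate-consensus significance filter
#'
#' An interaction is significant for a cell type if its combined-replicate
#' score is `>= score_threshold` (default 5); additionally, an interaction
#' with combined score in `[rescue_threshold, score_threshold)` is rescued
#' if it scores `> score_threshold` in at least one of the cell type's own
#' replicates while scoring `<= score_threshold` in every replicate of
#' every other cell type.
#'
#' @param combined `data.table(cell_type, bait_id, oe_id, score)` of
#'   combined-replicate scores (missing pairs count as score 0).
#' @param replicate_scores `data.table(cell_type, replicate, bait_id,
#'   oe_id, score)` of per-replicate scores.
#' @param score_threshold,rescue_threshold score cutoffs (defaults 5, 4).
#' @return `combined` with a logical `significant` column.
#' @export
consensus_filter <- function(combined, replicate_scores,
                             score_threshold = 5, rescue_threshold = 4) {
  if (is.null(replicate_scores) || !nrow(replicate_scores))
    stop("consensus_filter: replicate score table is required")
  cmb <- copy(as.data.table(combined))
  reps <- as.data.table(replicate_scores)
  key <- c("bait_id", "oe_id")
  own <- reps[, .(own_hi = any(score > score_threshold)), by = c("cell_type", key)]
  cmb <- merge(cmb, own, by = c("cell_type", key), all.x = TRUE)
  cmb[is.na(own_hi), own_hi := FALSE]
  ## for each pair and cell type: does any replicate of ANOTHER cell type exceed the threshold?
  hi <- reps[score > score_threshold, unique(.SD), .SDcols = c("cell_type", key)]
  cmb[, other_hi := FALSE]
  if (nrow(hi)) {
    per_pair <- hi[, .(cts = list(unique(cell_type))), by = key]
    cmb <- merge(cmb, per_pair, by = key, all.x = TRUE)
    cmb[, other_hi := mapply(function(ct, cts) !is.null(cts) && any(cts != ct),
                             cell_type, cts)]
    cmb[, cts := NULL]
  }
  cmb[, significant := score >= score_threshold |
        (score >= rescue_threshold & score < score_threshold & own_hi & !other_hi)]
  cmb[, c("own_hi", "other_hi") := NULL]
  cmb[]
}
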