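# Independent brute-force oracles used against the implementation.

# all-pairs interval overlap scan (half-open semantics)
brute_overlaps <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        query$start[i] < subject$end[j] && query$end[i] > subject$start[j]) {
      sid <- if (!is.null(subject$id)) subject$id[j] else j
      out[[length(out) + 1L]] <- c(i, sid)
    }
  }
  if (!length(out)) return(data.table::data.table(query = integer(), subject = integer()))
  m <- do.call(rbind, out)
  data.table::data.table(query = m[, 1], subject = m[, 2])[order(query, subject)]
}

# NB upper tail by direct probability-mass summation, in chunks until the
# remaining mass is negligible (independent of pnbinom)
nb_tail_sum <- function(n_obs, mu, r) {
  if (n_obs == 0) return(1)
  total <- 0
  k <- n_obs
  repeat {
    chunk <- sum(dnbinom(k:(k + 99999), size = r, mu = mu))
    total <- total + chunk
    k <- k + 100000
    if (chunk < 1e-14) break
  }
  total
}

# BH step-up by definition: p_adj(i) = min_{j: p_(j) >= p_i over ranks >= rank_i} ...
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # monotone minimum from the top
  run <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(1, run)
  adj
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
brute_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  idx <- utils::combn(na + nb, na)
  u_obs <- sum(rank(vals)[seq_len(na)]) - na * (na + 1) / 2
  u_all <- apply(idx, 2, function(k) sum(rank(vals)[k]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
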