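#' Simulation configuration
#'
#' Defines a fully specified synthetic PCHi-C study with known ground
#' truth: an in-silico digested genome with baited promoter fragments, an
#' enhancer landscape with a heavy-tailed H3K27ac-like signal (so a
#' ranked inflection point exists), distance-decaying negative-binomial
#' background counts with multiplicative bait/other-end factors, planted
#' promoter-enhancer contacts of configurable fold enrichment and range
#' composition per cell state, TF binding preferentially co-occupying
#' long-range planted contacts, and expression elevated at contacted
#' promoters.
#'
#' Default conditions: two 30 Mb chromosomes digested at ~4 kb (HindIII
#' scale), 160 baits, ~200 enhancer clusters of which 20 are true SEs
#' with a Pareto-amplified signal, background counts with mean 60 at
#' 100 kb decaying as `d^-1` and dispersion 8, two replicates, 60 planted
#' contacts per cell state at 8x enrichment, and long-range planted
#' fractions of 25% ("escLike") versus 7% ("epiLike") mirroring the two
#' pluripotent states compared by the pipeline.
#'
#' @param seed master RNG seed (integer).
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param mean_fragment_length mean restriction-fragment length (bp,
#'   >= 500).
#' @param n_baits number of baited fragments.
#' @param n_enhancer_peaks approximate number of enhancer peaks (>= 10).
#' @param n_true_se number of clusters designated true super-enhancers.
#' @param signal_tail_exponent Pareto tail exponent of the SE signal
#'   amplification (smaller = heavier tail = stochastically larger SE
#'   signal).
#' @param se_signal_scale amplification floor of true-SE signal over the
#'   background enhancer level.
#' @param bg_signal_sdlog log-sd of the background cluster signal.
#' @param decay_exponent power-law distance-decay exponent `alpha`
#'   (`mean ~ d^-alpha`).
#' @param decay_scale mean background count at the 100 kb reference
#'   distance.
#' @param n_reads_scale global multiplier on expected counts.
#' @param dispersion negative-binomial dispersion `r`
#'   (`var = mu + mu^2/r`).
#' @param max_distance maximum cis distance generated/tested (bp).
#' @param bait_factor_sdlog,oe_factor_sdlog log-sd of the multiplicative
#'   capture-efficiency factors (log-normal, mean 1).
#' @param n_planted planted promoter-SE contacts per cell state.
#' @param max_planted_per_se cap on planted contacts per SE region per
#'   cell state (keeps hubs at realistic sizes relative to the bait pool
#'   covering a region).
#' @param fold_enrichment fold enrichment of planted contacts (>= 1).
#' @param lri_fraction named vector: per cell state, the fraction of
#'   planted contacts that are long-range (> 800 kb).
#' @param n_replicates biological replicates per cell state.
#' @param tf_cooccupancy_prob probability that the SE end of a long-range
#'   planted contact is bound by the planted TF.
#' @param tf_base_rate binding rate at other SE ends.
#' @param bait_binding_prob binding rate at bait fragments.
#' @param n_tf_noise_peaks unrelated TF peaks scattered at random.
#' @param expr_base_log2,expr_sd_log2 baseline log2 expression mean / sd.
#' @param expr_uplift_log2 added log2 expression at promoters with a
#'   planted SE contact.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 3e7, chr2 = 3e7),
                       mean_fragment_length = 4000,
                       n_baits = 160,
                       n_enhancer_peaks = 600,
                       n_true_se = 20,
                       signal_tail_exponent = 1.5,
                       se_signal_scale = 30,
                       bg_signal_sdlog = 0.4,
                       decay_exponent = 1.0,
                       decay_scale = 60,
                       n_reads_scale = 1,
                       dispersion = 8,
                       max_distance = 6e6,
                       bait_factor_sdlog = 0.25,
                       oe_factor_sdlog = 0.25,
                       n_planted = 60,
                       max_planted_per_se = 3,
                       fold_enrichment = 8,
                       lri_fraction = c(escLike = 0.25, epiLike = 0.07),
                       n_replicates = 2,
                       tf_cooccupancy_prob = 0.86,
                       tf_base_rate = 0.58,
                       bait_binding_prob = 0.35,
                       n_tf_noise_peaks = 60,
                       expr_base_log2 = 3,
                       expr_sd_log2 = 1.2,
                       expr_uplift_log2 = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$mean_fragment_length >= 500,
            cfg$n_enhancer_peaks >= 10,
            cfg$fold_enrichment >= 1,
            cfg$dispersion > 0,
            all(cfg$lri_fraction >= 0 & cfg$lri_fraction <= 1),
            cfg$tf_cooccupancy_prob >= 0, cfg$tf_cooccupancy_prob <= 1,
            cfg$tf_base_rate >= 0, cfg$tf_base_rate <= 1,
            cfg$n_replicates >= 1, cfg$n_planted >= 0,
            !is.null(names(cfg$lri_fraction)))
  structure(cfg, class = "sim_config")
}

#' Simulate an in-silico digested genome with baits
#'
#' Fragment lengths are i.i.d. shifted-geometric around
#' `mean_fragment_length` (minimum 200 bp); bait fragments are sampled
#' uniformly without replacement and named `gene<id>`. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return a `fragment_map`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  min_len <- 200
  cuts <- lapply(names(config$chrom_sizes), function(cn) {
    size <- config$chrom_sizes[[cn]]
    n_max <- ceiling(size / min_len) + 10
    lens <- min_len + rgeom(ceiling(2.5 * size / config$mean_fragment_length),
                            1 / (config$mean_fragment_length - min_len))
    pos <- cumsum(lens)
    pos[pos < size]
  })
  names(cuts) <- names(config$chrom_sizes)
  fm <- build_fragment_map(config$chrom_sizes, cuts)
  if (config$n_baits > nrow(fm))
    stop("simulate_genome: n_baits (", config$n_baits, ") exceeds fragment count (",
         nrow(fm), ")")
  bait_ids <- sort(sample(fm$id, config$n_baits))
  fm[match(bait_ids, id), `:=`(is_bait = TRUE, genes = paste0("gene", bait_ids))]
  fm[]
}

#' TSS table of a simulated genome
#'
#' Promoter TSSs sit at the midpoints of baited fragments.
#'
#' @param fragmap a `fragment_map` with bait flags.
#' @return `data.table(chrom, pos, gene)`.
#' @export
simulated_tss <- function(fragmap) {
  b <- as.data.table(fragmap)[is_bait == TRUE]
  data.table(chrom = b$chrom, pos = floor((b$start + b$end) / 2), gene = b$genes)
}

#' Simulate an enhancer landscape with designated super-enhancers
#'
#' Enhancer peaks come in clusters (1-5 peaks, gaps < 12.5 kb, so
#' stitching merges the intended constituents; clusters > 30 kb apart).
#' Each cluster gets a log-normal background signal; `n_true_se`
#' designated clusters are amplified by `se_signal_scale` times a
#' Pareto(`signal_tail_exponent`) draw, giving the heavy upper tail that
#' creates the inflection on the ranked density curve. Treatment and
#' input are read counts out of fixed library totals (most ChIP reads
#' fall outside peaks); peaks avoid the TSS exclusion windows of the
#' baits.
#'
#' @param config a [sim_config()].
#' @param fragmap a `fragment_map` from [simulate_genome()].
#' @return `data.table(chrom, start, end, name, treatment, input)` with
#'   attributes `truth` (`data.table(cluster, chrom, start, end,
#'   is_true_se)`) and `library_sizes`.
#' @export
simulate_enhancer_landscape <- function(config, fragmap) {
  set.seed(config$seed + 1L)
  tss <- simulated_tss(fragmap)
  n_clusters <- max(10L, ceiling(config$n_enhancer_peaks / 3))
  sizes <- config$chrom_sizes
  margin <- 30000
  placed <- lapply(names(sizes), function(cn) list(s = numeric(), e = numeric()))
  names(placed) <- names(sizes)
  clusters <- vector("list", n_clusters)
  for (ci in seq_len(n_clusters)) {
    repeat {
      cn <- sample(names(sizes), 1, prob = sizes / sum(sizes))
      k <- sample(1:5, 1)
      widths <- round(runif(k, 800, 2500))
      gaps <- if (k > 1) round(runif(k - 1, 500, 11000)) else numeric()
      span <- sum(widths) + sum(gaps)
      s0 <- floor(runif(1, margin, sizes[[cn]] - span - margin))
      s <- s0 + cumsum(c(0, head(widths, -1) + gaps))
      e <- s + widths
      ## keep clear of other clusters and of TSS exclusion windows
      if (.overlaps_any(s0 - margin, s0 + span + margin,
                        placed[[cn]]$s, placed[[cn]]$e)) next
      t_chr <- tss[chrom == cn]
      if (nrow(t_chr) && any(vapply(seq_len(k), function(j)
        any(t_chr$pos - 3000 < e[j] & t_chr$pos + 3000 > s[j]), TRUE))) next
      placed[[cn]]$s <- c(placed[[cn]]$s, s0 - margin)
      placed[[cn]]$e <- c(placed[[cn]]$e, s0 + span + margin)
      clusters[[ci]] <- data.table(cluster = ci, chrom = cn, start = s, end = e)
      break
    }
  }
  pk <- rbindlist(clusters)
  ## signal: background log-normal per cluster; designated SEs amplified
  n_cl <- max(pk$cluster)
  base <- rlnorm(n_cl, meanlog = 0, sdlog = config$bg_signal_sdlog)
  amp <- rep(1, n_cl)
  true_se <- sort(sample(n_cl, min(config$n_true_se, n_cl)))
  amp[true_se] <- config$se_signal_scale *
    runif(length(true_se))^(-1 / config$signal_tail_exponent)  # Pareto(alpha), min 1
  per_peak <- base[pk$cluster] * amp[pk$cluster]
  pk[, input := round(runif(.N, 20, 60))]
  pk[, treatment := pk$input + round(40 * per_peak * (end - start) / 1500)]
  pk[, name := paste0("peak", seq_len(.N))]
  truth <- pk[, .(start = min(start), end = max(end)), by = .(cluster, chrom)]
  truth[, is_true_se := cluster %in% true_se]
  setcolorder(pk, c("chrom", "start", "end", "name", "treatment", "input"))
  setorder(pk, chrom, start)
  setattr(pk, "truth", truth[order(chrom, start)])
  setattr(pk, "library_sizes", c(treatment = 1e6, input = 1e6))
  pk[]
}

#' Plant promoter-SE contacts per cell state
#'
#' For each cell state, samples `n_planted` (bait, true-SE) cis pairs
#' such that a fraction `lri_fraction[cell]` of them are long-range
#' (midpoint distance > 800 kb) and the rest short-range, all within the
#' generated distance range and with non-empty constituent sets.
#'
#' @param config a [sim_config()].
#' @param fragmap a `fragment_map`.
#' @param truth cluster truth table from [simulate_enhancer_landscape()].
#' @return `data.table(cell_type, bait_id, cluster, chrom, start, end,
#'   fold, distance, true_long)`.
#' @export
plant_contacts <- function(config, fragmap, truth) {
  ses <- truth[is_true_se == TRUE]
  if (!nrow(ses)) stop("plant_contacts: truth table contains no true SEs")
  fm <- as.data.table(fragmap)
  baits <- fm[is_bait == TRUE]
  cand <- rbindlist(lapply(seq_len(nrow(ses)), function(si) {
    se <- ses[si]
    b <- baits[chrom == se$chrom]
    if (!nrow(b)) return(NULL)
    d <- abs((b$start + b$end) / 2 - (se$start + se$end) / 2)
    ## bait must be clear of the SE so the constituent set is non-empty
    ok <- d <= config$max_distance & d >= 1e5 &
      !(b$end > se$start - 2 * config$mean_fragment_length &
        b$start < se$end + 2 * config$mean_fragment_length)
    data.table(bait_id = b$id[ok], cluster = se$cluster, chrom = se$chrom,
               start = se$start, end = se$end, distance = d[ok])
  }))
  cand[, true_long := distance > 8e5]
  out <- vector("list", length(config$lri_fraction))
  for (ci in seq_along(config$lri_fraction)) {
    ct <- names(config$lri_fraction)[ci]
    set.seed(config$seed + 100L + ci)
    n_long <- round(config$n_planted * config$lri_fraction[[ci]])
    n_short <- config$n_planted - n_long
    long_pool <- cand[true_long == TRUE][sample(.N)]
    short_pool <- cand[true_long == FALSE][sample(.N)]
    cap <- config$max_planted_per_se
    take_capped <- function(pool, n_take, used) {
      picked <- integer()
      if (n_take == 0L) return(list(rows = pool[0], used = used))
      for (k in seq_len(nrow(pool))) {
        cl <- as.character(pool$cluster[k])
        cnt <- used[cl]
        if (is.na(cnt)) cnt <- 0L
        if (cnt >= cap) next
        used[cl] <- cnt + 1L
        picked <- c(picked, k)
        if (length(picked) == n_take) break
      }
      list(rows = pool[picked], used = used)
    }
    used <- setNames(integer(0), character(0))
    lp <- take_capped(long_pool, n_long, used)
    sp <- take_capped(short_pool, n_short, lp$used)
    if (nrow(lp$rows) < n_long || nrow(sp$rows) < n_short)
      stop("plant_contacts: candidate pool too small for cell type ", ct,
           " (raise n_true_se / n_baits or max_planted_per_se)")
    pick <- rbind(lp$rows, sp$rows)
    pick[, `:=`(cell_type = ct, fold = config$fold_enrichment)]
    out[[ci]] <- pick
  }
  res <- rbindlist(out)
  setcolorder(res, c("cell_type", "bait_id", "cluster", "chrom", "start", "end",
                     "fold", "distance", "true_long"))
  res[]
}

#' Simulate contact counts per cell state and replicate
#'
#' Background: `count(i, j) ~ NB(mean = decay_scale * (d/1e5)^-alpha *
#' s_i * s_j * n_reads_scale, dispersion = r)` over all cis bait-fragment
#' pairs within `max_distance` (bait and adjacent fragments excluded);
#' planted pairs have the mean multiplied by their fold enrichment. Only
#' cis pairs are generated; replicates are i.i.d. given the cell-state
#' truth. Zero counts are dropped (sparse triplets).
#'
#' @param config a [sim_config()].
#' @param fragmap a `fragment_map`.
#' @param planted planted-contact table from [plant_contacts()] (or
#'   `NULL` for a pure null).
#' @return nested list `contacts[[cell_type]][[replicate]]` of
#'   `data.table(bait_id, oe_id, count)`, with attribute `factors`
#'   (the true `s` factors).
#' @export
simulate_contacts <- function(config, fragmap, planted = NULL) {
  fm <- as.data.table(fragmap)
  if (!is.null(planted) && nrow(planted)) {
    pc <- merge(planted, fm[, .(bait_id = id, bait_chrom = chrom)], by = "bait_id")
    if (any(pc$bait_chrom != pc$chrom))
      stop("simulate_contacts: planted contact on a trans pair")
  }
  set.seed(config$seed + 2L)
  s_bait <- setNames(rlnorm(nrow(fm), 0, config$bait_factor_sdlog), fm$id)
  s_oe <- setNames(rlnorm(nrow(fm), 0, config$oe_factor_sdlog), fm$id)
  pairs <- enumerate_cis_pairs(fm, config$max_distance)
  pairs[, mu := config$decay_scale * (distance / 1e5)^(-config$decay_exponent) *
          s_bait[as.character(bait_id)] * s_oe[as.character(oe_id)] *
          config$n_reads_scale]
  cts <- if (is.null(planted) || !nrow(planted)) names(config$lri_fraction)
         else unique(planted$cell_type)
  out <- vector("list", length(cts)); names(out) <- cts
  for (ci in seq_along(cts)) {
    ct <- cts[ci]
    mu_ct <- pairs$mu
    if (!is.null(planted) && nrow(planted)) {
      pl <- planted[cell_type == ct]
      for (k in seq_len(nrow(pl))) {
        frs <- fm[chrom == pl$chrom[k] & start < pl$end[k] & end > pl$start[k], id]
        hit <- pairs$bait_id == pl$bait_id[k] & pairs$oe_id %in% frs
        mu_ct[hit] <- mu_ct[hit] * pl$fold[k]
      }
    }
    reps <- vector("list", config$n_replicates)
    for (ri in seq_len(config$n_replicates)) {
      set.seed(config$seed + 1000L * ci + ri)
      cnt <- rnbinom(length(mu_ct), size = config$dispersion, mu = mu_ct)
      keep <- cnt > 0
      reps[[ri]] <- data.table(bait_id = pairs$bait_id[keep],
                               oe_id = pairs$oe_id[keep], count = cnt[keep])
    }
    names(reps) <- paste0("rep", seq_len(config$n_replicates))
    out[[ct]] <- reps
  }
  setattr(out, "factors", list(s_bait = s_bait, s_oe = s_oe))
  out
}

#' Simulate TF binding and expression with planted structure
#'
#' A "NANOG-like" factor binds the SE end of planted long-range contacts
#' with probability `tf_cooccupancy_prob`, other planted SE ends at
#' `tf_base_rate`, bait fragments at `bait_binding_prob`, plus scattered
#' noise peaks. Expression is log-normal with `expr_uplift_log2` added at
#' promoters holding a planted SE contact in the given cell state.
#'
#' @param config a [sim_config()].
#' @param fragmap a `fragment_map`.
#' @param truth cluster truth table.
#' @param planted planted-contact table.
#' @return list with `tf_peaks` (`data.table(chrom, start, end, name)`)
#'   and `expression` (`data.table(gene, <cell types...>)`).
#' @export
simulate_binding_and_expression <- function(config, fragmap, truth, planted) {
  set.seed(config$seed + 3L)
  fm <- as.data.table(fragmap)
  ses <- truth[is_true_se == TRUE]
  ## region-level binding: co-occupancy rate if the SE holds any planted
  ## long-range contact (in any cell state), base rate otherwise
  long_clusters <- unique(planted[true_long == TRUE, cluster])
  p_bind <- ifelse(ses$cluster %in% long_clusters,
                   config$tf_cooccupancy_prob, config$tf_base_rate)
  bound <- runif(nrow(ses)) < p_bind
  se_peaks <- ses[bound, .(chrom, start = floor((start + end) / 2) - 400,
                           end = floor((start + end) / 2) + 400)]
  baits <- fm[is_bait == TRUE]
  b_bound <- runif(nrow(baits)) < config$bait_binding_prob
  bait_peaks <- baits[b_bound, .(chrom,
                                 start = floor((start + end) / 2) - 400,
                                 end = floor((start + end) / 2) + 400)]
  cs <- config$chrom_sizes
  noise_chr <- sample(names(cs), config$n_tf_noise_peaks, replace = TRUE,
                      prob = cs / sum(cs))
  noise_s <- floor(runif(config$n_tf_noise_peaks, 0, unlist(cs[noise_chr]) - 800))
  noise <- data.table(chrom = noise_chr, start = noise_s, end = noise_s + 800)
  tf <- rbindlist(list(se_peaks, bait_peaks, noise))
  setorder(tf, chrom, start)
  tf[, name := paste0("tfpeak", .I)]

  genes <- baits$genes
  expr <- data.table(gene = genes)
  for (ct in names(config$lri_fraction)) {
    contacted <- baits$id %in% planted[cell_type == ct, bait_id]
    expr[, (ct) := rnorm(length(genes), config$expr_base_log2, config$expr_sd_log2) +
            config$expr_uplift_log2 * contacted]
  }
  list(tf_peaks = tf[], expression = expr[])
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_enhancer_landscape()],
#' [plant_contacts()], [simulate_contacts()] and
#' [simulate_binding_and_expression()] under one config, returning all
#' components plus ground-truth tables. Fully deterministic given the
#' config (including its seed).
#'
#' @param config a [sim_config()].
#' @param null_contacts generate a pure background dataset (no planted
#'   contacts).
#' @return list of class `synthetic_dataset` with elements `fragmap`,
#'   `tss`, `enhancer_peaks`, `contacts`, `tf_peaks`, `expression`,
#'   `truth` (list: `clusters`, `planted`), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), null_contacts = FALSE) {
  fragmap <- simulate_genome(config)
  peaks <- simulate_enhancer_landscape(config, fragmap)
  truth <- attr(peaks, "truth")
  planted <- if (null_contacts) NULL else plant_contacts(config, fragmap, truth)
  contacts <- simulate_contacts(config, fragmap, planted)
  be <- simulate_binding_and_expression(config, fragmap, truth,
                                        if (is.null(planted))
                                          data.table(cell_type = character(),
                                                     bait_id = integer(),
                                                     cluster = integer(),
                                                     true_long = logical())
                                        else planted)
  structure(list(fragmap = fragmap, tss = simulated_tss(fragmap),
                 enhancer_peaks = peaks, contacts = contacts,
                 tf_peaks = be$tf_peaks, expression = be$expression,
                 truth = list(clusters = truth, planted = planted),
                 config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits every on-disk dialect the pipeline reads: fragment map, baitmap,
#' per-cell-type per-replicate contact triplets, enhancer signal-BED, TF
#' BED, expression TSV, and `truth/*.tsv` tables.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fragment_map(ds$fragmap, file.path(dir, "fragments.tsv"))
  write_baitmap(ds$fragmap, file.path(dir, "baitmap.tsv"))
  for (ct in names(ds$contacts))
    for (rp in names(ds$contacts[[ct]]))
      write_contacts(ds$contacts[[ct]][[rp]],
                     file.path(dir, sprintf("contacts_%s_%s.tsv", ct, rp)))
  fwrite(ds$enhancer_peaks, file.path(dir, "enhancer_peaks.bed"),
         sep = "\t", col.names = FALSE)
  write_bed(ds$tf_peaks, file.path(dir, "tf_peaks.bed"))
  write_expression(ds$expression, file.path(dir, "expression.tsv"))
  fwrite(ds$truth$clusters, file.path(dir, "truth", "clusters.tsv"), sep = "\t")
  if (!is.null(ds$truth$planted))
    fwrite(ds$truth$planted, file.path(dir, "truth", "planted.tsv"), sep = "\t")
  invisible(dir)
}
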