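#' Pipeline configuration
#'
#' One master seed drives every stage (per-stage seeds are derived by
#' fixed offsets); stage parameters default to the package defaults.
#'
#' @param seed master seed.
#' @param sim a [sim_config()] (its own seed is overridden by
#'   `seed + 10`).
#' @param se an [se_config()] (tier size defaults to 40 at the default
#'   simulated landscape scale, ~200 clusters).
#' @param lri an [lri_config()].
#' @param score_threshold,rescue_threshold interaction score cutoffs.
#' @param d0,beta p-value weighting parameters.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(),
                            se = se_config(tier_size = 40),
                            lri = lri_config(),
                            score_threshold = 5,
                            rescue_threshold = 4,
                            d0 = 3e5, beta = 0.4) {
  sim$seed <- seed + 10L
  structure(list(seed = seed, sim = sim, se = se, lri = lri,
                 score_threshold = score_threshold,
                 rescue_threshold = rescue_threshold, d0 = d0, beta = beta),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `seed`, `score_threshold`, `rescue_threshold`, `d0`,
#' `beta` and nested blocks `sim`, `se`, `lri` override the defaults of
#' [pipeline_config()], [sim_config()], [se_config()], [lri_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("chrom_sizes", "lri_fraction"))
    if (!is.null(y$sim[[nm]])) y$sim[[nm]] <- unlist(y$sim[[nm]])
  sim <- do.call(sim_config, c(y$sim %||% list()))
  se <- do.call(se_config, y$se %||% list())
  lri <- do.call(lri_config, y$lri %||% list())
  args <- y[setdiff(names(y), c("sim", "se", "lri"))]
  do.call(pipeline_config, c(list(sim = sim, se = se, lri = lri), args))
}

#' Run the full promoter-SE interactome pipeline
#'
#' Stages, in dependency order: synthetic-data generation; SE calling
#' (stitch, score, inflection threshold, tiers); per-cell-state
#' background fit on pooled replicates and composite interaction calling
#' over SE / NE / LE / shuffled-control regions; distance classification
#' and per-SE engagement classes; cross-cell-state comparison
#' (SE-interacting gene sets, LRI-proportion chi-square with BH
#' adjustment, TF enrichment, expression rank test, hub statistics). All
#' stage outputs are written as TSV under `out_dir` together with a
#' `manifest.json` recording the config hash, seeds and versions; a rerun
#' with the same config reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list with all in-memory stage results.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## -- simulate ------------------------------------------------------
  ds <- stage("simulate", simulate_dataset(config$sim))
  write_synthetic_dataset(ds, file.path(out_dir, "data"))

  ## -- call-se -------------------------------------------------------
  se_res <- stage("call-se", {
    stitched <- stitch_peaks(ds$enhancer_peaks,
                             tss = ds$tss[, .(chrom, pos)], config = config$se)
    scored <- score_stitched(stitched,
                             library_sizes = attr(ds$enhancer_peaks, "library_sizes"))
    called <- call_super_enhancers(scored)
    tiers <- select_enhancer_tiers(called, config$se)
    list(called = called, tiers = tiers)
  })
  fwrite(se_res$called[, .(chrom, start, end, region_id, density, rank_, is_SE)],
         file.path(out_dir, "stitched_enhancers.tsv"), sep = "\t")

  ses <- se_res$called[is_SE == TRUE, .(region_id, chrom, start, end)]
  ses <- filter_regions_overlapping_baits(ses, ds$fragmap)
  cs <- fm_chrom_sizes(ds$fragmap)

  ## -- make-controls -------------------------------------------------
  ctrl <- stage("make-controls",
                shuffle_within_chromosome(ses, cs, seed = config$seed + 20L))
  ne_ext <- stage("make-controls", extend_to_size_match(
    se_res$tiers$NE[, .(region_id, chrom, start, end)], ses, ds$fragmap,
    seed = config$seed + 21L))
  le_ext <- stage("make-controls", extend_to_size_match(
    se_res$tiers$LE[, .(region_id, chrom, start, end)], ses, ds$fragmap,
    seed = config$seed + 22L))
  regions <- rbindlist(list(
    ses[, .(chrom, start, end, source_label = "SE")],
    ne_ext[, .(chrom, start, end, source_label = "NE")],
    le_ext[, .(chrom, start, end, source_label = "LE")],
    ctrl[, .(chrom, start, end, source_label = "CTRL")]))
  regions[, region_id := .I]
  write_bed(regions[, .(chrom, start, end, name = paste0(source_label, "_", region_id))],
            file.path(out_dir, "regions.bed"))

  ## -- call-interactions + se-interactome per cell state -------------
  bait_ids <- as.data.table(ds$fragmap)[is_bait == TRUE, id]
  per_ct <- list()
  for (ct in names(ds$contacts)) {
    reps <- ds$contacts[[ct]]
    pooled <- pool_replicates(reps)
    bg <- stage("call-interactions",
                fit_background(pooled, ds$fragmap,
                               max_distance = config$sim$max_distance))
    comp <- stage("se-interactome",
                  call_composite_interactions(bait_ids, regions, pooled, bg,
                                              ds$fragmap,
                                              score_threshold = config$score_threshold,
                                              d0 = config$d0, beta = config$beta))
    comp <- classify_range(comp, config$lri)
    per_ct[[ct]] <- list(background = bg, composite = comp)
    fwrite(comp[, .(region_id, bait_id, source_label, n_frag, N_obs, N_exp, p,
                    score, distance, significant, range_class)],
           file.path(out_dir, sprintf("composite_%s.tsv", ct)), sep = "\t")
  }

  ## -- compare -------------------------------------------------------
  cmp <- stage("compare", {
    fm <- as.data.table(ds$fragmap)
    gene_of <- setNames(fm$genes, fm$id)
    sig_se <- lapply(per_ct, function(x)
      x$composite[significant == TRUE & source_label == "SE"])
    genes_by_ct <- lapply(sig_se, function(s) unique(unname(gene_of[as.character(s$bait_id)])))
    sets <- compare_interactomes(genes_by_ct)
    lri_tab <- vapply(sig_se, function(s)
      c(long = sum(s$range_class == "long"), short = sum(s$range_class == "short")),
      numeric(2))
    lri_frac <- lri_tab["long", ] / colSums(lri_tab)
    cts <- names(sig_se)
    chisq <- if (length(cts) >= 2 && all(colSums(lri_tab[, 1:2]) > 0))
      tryCatch(chisq_independence(t(lri_tab[, 1:2])), error = function(e) NULL)
    else NULL
    engagement <- lapply(sig_se, classify_se_engagement)
    hubs <- lapply(sig_se, hub_statistics)
    list(gene_sets = sets, lri_table = lri_tab, lri_fraction = lri_frac,
         lri_chisq = chisq, engagement = engagement, hubs = hubs)
  })

  ## -- manifest ------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stage_seeds = list(sim = config$sim$seed, shuffle = config$seed + 20L,
                       ne_extend = config$seed + 21L, le_extend = config$seed + 22L),
    package_version = as.character(utils::packageVersion("sehub")),
    r_version = R.version.string,
    n_fragments = nrow(ds$fragmap),
    n_baits = length(bait_ids),
    n_se = nrow(ses),
    cell_types = names(ds$contacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = ds, se = se_res, regions = regions,
                 controls = list(shuffle = ctrl, ne = ne_ext, le = le_ext),
                 per_cell_type = per_ct, comparison = cmp,
                 manifest = manifest))
}
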