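#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, the convention used
#' throughout the package (and natively by BED).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; require `0 <= start < end`.
#' @param ... further equal-length columns (e.g. `name`, `signal`).
#' @return a `data.table` with columns `chrom`, `start`, `end`, and any
#'   extra columns, ordered as given.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  x <- data.table(chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end), ...)
  validate_intervals(x)
  x
}

#' Validate interval invariants
#'
#' Checks `start >= 0` and `start < end` on every row; errors otherwise.
#'
#' @param x a data.frame with `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at row %d (start=%s, end=%s); need 0 <= start < end",
                 what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

#' Build a restriction-fragment map from cut positions
#'
#' Emulates an in-silico digestion: per chromosome, `k` internal cut
#' positions yield `k + 1` fragments tiling `[0, size)` exactly.
#' Fragment ids are integers assigned in genome order (order of
#' `chrom_sizes`, then position) and are stable across runs.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @param cut_positions named list of sorted cut positions per chromosome,
#'   each strictly inside `(0, size)` and strictly increasing. Chromosomes
#'   absent from the list get a single fragment.
#' @param baits optional named list or vector: fragment id -> gene name(s)
#'   (character vector or `";"`-separated string) marking baited
#'   (promoter-containing) fragments.
#' @return a `fragment_map`: `data.table` with columns `chrom`, `start`,
#'   `end`, `id`, `is_bait`, `genes`, plus a `chrom_sizes` attribute.
#' @export
build_fragment_map <- function(chrom_sizes, cut_positions = list(), baits = list()) {
  stopifnot(length(chrom_sizes) > 0, !is.null(names(chrom_sizes)))
  unknown <- setdiff(names(cut_positions), names(chrom_sizes))
  if (length(unknown)) stop("cut positions given for unknown chromosome: ", unknown[1])
  pieces <- lapply(names(chrom_sizes), function(cn) {
    size <- chrom_sizes[[cn]]
    cuts <- as.numeric(cut_positions[[cn]])
    if (length(cuts)) {
      if (is.unsorted(cuts, strictly = TRUE))
        stop("cut positions on ", cn, " must be strictly increasing")
      if (any(cuts <= 0 | cuts >= size))
        stop("cut positions on ", cn, " must lie strictly inside (0, ", size, ")")
    }
    bounds <- c(0, cuts, size)
    data.table(chrom = cn, start = bounds[-length(bounds)], end = bounds[-1])
  })
  fm <- rbindlist(pieces)
  fm[, id := seq_len(.N)]
  fm[, is_bait := FALSE]
  fm[, genes := NA_character_]
  if (length(baits)) {
    ids <- suppressWarnings(as.integer(names(baits)))
    if (anyNA(ids)) stop("bait ids must be integer fragment ids; got: ",
                         names(baits)[which(is.na(ids))[1]])
    missing <- setdiff(ids, fm$id)
    if (length(missing)) stop("bait fragment id not in map: ", missing[1])
    gene_str <- vapply(baits, function(g) paste(g, collapse = ";"), character(1))
    fm[match(ids, id), `:=`(is_bait = TRUE, genes = gene_str)]
  }
  setattr(fm, "chrom_sizes", chrom_sizes)
  setattr(fm, "class", c("fragment_map", class(fm)))
  fm[]
}

#' Chromosome sizes of a fragment map
#'
#' Uses the stored attribute when present, otherwise the tiling invariant
#' (max fragment end per chromosome equals the chromosome size).
#'
#' @param fragmap a `fragment_map`.
#' @return named numeric vector.
#' @export
fm_chrom_sizes <- function(fragmap) {
  cs <- attr(fragmap, "chrom_sizes")
  if (!is.null(cs)) return(cs)
  s <- fragmap[, max(end), by = chrom]
  setNames(s$V1, s$chrom)
}

#' Validate fragment-map invariants
#'
#' Fragments must be sorted, non-overlapping and contiguous within each
#' chromosome (each fragment's end equals the next fragment's start), and
#' tile `[0, size)`.
#'
#' @param fragmap a `fragment_map`.
#' @return `fragmap`, invisibly; errors on violation.
#' @export
validate_fragment_map <- function(fragmap) {
  validate_intervals(fragmap, "fragment map")
  ok <- fragmap[, {
    o <- order(start)
    all(start[o][1] == 0) && all(abs(end[o][-.N] - start[o][-1]) < 1e-9)
  }, by = chrom]
  if (!all(ok$V1)) stop("fragment map not contiguous on ", ok$chrom[!ok$V1][1])
  if (anyDuplicated(fragmap$id)) stop("duplicated fragment id")
  invisible(fragmap)
}

## internal: 0-based half-open data.frame -> GRanges (1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Find overlapping interval pairs
#'
#' Reports a pair iff the two intervals share at least 1 bp under
#' half-open semantics (abutting intervals do not overlap). Backed by
#' [GenomicRanges::findOverlaps()].
#'
#' @param query,subject data.frames with `chrom`, `start`, `end` (e.g. a
#'   peak set or a `fragment_map`).
#' @return `data.table(query, subject)` of indices (1-based row numbers;
#'   for a subject carrying an `id` column, `subject` is that id), sorted
#'   by query then subject. Empty inputs give an empty result.
#' @export
find_overlaps <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.table(query = integer(), subject = integer()))
  validate_intervals(query, "query"); validate_intervals(subject, "subject")
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(query), .as_granges(subject)))
  sidx <- S4Vectors::subjectHits(hits)
  sid <- if (!is.null(subject$id)) subject$id[sidx] else sidx
  res <- data.table(query = S4Vectors::queryHits(hits), subject = sid)
  setorder(res, query, subject)
  res[]
}

#' Fragment midpoints
#'
#' @param x intervals with `start`, `end`.
#' @return numeric vector of `(start + end) / 2`.
#' @export
interval_midpoint <- function(x) (x$start + x$end) / 2
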