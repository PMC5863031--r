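## Readers / writers for the pipeline's on-disk dialects. All files are
## plain TSV; coordinates on disk are 0-based half-open (BED-style), the
## same convention used in memory, so no shifting happens here.

.read_tsv_checked <- function(path, n_min, n_max, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_min | nf > n_max)
  if (length(bad)) stop(sprintf("%s: malformed line %d in %s (%d fields, expected %d..%d)",
                                what, bad[1], path, nf[bad[1]], n_min, n_max))
  fields
}

.num_checked <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) stop(what, ": non-numeric field in ", path,
                     " at line ", which(is.na(v))[1])
  v
}

#' Read / write a fragment map
#'
#' Dialect: headerless TSV `chrom  start  end  fragment_id`.
#'
#' @param path file path.
#' @param fragmap a `fragment_map` (writer).
#' @param chrom_sizes optional named vector; inferred from the tiling when
#'   omitted.
#' @return reader: a `fragment_map` (bait annotation all-`FALSE`; combine
#'   with [read_baitmap()]); writer: `path`, invisibly.
#' @seealso [read_baitmap()]
#' @export
read_fragment_map <- function(path, chrom_sizes = NULL) {
  f <- .read_tsv_checked(path, 4, 4, "fragment-map")
  if (is.null(f)) stop("fragment-map: empty file: ", path)
  fm <- data.table(chrom = vapply(f, `[`, "", 1),
                   start = .num_checked(vapply(f, `[`, "", 2), "fragment-map", path),
                   end   = .num_checked(vapply(f, `[`, "", 3), "fragment-map", path),
                   id    = as.integer(.num_checked(vapply(f, `[`, "", 4), "fragment-map", path)))
  fm[, is_bait := FALSE]
  fm[, genes := NA_character_]
  validate_intervals(fm, "fragment-map")
  if (!is.null(chrom_sizes)) setattr(fm, "chrom_sizes", chrom_sizes)
  setattr(fm, "class", c("fragment_map", class(fm)))
  validate_fragment_map(fm)
  fm[]
}

#' @rdname read_fragment_map
#' @export
write_fragment_map <- function(fragmap, path) {
  fwrite(fragmap[, .(chrom, start, end, id)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a baitmap
#'
#' Dialect: headerless TSV `chrom  start  end  fragment_id  gene_names`
#' with `";"`-separated gene names. Applied to a fragment map with
#' [apply_baitmap()].
#'
#' @param path file path.
#' @param fragmap a `fragment_map` with bait annotation (writer) or to
#'   annotate (apply).
#' @param baitmap reader output.
#' @return reader: `data.table(chrom, start, end, id, genes)`.
#' @export
read_baitmap <- function(path) {
  f <- .read_tsv_checked(path, 5, 5, "baitmap")
  if (is.null(f)) stop("baitmap: empty file: ", path)
  data.table(chrom = vapply(f, `[`, "", 1),
             start = .num_checked(vapply(f, `[`, "", 2), "baitmap", path),
             end   = .num_checked(vapply(f, `[`, "", 3), "baitmap", path),
             id    = as.integer(.num_checked(vapply(f, `[`, "", 4), "baitmap", path)),
             genes = vapply(f, `[`, "", 5))
}

#' @rdname read_baitmap
#' @export
write_baitmap <- function(fragmap, path) {
  fwrite(fragmap[is_bait == TRUE, .(chrom, start, end, id, genes)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname read_baitmap
#' @export
apply_baitmap <- function(fragmap, baitmap) {
  missing <- setdiff(baitmap$id, fragmap$id)
  if (length(missing)) stop("baitmap id not in fragment map: ", missing[1])
  fragmap[, is_bait := FALSE]
  fragmap[, genes := NA_character_]
  fragmap[match(baitmap$id, id), `:=`(is_bait = TRUE, genes = baitmap$genes)]
  fragmap[]
}

#' Read / write contact-count triplets
#'
#' Dialect: headerless TSV `bait_fragment_id  otherend_fragment_id  count`,
#' one file per replicate per cell type; only non-zero cis counts are
#' stored.
#'
#' @param path file path.
#' @param contacts `data.table(bait_id, oe_id, count)`.
#' @return reader: `data.table(bait_id, oe_id, count)`.
#' @export
read_contacts <- function(path) {
  f <- .read_tsv_checked(path, 3, 3, "contact-triplets")
  if (is.null(f))
    return(data.table(bait_id = integer(), oe_id = integer(), count = numeric()))
  ct <- data.table(
    bait_id = as.integer(.num_checked(vapply(f, `[`, "", 1), "contact-triplets", path)),
    oe_id   = as.integer(.num_checked(vapply(f, `[`, "", 2), "contact-triplets", path)),
    count   = .num_checked(vapply(f, `[`, "", 3), "contact-triplets", path))
  if (any(ct$count < 0)) stop("contact-triplets: negative count at line ",
                              which(ct$count < 0)[1], " in ", path)
  ct
}

#' @rdname read_contacts
#' @export
write_contacts <- function(contacts, path) {
  fwrite(contacts[, .(bait_id, oe_id, count)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write BED peak files
#'
#' BED4+ `chrom start end name [signal ...]`: plain peaks carry an
#' optional numeric `signal` column; enhancer peak files carry two numeric
#' columns `treatment` and `input` (read counts in the ChIP and input
#' libraries).
#'
#' @param path file path.
#' @param x intervals to write; extra columns beyond `chrom,start,end`
#'   are written in the order given.
#' @return reader: `data.table` with `chrom,start,end[,name][,signal]`
#'   (or `treatment,input` for `read_enhancer_peaks`).
#' @export
read_bed <- function(path) {
  f <- .read_tsv_checked(path, 3, 5, "peaks-BED")
  if (is.null(f)) return(data.table(chrom = character(), start = numeric(),
                                    end = numeric(), name = character()))
  nf <- lengths(f)
  x <- data.table(chrom = vapply(f, `[`, "", 1),
                  start = .num_checked(vapply(f, `[`, "", 2), "peaks-BED", path),
                  end   = .num_checked(vapply(f, `[`, "", 3), "peaks-BED", path))
  if (all(nf >= 4)) x[, name := vapply(f, `[`, "", 4)]
  if (all(nf >= 5)) x[, signal := .num_checked(vapply(f, `[`, "", 5), "peaks-BED", path)]
  validate_intervals(x, "peaks-BED")
  x
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "peaks-BED")
  fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
read_enhancer_peaks <- function(path) {
  f <- .read_tsv_checked(path, 6, 6, "signal-BED")
  if (is.null(f)) stop("signal-BED: empty file: ", path)
  x <- data.table(chrom = vapply(f, `[`, "", 1),
                  start = .num_checked(vapply(f, `[`, "", 2), "signal-BED", path),
                  end   = .num_checked(vapply(f, `[`, "", 3), "signal-BED", path),
                  name  = vapply(f, `[`, "", 4),
                  treatment = .num_checked(vapply(f, `[`, "", 5), "signal-BED", path),
                  input     = .num_checked(vapply(f, `[`, "", 6), "signal-BED", path))
  validate_intervals(x, "signal-BED")
  x
}

#' Read / write an expression table
#'
#' TSV with header; first column `gene`, remaining columns numeric
#' expression values (e.g. log2 RPKM per cell type).
#'
#' @param path file path.
#' @param x expression `data.table`.
#' @return reader: `data.table`.
#' @export
read_expression <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE)
  if (names(x)[1] != "gene") stop("expression-TSV: first column must be 'gene' in ", path)
  num <- vapply(x[, -1], is.numeric, TRUE)
  if (!all(num)) stop("expression-TSV: non-numeric column '", names(num)[!num][1],
                      "' in ", path)
  x
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  fwrite(x, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read / write the canonical interaction table
#'
#' TSV with header and columns `bait_chrom, bait_start, bait_end,
#' bait_genes, oe_chrom, oe_start, oe_end, oe_id, N_obs, N_exp, p, score,
#' distance` (the package's ibed-like dialect). An interaction with
#' `score >= 5` is a high-confidence call.
#'
#' @param path file path.
#' @param x interaction `data.table` with at least those columns.
#' @return reader: `data.table`.
#' @export
read_interactions <- function(path) {
  cols <- c("bait_chrom", "bait_start", "bait_end", "bait_genes", "oe_chrom",
            "oe_start", "oe_end", "oe_id", "N_obs", "N_exp", "p", "score", "distance")
  x <- fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(cols, names(x))
  if (length(missing)) stop("interaction-table: missing column '", missing[1], "' in ", path)
  if (any(x$p < 0 | x$p > 1)) stop("interaction-table: p outside [0,1] at line ",
                                   which(x$p < 0 | x$p > 1)[1] + 1, " in ", path)
  x
}

#' @rdname read_interactions
#' @export
write_interactions <- function(x, path) {
  fwrite(x, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
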