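#' Segmented single-cell count container
#'
#' Bundles a cells-by-segments matrix of non-negative integer counts for one
#' modality (RNA or ATAC) together with cell barcodes, segment identifiers and
#' per-cell library size factors. This is the representation the mixture model
#' consumes: each column is a genomic segment assumed to carry a single latent
#' copy-number state per clone, each row a cell.
#'
#' @param counts Numeric matrix, cells x segments, non-negative integers.
#' @param barcodes Character vector of unique cell identifiers (one per row).
#' @param segment_ids Character vector of segment identifiers (one per column).
#' @param modality `"RNA"` or `"ATAC"`.
#' @param library_factors Optional positive per-cell scaling factors; computed
#'   with [compute_library_factors()] when `NULL`.
#'
#' @return An object of class `segmented_counts`: a list with elements
#'   `counts`, `barcodes`, `segment_ids`, `modality`, `library_factors`.
#' @export
segmented_counts <- function(counts, barcodes, segment_ids,
                             modality = c("RNA", "ATAC"),
                             library_factors = NULL) {
  modality <- match.arg(modality)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be finite non-negative integers")
  }
  counts <- round(counts)
  barcodes <- as.character(barcodes)
  segment_ids <- as.character(segment_ids)
  if (length(barcodes) != nrow(counts))
    stop("one barcode per row of counts required")
  if (anyDuplicated(barcodes))
    stop("barcodes must be unique")
  if (length(segment_ids) != ncol(counts))
    stop("one segment_id per column of counts required")
  if (anyDuplicated(segment_ids))
    stop("segment_ids must be unique")
  dimnames(counts) <- list(barcodes, segment_ids)
  if (is.null(library_factors)) {
    library_factors <- compute_library_factors(counts)
  } else {
    if (length(library_factors) != nrow(counts))
      stop("one library factor per cell required")
    if (any(!is.finite(library_factors)) || any(library_factors <= 0))
      stop("library factors must be strictly positive")
  }
  structure(
    list(counts = counts, barcodes = barcodes, segment_ids = segment_ids,
         modality = modality, library_factors = as.numeric(library_factors)),
    class = "segmented_counts"
  )
}

#' @export
print.segmented_counts <- function(x, ...) {
  cat(sprintf("<segmented_counts> %s: %d cells x %d segments\n",
              x$modality, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.segmented_counts <- function(x) dim(x$counts)

#' Read a genome segmentation from a BED-like file
#'
#' Parses a tab-separated file with at least three columns (chrom, start, end;
#' 0-based half-open coordinates). An optional fourth column gives the segment
#' identifier and an optional fifth the expected (prior) copy number of the
#' segment, used to centre the Dirichlet prior. Missing identifiers are
#' auto-generated as `"chrom:start-end"`; missing expected copy numbers default
#' to 2 (diploid). Records are sorted by (chrom, start) and segments on the
#' same chromosome must not overlap.
#'
#' @param path Path to the BED-like file (plain or gzipped).
#' @return A `data.frame` of class `segmentation` with columns `chrom`,
#'   `start`, `end`, `segment_id`, `expected_cn`.
#' @export
read_segments <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) stop("no segment records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3L))
    stop("line ", which(n_col < 3L)[1], ": fewer than 3 tab-separated columns")
  parse_int <- function(s, what, line) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v) || v != floor(v))
      stop("line ", line, ": malformed ", what, " coordinate '", s, "'")
    v
  }
  recs <- lapply(seq_along(fields), function(j) {
    f <- fields[[j]]
    start <- parse_int(f[2], "start", j)
    end <- parse_int(f[3], "end", j)
    if (start < 0) stop("line ", j, ": negative start coordinate")
    if (start >= end)
      stop("line ", j, ": empty or inverted interval (start >= end)")
    id <- if (length(f) >= 4 && nzchar(f[4])) f[4] else
      sprintf("%s:%d-%d", f[1], start, end)
    cn <- if (length(f) >= 5 && nzchar(f[5])) {
      v <- suppressWarnings(as.numeric(f[5]))
      if (is.na(v) || v != floor(v) || v < 1)
        stop("line ", j, ": expected_cn must be a positive integer")
      as.integer(v)
    } else 2L
    data.frame(chrom = f[1], start = start, end = end, segment_id = id,
               expected_cn = cn, stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, recs)
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  if (anyDuplicated(seg$segment_id))
    stop("duplicated segment_id: ",
         paste(unique(seg$segment_id[duplicated(seg$segment_id)]), collapse = ", "))
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", chr)
  }
  class(seg) <- c("segmentation", "data.frame")
  seg
}

#' Read a 10x-style MatrixMarket triplet into a feature count matrix
#'
#' Reads a sparse feature-by-cell matrix (`matrix.mtx[.gz]`) together with a
#' feature table (`features.tsv[.gz]`: id, name, chrom, start, end) and a
#' barcode list (`barcodes.tsv[.gz]`).
#'
#' @param dir Directory containing the three files, or a character vector of
#'   length 3 with the paths `c(mtx, features, barcodes)`.
#' @return A list with `counts` (features x cells, sparse), and a `features`
#'   data.frame with columns `feature_id`, `name`, `chrom`, `start`, `end`,
#'   and `barcodes`.
#' @export
read_feature_matrix <- function(dir) {
  find1 <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    stop("cannot locate ", stems[1], "[.gz] in ", dir)
  }
  if (length(dir) == 3L && all(file.exists(dir))) {
    paths <- dir
  } else {
    paths <- c(find1(c("matrix.mtx")), find1(c("features.tsv", "genes.tsv")),
               find1(c("barcodes.tsv")))
  }
  open_maybe_gz <- function(p) if (grepl("\\.gz$", p)) gzfile(p) else p
  m <- Matrix::readMM(open_maybe_gz(paths[1]))
  feat <- utils::read.table(open_maybe_gz(paths[2]), sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(feat) < 5)
    stop("features table needs 5 columns: id, name, chrom, start, end")
  names(feat)[1:5] <- c("feature_id", "name", "chrom", "start", "end")
  bc <- utils::read.table(open_maybe_gz(paths[3]), sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)[[1]]
  if (nrow(feat) != nrow(m) || length(bc) != ncol(m))
    stop("matrix dimensions do not match features/barcodes tables")
  list(counts = m, features = feat[, 1:5], barcodes = as.character(bc))
}

#' Aggregate per-feature counts to segment-level counts
#'
#' Assigns each feature (gene or peak) to the segment containing its midpoint
#' and sums counts per segment within each cell. Features whose midpoint falls
#' in no segment are dropped.
#'
#' @param features A list as returned by [read_feature_matrix()], or any list
#'   with `counts` (features x cells), `features` (data.frame with `chrom`,
#'   `start`, `end`) and `barcodes`.
#' @param segments A `segmentation` from [read_segments()].
#' @param modality `"RNA"` or `"ATAC"`.
#' @return A [segmented_counts()] object with attribute `features_per_segment`
#'   (named integer vector).
#' @export
aggregate_to_segments <- function(features, segments,
                                  modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  ft <- features$features
  mid <- floor((ft$start + ft$end) / 2)
  # BED half-open segments: midpoint m belongs to [start, end) i.e. start<=m<end
  gr_feat <- GenomicRanges::GRanges(ft$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  gr_seg <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start + 1L,
                                                    segments$end))
  hits <- GenomicRanges::findOverlaps(gr_feat, gr_seg, select = "first")
  assigned <- !is.na(hits)
  if (!any(assigned))
    stop("segmentation and features do not overlap")
  m <- features$counts[assigned, , drop = FALSE]
  grp <- factor(hits[assigned], levels = seq_len(nrow(segments)))
  # sum feature rows per segment; works for sparse and dense inputs
  agg <- matrix(0, nrow = nrow(segments), ncol = ncol(m))
  for (lev in levels(grp)[tabulate(grp) > 0]) {
    rows <- which(grp == lev)
    agg[as.integer(lev), ] <- as.numeric(Matrix::colSums(m[rows, , drop = FALSE]))
  }
  nfeat <- tabulate(grp, nbins = nrow(segments))
  names(nfeat) <- segments$segment_id
  out <- segmented_counts(t(agg), features$barcodes, segments$segment_id,
                          modality = modality)
  attr(out, "features_per_segment") <- nfeat
  attr(out, "n_features_dropped") <- sum(!assigned)
  out
}

#' Per-cell library size factors
#'
#' The library factor of a cell is its total count divided by the mean total
#' count over cells, so the factors average to 1 and the segment rates stay
#' interpretable as expected counts per copy in an average cell.
#'
#' @param counts A cells x segments count matrix or a `segmented_counts`.
#' @return Positive numeric vector, one factor per cell, mean 1.
#' @export
compute_library_factors <- function(counts) {
  if (inherits(counts, "segmented_counts")) counts <- counts$counts
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    bad <- rownames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("cells with zero total count: ", paste(bad, collapse = ", "))
  }
  as.numeric(totals / mean(totals))
}

#' Remove segments with too many zero-count cells
#'
#' A segment is dropped when, in any provided modality, the fraction of cells
#' with zero count exceeds `max_zero_fraction` (default 0.10, i.e. segments
#' with more than 10% zero-count cells are removed). Removal is synchronised
#' across modalities so both keep an identical segment list.
#'
#' @param ... One or more `segmented_counts` objects (e.g. RNA and ATAC).
#' @param max_zero_fraction Maximum tolerated fraction of zero-count cells.
#' @return A list of filtered `segmented_counts` (or a single object when one
#'   was given), with attribute `removed_segments` listing dropped ids.
#' @export
filter_segments <- function(..., max_zero_fraction = 0.10) {
  data <- list(...)
  if (length(data) == 1L && is.list(data[[1]]) &&
      !inherits(data[[1]], "segmented_counts")) data <- data[[1]]
  stopifnot(length(data) >= 1)
  ids <- data[[1]]$segment_ids
  for (d in data) {
    if (!inherits(d, "segmented_counts")) stop("inputs must be segmented_counts")
    if (!identical(d$segment_ids, ids))
      stop("modalities must share an identical segment list")
  }
  drop <- rep(FALSE, length(ids))
  for (d in data) {
    zf <- colMeans(d$counts == 0)
    drop <- drop | (zf > max_zero_fraction)
  }
  if (all(drop))
    stop("all segments removed at max_zero_fraction = ", max_zero_fraction,
         "; consider a looser threshold")
  out <- lapply(data, function(d) {
    res <- segmented_counts(d$counts[, !drop, drop = FALSE], d$barcodes,
                            ids[!drop], modality = d$modality,
                            library_factors = d$library_factors)
    res
  })
  removed <- ids[drop]
  if (length(data) == 1L) {
    attr(out[[1]], "removed_segments") <- removed
    return(out[[1]])
  }
  attr(out, "removed_segments") <- removed
  out
}

#' Pair RNA and ATAC counts from a multiome assay
#'
#' Restricts both modalities to the intersection of their cell barcodes and
#' orders the cells identically, as required by the multiome model where one
#' cluster-assignment variable per physical cell drives both measurements.
#'
#' @param rna,atac `segmented_counts` for the two modalities, sharing the
#'   segment list.
#' @return A list `list(rna =, atac =)` with identical barcode vectors, plus
#'   attribute `dropped` giving the number of barcodes dropped per modality.
#' @export
pair_multiome <- function(rna, atac) {
  if (!identical(rna$segment_ids, atac$segment_ids))
    stop("modalities must share an identical segment list")
  common <- intersect(rna$barcodes, atac$barcodes)
  if (length(common) == 0L)
    stop("no shared barcodes between modalities; use the flat model")
  sub <- function(d) {
    idx <- match(common, d$barcodes)
    segmented_counts(d$counts[idx, , drop = FALSE], common, d$segment_ids,
                     modality = d$modality,
                     library_factors = d$library_factors[idx])
  }
  out <- list(rna = sub(rna), atac = sub(atac))
  attr(out, "dropped") <- c(rna = length(rna$barcodes) - length(common),
                            atac = length(atac$barcodes) - length(common))
  out
}

#' Read a pre-aggregated cells-by-segments count table
#'
#' Delimited text with a header of segment ids and the cell barcode in the
#' first column — the format [write_dataset()] produces.
#'
#' @param path Path to the delimited file (plain or gzipped).
#' @param modality `"RNA"` or `"ATAC"`.
#' @param sep Field separator (default tab).
#' @return A [segmented_counts()] object.
#' @export
read_segment_table <- function(path, modality = c("RNA", "ATAC"), sep = "\t") {
  modality <- match.arg(modality)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.table(con, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  segmented_counts(as.matrix(df[, -1, drop = FALSE]), df[[1]],
                   colnames(df)[-1], modality = modality)
}
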