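#' Hi-C contact matrix container
#'
#' Bundle a symmetric matrix of Hi-C read counts with the genomic bins that
#' index its rows and columns. Bins use the BED convention: 0-based,
#' half-open, sorted, non-overlapping, all on one chromosome. Bin order
#' defines matrix index. Diagonal entries are carried through but ignored by
#' all model code, which works on off-diagonal counts only.
#'
#' @param counts square numeric matrix of non-negative integer counts;
#'   must be symmetric (small numeric asymmetries below `tol` are averaged
#'   away).
#' @param bins data frame with columns `chrom`, `start`, `end`; one row per
#'   matrix row. If missing, unit-width bins on chromosome `"chrU"` are
#'   fabricated.
#' @param tol tolerance for the symmetry check.
#' @return an object of class `contact_matrix`: a list with elements
#'   `counts` (matrix) and `bins` (data frame).
#' @examples
#' cm <- contact_matrix(matrix(c(0, 5, 5, 0), 2), data.frame(
#'   chrom = "chr1", start = c(0, 40000), end = c(40000, 80000)))
#' dim(cm$counts)
#' @export
contact_matrix <- function(counts, bins = NULL, tol = 1e-8) {
  counts <- as.matrix(counts)
  dimnames(counts) <- NULL
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts must be square")
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (max(abs(counts - t(counts))) > tol)
    stop("counts matrix is not symmetric within tolerance ", tol)
  counts <- (counts + t(counts)) / 2
  if (max(abs(counts - round(counts))) > tol)
    stop("counts must be integers (within tolerance)")
  counts <- round(counts)
  storage.mode(counts) <- "double"
  if (is.null(bins)) {
    bins <- data.frame(chrom = "chrU", start = seq_len(n) - 1, end = seq_len(n))
  }
  bins <- validate_bins(bins, n)
  structure(list(counts = counts, bins = bins), class = "contact_matrix")
}

validate_bins <- function(bins, n = NULL) {
  bins <- as.data.frame(bins)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bins)))
    stop("bins must have columns chrom, start, end")
  bins <- bins[, need]
  bins$chrom <- as.character(bins$chrom)
  if (!is.null(n) && nrow(bins) != n)
    stop("bins (", nrow(bins), " rows) do not match matrix dimension ", n)
  if (any(bins$end <= bins$start)) stop("bins must satisfy end > start")
  if (length(unique(bins$chrom)) != 1)
    stop("all bins of a contact matrix must be on one chromosome")
  if (nrow(bins) > 1) {
    if (is.unsorted(bins$start, strictly = TRUE)) stop("bins must be sorted")
    if (any(bins$start[-1] < bins$end[-nrow(bins)]))
      stop("bins must be non-overlapping")
  }
  rownames(bins) <- NULL
  bins
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  cat("Hi-C contact matrix: ", n, " bins on ", x$bins$chrom[1],
      " [", x$bins$start[1], "-", x$bins$end[n], "), ",
      "total off-diagonal count ", sum(x$counts[upper.tri(x$counts)]),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Per-locus bias covariates
#'
#' Validate a table of the three systematic Hi-C bias covariates per bin:
#' restriction fragment-end count, mean GC content and mean mappability of
#' fragment ends. All three multiply the expected contact count on the log
#' scale, so they must be strictly positive.
#'
#' @param frag_ends positive counts of restriction fragment ends per bin, or
#'   a data frame holding all three columns.
#' @param gc GC content fraction in (0, 1].
#' @param mappability mappability fraction in (0, 1].
#' @return data frame of class `locus_features` with columns `frag_ends`,
#'   `gc`, `mappability`.
#' @export
locus_features <- function(frag_ends, gc = NULL, mappability = NULL) {
  if (is.data.frame(frag_ends)) {
    df <- frag_ends
    if (!all(c("frag_ends", "gc", "mappability") %in% names(df)))
      stop("feature table needs columns frag_ends, gc, mappability")
    df <- df[, c("frag_ends", "gc", "mappability")]
  } else {
    df <- data.frame(frag_ends = frag_ends, gc = gc, mappability = mappability)
  }
  if (anyNA(df)) stop("features must not contain NA")
  if (any(df$frag_ends <= 0)) stop("frag_ends must be positive")
  if (any(df$gc <= 0 | df$gc > 1)) stop("gc must lie in (0, 1]")
  if (any(df$mappability <= 0 | df$mappability > 1))
    stop("mappability must lie in (0, 1]")
  rownames(df) <- NULL
  class(df) <- c("locus_features", "data.frame")
  df
}

#' Read a Hi-C contact matrix from disk
#'
#' Two plain-text layouts are supported: a dense N x N TSV of counts, or a
#' sparse 3-column TSV of `(bin_i, bin_j, count)` triplets with 0-based bin
#' indices (not basepairs). Triplet entries are mirrored into both triangles
#' and absent pairs are zero. A companion BED3 bin table supplies the
#' genomic coordinates.
#'
#' @param path path to the matrix file.
#' @param format `"dense"` or `"triplet"`.
#' @param bins_path optional path to a BED3 file (chrom, start, end) with one
#'   row per bin; required for the triplet format unless `n_bins` is given.
#' @param n_bins number of bins, needed for triplet input without a bin
#'   table (indices alone do not determine trailing empty bins).
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "triplet"),
                                bins_path = NULL, n_bins = NULL) {
  format <- match.arg(format)
  bins <- if (!is.null(bins_path)) read_bins(bins_path) else NULL
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    return(contact_matrix(m, bins))
  }
  trip <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("i", "j", "count"))
  if (any(trip$count < 0)) stop("negative counts in triplet file ", path)
  n <- if (!is.null(bins)) nrow(bins) else n_bins
  if (is.null(n)) n <- max(trip$i, trip$j) + 1
  if (any(trip$i < 0 | trip$j < 0 | trip$i >= n | trip$j >= n))
    stop("triplet bin index out of range [0, ", n - 1, "]")
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(trip))) {
    i <- trip$i[r] + 1; j <- trip$j[r] + 1
    m[i, j] <- m[i, j] + trip$count[r]
    if (i != j) m[j, i] <- m[j, i] + trip$count[r]
  }
  contact_matrix(m, bins)
}

#' Write a contact matrix to disk
#'
#' @param cm a [contact_matrix()].
#' @param path output path for the matrix.
#' @param format `"dense"` or `"triplet"` (upper triangle incl. diagonal,
#'   zero entries omitted).
#' @param bins_path optional path for the companion BED3 bin table.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path, format = c("dense", "triplet"),
                                 bins_path = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(cm$counts, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0,
                 arr.ind = TRUE)
    trip <- data.frame(i = idx[, 1] - 1, j = idx[, 2] - 1,
                       count = cm$counts[idx])
    trip <- trip[order(trip$i, trip$j), ]
    utils::write.table(trip, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(bins_path)) write_bins(cm$bins, bins_path)
  invisible(path)
}

#' @rdname read_contact_matrix
#' @export
read_bins <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"))
  validate_bins(b)
}

write_bins <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-locus bias covariates (BED3 + 3 numeric columns)
#'
#' @param path TSV with columns chrom, start, end, frag_ends, gc,
#'   mappability and no header.
#' @return list with `features` (a [locus_features()]) and `bins`.
#' @export
read_locus_features <- function(path) {
  f <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "frag_ends", "gc", "mappability"))
  list(features = locus_features(f[, 4:6]), bins = validate_bins(f[, 1:3]))
}

#' @rdname read_locus_features
#' @param features a [locus_features()] table.
#' @param bins bin table matching `features` row for row.
#' @export
write_locus_features <- function(features, bins, path) {
  stopifnot(nrow(features) == nrow(bins))
  utils::write.table(cbind(bins, as.data.frame(features)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read topological domain intervals (BED4)
#'
#' @param path BED4 file: chrom, start, end, label.
#' @return data frame sorted by chrom and start; overlapping intervals on a
#'   chromosome are an error.
#' @export
read_domains <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "label"))
  d$chrom <- as.character(d$chrom)
  d$label <- as.character(d$label)
  if (any(d$end <= d$start)) stop("domain intervals must satisfy end > start")
  d <- d[order(d$chrom, d$start), ]
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, ]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      stop("overlapping domains on ", ch)
  }
  rownames(d) <- NULL
  d
}

#' Filter out unreliable loci
#'
#' Loci with too few restriction fragment ends, too low GC content or too
#' low mappability carry uninformative, bias-dominated counts and are
#' removed before modelling. A locus is removed when its value is less than
#' or equal to the threshold (a locus exactly at a threshold is dropped).
#' Defaults: fragment ends <= 5, GC <= 0.3, mappability <= 0.8.
#'
#' @param cm a [contact_matrix()].
#' @param lf a [locus_features()] table aligned with `cm`.
#' @param thresholds named list with elements `frag_ends`, `gc`,
#'   `mappability`.
#' @return list with elements `cm`, `lf` (filtered) and `kept`, the original
#'   (1-based) indices of the retained loci.
#' @export
filter_loci <- function(cm, lf,
                        thresholds = list(frag_ends = 5, gc = 0.3,
                                          mappability = 0.8)) {
  stopifnot(inherits(cm, "contact_matrix"), nrow(lf) == nrow(cm$counts))
  keep <- lf$frag_ends > thresholds$frag_ends &
    lf$gc > thresholds$gc &
    lf$mappability > thresholds$mappability
  kept <- which(keep)
  if (length(kept) < 3)
    stop("fewer than 3 loci remain after filtering; region unusable")
  out_cm <- contact_matrix(cm$counts[kept, kept, drop = FALSE],
                           cm$bins[kept, , drop = FALSE])
  out_lf <- locus_features(as.data.frame(lf)[kept, , drop = FALSE])
  list(cm = out_cm, lf = out_lf, kept = kept)
}

#' Extract the sub-matrix of bins inside a genomic interval
#'
#' Bins fully contained in `[start, end)` on `chrom` are retained in their
#' original order; the feature table is subset in parallel.
#'
#' @inheritParams filter_loci
#' @param chrom,start,end target interval (0-based, half-open).
#' @return list with elements `cm`, `lf` and `kept` (original indices).
#' @export
extract_submatrix <- function(cm, lf, chrom, start, end) {
  stopifnot(inherits(cm, "contact_matrix"))
  b <- cm$bins
  kept <- which(b$chrom == chrom & b$start >= start & b$end <= end)
  if (length(kept) == 0)
    stop("interval ", chrom, ":", start, "-", end,
         " overlaps no bin of the matrix")
  out_cm <- contact_matrix(cm$counts[kept, kept, drop = FALSE],
                           b[kept, , drop = FALSE])
  out_lf <- if (is.null(lf)) NULL else
    locus_features(as.data.frame(lf)[kept, , drop = FALSE])
  list(cm = out_cm, lf = out_lf, kept = kept)
}
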