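#' Interpretive thresholds for the normalized RMSD
#'
#' Empirical similarity scale: normalized RMSD below 0.1 indicates high
#' similarity, between 0.1 and 0.2 moderate similarity, above 0.2 low
#' similarity.
#' @export
RMSD_SIMILARITY_THRESHOLDS <- c(high = 0.1, moderate = 0.2)

#' Cylinder height-to-diameter (HD) ratio of a structure
#'
#' The structure is centred, rotated to its principal axes (PCA, first
#' component along x), and approximated by a cylinder: height = difference
#' between the 90% and 10% quantiles of the first-axis coordinates; radius
#' = twice the median radial distance in the plane of the second and third
#' components. The raw HD ratio is height over diameter; it is then
#' normalized by the region size relative to `n_ref` loci, so structures of
#' different genomic extent are comparable. Elongated structures have
#' larger HD ratios.
#'
#' @param s N x 3 coordinate matrix (N >= 4, not collinear).
#' @param n_ref reference locus count for the size normalization (default
#'   25, about 1 Mb at 40 KB resolution).
#' @return object of class `cylinder_fit`: `height`, `radius`, `diameter`,
#'   `hd_raw`, `hd_ratio`, and the principal axis rotation `pc_axes`.
#' @export
hd_ratio <- function(s, n_ref = 25) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n < 4) stop("need at least 4 loci for a cylinder fit")
  pc <- stats::prcomp(s, center = TRUE, scale. = FALSE)
  y <- pc$x                                  # rotated, centred coordinates
  height <- diff(stats::quantile(y[, 1], c(0.1, 0.9), names = FALSE))
  radial <- sqrt(y[, 2]^2 + y[, 3]^2)
  med_r <- stats::median(radial)
  if (med_r == 0) stop("collinear structure: cylinder radius undefined")
  radius <- 2 * med_r
  hd_raw <- height / (2 * radius)
  structure(list(height = height, radius = radius, diameter = 2 * radius,
                 hd_raw = hd_raw, hd_ratio = hd_raw / (n / n_ref),
                 n_loci = n, n_ref = n_ref, pc_axes = pc$rotation),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "cylinder fit: height %.3g, diameter %.3g, HD ratio %.3g (raw %.3g, %d loci)\n",
    x$height, x$diameter, x$hd_ratio, x$hd_raw, x$n_loci))
  invisible(x)
}

#' Scale-invariant optimal superposition of two structures
#'
#' Removes the arbitrary global scale, translation and rotation between two
#' bead structures and reports a dimensionless normalized RMSD. The scale
#' between the structures is estimated by regressing the pairwise distances
#' of `b` on those of `a` through the origin (distances are non-negative
#' and proportional under global scaling, so no intercept). Both structures
#' are then centred and brought to unit radius of gyration — a symmetric
#' normalization, so `rmsd(a, b) == rmsd(b, a)` exactly — and the optimal
#' proper rotation is obtained from the SVD of the cross-covariance matrix
#' (reflection-corrected to determinant +1; mirror images are treated by
#' the explicit mirror flag of the arrangement model, not by alignment).
#' The normalized RMSD is the root mean square residual of the superposed
#' unit-size structures; on this scale values below 0.1 indicate high
#' similarity and above 0.2 low similarity.
#'
#' @param a,b N x 3 coordinate matrices with equal N >= 3.
#' @return object of class `alignment`: `rmsd`, `scale` (fitted slope of
#'   b's distances on a's), `rotation` (3 x 3, determinant +1) mapping the
#'   normalized `b` onto the normalized `a`.
#' @export
optimal_superposition <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("structures must have equal dimensions")
  if (nrow(a) < 3) stop("need at least 3 loci")
  da <- stats::dist(a); db <- stats::dist(b)
  if (sum(da^2) == 0 || sum(db^2) == 0)
    stop("degenerate structure: all points coincide")
  slope <- sum(da * db) / sum(da * da)       # origin regression db ~ da
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  rga <- sqrt(mean(rowSums(ac^2)))
  rgb <- sqrt(mean(rowSums(bc^2)))
  an <- ac / rga
  bn <- bc / rgb
  sv <- svd(crossprod(bn, an))               # minimises ||an - bn R||
  dsign <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  resid <- an - bn %*% rot
  structure(list(rmsd = sqrt(mean(rowSums(resid^2))),
                 scale = slope, rotation = rot,
                 rg_a = rga, rg_b = rgb),
            class = "alignment")
}

#' @export
print.alignment <- function(x, digits = 4, ...) {
  cat(sprintf("superposition: normalized RMSD %.4g (scale %.4g)\n",
              x$rmsd, x$scale))
  invisible(x)
}

#' Sliding-window local structure comparison
#'
#' Scans two equally long structures with a window of `window` consecutive
#' units (default ten domains) and reports the normalized RMSD of each
#' local superposition, giving `K - window + 1` values for structures of
#' length K.
#'
#' @param a,b coordinate matrices of equal length K >= `window`.
#' @param window number of consecutive units per window.
#' @return numeric vector of length `K - window + 1`.
#' @export
sliding_window_rmsd <- function(a, b, window = 10) {
  a <- as.matrix(a); b <- as.matrix(b)
  k <- nrow(a)
  if (nrow(b) != k) stop("structures must have equal length")
  if (k < window) stop("structures shorter than the window")
  vapply(seq_len(k - window + 1), function(i) {
    idx <- i:(i + window - 1)
    optimal_superposition(a[idx, ], b[idx, ])$rmsd
  }, numeric(1))
}

#' Plane-separation Fisher test
#'
#' Tests whether two groups of points (e.g. domains with high versus low
#' values of a genomic feature, split at the 33rd and 67th percentiles)
#' segregate on opposite sides of the least-squares plane fitted through
#' the middle group. The plane is the total-least-squares fit (through the
#' mid-group centroid, normal along the smallest principal component of the
#' mid points). Low/high points are classified by the side of the plane
#' they fall on and the resulting 2 x 2 contingency table is tested with
#' Fisher's exact test (two-sided).
#'
#' @param s N x 3 matrix of (domain centroid) coordinates.
#' @param labels character/factor vector with levels `"low"`, `"mid"`,
#'   `"high"`.
#' @return list with `odds_ratio` (sample OR; Haldane-corrected — 0.5
#'   added to every cell — when the table has a zero), `p_value`, `table`
#'   (2 x 2: group x side) and the plane (`normal`, `centroid`).
#' @export
plane_separation_test <- function(s, labels) {
  s <- as.matrix(s)
  labels <- as.character(labels)
  stopifnot(nrow(s) == length(labels))
  if (!all(labels %in% c("low", "mid", "high")))
    stop("labels must be 'low', 'mid' or 'high'")
  mid <- s[labels == "mid", , drop = FALSE]
  if (nrow(mid) < 3) stop("need at least 3 mid-group points to fit a plane")
  ctr <- colMeans(mid)
  mc <- sweep(mid, 2, ctr)
  sv <- svd(mc)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("mid-group points are collinear: plane under-determined")
  normal <- sv$v[, 3]
  side <- function(x) sign(sweep(x, 2, ctr) %*% normal)
  lo <- side(s[labels == "low", , drop = FALSE])
  hi <- side(s[labels == "high", , drop = FALSE])
  if (length(lo) == 0 || length(hi) == 0)
    stop("need at least one point in each of the low and high groups")
  tab <- rbind(low = c(sum(lo > 0), sum(lo <= 0)),
               high = c(sum(hi > 0), sum(hi <= 0)))
  colnames(tab) <- c("side+", "side-")
  ft <- stats::fisher.test(tab)
  or <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value, table = tab,
       normal = normal, centroid = ctr)
}

#' Percentile grouping for the plane-separation test
#'
#' Splits a numeric feature at its 33rd and 67th percentiles into
#' low/mid/high groups.
#'
#' @param x numeric feature per point.
#' @return character vector of `"low"`, `"mid"`, `"high"`.
#' @export
feature_groups <- function(x) {
  q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
  ifelse(x <= q[1], "low", ifelse(x > q[2], "high", "mid"))
}
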