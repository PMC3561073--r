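#' Spatial arrangement of one sub-structure relative to another
#'
#' An arrangement is a proper rotation given by three Euler angles (Z-Y-Z
#' convention) optionally composed with a mirror reflection, applied to the
#' downstream sub-structure about its anchoring point. The mirror matrix is
#' `diag(1, 1, s)` with `s = -1` for a reflected arrangement, so the
#' determinant of the full transform equals the mirror flag.
#'
#' @param euler numeric length-3 vector `(alpha, beta, gamma)` in radians.
#' @param mirror `+1` or `-1`.
#' @return object of class `arrangement`: list with `euler`, `mirror` and
#'   the 3 x 3 orthogonal `transform`.
#' @export
arrangement_transform <- function(euler, mirror = 1) {
  if (length(euler) != 3 || any(!is.finite(euler)))
    stop("euler must be three finite angles")
  if (!mirror %in% c(-1, 1)) stop("mirror must be +1 or -1")
  rz <- function(t) matrix(c(cos(t), sin(t), 0,
                             -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t),
                             0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  r <- rz(euler[1]) %*% ry(euler[2]) %*% rz(euler[3])
  m <- diag(c(1, 1, mirror))
  structure(list(euler = euler, mirror = mirror, transform = m %*% r),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, digits = 3, ...) {
  cat(sprintf("arrangement: euler = (%s), mirror = %+d\n",
              paste(round(x$euler, digits), collapse = ", "), x$mirror))
  invisible(x)
}

#' Enumerate the candidate arrangement grid
#'
#' Each Euler angle range (alpha in \[0, 2pi), beta in \[0, pi\], gamma in
#' \[0, 2pi)) is discretized into `bins_per_angle` equal bins and
#' represented by the bin centers; the grid is crossed with both mirror
#' flags. Candidates whose transform matrices coincide within `dedup_tol`
#' (e.g. at the beta bin touching a gimbal-degenerate slice) are merged, so
#' at the default of 4 bins per angle at most 4 x 4 x 4 x 2 = 128 distinct
#' arrangements are returned.
#'
#' @param bins_per_angle number of bins per Euler angle (>= 1).
#' @param dedup_tol max-norm tolerance under which two transforms are
#'   considered the same arrangement.
#' @return list of [arrangement_transform()] objects.
#' @export
enumerate_arrangements <- function(bins_per_angle = 4, dedup_tol = 1e-8) {
  if (bins_per_angle < 1) stop("bins_per_angle must be >= 1")
  centers <- function(lo, hi) lo + (seq_len(bins_per_angle) - 0.5) *
    (hi - lo) / bins_per_angle
  alphas <- centers(0, 2 * pi)
  betas <- centers(0, pi)
  gammas <- centers(0, 2 * pi)
  out <- list()
  for (mir in c(1, -1)) for (a in alphas) for (b in betas) for (g in gammas)
    out[[length(out) + 1]] <- arrangement_transform(c(a, b, g), mir)
  # merge candidates whose transforms coincide within tolerance (e.g. at a
  # gimbal-degenerate slice); signature keys make this O(K log K)
  digits <- max(0, floor(-log10(dedup_tol)) - 1)
  sig <- vapply(out, function(arr)
    paste(round(arr$transform, digits), collapse = ","), character(1))
  out[!duplicated(sig)]
}

#' Place the downstream sub-structure under an arrangement
#'
#' Region B is anchored so that its first bead sits one mean bond length
#' beyond region A's last bead, along the tangent of A's final bond; the
#' arrangement transform is then applied to B about that anchor. Chain
#' adjacency across the junction is thereby preserved for every
#' arrangement, and intra-B geometry is rigid (distances preserved;
#' chirality flips when `mirror = -1`).
#'
#' @param struct_a,struct_b coordinate matrices of the upstream and
#'   downstream regions.
#' @param arr an [arrangement_transform()].
#' @return transformed coordinates of region B.
#' @export
place_region_b <- function(struct_a, struct_b, arr) {
  a <- as.matrix(struct_a); b <- as.matrix(struct_b)
  na <- nrow(a)
  if (na < 2) stop("region A needs at least 2 beads to define a tangent")
  tangent <- a[na, ] - a[na - 1, ]
  tl <- sqrt(sum(tangent^2))
  if (tl == 0) stop("degenerate region A: last two beads coincide")
  bond <- mean(c(bond_lengths(a), bond_lengths(b)))
  anchor <- a[na, ] + bond * tangent / tl
  bc <- sweep(b, 2, b[1, ])
  bt <- bc %*% t(arr$transform)
  sweep(bt, 2, anchor, "+")
}

bond_lengths <- function(s) {
  n <- nrow(s)
  if (n < 2) return(numeric(0))
  sqrt(rowSums((s[-1, , drop = FALSE] - s[-n, , drop = FALSE])^2))
}

#' Arrangement mixture container
#'
#' @param arrangements list of [arrangement_transform()] objects.
#' @param proportions non-negative weights summing to 1 (length K).
#' @return object of class `arrangement_mixture`.
#' @export
arrangement_mixture <- function(arrangements, proportions) {
  k <- length(arrangements)
  if (k < 1) stop("at least one arrangement required")
  if (length(proportions) != k) stop("proportions must match arrangements")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  structure(list(arrangements = arrangements,
                 proportions = as.numeric(proportions)),
            class = "arrangement_mixture")
}

#' @export
print.arrangement_mixture <- function(x, digits = 3, ...) {
  cat("arrangement mixture with", length(x$arrangements), "component(s)\n")
  for (k in seq_along(x$arrangements))
    cat(sprintf("  pi = %.3f  euler = (%s)  mirror = %+d\n",
                x$proportions[k],
                paste(round(x$arrangements[[k]]$euler, digits),
                      collapse = ", "),
                x$arrangements[[k]]$mirror))
  invisible(x)
}

# Cross-region log-distance matrices, one N_A x N_B matrix per arrangement.
cross_log_distances <- function(struct_a, struct_b, arrangements) {
  a <- as.matrix(struct_a)
  lapply(arrangements, function(arr) {
    bp <- place_region_b(a, struct_b, arr)
    d2 <- outer(rowSums(a^2), rowSums(bp^2), "+") - 2 * a %*% t(bp)
    d2[d2 < 0] <- 0
    if (any(d2 == 0)) stop("zero cross-region distance under an arrangement")
    0.5 * log(d2)
  })
}

# Cross-region bias term ln(x_i x_j) etc. as one N_A x N_B matrix.
cross_bias_matrix <- function(lf_a, lf_b, p) {
  p[["beta_e"]] * outer(log(lf_a$frag_ends), log(lf_b$frag_ends), "+") +
    p[["beta_g"]] * outer(log(lf_a$gc), log(lf_b$gc), "+") +
    p[["beta_m"]] * outer(log(lf_a$mappability), log(lf_b$mappability), "+")
}

#' Mixture Poisson rates for inter-region contacts
#'
#' The expected count between locus i of region A and locus j of region B
#' is the proportion-weighted sum over arrangements of the single-structure
#' log-linear rate, with the i-j distance evaluated under each arrangement:
#' \deqn{\lambda_{ij} = \sum_k \pi_k \exp(\beta_0 + \beta_d \ln d_{ijk}
#'   + \beta_e \ln(x_i x_j) + \beta_g \ln(g_i g_j) + \beta_m \ln(m_i m_j))}
#'
#' @param struct_a,struct_b sub-region coordinate matrices (BACH fits).
#' @param mixture an [arrangement_mixture()].
#' @param lf_a,lf_b [locus_features()] for the two regions (`NULL` for the
#'   no-bias variant; both must then be `NULL`).
#' @param p a [model_params()] vector.
#' @return N_A x N_B positive rate matrix.
#' @export
mixture_rates <- function(struct_a, struct_b, mixture, lf_a, lf_b, p) {
  lds <- cross_log_distances(struct_a, struct_b, mixture$arrangements)
  bias <- if (!is.null(lf_a)) cross_bias_matrix(lf_a, lf_b, p) else 0
  lam <- 0
  for (k in seq_along(lds))
    lam <- lam + mixture$proportions[k] *
      exp(p[["beta0"]] + p[["beta_d"]] * lds[[k]] + bias)
  lam
}

#' Select mutually distinguishable candidate arrangements
#'
#' Arrangements whose cross-region rate patterns are proportional (up to a
#' constant) are confounded with the model intercept: a small admixture of
#' one is statistically invisible under another, no matter the sequencing
#' depth. This helper scores each candidate pair by the expected
#' log-likelihood drop when data generated under one arrangement are
#' contaminated by a fraction `eps` of the other (with the global scale
#' profiled out), and greedily selects `k` candidates maximizing the
#' minimum pairwise penalty. Use it to build a well-separated candidate
#' set for mixture inference; proportions among near-confounded candidates
#' are not identifiable.
#'
#' @param struct_a,struct_b sub-region coordinate matrices.
#' @param k number of candidates to select.
#' @param candidates pool to select from (default the 4-bin Euler grid).
#' @param beta_d distance-decay exponent used for the patterns.
#' @param eps contamination fraction for the score.
#' @return list of arrangements (length `k`) with attribute
#'   `"min_penalty"`, the smallest pairwise penalty in the selection (per
#'   unit `exp(beta0)`; scales linearly with depth).
#' @export
select_separated_arrangements <- function(struct_a, struct_b, k,
                                          candidates =
                                            enumerate_arrangements(4),
                                          beta_d = -1, eps = 0.1) {
  K <- length(candidates)
  if (k > K) stop("k exceeds the candidate pool")
  p <- model_params(beta0 = 0, beta_d = beta_d)
  W <- vapply(candidates, function(a)
    as.numeric(mixture_rates(struct_a, struct_b,
                             arrangement_mixture(list(a), 1),
                             NULL, NULL, p)),
    numeric(nrow(as.matrix(struct_a)) * nrow(as.matrix(struct_b))))
  pen <- matrix(Inf, K, K)
  for (j in seq_len(K)) for (kk in seq_len(K)) if (j != kk) {
    lam0 <- W[, j]
    lamc <- (1 - eps) * lam0 + eps * W[, kk]
    lamc <- lamc * sum(lam0) / sum(lamc)     # profile out the intercept
    pen[j, kk] <- -sum(lam0 * log(lamc / lam0) - (lamc - lam0))
  }
  sym <- pmin(pen, t(pen))
  sel <- which.max(apply(sym, 1, function(r) stats::median(r[is.finite(r)])))
  while (length(sel) < k) {
    rest <- setdiff(seq_len(K), sel)
    scores <- vapply(rest, function(c.) min(sym[c., sel]), numeric(1))
    sel <- c(sel, rest[which.max(scores)])
  }
  out <- candidates[sel]
  m <- sym[sel, sel]; diag(m) <- Inf
  attr(out, "min_penalty") <- min(m)
  out
}

#' Count effective mixture components
#'
#' An effective structure is a mixture component whose (posterior mean)
#' proportion strictly exceeds `threshold` (default 5%).
#'
#' @param mixture an [arrangement_mixture()] or a bare proportion vector.
#' @param threshold proportion cutoff in (0, 1).
#' @return integer count.
#' @export
effective_structures <- function(mixture, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  pr <- if (inherits(mixture, "arrangement_mixture")) mixture$proportions
        else as.numeric(mixture)
  sum(pr > threshold)
}
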