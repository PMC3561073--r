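#' Poisson rate model parameters
#'
#' The log-linear Poisson rate for the off-diagonal Hi-C count between loci
#' i and j is
#' \deqn{\ln \lambda_{ij} = \beta_0 + \beta_d \ln d_{ij}
#'   + \beta_e \ln(x_i x_j) + \beta_g \ln(g_i g_j) + \beta_m \ln(m_i m_j)}
#' where \eqn{d_{ij}} is the Euclidean distance between the beads
#' representing the loci and \eqn{x, g, m} are the fragment-end count, GC
#' content and mappability covariates. \eqn{\beta_d} measures the strength
#' of the negative association between counts and spatial distance and is
#' expected to be negative.
#'
#' @param beta0 intercept (log baseline rate).
#' @param beta_d distance-decay exponent.
#' @param beta_e,beta_g,beta_m bias-covariate coefficients (enzyme, GC,
#'   mappability).
#' @return named numeric vector of class `model_params`.
#' @export
model_params <- function(beta0 = 0, beta_d = -1, beta_e = 0, beta_g = 0,
                         beta_m = 0) {
  p <- c(beta0 = beta0, beta_d = beta_d, beta_e = beta_e,
         beta_g = beta_g, beta_m = beta_m)
  if (any(!is.finite(p))) stop("model parameters must be finite")
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, digits = 4, ...) {
  cat("Poisson rate parameters:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Pairwise Euclidean distances of a bead structure
#'
#' @param s N x 3 matrix of bead coordinates (one row per locus).
#' @param check error when two distinct beads coincide (their log-distance
#'   would be -Inf in the rate model).
#' @return symmetric N x N matrix with zero diagonal.
#' @export
pairwise_distances <- function(s, check = TRUE) {
  s <- as.matrix(s)
  if (ncol(s) != 3) stop("structure must be N x 3")
  if (any(!is.finite(s))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(s))
  dimnames(d) <- NULL
  if (check && nrow(s) > 1) {
    off <- d[upper.tri(d)]
    if (any(off == 0)) stop("coincident distinct loci (zero distance)")
  }
  d
}

# Precompute the symmetric log-covariate matrices ln(x_i x_j), ln(g_i g_j),
# ln(m_i m_j). Done once per fit; every likelihood/gradient call reuses them.
bias_log_matrices <- function(lf) {
  lx <- log(lf$frag_ends); lg <- log(lf$gc); lm <- log(lf$mappability)
  list(e = outer(lx, lx, "+"), g = outer(lg, lg, "+"),
       m = outer(lm, lm, "+"))
}

# Log-rate matrix given a distance matrix and precomputed bias matrices;
# diagonal is unusable (log 0) and set to 0 — callers mask it.
log_rates_from_dist <- function(d, bl, p, bias = TRUE) {
  ld <- d
  diag(ld) <- 1                     # placeholder; diagonal never used
  ld <- log(ld)
  eta <- p[["beta0"]] + p[["beta_d"]] * ld
  if (bias)
    eta <- eta + p[["beta_e"]] * bl$e + p[["beta_g"]] * bl$g +
      p[["beta_m"]] * bl$m
  diag(eta) <- 0
  eta
}

#' Expected Hi-C rates for a structure
#'
#' Evaluates the log-linear Poisson rate \eqn{\lambda_{ij}} for every locus
#' pair of a 3D structure given bias covariates and model parameters.
#'
#' @param s N x 3 coordinate matrix.
#' @param lf a [locus_features()] table with N rows, or `NULL` to omit the
#'   bias terms (the no-bias model variant).
#' @param p a [model_params()] vector.
#' @return symmetric N x N positive rate matrix; the diagonal is set to 0
#'   and carries no meaning.
#' @export
poisson_rates <- function(s, lf, p) {
  d <- pairwise_distances(s)
  n <- nrow(d)
  if (!is.null(lf)) {
    if (nrow(lf) != n) stop("features do not match structure size")
    bl <- bias_log_matrices(lf)
  } else bl <- NULL
  lam <- exp(log_rates_from_dist(d, bl, p, bias = !is.null(lf)))
  diag(lam) <- 0
  lam
}

#' Poisson log-likelihood of a contact matrix
#'
#' Sum of Poisson log-densities over unordered off-diagonal locus pairs,
#' \eqn{\sum_{i<j} n_{ij}\ln\lambda_{ij} - \lambda_{ij} - \ln(n_{ij}!)}.
#' `lgamma` is used for the factorial term.
#'
#' @param cm a [contact_matrix()] or a plain symmetric count matrix.
#' @param rates symmetric positive rate matrix of matching dimension.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(cm, rates) {
  n <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  if (!all(dim(n) == dim(rates))) stop("dimension mismatch")
  ut <- upper.tri(n)
  nn <- n[ut]; ll <- rates[ut]
  sum(nn * log(ll) - ll - lgamma(nn + 1))
}

# Joint log-likelihood and analytic gradients in one pass.
# Returns list(loglik, grad_coords [N x 3], grad_params [5]).
# Under flat priors the posterior gradient equals the likelihood gradient.
loglik_and_grads <- function(counts, s, bl, p, bias = TRUE,
                             want_coords = TRUE, want_params = TRUE) {
  d <- as.matrix(stats::dist(s))
  dimnames(d) <- NULL
  n <- nrow(d)
  if (any(d[upper.tri(d)] == 0)) stop("coincident distinct loci (zero distance)")
  ld <- d; diag(ld) <- 1; ld <- log(ld)
  eta <- p[["beta0"]] + p[["beta_d"]] * ld
  if (bias)
    eta <- eta + p[["beta_e"]] * bl$e + p[["beta_g"]] * bl$g +
      p[["beta_m"]] * bl$m
  lam <- exp(eta)
  diag(lam) <- 0
  ut <- upper.tri(counts)
  loglik <- sum(counts[ut] * eta[ut] - lam[ut] - lgamma(counts[ut] + 1))
  out <- list(loglik = loglik)
  resid <- counts - lam                 # symmetric, diagonal = counts diag (masked below)
  diag(resid) <- 0
  if (want_coords) {
    # d ln(lambda_ij)/d p_i = beta_d (p_i - p_j)/d_ij^2
    w <- resid * p[["beta_d"]] / (d * d + diag(n))  # diag guard; resid diag 0
    g <- s * rowSums(w) - w %*% s
    out$grad_coords <- g
  }
  if (want_params) {
    gp <- c(beta0 = sum(resid[ut]),
            beta_d = sum(resid[ut] * ld[ut]),
            beta_e = if (bias) sum(resid[ut] * bl$e[ut]) else 0,
            beta_g = if (bias) sum(resid[ut] * bl$g[ut]) else 0,
            beta_m = if (bias) sum(resid[ut] * bl$m[ut]) else 0)
    out$grad_params <- gp
  }
  out
}

#' Gradient of the log-posterior
#'
#' Analytic gradient of the Poisson log-likelihood (equal to the
#' log-posterior gradient under the flat priors used throughout) with
#' respect to the bead coordinates and the five rate parameters.
#'
#' @inheritParams poisson_rates
#' @param cm a [contact_matrix()] or plain count matrix.
#' @return list with `coords` (N x 3) and `params` (length 5, named).
#' @export
grad_log_posterior <- function(cm, s, lf, p) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  s <- as.matrix(s)
  bias <- !is.null(lf)
  bl <- if (bias) bias_log_matrices(lf) else NULL
  r <- loglik_and_grads(counts, s, bl, p, bias = bias)
  list(coords = r$grad_coords, params = r$grad_params)
}

#' Akaike information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @return `2 * k - 2 * loglik`; smaller is better.
#' @export
aic <- function(loglik, k) {
  if (k < 0) stop("k must be non-negative")
  2 * k - 2 * loglik
}

#' Serialize a structure to TSV
#'
#' Columns: locus index (1-based), chrom, start, end, x, y, z.
#'
#' @param s N x 3 coordinate matrix.
#' @param bins bin table (chrom, start, end) with N rows; fabricated if
#'   `NULL`.
#' @param path output path.
#' @export
write_structure <- function(s, path, bins = NULL) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (is.null(bins))
    bins <- data.frame(chrom = "chrU", start = seq_len(n) - 1,
                       end = seq_len(n))
  df <- data.frame(locus = seq_len(n), bins[, c("chrom", "start", "end")],
                   x = s[, 1], y = s[, 2], z = s[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @return `read_structure` returns a list with `coords` (N x 3) and `bins`.
#' @export
read_structure <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("locus", "chrom", "start", "end",
                                        "x", "y", "z"))
  list(coords = as.matrix(df[, c("x", "y", "z")]),
       bins = validate_bins(df[, c("chrom", "start", "end")]))
}
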