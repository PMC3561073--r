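#' Expected Hi-C contact matrix of a fitted structure
#'
#' Convenience wrapper around [poisson_rates()] evaluating the fitted
#' model's expected counts; with a [bach()] fit this is the posterior-mode
#' expectation (same as [predict.bach_fit()]).
#'
#' @param s N x 3 structure, or a `bach_fit`.
#' @param lf covariates (ignored when `s` is a fit).
#' @param p parameters (ignored when `s` is a fit).
#' @return symmetric rate matrix.
#' @export
expected_matrix <- function(s, lf = NULL, p = NULL) {
  if (inherits(s, "bach_fit")) return(predict(s))
  poisson_rates(s, lf, p)
}

#' Residual contact matrix for the second-stage fit
#'
#' Entry-wise `round(max(0, n_ij - lambda_ij / 2))`: the observed counts
#' minus half the expected matrix of the first-stage structure, clamped at
#' zero and rounded so the result is again a valid count matrix. If a
#' dominant structure generated the data it still dominates the residual
#' matrix; if not, the residual has little in common with the original.
#'
#' @param cm a [contact_matrix()] or plain symmetric count matrix.
#' @param expected expected rate matrix of matching dimension.
#' @return residual counts, same representation as `cm`.
#' @export
residual_matrix <- function(cm, expected) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  if (!all(dim(counts) == dim(expected))) stop("dimension mismatch")
  r <- round(pmax(counts - expected / 2, 0))   # pmax keeps dim of 1st arg
  diag(r) <- 0
  r <- (r + t(r)) / 2     # expected is symmetric; guard against fp drift
  if (inherits(cm, "contact_matrix")) contact_matrix(round(r), cm$bins)
  else round(r)
}

#' Chirality-blind normalized RMSD
#'
#' The Hi-C likelihood depends on a structure only through pairwise
#' distances, so a fitted structure's handedness is arbitrary (a reflected
#' copy fits identically). Structure comparisons between independent fits
#' are therefore made on the chirality quotient: the smaller of the
#' normalized RMSD against `b` and against its mirror image.
#'
#' @param a,b coordinate matrices of equal length.
#' @return scalar RMSD.
#' @export
rmsd_up_to_mirror <- function(a, b) {
  b <- as.matrix(b)
  min(optimal_superposition(a, b)$rmsd,
      optimal_superposition(a, b %*% diag(c(1, 1, -1)))$rmsd)
}

#' Random-walk RMSD reference distribution
#'
#' Empirical distribution of the chirality-blind normalized RMSD (see
#' [rmsd_up_to_mirror()]) between two independent random-walk backbones of
#' the target length; the null against which the two-step procedure judges
#' whether its two fitted structures are closer than chance. The
#' distribution depends only weakly on the number of loci.
#'
#' @param n_loci number of beads per walk.
#' @param n_reps number of independent walk pairs (>= 100; default 1000).
#' @param seed optional seed.
#' @return object of class `rmsd_reference`: sorted `draws` and the
#'   generating settings. Use [tail_probability()] to evaluate an observed
#'   RMSD against it.
#' @export
rmsd_reference <- function(n_loci, n_reps = 1000, seed = NULL) {
  if (n_reps < 100) stop("n_reps must be >= 100")
  draws <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    rmsd_up_to_mirror(random_walk(n_loci), random_walk(n_loci))
  }, numeric(1)))
  structure(list(draws = sort(draws), n_loci = n_loci, n_reps = n_reps),
            class = "rmsd_reference")
}

#' @export
print.rmsd_reference <- function(x, ...) {
  cat(sprintf(
    "random-walk RMSD reference: %d draws at %d loci, median %.3f [5%% %.3f]\n",
    x$n_reps, x$n_loci, stats::median(x$draws),
    stats::quantile(x$draws, 0.05, names = FALSE)))
  invisible(x)
}

#' Tail probability of an observed RMSD under the reference
#'
#' Fraction of reference draws less than or equal to the observed value;
#' observed values below every draw score at most `1/n_reps`.
#'
#' @param ref an [rmsd_reference()].
#' @param observed observed normalized RMSD (vectorized).
#' @return tail probabilities in \[0, 1\].
#' @export
tail_probability <- function(ref, observed) {
  vapply(observed, function(o) mean(ref$draws <= o), numeric(1))
}

#' Two-step dominant-structure procedure
#'
#' Tests whether a cell population has one dominant 3D structure. Step one
#' fits the consensus model to the contact matrix and takes the posterior
#' mode structure s1. Step two subtracts half of s1's expected matrix from
#' the counts (clamped, rounded) and refits, giving s2. If a dominant
#' structure exists, the residual matrix is still dominated by it, so s1
#' and s2 are similar; otherwise they are not. Similarity is judged by the
#' normalized RMSD against the random-walk reference distribution: the
#' population is called dominant when the observed RMSD falls in the lower
#' 5% tail.
#'
#' The procedure's discrimination relies on mode diversity: if the
#' population is a mixture, subtracting half of s1's expectation weakens
#' precisely the basin s1 occupies, and a refit exploring several basins
#' lands elsewhere. The default configuration therefore runs ten parallel
#' chains with diversified initial structures (`init = "diverse"`) and
#' keeps the highest-posterior mode of each fit.
#'
#' @param cm a [contact_matrix()] (or plain symmetric count matrix).
#' @param lf a [locus_features()] or `NULL`.
#' @param config a [bach_config()] used for both BACH runs.
#' @param n_reps reference-distribution draws.
#' @param alpha dominance tail level (default 0.05).
#' @param ref optional precomputed [rmsd_reference()] for the right
#'   `n_loci` (recomputed otherwise).
#' @return object of class `two_step_result`: `s1`, `s2`, `rmsd`,
#'   `tail_probability`, `dominant`, `converged` and the two fits.
#' @export
two_step_procedure <- function(cm, lf = NULL,
                               config = bach_config(n_chains = 10,
                                                    init = "diverse"),
                               n_reps = 1000, alpha = 0.05, ref = NULL) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  with_seed(config$seed, {
    cfg <- config; cfg$seed <- NULL
    fit1 <- bach(cm, lf, cfg)
    resid <- residual_matrix(counts, predict(fit1))
    fit2 <- bach(resid, lf, cfg)
    s1 <- fit1$mode_structure
    s2 <- fit2$mode_structure
    rmsd <- rmsd_up_to_mirror(s1, s2)
    if (is.null(ref) || ref$n_loci != nrow(counts))
      ref <- rmsd_reference(nrow(counts), n_reps)
    tp <- tail_probability(ref, rmsd)
    structure(list(s1 = s1, s2 = s2, rmsd = rmsd, tail_probability = tp,
                   dominant = tp < alpha, alpha = alpha,
                   converged = fit1$converged && fit2$converged,
                   fit1 = fit1, fit2 = fit2, reference = ref),
              class = "two_step_result")
  })
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf(
    "two-step dominance test: RMSD(s1, s2) = %.3f, tail probability %.3f\n",
    x$rmsd, x$tail_probability))
  cat("  dominant structure: ", if (x$dominant) "YES" else "no",
      sprintf(" (lower %g%% rule)", 100 * x$alpha),
      if (!x$converged) "  [warning: a BACH run did not converge]", "\n",
      sep = "")
  invisible(x)
}
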