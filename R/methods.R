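#' @export
print.bach_fit <- function(x, ...) {
  cat("BACH fit: ", x$n_loci, " loci, ",
      length(x$samples), " posterior samples from ",
      x$config$n_chains, " chain(s)\n", sep = "")
  cat(sprintf("  log-likelihood at mode: %.2f   AIC: %.2f (k = %d)\n",
              x$loglik, x$aic, x$n_params))
  if (!is.na(x$gelman_rubin))
    cat(sprintf("  Gelman-Rubin (loglik): %.3f  [%s]\n", x$gelman_rubin,
                if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  HMC acceptance rate: %.2f\n", x$accept_rate))
  invisible(x)
}

#' @export
summary.bach_fit <- function(object, ...) {
  pm <- do.call(rbind, lapply(object$samples, function(s) unclass(s$params)))
  out <- list(
    n_loci = object$n_loci,
    n_samples = length(object$samples),
    params = rbind(mean = colMeans(pm),
                   `2.5%` = apply(pm, 2, stats::quantile, 0.025),
                   `97.5%` = apply(pm, 2, stats::quantile, 0.975),
                   mode = unclass(object$mode_params)),
    loglik = object$loglik, aic = object$aic,
    gelman_rubin = object$gelman_rubin, converged = object$converged,
    accept_rate = object$accept_rate)
  class(out) <- "summary.bach_fit"
  out
}

#' @export
print.summary.bach_fit <- function(x, digits = 3, ...) {
  cat("BACH posterior summary (", x$n_loci, " loci, ", x$n_samples,
      " samples)\n\n", sep = "")
  print(round(x$params, digits))
  cat(sprintf("\nlog-likelihood at mode: %.2f   AIC: %.2f\n",
              x$loglik, x$aic))
  if (!is.na(x$gelman_rubin))
    cat(sprintf("Gelman-Rubin (loglik): %.3f  [%s]\n", x$gelman_rubin,
                if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.bach_fit <- function(object, type = c("mean", "mode"), ...) {
  type <- match.arg(type)
  if (type == "mode") return(unclass(object$mode_params))
  pm <- do.call(rbind, lapply(object$samples, function(s) unclass(s$params)))
  colMeans(pm)
}

#' Expected contact matrix of a fitted model
#'
#' Evaluates the fitted Poisson rates at the posterior mode (structure and
#' parameters together), i.e. the expected Hi-C contact matrix under the
#' fitted consensus structure.
#'
#' @param object a [bach()] fit.
#' @param ... unused.
#' @return symmetric rate matrix (diagonal zero).
#' @export
predict.bach_fit <- function(object, ...) {
  poisson_rates(object$mode_structure, object$lf, object$mode_params)
}

#' @export
fitted.bach_fit <- function(object, ...) predict(object)

#' @export
residuals.bach_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  lam <- predict(object)
  r <- object$cm$counts - lam
  diag(r) <- 0
  if (type == "pearson") {
    r <- r / sqrt(pmax(lam, .Machine$double.eps))
    diag(r) <- 0
  }
  r
}

#' Simulate contact matrices from a fitted model
#'
#' Parametric-bootstrap draws: independent Poisson counts per unordered
#' locus pair at the fitted (posterior mode) rates.
#'
#' @param object a [bach()] fit.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` symmetric count matrices.
#' @export
simulate.bach_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lam <- predict(object)
  with_seed(seed, replicate(nsim, draw_counts(lam), simplify = FALSE))
}

#' Plot a fitted structure
#'
#' Draws the posterior-mode bead chain projected on the first two principal
#' components, with bead index labels, plus the posterior-mean distance
#' matrix as an image.
#'
#' @param x a [bach()] fit.
#' @param which `1` structure projection, `2` posterior mean distance
#'   matrix, or both.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bach_fit <- function(x, which = 1, ...) {
  if (1 %in% which) {
    s <- scale(x$mode_structure, scale = FALSE)
    pc <- stats::prcomp(s)$x
    graphics::plot(pc[, 1], pc[, 2], type = "o", pch = 16,
                   xlab = "PC1", ylab = "PC2",
                   main = "Posterior mode structure", ...)
    graphics::text(pc[, 1], pc[, 2], labels = seq_len(nrow(pc)), pos = 3,
                   cex = 0.6)
  }
  if (2 %in% which) {
    graphics::image(x$distance_posterior$mean,
                    main = "Posterior mean pairwise distance")
  }
  invisible(x)
}
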