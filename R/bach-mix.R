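# Mixture model internals. The cross-block rate is
#   lambda_m = sum_k pi_k * exp(beta0 + beta_d * LD[k, m] + B_m)
# over flattened cross pairs m, with B_m the bias term and LD the fixed
# per-arrangement log cross-distances (sub-structures are held at their
# BACH estimates). Proportions are parameterized on the softmax scale
# (a_K pinned at 0) so HMC runs unconstrained; gradients are analytic.

# theta = (a_1..a_K, beta0, beta_d[, beta_e, beta_g, beta_m]). The logits
# are unpinned: a common shift is an exact gauge (softmax normalizes it
# away), so every component's proportion is driven by its own logit and
# unsupported components stay in the corner where the EM initializer put
# them. The model has K - 1 proportion degrees of freedom regardless.
mix_unpack <- function(theta, K, bias) {
  a <- theta[seq_len(K)]
  p <- model_params(beta0 = theta[K + 1], beta_d = theta[K + 2],
                    beta_e = if (bias) theta[K + 3] else 0,
                    beta_g = if (bias) theta[K + 4] else 0,
                    beta_m = if (bias) theta[K + 5] else 0)
  list(a = a, p = p, pi = softmax(a))
}

softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

# log-likelihood and gradient in the packed parameterization.
# LD: K x M matrix of log cross-distances; bvec: list of M-vectors (bias
# components) or NULL; nn: M-vector of counts.
mix_loglik_grad <- function(theta, LD, bvec, nn, K, bias,
                            enforce_negative_decay, want_grad = TRUE) {
  if (any(!is.finite(theta))) return(list(loglik = -Inf))
  up <- mix_unpack(theta, K, bias)
  p <- up$p; pi_k <- up$pi
  if (enforce_negative_decay && p[["beta_d"]] >= 0)
    return(list(loglik = -Inf))
  B <- if (bias)
    p[["beta_e"]] * bvec$e + p[["beta_g"]] * bvec$g +
      p[["beta_m"]] * bvec$m else 0
  W <- exp(sweep(p[["beta_d"]] * LD, 2, p[["beta0"]] + B, "+"))
  lam <- as.numeric(crossprod(W, pi_k))
  if (any(!is.finite(lam)) || any(lam <= 0)) return(list(loglik = -Inf))
  # flat (non-informative) prior on the unconstrained logits, as for the
  # other parameters; posterior gradient = likelihood gradient
  ll <- sum(nn * log(lam) - lam - lgamma(nn + 1))
  out <- list(loglik = ll, pi = pi_k)
  if (!want_grad) return(out)
  r <- nn / lam - 1
  # d lambda_m / d a_k = pi_k (W[k,m] - lambda_m)
  ga <- vapply(seq_len(K), function(k)
    sum(r * pi_k[k] * (W[k, ] - lam)), numeric(1))
  piW <- pi_k * W
  g0 <- sum(r * lam)
  gd <- sum(r * colSums(piW * LD))
  gr <- c(ga, g0, gd)
  if (bias)
    gr <- c(gr, sum(r * lam * bvec$e), sum(r * lam * bvec$g),
            sum(r * lam * bvec$m))
  out$grad <- gr
  out
}

mix_hmc_chain <- function(LD, bvec, nn, K, bias, theta0, cfg,
                          chain_id) {
  eps <- if (is.null(cfg$hmc_step_size)) 0.005 else cfg$hmc_step_size
  L <- cfg$hmc_leapfrog
  theta <- theta0
  cur <- mix_loglik_grad(theta, LD, bvec, nn, K, bias,
                         cfg$enforce_negative_decay)
  keep_at <- seq(cfg$burn_in + cfg$thin, cfg$n_iter, by = cfg$thin)
  samples <- vector("list", length(keep_at)); ks <- 0L
  acc_win <- 0; win_n <- 0; acc_total <- 0
  loglik_trace <- numeric(cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    mom <- stats::rnorm(length(theta))
    h0 <- -cur$loglik + 0.5 * sum(mom^2)
    q <- theta; g <- cur$grad
    mom2 <- mom + 0.5 * eps * g
    st <- NULL; bad <- FALSE
    for (l in seq_len(L)) {
      q <- q + eps * mom2
      st <- mix_loglik_grad(q, LD, bvec, nn, K, bias,
                            cfg$enforce_negative_decay)
      if (!is.finite(st$loglik)) { bad <- TRUE; break }
      if (l < L) mom2 <- mom2 + eps * st$grad
    }
    accepted <- FALSE
    if (!bad) {
      mom2 <- mom2 + 0.5 * eps * st$grad
      h1 <- -st$loglik + 0.5 * sum(mom2^2)
      if (is.finite(h1) && log(stats::runif(1)) < h0 - h1) {
        theta <- q; cur <- st; accepted <- TRUE
      }
    }
    acc_win <- acc_win + accepted; win_n <- win_n + 1
    acc_total <- acc_total + accepted
    if (it <= cfg$burn_in && win_n >= 25) {
      rate <- acc_win / win_n
      if (rate < 0.6) eps <- eps * 0.8 else if (rate > 0.9) eps <- eps * 1.25
      acc_win <- 0; win_n <- 0
    }
    loglik_trace[it] <- cur$loglik
    if (ks < length(keep_at) && it == keep_at[ks + 1L]) {
      ks <- ks + 1L
      up <- mix_unpack(theta, K, bias)
      samples[[ks]] <- list(theta = theta, pi = up$pi, params = up$p,
                            loglik = cur$loglik, chain = chain_id,
                            iteration = it)
    }
  }
  list(samples = samples, loglik_trace = loglik_trace,
       accept_rate = acc_total / cfg$n_iter)
}

# ECM initialization: with the decay exponent held at -1, alternate an EM
# pass for the component intensities u_k (their scale absorbs the
# intercept) with a Poisson GLM for the bias coefficients given the
# mixture offset. Lands at the high-likelihood corner of the simplex so
# that unsupported arrangement logits start (and stay) deeply negative.
mix_ecm_init <- function(LD, bvec, nn, bias) {
  K <- nrow(LD)
  W0 <- exp(-LD)                              # K x M, beta_d = -1
  b0 <- log(mean(nn) + 1e-8) - log(mean(colMeans(W0)))
  u <- rep(exp(b0) / K, K)
  bcoef <- c(0, 0, 0)
  Bm <- 0
  em_iters <- if (K > 200) 150 else 300   # large grids: EM cost dominates
  for (round in seq_len(if (bias) 4 else 1)) {
    Em <- exp(Bm)
    WE <- sweep(W0, 2, Em, "*")
    for (it in seq_len(em_iters)) {
      lam0 <- as.numeric(crossprod(WE, u))
      u <- u * as.numeric(WE %*% (nn / lam0)) / rowSums(WE)
      u <- pmax(u, 1e-10)
    }
    if (bias) {
      off <- log(as.numeric(crossprod(W0, u)))
      df <- data.frame(y = nn, e = bvec$e, g = bvec$g, m = bvec$m)
      gfit <- tryCatch(
        stats::glm(y ~ e + g + m, family = stats::poisson(), data = df,
                   offset = off),
        error = function(e) NULL)
      if (is.null(gfit) || anyNA(stats::coef(gfit))) break
      cf <- stats::coef(gfit)
      u <- u * exp(cf[["(Intercept)"]])
      bcoef <- cf[c("e", "g", "m")]          # total bias given the offset
      Bm <- bcoef[1] * bvec$e + bcoef[2] * bvec$g + bcoef[3] * bvec$m
    }
  }
  list(pi0 = u / sum(u), b0 = log(sum(u)), bcoef = unname(bcoef))
}

run_mix_mcmc <- function(LD, bvec, nn, arrangements, bias, cfg,
                         init = NULL) {
  K <- length(arrangements)
  if (is.null(init)) init <- mix_ecm_init(LD, bvec, nn, bias)
  theta0 <- unname(c(log(pmax(init$pi0, 1e-10)), init$b0, -1,
                     if (bias) init$bcoef))
  chains <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    jitter <- stats::rnorm(length(theta0), sd = 0.05)
    chains[[ch]] <- mix_hmc_chain(LD, bvec, nn, K, bias,
                                  theta0 + jitter, cfg, ch)
  }
  samples <- do.call(c, lapply(chains, `[[`, "samples"))
  pi_mat <- do.call(rbind, lapply(samples, `[[`, "pi"))
  lls <- vapply(samples, `[[`, numeric(1), "loglik")
  gr <- if (cfg$n_chains >= 2)
    gelman_rubin(lapply(chains, function(c.)
      c.$loglik_trace[(cfg$burn_in + 1):cfg$n_iter])) else NA_real_
  list(samples = samples, pi_mean = colMeans(pi_mat),
       mode_i = which.max(lls), loglik = max(lls), gelman_rubin = gr,
       accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept_rate")))
}

# Maximize the mixture model's total log-likelihood (both intra blocks and
# the cross-block mixture at fixed proportions) over the shared rate
# parameters. Structures and proportions are held fixed; BFGS on the 2 (no
# bias) or 5 (bias) coefficients.
optimize_mix_betas <- function(counts, ia, ib, sa, sb, lf_a, lf_b, LD,
                               bvec, pi_mean, p_init, bias) {
  na <- length(ia); nb <- length(ib)
  ut_a <- upper.tri(matrix(0, na, na)); ut_b <- upper.tri(matrix(0, nb, nb))
  ld_a <- log(as.matrix(stats::dist(sa))[ut_a])
  ld_b <- log(as.matrix(stats::dist(sb))[ut_b])
  nn_a <- counts[ia, ia][ut_a]; nn_b <- counts[ib, ib][ut_b]
  nn_x <- as.numeric(counts[ia, ib])
  bl_a <- if (bias) bias_log_matrices(lf_a) else NULL
  bl_b <- if (bias) bias_log_matrices(lf_b) else NULL
  bv_a <- if (bias) list(e = bl_a$e[ut_a], g = bl_a$g[ut_a],
                         m = bl_a$m[ut_a]) else NULL
  bv_b <- if (bias) list(e = bl_b$e[ut_b], g = bl_b$g[ut_b],
                         m = bl_b$m[ut_b]) else NULL
  part_ll <- function(b, ld, bv, nn, mix_LD = NULL) {
    eta_bias <- if (bias) b[3] * bv$e + b[4] * bv$g + b[5] * bv$m else 0
    if (is.null(mix_LD)) {
      eta <- b[1] + b[2] * as.numeric(ld) + eta_bias
      lam <- exp(eta)
      list(ll = sum(nn * eta - lam),
           resid = nn - lam, eta_ld = as.numeric(ld),
           bias_terms = if (bias) bv else NULL, lam = lam)
    } else {
      W <- exp(sweep(b[2] * mix_LD, 2, b[1] + eta_bias, "+"))
      lam <- as.numeric(crossprod(W, pi_mean))
      r <- nn / lam - 1
      list(ll = sum(nn * log(lam) - lam),
           g0 = sum(r * lam),
           gd = sum(r * colSums(pi_mean * W * mix_LD)),
           ge = if (bias) sum(r * lam * bv$e) else 0,
           gg = if (bias) sum(r * lam * bv$g) else 0,
           gm = if (bias) sum(r * lam * bv$m) else 0)
    }
  }
  pvec <- function(p) unname(unclass(p))[if (bias) 1:5 else 1:2]
  fn <- function(b) {
    la <- part_ll(b, ld_a, bv_a, nn_a)
    lb <- part_ll(b, ld_b, bv_b, nn_b)
    lx <- part_ll(b, NULL, bvec, nn_x, mix_LD = LD)
    -(la$ll + lb$ll + lx$ll)
  }
  gr <- function(b) {
    g <- numeric(length(b))
    for (part in list(part_ll(b, ld_a, bv_a, nn_a),
                      part_ll(b, ld_b, bv_b, nn_b))) {
      g[1] <- g[1] + sum(part$resid)
      g[2] <- g[2] + sum(part$resid * part$eta_ld)
      if (bias) {
        g[3] <- g[3] + sum(part$resid * part$bias_terms$e)
        g[4] <- g[4] + sum(part$resid * part$bias_terms$g)
        g[5] <- g[5] + sum(part$resid * part$bias_terms$m)
      }
    }
    lx <- part_ll(b, NULL, bvec, nn_x, mix_LD = LD)
    g[1] <- g[1] + lx$g0; g[2] <- g[2] + lx$gd
    if (bias) { g[3] <- g[3] + lx$ge; g[4] <- g[4] + lx$gg
                g[5] <- g[5] + lx$gm }
    -g
  }
  b0 <- pvec(p_init)
  opt <- tryCatch(stats::optim(b0, fn, gr, method = "BFGS",
                               control = list(maxit = 200)),
                  error = function(e) list(par = b0, value = fn(b0)))
  lg_const <- sum(lgamma(c(nn_a, nn_b, nn_x) + 1))
  b <- opt$par
  p <- model_params(beta0 = b[1], beta_d = b[2],
                    beta_e = if (bias) b[3] else 0,
                    beta_g = if (bias) b[4] else 0,
                    beta_m = if (bias) b[5] else 0)
  list(params = p, loglik = -opt$value - lg_const)
}

#' Fit the arrangement-mixture model (BACH-MIX)
#'
#' Models the cross-block Hi-C counts between two adjacent sub-regions as a
#' Poisson mixture over a discrete set of candidate spatial arrangements
#' (Euler-angle rotations crossed with a mirror flag) of region B relative
#' to region A. The consensus sub-structures are first estimated by
#' applying [bach()] to each intra-region block separately (or supplied via
#' `fit_a` / `fit_b`); the mixture proportions (softmax scale) and the rate
#' parameters are then updated jointly by Hamiltonian Monte Carlo. After
#' the run, arrangements with posterior mean proportion below `prune`
#' (default 1%) are removed and the reduced model is refit.
#'
#' @param cm full-region [contact_matrix()] (or plain symmetric matrix)
#'   covering both sub-regions.
#' @param lf a [locus_features()] for the full region, or `NULL`.
#' @param split_at index of the last locus of sub-region A; defaults to
#'   half the region.
#' @param config a [bach_config()] used for both the sub-region BACH runs
#'   and the mixture sampler.
#' @param bins_per_angle Euler-angle discretization for
#'   [enumerate_arrangements()] (ignored when `arrangements` is given).
#' @param arrangements optional explicit list of candidate
#'   [arrangement_transform()]s.
#' @param prune posterior-mean proportion below which a component is
#'   removed before the refit.
#' @param fit_a,fit_b optional precomputed [bach()] fits of the two
#'   sub-regions.
#' @param struct_a,struct_b optional sub-structures given directly as N x 3
#'   matrices (bypasses the sub-region BACH runs entirely).
#' @param prescreen_max when the candidate set is larger than this, an EM
#'   pass pre-screens it and posterior sampling runs on the components the
#'   likelihood supports (the same sparsification principle as the 1%
#'   prune-and-refit, applied at initialization). Large fine grids are
#'   needed when sub-structures come from separate fits, whose orientation
#'   relative to each other is arbitrary.
#' @return object of class `bach_mix_fit`: the final `mixture` (an
#'   [arrangement_mixture()] with posterior mean proportions), `pi_mean`,
#'   `samples`, cross-block and total log-likelihoods, `aic`
#'   (k = 3 N_A + 3 N_B + 5 + (K - 1)), `effective` counts at the 1%, 5%
#'   and 10% thresholds, convergence diagnostics and the sub-region fits.
#' @export
bach_mix <- function(cm, lf = NULL, split_at = NULL,
                     config = bach_config(), bins_per_angle = 4,
                     arrangements = NULL, prune = 0.01,
                     fit_a = NULL, fit_b = NULL,
                     struct_a = NULL, struct_b = NULL,
                     prescreen_max = 24) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  n <- nrow(counts)
  if (is.null(split_at)) split_at <- floor(n / 2)
  stopifnot(split_at >= 3, n - split_at >= 3)
  ia <- seq_len(split_at); ib <- (split_at + 1):n
  bias <- config$bias && !is.null(lf)
  lf_a <- if (bias) locus_features(as.data.frame(lf)[ia, ]) else NULL
  lf_b <- if (bias) locus_features(as.data.frame(lf)[ib, ]) else NULL
  with_seed(config$seed, {
    sub_cfg <- config
    sub_cfg$seed <- NULL                  # runs under the governing stream
    if (is.null(struct_a)) {
      if (is.null(fit_a))
        fit_a <- bach(counts[ia, ia], lf_a, sub_cfg)
      struct_a <- fit_a$mode_structure
    }
    if (is.null(struct_b)) {
      if (is.null(fit_b))
        fit_b <- bach(counts[ib, ib], lf_b, sub_cfg)
      struct_b <- fit_b$mode_structure
    }
    # common gauge: each sub-structure is only defined up to scale (it
    # trades off with its fit's intercept), so both are brought to unit
    # mean bond length; the mixture's shared rate parameters live in that
    # gauge across the intra- and cross-blocks
    sa <- as.matrix(struct_a); sa <- sa / mean(bond_lengths(sa))
    sb <- as.matrix(struct_b); sb <- sb / mean(bond_lengths(sb))
    stopifnot(nrow(sa) == length(ia), nrow(sb) == length(ib))
    if (is.null(arrangements))
      arrangements <- enumerate_arrangements(bins_per_angle)
    cross <- counts[ia, ib, drop = FALSE]
    nn <- as.numeric(cross)
    bvec <- if (bias) {
      cb <- function(x_a, x_b) as.numeric(outer(log(x_a), log(x_b), "+"))
      list(e = cb(lf_a$frag_ends, lf_b$frag_ends),
           g = cb(lf_a$gc, lf_b$gc),
           m = cb(lf_a$mappability, lf_b$mappability))
    } else NULL
    make_LD <- function(arrs) {
      lds <- cross_log_distances(sa, sb, arrs)
      do.call(rbind, lapply(lds, as.numeric))
    }
    LD <- make_LD(arrangements)
    init <- mix_ecm_init(LD, bvec, nn, bias)
    if (length(arrangements) > prescreen_max) {
      # EM pre-screen of a large candidate grid: posterior sampling runs
      # on the components the likelihood supports (same sparsification
      # principle as the 1% prune-and-refit, applied at initialization)
      keep0 <- which(init$pi0 >= prune / 10)
      if (length(keep0) < 2)
        keep0 <- order(init$pi0, decreasing = TRUE)[1:2]
      arrangements <- arrangements[keep0]
      LD <- LD[keep0, , drop = FALSE]
      init$pi0 <- init$pi0[keep0] / sum(init$pi0[keep0])
    }
    res <- run_mix_mcmc(LD, bvec, nn, arrangements, bias, config, init)
    kept <- which(res$pi_mean >= prune)
    pruned <- length(kept) < length(arrangements)
    if (pruned && length(kept) >= 1) {
      arrangements <- arrangements[kept]
      res <- run_mix_mcmc(make_LD(arrangements), bvec, nn, arrangements,
                          bias, config)
    }
    pi_mean <- res$pi_mean / sum(res$pi_mean)
    K <- length(arrangements)
    mode <- res$samples[[res$mode_i]]
    # Total model likelihood: one shared set of rate parameters over the
    # two intra-region blocks (at the fixed sub-structures) and the
    # cross-block mixture (at the posterior mean proportions), maximized
    # over those parameters — this is the likelihood the AIC parameter
    # count k = 3 N_A + 3 N_B + 5 + (K - 1) refers to.
    opt <- optimize_mix_betas(counts, ia, ib, sa, sb, lf_a, lf_b,
                              make_LD(arrangements), bvec, pi_mean,
                              mode$params, bias)
    p_mode <- opt$params
    loglik_total <- opt$loglik
    k <- 3 * length(ia) + 3 * length(ib) + (if (bias) 5 else 2) + (K - 1)
    structure(list(
      mixture = arrangement_mixture(arrangements, pi_mean),
      pi_mean = pi_mean,
      samples = res$samples,
      mode_params = p_mode,
      loglik_cross = res$loglik,
      loglik = loglik_total,
      aic = aic(loglik_total, k),
      n_params = k,
      effective = vapply(c(0.01, 0.05, 0.10), function(t)
        effective_structures(pi_mean, t), numeric(1)),
      gelman_rubin = res$gelman_rubin,
      converged = is.na(res$gelman_rubin) || res$gelman_rubin <= 1.1,
      accept_rate = res$accept_rate,
      pruned = pruned,
      fit_a = fit_a, fit_b = fit_b,
      struct_a = sa, struct_b = sb,
      n_a = length(ia), n_b = length(ib),
      split_at = split_at, bias = bias,
      config = config), class = "bach_mix_fit")
  })
}

#' @export
print.bach_mix_fit <- function(x, ...) {
  cat("BACH-MIX fit: ", x$n_a, " + ", x$n_b, " loci, K = ",
      length(x$mixture$arrangements), " arrangement(s)",
      if (x$pruned) " (after pruning)", "\n", sep = "")
  print(x$mixture)
  cat(sprintf("  total log-likelihood: %.2f   AIC: %.2f (k = %d)\n",
              x$loglik, x$aic, x$n_params))
  cat("  effective structures at 1%/5%/10%: ",
      paste(x$effective, collapse = "/"), "\n", sep = "")
  if (!is.na(x$gelman_rubin))
    cat(sprintf("  Gelman-Rubin (loglik): %.3f  [%s]\n", x$gelman_rubin,
                if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.bach_mix_fit <- function(object, ...) {
  list(proportions = object$pi_mean, params = unclass(object$mode_params))
}

#' Model selection between the consensus and mixture models
#'
#' Compares a single-structure [bach()] fit of a region with a
#' [bach_mix()] fit of the same region by AIC (both likelihoods cover all
#' locus pairs of the region; gauge degrees of freedom are included in both
#' parameter counts and cancel in the comparison).
#'
#' @param bach_fit a [bach()] fit of the full region.
#' @param mix_fit a [bach_mix()] fit of the same region.
#' @return list with `selected` (`"BACH"` or `"BACH-MIX"`), `aic_bach`,
#'   `aic_mix` and `delta` (`aic_mix - aic_bach`).
#' @export
compare_models_aic <- function(bach_fit, mix_fit) {
  stopifnot(inherits(bach_fit, "bach_fit"), inherits(mix_fit, "bach_mix_fit"))
  list(selected = if (bach_fit$aic <= mix_fit$aic) "BACH" else "BACH-MIX",
       aic_bach = bach_fit$aic, aic_mix = mix_fit$aic,
       delta = mix_fit$aic - bach_fit$aic)
}
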