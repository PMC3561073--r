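test_that("pairwise distances: closed form, symmetry, rigid invariance", {
  s <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(pairwise_distances(s)[1, 2], 5)
  set.seed(1)
  s <- matrix(rnorm(18), 6, 3)
  d <- pairwise_distances(s)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 6))
  r <- random_rotation()
  expect_equal(pairwise_distances(sweep(s %*% t(r), 2, c(1, -2, 3), "+")), d,
               tolerance = 1e-12)
  expect_error(pairwise_distances(rbind(c(0, 0, 0), c(0, 0, 0))),
               "coincident")
})

test_that("poisson_rates matches the log-linear closed form", {
  s <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 5, 0))
  lam <- poisson_rates(s, NULL, model_params(beta0 = log(10), beta_d = -1))
  expect_equal(lam[1, 2], 5)                        # 10 / 2
  expect_equal(lam[1, 3], 2)                        # 10 / 5
  # beta_d = 0: constant rates
  lam0 <- poisson_rates(s, NULL, model_params(beta0 = 1.3, beta_d = 0))
  expect_true(all(abs(lam0[upper.tri(lam0)] - exp(1.3)) < 1e-12))
  # log-linearity in a covariate: doubling x_i scales row i by 2^beta_e
  lf <- locus_features(c(10, 10, 10), c(0.5, 0.5, 0.5), c(0.9, 0.9, 0.9))
  p <- model_params(0, -1, beta_e = 1)
  lam1 <- poisson_rates(s, lf, p)
  lf2 <- lf; lf2$frag_ends[1] <- 20
  lam2 <- poisson_rates(s, lf2, p)
  expect_equal(lam2[1, 2] / lam1[1, 2], 2)
  expect_equal(lam2[2, 3], lam1[2, 3])
})

test_that("log-likelihood is the off-diagonal Poisson sum", {
  cm <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(log_likelihood(cm, matrix(c(0, 2, 2, 0), 2)),
               3 * log(2) - 2 - log(6))
  n <- 5
  zero <- matrix(0, n, n)
  expect_equal(log_likelihood(zero, matrix(1, n, n)), -choose(n, 2))
  # per-pair maximum at lambda = n
  counts <- matrix(c(0, 4, 4, 0), 2)
  base <- log_likelihood(counts, matrix(c(0, 4, 4, 0), 2))
  for (l in c(2, 3.5, 4.5, 7))
    expect_lt(log_likelihood(counts, matrix(c(0, l, l, 0), 2)), base)
})

test_that("likelihood is invariant under rigid motions of the structure", {
  set.seed(7)
  d <- tiny_dataset(7, seed = 7)
  p <- model_params(2, -1, 0.2, 0.1, 0.3)
  s <- d$truth$structure
  base <- log_likelihood(d$cm, poisson_rates(s, d$lf, p))
  for (i in 1:3) {
    r <- random_rotation()
    if (i == 3) r <- r %*% diag(c(1, 1, -1))      # include a reflection
    s2 <- sweep(s %*% t(r), 2, rnorm(3), "+")
    expect_equal(log_likelihood(d$cm, poisson_rates(s2, d$lf, p)), base,
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match central differences", {
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(5:8, 1)
    s <- matrix(rnorm(n * 3), n, 3)
    lf <- simulate_features(n, seed = rep)
    p <- model_params(rnorm(1), -runif(1, 0.5, 1.5), rnorm(1, 0, 0.3),
                      rnorm(1, 0, 0.3), rnorm(1, 0, 0.3))
    cmat <- matrix(rpois(n * n, 6), n, n); cmat <- cmat + t(cmat)
    diag(cmat) <- 0
    g <- grad_log_posterior(cmat, s, lf, p)
    f <- function(sv, pv)
      log_likelihood(cmat, poisson_rates(matrix(sv, n, 3), lf,
                                         do.call(model_params, as.list(pv))))
    eps <- 1e-6
    sv <- as.numeric(s); pv <- unname(unclass(p))
    num_c <- vapply(seq_along(sv), function(i) {
      e <- replace(numeric(length(sv)), i, eps)
      (f(sv + e, pv) - f(sv - e, pv)) / (2 * eps)
    }, numeric(1))
    num_p <- vapply(1:5, function(i) {
      e <- replace(numeric(5), i, eps)
      (f(sv, pv + e) - f(sv, pv - e)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num_c - as.numeric(g$coords))), 1e-5)
    expect_lt(max(abs(num_p - unname(g$params))), 1e-5)
  }
})

test_that("gradient is zero at saturation and sums to zero over translations", {
  d <- tiny_dataset(6, seed = 9)
  # at lambda = n for all pairs the parameter gradient vanishes: build
  # counts from the model rates themselves
  p <- d$truth$params
  lam <- poisson_rates(d$truth$structure, d$lf, p)
  cmat <- lam; diag(cmat) <- 0
  g <- grad_log_posterior(cmat, d$truth$structure, d$lf, p)
  expect_lt(max(abs(g$params)), 1e-8)
  # translation invariance: coordinate gradients sum to zero per axis
  g2 <- grad_log_posterior(d$cm, d$truth$structure, d$lf, p)
  expect_lt(max(abs(colSums(g2$coords))), 1e-8)
})

test_that("aic follows 2k - 2 loglik and its monotonicities", {
  expect_equal(aic(-100, 5), 210)
  expect_lt(aic(-50, 2), aic(-50, 4))
  expect_equal(aic(-50, 2), aic(-49, 3))
  expect_error(aic(-1, -1), "non-negative")
})

test_that("structure TSV round trip", {
  tdir <- withr::local_tempdir()
  s <- matrix(rnorm(15), 5, 3)
  p <- file.path(tdir, "s.tsv")
  write_structure(s, p)
  back <- read_structure(p)
  expect_equal(back$coords, s, tolerance = 1e-12, ignore_attr = TRUE)
})
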