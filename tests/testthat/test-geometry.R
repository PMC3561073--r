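test_that("HD ratio of a dense uniform helix matches the analytic value", {
  h <- helix_backbone(3000, height = 10, radius = 1, turns = 40)
  cf <- hd_ratio(h)
  # uniform axial density: q90 - q10 = 0.8 h; median radial distance = r
  expect_equal(cf$hd_raw, 0.8 * 10 / (4 * 1), tolerance = 0.05 / 2)
  expect_equal(cf$hd_ratio, cf$hd_raw / (3000 / 25))
})

test_that("HD ratio is invariant under rigid motion and uniform scaling", {
  set.seed(21)
  s <- random_walk(30, seed = 21)
  base <- hd_ratio(s)$hd_raw
  r <- random_rotation()
  moved <- sweep(s %*% t(r), 2, c(5, -1, 2), "+")
  expect_equal(hd_ratio(moved)$hd_raw, base, tolerance = 1e-9)
  expect_equal(hd_ratio(3.7 * s)$hd_raw, base, tolerance = 1e-9)
  expect_error(hd_ratio(line_backbone(10)), "collinear")
})

test_that("HD ratio of an isotropic cloud concentrates regardless of rotation", {
  set.seed(22)
  vals <- replicate(20, {
    x <- matrix(rnorm(300 * 3), 300, 3) %*% t(random_rotation())
    hd_ratio(x)$hd_raw
  })
  expect_lt(stats::sd(vals) / mean(vals), 0.15)
})

test_that("superposition removes scale, rotation and translation", {
  set.seed(23)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(optimal_superposition(a, a)$rmsd, 0, tolerance = 1e-12)
  r <- random_rotation()
  b <- 2 * a %*% t(r) + matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  al <- optimal_superposition(a, b)
  expect_lt(al$rmsd, 1e-8)
  expect_equal(al$scale, 2, tolerance = 1e-10)
  expect_equal(det(al$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD is symmetric and matches a rotation-grid oracle", {
  set.seed(24)
  for (rep in 1:2) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    r1 <- optimal_superposition(a, b)$rmsd
    expect_equal(r1, optimal_superposition(b, a)$rmsd, tolerance = 1e-6)
    # brute-force oracle: minimize over proper rotations (Euler grid plus
    # local polish), on the same unit-gyration normalization
    an <- scale(a, scale = FALSE); an <- an / sqrt(mean(rowSums(an^2)))
    bn <- scale(b, scale = FALSE); bn <- bn / sqrt(mean(rowSums(bn^2)))
    obj <- function(e) {
      rot <- arrangement_transform(e, 1)$transform
      sqrt(mean(rowSums((an - bn %*% t(rot))^2)))
    }
    gr <- seq(0, 2 * pi, length.out = 13)[-13]
    gb <- seq(0, pi, length.out = 7)
    best <- Inf; beste <- NULL
    for (x in gr) for (y in gb) for (z in gr) {
      v <- obj(c(x, y, z))
      if (v < best) { best <- v; beste <- c(x, y, z) }
    }
    pol <- stats::optim(beste, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    expect_equal(r1, pol$value, tolerance = 1e-3)
  }
})

test_that("sliding-window RMSD has length K - window + 1", {
  set.seed(25)
  a <- random_walk(19, seed = 1); b <- random_walk(19, seed = 2)
  expect_length(sliding_window_rmsd(a, b, 10), 10)      # K - 9
  expect_length(sliding_window_rmsd(a[1:10, ], b[1:10, ], 10), 1)
  expect_true(all(sliding_window_rmsd(a, a, 10) < 1e-10))
  expect_error(sliding_window_rmsd(a[1:5, ], b[1:5, ], 10), "shorter")
})

test_that("interpretive RMSD thresholds are exposed", {
  expect_equal(unname(RMSD_SIMILARITY_THRESHOLDS), c(0.1, 0.2))
})

test_that("plane separation test reproduces the hypergeometric oracle", {
  set.seed(26)
  s <- rbind(cbind(runif(6, 1, 2), rnorm(6), rnorm(6)),
             cbind(runif(6, -2, -1), rnorm(6), rnorm(6)),
             cbind(rep(0, 3), rnorm(3), rnorm(3)))
  labels <- c(rep("high", 6), rep("low", 6), rep("mid", 3))
  res <- plane_separation_test(s, labels)
  expect_equal(sort(as.numeric(res$table)), c(0, 0, 6, 6))
  expect_equal(res$p_value, 2 / 924, tolerance = 1e-10)
  # degenerate all-on-one-side table: Haldane-corrected odds ratio
  s2 <- rbind(cbind(runif(4, 1, 2), rnorm(4), rnorm(4)),
              cbind(runif(4, 1, 2), rnorm(4), rnorm(4)),
              cbind(rep(0, 3), rnorm(3), rnorm(3)))
  labels2 <- c(rep("high", 4), rep("low", 4), rep("mid", 3))
  res2 <- plane_separation_test(s2, labels2)
  expect_true(is.finite(res2$odds_ratio))
  expect_error(plane_separation_test(s[1:13, ], labels[c(1:12, 15)]),
               "at least 3 mid")
})

test_that("plane test p-values are unremarkable under label shuffling", {
  set.seed(27)
  s <- matrix(rnorm(60), 20, 3)
  ps <- replicate(100, {
    lab <- sample(c(rep("low", 7), rep("high", 7), rep("mid", 6)))
    plane_separation_test(s, lab)$p_value
  })
  expect_gt(stats::median(ps), 0.1)
})

test_that("feature grouping splits at the 33rd/67th percentiles", {
  g <- feature_groups(1:99)
  expect_equal(sum(g == "low"), 33)
  expect_equal(sum(g == "high"), 33)
  expect_equal(sum(g == "mid"), 33)
})
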