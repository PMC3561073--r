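test_that("arrangement transforms: identity, determinant, axis-angle oracle", {
  id <- arrangement_transform(c(0, 0, 0), 1)
  expect_equal(id$transform, diag(3), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:5) {
    e <- runif(3, 0, 2 * pi)
    m <- sample(c(1, -1), 1)
    a <- arrangement_transform(e, m)
    expect_equal(det(a$transform), m, tolerance = 1e-10)
    expect_equal(crossprod(a$transform), diag(3), tolerance = 1e-10)
  }
  # R(alpha, 0, 0) is a rotation by alpha about z: check against the
  # axis-angle (Rodrigues) construction with axis (0,0,1)
  for (al in c(0.3, 1.2, 2.5)) {
    rodrigues <- function(axis, th) {
      k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                    axis[2], -axis[1], 0), 3, 3)
      diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
    }
    expect_equal(arrangement_transform(c(al, 0, 0), 1)$transform,
                 rodrigues(c(0, 0, 1), al), tolerance = 1e-10)
  }
})

test_that("arrangement grid enumeration and deduplication", {
  expect_length(enumerate_arrangements(1), 2)        # one cell x 2 mirrors
  grid <- enumerate_arrangements(4)
  expect_lte(length(grid), 128)
  for (a in grid[seq(1, length(grid), by = 17)])
    expect_equal(crossprod(a$transform), diag(3), tolerance = 1e-10)
  # all pairwise transform differences exceed the dedup tolerance
  # (exhaustive pairwise oracle)
  mats <- lapply(grid, `[[`, "transform")
  mind <- Inf
  for (i in seq_along(mats)[-1])
    for (j in seq_len(i - 1))
      mind <- min(mind, max(abs(mats[[i]] - mats[[j]])))
  expect_gt(mind, 1e-8)
})

test_that("placing region B is rigid and flips chirality under mirror", {
  set.seed(3)
  a <- random_walk(8, seed = 31)
  b <- random_walk(6, seed = 32)
  db <- pairwise_distances(b)
  signed_vol <- function(x) det(rbind(x[2, ] - x[1, ], x[3, ] - x[1, ],
                                      x[4, ] - x[1, ]))
  id <- arrangement_transform(c(0, 0, 0), 1)
  bp <- place_region_b(a, b, id)
  # identity arrangement: B unchanged up to the anchoring translation
  expect_equal(sweep(bp, 2, bp[1, ]), sweep(b, 2, b[1, ]), tolerance = 1e-10)
  for (mir in c(1, -1)) {
    arr <- arrangement_transform(c(0.7, 1.1, 2.0), mir)
    bp <- place_region_b(a, b, arr)
    expect_equal(pairwise_distances(bp), db, tolerance = 1e-10)
    v0 <- signed_vol(b[1:4, ]); v1 <- signed_vol(bp[1:4, ])
    expect_equal(sign(v1), mir * sign(v0))
  }
  expect_error(place_region_b(rbind(c(0, 0, 0), c(0, 0, 0)), b, id),
               "degenerate")
})

test_that("mixture rates reduce, degenerate and stay linear in proportions", {
  sa <- arc_backbone(6); sb <- arc_backbone(5)
  lf <- simulate_features(11, seed = 8)
  lf_a <- locus_features(as.data.frame(lf)[1:6, ])
  lf_b <- locus_features(as.data.frame(lf)[7:11, ])
  p <- model_params(2, -1, 0.3, 0.2, 0.1)
  arr1 <- arrangement_transform(c(0.5, 0.8, 0.2), 1)
  arr2 <- arrangement_transform(c(2.5, 2.0, 1.2), -1)
  # K = 1 equals the single-structure rates on the composed cross block
  lam1 <- mixture_rates(sa, sb, arrangement_mixture(list(arr1), 1),
                        lf_a, lf_b, p)
  comp <- rbind(sa, place_region_b(sa, sb, arr1))
  full <- poisson_rates(comp, lf, p)
  expect_equal(lam1, full[1:6, 7:11], tolerance = 1e-10)
  # identical transforms at 50/50 degenerate to K = 1
  lam_dup <- mixture_rates(sa, sb,
                           arrangement_mixture(list(arr1, arr1),
                                               c(0.5, 0.5)),
                           lf_a, lf_b, p)
  expect_equal(lam_dup, lam1, tolerance = 1e-12)
  # linearity in pi at fixed arrangements
  lam2 <- mixture_rates(sa, sb, arrangement_mixture(list(arr2), 1),
                        lf_a, lf_b, p)
  for (w in c(0.25, 0.6)) {
    lam_mix <- mixture_rates(sa, sb,
                             arrangement_mixture(list(arr1, arr2),
                                                 c(w, 1 - w)),
                             lf_a, lf_b, p)
    expect_equal(lam_mix, w * lam1 + (1 - w) * lam2, tolerance = 1e-10)
  }
})

test_that("effective structure counting", {
  expect_equal(effective_structures(c(0.90, 0.06, 0.04), 0.05), 2)
  expect_equal(effective_structures(c(1.0), 0.5), 1)
  expect_error(effective_structures(c(1), 1.5), "threshold")
  pr <- c(0.5, 0.3, 0.12, 0.05, 0.02, 0.01)
  counts <- vapply(c(0.01, 0.05, 0.10), effective_structures,
                   numeric(1), mixture = pr)
  expect_true(all(diff(counts) <= 0))
})

test_that("mixture container validates proportions", {
  a <- arrangement_transform(c(0, 0, 0), 1)
  expect_error(arrangement_mixture(list(a), c(0.5, 0.5)), "match")
  expect_error(arrangement_mixture(list(a, a), c(0.7, 0.7)), "sum to 1")
  expect_error(arrangement_mixture(list(), numeric(0)), "at least one")
})
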