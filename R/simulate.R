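#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the
#' caller's RNG state afterwards, so seeded computations never disturb the
#' surrounding random stream. Every generator in the package is a pure
#' function of its seed through this mechanism. A `NULL` seed evaluates
#' the expression on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random-walk polymer backbone
#'
#' A free ideal chain: step directions drawn uniformly on the sphere, fixed
#' step length, first bead at the origin. This is the backbone model used
#' for the RMSD reference distribution of the two-step dominance test.
#'
#' @param n_loci number of beads (>= 2); the walk has `n_loci - 1` steps.
#' @param step_len bond length.
#' @param seed optional integer seed; the walk is a pure function of it.
#' @return `n_loci` x 3 coordinate matrix.
#' @export
random_walk <- function(n_loci, step_len = 1, seed = NULL) {
  if (n_loci < 2) stop("n_loci must be >= 2")
  with_seed(seed, {
    z <- matrix(stats::rnorm(3 * (n_loci - 1)), ncol = 3)
    steps <- z / sqrt(rowSums(z^2)) * step_len
    rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  })
}

#' Helix backbone
#'
#' Beads evenly spaced along a circular helix of given height and radius,
#' axis along z. Included as a backbone with analytic cylinder geometry:
#' for dense uniform sampling the raw height-to-diameter ratio of the
#' fitted cylinder is `0.8 * height / (4 * radius)`.
#'
#' @param n_loci number of beads.
#' @param height axial extent.
#' @param radius helix radius.
#' @param turns number of full turns.
#' @return `n_loci` x 3 coordinate matrix.
#' @export
helix_backbone <- function(n_loci, height = 10, radius = 1, turns = 5) {
  u <- seq(0, 1, length.out = n_loci)
  t <- 2 * pi * turns * u
  cbind(radius * cos(t), radius * sin(t), height * u)
}

#' Straight-line backbone
#'
#' @param n_loci number of beads.
#' @param step_len spacing between consecutive beads (along x).
#' @return `n_loci` x 3 coordinate matrix.
#' @export
line_backbone <- function(n_loci, step_len = 1) {
  cbind((seq_len(n_loci) - 1) * step_len, 0, 0)
}

make_backbone <- function(kind, n_loci, seed = NULL) {
  switch(kind,
         random_walk = random_walk(n_loci, seed = seed),
         helix = helix_backbone(n_loci),
         line = line_backbone(n_loci),
         stop("unknown backbone kind: ", kind))
}

#' Simulate per-locus bias covariates
#'
#' Marginals chosen to resemble real 40 KB mammalian Hi-C bins: fragment-end
#' counts roughly lognormal around 30 per bin, GC in (0.3, 0.65),
#' mappability in (0.8, 1]. All values clear the default filtering
#' thresholds by construction, so simulated regions are never truncated by
#' preprocessing.
#'
#' @param n_loci number of bins (>= 3).
#' @param seed optional integer seed.
#' @return a [locus_features()] table.
#' @export
simulate_features <- function(n_loci, seed = NULL) {
  if (n_loci < 3) stop("n_loci must be >= 3")
  with_seed(seed, {
    fe <- pmax(6, round(stats::rlnorm(n_loci, log(30), 0.35)))
    gc <- stats::runif(n_loci, 0.32, 0.64)
    mp <- stats::runif(n_loci, 0.82, 1.0)
    locus_features(fe, gc, mp)
  })
}

#' Intercept for a target sequencing depth
#'
#' Given a structure, covariates and the non-intercept parameters, returns
#' the `beta0` at which the mean off-diagonal Poisson rate equals
#' `target_mean`. Depth is the single difficulty knob of the simulator.
#'
#' @param target_mean desired mean expected count per locus pair.
#' @param s backbone coordinates.
#' @param lf covariates (or `NULL` for the no-bias model).
#' @param p a [model_params()]; its `beta0` entry is ignored.
#' @return scalar `beta0`.
#' @export
beta0_for_depth <- function(target_mean, s, lf, p) {
  p0 <- p; p0[["beta0"]] <- 0
  lam <- poisson_rates(s, lf, p0)
  log(target_mean) - log(mean(lam[upper.tri(lam)]))
}

#' Simulation scenario
#'
#' Collects everything that defines a synthetic Hi-C dataset: region size,
#' backbone model, rate parameters, sequencing depth and (optionally) an
#' arrangement mixture for two adjacent sub-regions. The seed is mandatory:
#' every generated dataset is a pure function of its scenario.
#'
#' @param n_loci number of bins in the region.
#' @param backbone `"random_walk"`, `"helix"` or `"line"`.
#' @param params a [model_params()]. When `target_mean` is given, `beta0`
#'   is recomputed per dataset to hit that depth.
#' @param target_mean mean expected count per pair, or `NULL` to use
#'   `params["beta0"]` as-is.
#' @param mixture optional [arrangement_mixture()]; when present the region
#'   is split in half and cross-block counts follow the mixture model.
#' @param split_at index of the last locus of sub-region A (defaults to
#'   `floor(n_loci / 2)`).
#' @param struct_a,struct_b optional explicit sub-structures for mixture
#'   scenarios (otherwise drawn from the backbone model).
#' @param bin_size bin width in bp for the fabricated bin table.
#' @param seed integer seed (required).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_loci, backbone = "random_walk",
                         params = model_params(beta0 = 3, beta_d = -1,
                                               beta_e = 0.3, beta_g = 0.3,
                                               beta_m = 0.3),
                         target_mean = NULL, mixture = NULL,
                         split_at = NULL, struct_a = NULL, struct_b = NULL,
                         bin_size = 40000L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (!is.null(mixture) && !inherits(mixture, "arrangement_mixture"))
    stop("mixture must be an arrangement_mixture")
  structure(list(n_loci = n_loci, backbone = backbone, params = params,
                 target_mean = target_mean, mixture = mixture,
                 split_at = if (is.null(split_at)) floor(n_loci / 2)
                            else split_at,
                 struct_a = struct_a, struct_b = struct_b,
                 bin_size = bin_size, seed = as.integer(seed)),
            class = "sim_scenario")
}

sim_bins <- function(n_loci, bin_size, chrom = "chrS") {
  data.frame(chrom = chrom, start = (seq_len(n_loci) - 1) * bin_size,
             end = seq_len(n_loci) * bin_size)
}

draw_counts <- function(lam) {
  n <- nrow(lam)
  counts <- matrix(0, n, n)
  ut <- which(upper.tri(lam))
  counts[ut] <- stats::rpois(length(ut), lam[ut])
  counts + t(counts)
}

#' Simulate a single-population Hi-C contact matrix
#'
#' Draws a backbone, evaluates the log-linear Poisson rates, and draws one
#' independent Poisson count per unordered locus pair (mirrored into both
#' triangles; the diagonal is zero).
#'
#' @param scenario a [sim_scenario()] without a mixture component.
#' @return list with `cm` (a [contact_matrix()]), `lf`
#'   (a [locus_features()]) and `truth` (structure, params, rates).
#' @export
simulate_single_population <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$mixture))
    stop("scenario has a mixture; use simulate_mixture_population")
  with_seed(scenario$seed, {
    s <- make_backbone(scenario$backbone, scenario$n_loci)
    lf <- simulate_features(scenario$n_loci)
    p <- scenario$params
    if (!is.null(scenario$target_mean))
      p[["beta0"]] <- beta0_for_depth(scenario$target_mean, s, lf, p)
    lam <- poisson_rates(s, lf, p)
    cm <- contact_matrix(draw_counts(lam),
                         sim_bins(scenario$n_loci, scenario$bin_size))
    list(cm = cm, lf = lf,
         truth = list(structure = s, params = p, rates = lam))
  })
}

#' Simulate a mixture-population Hi-C dataset
#'
#' The region is split into two adjacent sub-regions with fixed consensus
#' sub-structures; cells differ only in the spatial arrangement of region B
#' relative to region A. Intra-region counts follow the single-structure
#' model; cross-region counts are Poisson with the proportion-weighted
#' mixture rate over arrangements.
#'
#' @param scenario a [sim_scenario()] whose `mixture` is set.
#' @return list with `cm` (full region [contact_matrix()]), `cross`
#'   (N_A x N_B cross-block counts), `lf`, `split_at`, and `truth`
#'   (sub-structures, mixture, params).
#' @export
simulate_mixture_population <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  mix <- scenario$mixture
  if (is.null(mix)) stop("scenario has no mixture component")
  if (length(mix$arrangements) == 0) stop("empty arrangement list")
  with_seed(scenario$seed, {
    na <- scenario$split_at
    nb <- scenario$n_loci - na
    stopifnot(na >= 3, nb >= 3)
    sa <- if (is.null(scenario$struct_a)) make_backbone(scenario$backbone, na)
          else as.matrix(scenario$struct_a)
    sb <- if (is.null(scenario$struct_b)) make_backbone(scenario$backbone, nb)
          else as.matrix(scenario$struct_b)
    stopifnot(nrow(sa) == na, nrow(sb) == nb)
    lf <- simulate_features(scenario$n_loci)
    lf_a <- locus_features(as.data.frame(lf)[seq_len(na), ])
    lf_b <- locus_features(as.data.frame(lf)[na + seq_len(nb), ])
    p <- scenario$params
    if (!is.null(scenario$target_mean)) {
      # calibrate depth on the identity-arranged composite region
      comp <- rbind(sa, place_region_b(sa, sb,
                                       arrangement_transform(c(0, 0, 0), 1)))
      p[["beta0"]] <- beta0_for_depth(scenario$target_mean, comp, lf, p)
    }
    lam_a <- poisson_rates(sa, lf_a, p)
    lam_b <- poisson_rates(sb, lf_b, p)
    lam_x <- mixture_rates(sa, sb, mix, lf_a, lf_b, p)
    counts <- matrix(0, scenario$n_loci, scenario$n_loci)
    ia <- seq_len(na); ib <- na + seq_len(nb)
    counts[ia, ia] <- draw_counts(lam_a)
    counts[ib, ib] <- draw_counts(lam_b)
    cross <- matrix(stats::rpois(na * nb, lam_x), na, nb)
    counts[ia, ib] <- cross
    counts[ib, ia] <- t(cross)
    cm <- contact_matrix(counts, sim_bins(scenario$n_loci, scenario$bin_size))
    list(cm = cm, cross = cross, lf = lf, split_at = na,
         truth = list(struct_a = sa, struct_b = sb, mixture = mix,
                      params = p, rates_cross = lam_x))
  })
}
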