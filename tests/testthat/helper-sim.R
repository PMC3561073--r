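# Shared fixtures, all generated in code.

# small deterministic count matrix with matching features
tiny_dataset <- function(n = 6, seed = 1) {
  sim <- simulate_single_population(
    sim_scenario(n, "random_walk", target_mean = 20, seed = seed))
  list(cm = sim$cm, lf = sim$lf, truth = sim$truth)
}

# elongated arc used for arrangement studies: real topological domains are
# elongated, which makes spatial arrangements geometrically distinguishable
arc_backbone <- function(n) helix_backbone(n, height = 6, radius = 2,
                                           turns = 0.75)

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# deep mixture dataset over a fixed candidate set (generating sub-structures
# are the arcs; cross-block counts follow the arrangement mixture)
mixture_dataset <- function(truth_idx, truth_pi, cands, seed,
                            n_half = 13, beta0 = 6) {
  s <- arc_backbone(n_half)
  mx <- arrangement_mixture(cands[truth_idx], truth_pi)
  sc <- sim_scenario(2 * n_half,
                     params = model_params(beta0, -1, 0.3, 0.3, 0.3),
                     mixture = mx, struct_a = s, struct_b = s, seed = seed)
  sim <- simulate_mixture_population(sc)
  c(sim, list(struct = s))
}

fast_config <- function(seed = 1, ...) {
  bach_config(n_chains = 2, n_iter = 400, burn_in = 150, thin = 10,
              sis_particles = 20, sis_enrich = 3, seed = seed, ...)
}
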