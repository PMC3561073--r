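# bach3d — Bayesian 3D chromatin structure inference from Hi-C data

Hi-C experiments count ligation events between pairs of genomic loci
across millions of cells. Those counts carry two entangled signals: the
3D folding of chromatin (spatially close loci ligate more often) and
systematic experimental biases (restriction-site density, GC content,
mappability). `bach3d` is for computational biologists who want to turn a
binned Hi-C contact matrix into a posterior distribution over 3D
structures — and to ask whether one consensus structure is even the right
description of the cell population.

## The models

**Consensus structure (BACH).** Each of the $N$ loci of a region is a
bead $p_i \in \mathbb{R}^3$, and the off-diagonal contact count
$n_{ij}$ is Poisson with

$$\ln \lambda_{ij} = \beta_0 + \beta_d \ln \lVert p_i - p_j \rVert
  + \beta_e \ln(x_i x_j) + \beta_g \ln(g_i g_j) + \beta_m \ln(m_i m_j),$$

where $x, g, m$ are fragment-end count, GC content and mappability per
bin and $\beta_d < 0$ is the distance decay. Inference is fully Bayesian
with flat priors: Poisson-regression initialization, sequential
importance sampling to grow an initial polymer, then a Gibbs sampler
alternating Hamiltonian Monte Carlo coordinate updates with slice-sampled
parameter updates, across parallel chains monitored by the Gelman–Rubin
statistic.

**Structural variation (BACH-MIX).** For two adjacent sub-regions with
fixed internal structures, the spatial *arrangement* of one relative to
the other (a Z–Y–Z Euler rotation plus an optional mirror flip) is
allowed to vary across cells; cross-region counts follow a Poisson
mixture over a discretized arrangement set with multinomial proportions,
inferred jointly with the rate parameters by HMC, then pruned at the 1%
rule. *Effective structures* are components above 5%.

Also included: the cylinder height-to-diameter (HD) ratio of a structure,
scale- and rigid-motion-invariant normalized RMSD superposition,
sliding-window local structure comparison, a plane-separation Fisher
test, a two-step dominant-structure test against a random-walk RMSD null,
and a fully seeded synthetic Hi-C generator. The methods vignette
(`vignettes/bach-methods.Rmd`) documents every model, convention and
measured limitation.

## A worked example

Simulate a 20-locus (800 KB at 40 KB resolution) region at deep coverage
and refit it:

```r
library(bach3d)

sim <- simulate_single_population(
  sim_scenario(n_loci = 20, backbone = "random_walk",
               target_mean = 60, seed = 42))
sim$cm
#> Hi-C contact matrix: 20 bins on chrS [0-800000), total off-diagonal count 11164

fit <- bach(sim$cm, sim$lf, bach_config(seed = 42))
summary(fit)
#> BACH posterior summary (20 loci, 240 samples)
#>
#>        beta0 beta_d beta_e beta_g beta_m
#> mean  10.625 -1.004  0.308  0.147  0.323
#> 2.5%   8.569 -1.046  0.225  0.001 -0.160
#> 97.5% 11.788 -0.964  0.383  0.320  0.699
#> mode  11.245 -1.004  0.252  0.211  0.417
#>
#> log-likelihood at mode: -630.15   AIC: 1390.31
#> Gelman-Rubin (loglik): 1.004  [converged]

truth <- pairwise_distances(sim$truth$structure)
ut <- upper.tri(truth)
cor(truth[ut], fit$distance_posterior$mean[ut])
#> [1] 0.99

hd_ratio(fit$mode_structure)
#> cylinder fit: height 9.62e+03, diameter 9.21e+03, HD ratio 1.31 (raw 1.04, 20 loci)
```

The generating decay exponent was $\beta_d = -1$ and all three bias
coefficients were 0.3: the posterior recovers the decay almost exactly,
brackets the bias coefficients, and the posterior-mean pairwise distances
correlate with the generating structure at $r = 0.99$. (The absolute
coordinate scale is arbitrary — it trades off exactly with $\beta_0$ —
which is why distance summaries are reported in a normalized gauge and
the HD ratio is scale-free.) `predict()` gives the fitted expected
contact matrix, `residuals()` its residuals, `simulate()` parametric
bootstrap matrices, and `plot()` the fitted structure.

A thin command-line wrapper over the same functions is installed at
`inst/cli/bach.R` (subcommands `simulate`, `fit`, `mix`, `geom`,
`twostep`, `pipeline`).

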