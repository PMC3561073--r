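---
title: "Bayesian 3D chromatin structure inference from Hi-C: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian 3D chromatin structure inference from Hi-C: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bach3d)
```

## The model

A genomic region is divided into $N$ consecutive, disjoint loci of equal
size (typically 40 KB), each represented by a bead $p_i \in \mathbb{R}^3$.
The Hi-C contact count $n_{ij}$ between loci $i \ne j$ is modelled as
Poisson with a log-linear rate combining the spatial distance
$d_{ij} = \lVert p_i - p_j \rVert$ with the three known systematic bias
covariates of Hi-C — restriction fragment-end count $x_i$, GC content
$g_i$ and mappability $m_i$:

$$\ln \lambda_{ij} \;=\; \beta_0 + \beta_d \ln d_{ij}
  + \beta_e \ln(x_i x_j) + \beta_g \ln(g_i g_j) + \beta_m \ln(m_i m_j).$$

$\beta_d < 0$ captures the distance decay of contact frequency;
$\beta_e, \beta_g, \beta_m$ absorb the multiplicative biases. The joint
likelihood is the product of Poisson terms over unordered off-diagonal
pairs; the diagonal is never used. All priors are flat (non-informative),
so the log-posterior gradient equals the likelihood gradient. Setting
`bias = FALSE` in `bach_config()` drops the three bias terms, giving the
uncorrected model variant.

### What is and is not identified

The likelihood depends on the structure only through pairwise distances,
so the posterior is invariant under translation, rotation and reflection
of the beads, and a global rescaling $p_i \mapsto c\,p_i$ is exactly
absorbed by $\beta_0 \mapsto \beta_0 - \beta_d \ln c$. None of these gauge
freedoms are fixed in the sampler; instead,

* distance summaries (`distance_posterior`) are reported in the
  unit-mean-bond-length gauge — each retained sample is rescaled so its
  mean adjacent-bead distance is 1 — which makes per-pair credible
  intervals well defined;
* structures are compared after superposition
  (`optimal_superposition()`), which removes scale and rigid motion;
* handedness is not determined by the data at all: a reflected structure
  fits identically. Comparisons between independent fits therefore use
  the chirality-blind RMSD (`rmsd_up_to_mirror()`); within the
  arrangement mixture model reflection is an explicit, inferred mirror
  flag.

At moderate sequencing depth one further *soft* degeneracy matters: a
power-law compression of all distances ($d \mapsto d^\gamma$) combined
with $\beta_d \mapsto \beta_d/\gamma$ changes the rates only through the
imperfect embeddability of the compressed distances. At a mean of ~15
reads per locus pair the flat-prior posterior visibly prefers slightly
compressed long-range distances with a steeper decay (the posterior mode
attains a higher likelihood than the generating truth — ordinary
finite-data overfitting, not a sampler defect), and credible-interval
coverage of true distances degrades. At the deep-coverage settings the
simulator defaults to (below) the effect is negligible.

## Three-stage inference

`bach()` implements the three-stage procedure:

1. **Initialization by Poisson regression.** `init_params_glm()` fits a
   Poisson GLM of the off-diagonal counts on $\ln|i-j|$ (genomic distance
   as a proxy for log spatial distance before any structure exists) and
   the three log bias products. A non-convergent GLM falls back to
   $(\ln \bar n, -1, 0, 0, 0)$ with a warning.
2. **Sequential importance sampling.** `sis_initial_structure()` grows
   each of `sis_particles` (default 100) structures bead by bead. Every
   particle proposes `sis_enrich` (default 10) candidate positions from
   an isotropic Gaussian centred on the previous bead, with scale set by
   solving the fitted decay model at the observed mean adjacent-pair
   count; a candidate is selected with probability proportional to the
   partial likelihood of all observed contacts involving the new bead,
   and the marginal candidate weight accumulates into the particle
   weight. When the effective sample size drops below half the particle
   count, particles are resampled by weight (rejection control). The
   highest-weight completed structure seeds each chain. If all weights
   underflow, the proposal scale is doubled (three attempts) before
   giving up.
3. **Gibbs refinement.** Each iteration updates the coordinates with one
   hybrid (Hamiltonian) Monte Carlo trajectory — leapfrog with the exact
   analytic gradient, default 10 steps, step size auto-tuned during
   burn-in toward a 0.6–0.9 acceptance rate — and then updates each rate
   parameter from its univariate log-concave conditional by slice
   sampling (stepping-out/shrinkage), which has the same stationary law
   as adaptive rejection sampling. With `enforce_negative_decay = TRUE`
   (default) proposals with $\beta_d \ge 0$ are rejected.

Defaults are three independent chains of 5,000 iterations, the first
1,000 dropped, every 50th retained sample used for inference; convergence
is monitored by the Gelman–Rubin statistic on the log-likelihood trace
(values $\le 1.1$ taken as converged, otherwise the fit is flagged). The
posterior "mode" is the retained sample with the highest posterior
(= likelihood) value. The AIC is $2k - 2\ell_{\text{mode}}$ with
$k = 3N + 5$ ($3N + 2$ without bias terms).

In practice the leapfrog step size settles just below the integrator's
stability limit, which is set by the stiffest directions (short-range,
high-count pairs); overall acceptance rates near 1 are therefore normal
for this posterior and do not indicate an untuned sampler.

## The arrangement mixture (BACH-MIX)

Two adjacent sub-regions A and B are each assumed to have a consensus
internal structure, while the *arrangement* of B relative to A varies
across the cell population. An arrangement is a Z–Y–Z Euler rotation
$R(\alpha, \beta, \gamma)$ composed with a mirror matrix
$M = \mathrm{diag}(1, 1, s)$, $s \in \{+1, -1\}$, applied to B about its
anchor. The anchoring convention places B's first bead one mean bond
length beyond A's last bead along A's terminal bond direction — this
preserves chain adjacency across the junction under every arrangement
and is a package convention (only the rotation/mirror algebra is given
by the model itself).

The cross-block count between locus $i$ of A and $j$ of B is Poisson with
the proportion-weighted rate
$\lambda_{ij} = \sum_k \pi_k \exp(\beta_0 + \beta_d \ln d_{ijk} + \text{bias})$,
where $d_{ijk}$ is the $i$–$j$ distance under arrangement $k$. The
continuous arrangement space is discretized: each Euler angle range is
split into `bins_per_angle` equal bins represented by their centres,
crossed with both mirrors (128 candidates at the default of 4 bins per
angle; coincident transforms are merged).

`bach_mix()` infers the proportions on the softmax scale jointly with the
rate parameters by HMC with analytic gradients. Implementation choices
that matter:

* **Unpinned logits.** All $K$ logits are free; the common shift is an
  exact gauge (softmax normalizes it away). Pinning one logit couples a
  dead component to the drifting overall level and lets it spuriously
  reabsorb mass.
* **ECM initialization.** With $\beta_d$ held at $-1$, an EM pass on the
  per-component intensities alternates with a Poisson GLM for the bias
  coefficients given the mixture offset. This starts the chain at the
  likelihood-supported corner of the simplex, so unsupported logits begin
  (and, the conditional likelihood being flat there, remain) deeply
  negative.
* **Pre-screening.** Candidate sets larger than `prescreen_max` (24) are
  reduced to the EM-supported components before sampling — the same
  sparsification principle as the post-hoc rule below, applied at
  initialization, which keeps the HMC dimension manageable for fine
  grids.
* **Prune and refit.** After sampling, components with posterior mean
  proportion below 1% are removed and the reduced model refit once.
  *Effective structures* are components with proportion above 5% (1% and
  10% are also reported).
* **Total likelihood for AIC.** The mixture model's AIC uses
  $k = 3N_A + 3N_B + 5 + (K - 1)$ and a likelihood spanning both intra
  blocks (at the fixed sub-structures) and the cross-block mixture, with
  one shared set of rate parameters maximized against exactly that
  likelihood (BFGS with analytic gradients). Both sub-structures are
  first brought to unit mean bond length so the shared parameters live in
  one gauge. Gauge degrees of freedom appear in both models' counts and
  cancel in the comparison.

### When are arrangement proportions identifiable?

Two candidate arrangements whose cross-block rate patterns are
proportional (up to a constant) are confounded with the intercept: a
small admixture of one is invisible under the other at *any* sequencing
depth. This happens readily — for isotropic (random-walk-like)
sub-structures most rotations barely change the anchor-centred distance
profile, and "far" arrangements hide inside "near" ones as a global
rescale. Quantitatively, contaminating a component by a fraction
$\varepsilon$ of another costs an expected log-likelihood
$\approx \tfrac{1}{2}\varepsilon^2 \chi^2$, with $\chi^2$ the
intercept-profiled divergence between the two patterns — quadratic in
$\varepsilon$, so resolving the 1% pruning rule needs large $\chi^2$.
`select_separated_arrangements()` computes these penalties and greedily
selects a mutually distinguishable candidate set; the recovery studies in
the test suite use elongated arc-shaped sub-structures (real topological
domains are elongated) and deep cross-block coverage, which together put
the mixture solidly in the identified regime. An independent EM oracle
confirms the proportion MLE is sharp under those conditions.

A further caveat applies when the sub-structures are themselves estimated
from the intra-region blocks: their orientation relative to each other is
arbitrary (rotation and reflection are gauge within each sub-fit), so the
required arrangement falls between grid points, and the residual *shape*
error of the estimates imposes a cross-block likelihood tax that grows
linearly with depth. At deep coverage this tax exceeds the consensus
model's misfit, and AIC then prefers the consensus model even on true
mixtures. Grid refinement beyond 8 bins per angle does not remove the
effect (quantization is no longer the binding error source). The model
selection studies therefore supply the generating sub-structures,
isolating the consensus-versus-mixture comparison; this is a real
limitation of two-stage arrangement inference worth knowing about before
interpreting AIC comparisons on data.

## Geometry statistics

**HD ratio** (`hd_ratio()`): the structure is centred and rotated to its
principal axes; the cylinder height is the 90%–10% quantile spread of the
first-axis coordinates and the radius is twice the median radial distance
in the PC2–PC3 plane. The raw ratio height/diameter is normalized by
$N / n_{\mathrm{ref}}$ with $n_{\mathrm{ref}} = 25$ loci (≈ 1 MB at
40 KB), so regions of different genomic extent are comparable; the
normalization constant is a package convention exposed as an argument.
For a dense uniform helix of height $h$ and radius $r$ the raw ratio is
$0.8h/4r$, which the tests verify analytically.

**Normalized RMSD** (`optimal_superposition()`): the scale between two
structures is estimated by regressing the pairwise distances of one on
the other through the origin (distances are non-negative and proportional
under global scaling, so no intercept); both structures are centred and
brought to unit radius of gyration — a symmetric normalization, making
the RMSD exactly symmetric in its arguments and dimensionless — and the
optimal proper rotation comes from the SVD of the cross-covariance with
reflection correction. Values below 0.1 indicate high similarity,
0.1–0.2 moderate, above 0.2 low. The unit-gyration normalization is a
package convention chosen to make the statistic agree with that
interpretive scale while being exactly symmetric; reflections are
deliberately *not* absorbed by the alignment (they carry signal for the
mixture model) except where both arguments are independent fits, where
`rmsd_up_to_mirror()` quotients out the unidentified handedness.

**Plane separation** (`plane_separation_test()`): the plane through the
mid-group points is the total-least-squares fit (normal along their
smallest principal component); low/high points are classified by side and
the 2×2 table is tested with Fisher's exact test. The odds ratio is the
sample odds ratio, Haldane-corrected (0.5 added to each cell) when the
table contains a zero.

## The two-step dominance test

`two_step_procedure()` asks whether a population has one dominant
structure: fit the consensus model (mode $s_1$), subtract half of the
expected matrix implied by $s_1$ from the counts — clamped at zero and
rounded, so the residual is again a valid count matrix — refit (mode
$s_2$), and compare $s_1$ with $s_2$ by chirality-blind normalized RMSD.
The null reference is the empirical RMSD distribution between pairs of
independent free ideal chains (uniform step directions, unit steps) of
the same length, 1,000 pairs by default; dominance is called when the
observed RMSD falls in the lower 5% tail. The chirality quotient is
essential here: the two fits' handednesses are independent coin flips, so
without it half of all genuinely dominant cases would be missed.

### Operating characteristics, measured

The statistic is fundamentally a measure of refit *reproducibility*. On
single-population simulations at deep coverage it behaves as intended
(dominance called in essentially every replicate at $N = 20$ units). On
an equal mixture of two *independent* random-walk populations, however,
the Poisson embedding finds a stable "compromise" structure — the best
embeddable approximation of the averaged rate matrix — and the
residual-matrix refit finds it again, so dominance is frequently
over-called (about 60% of replicates at a mean of 60 reads per unit
pair, even though the generating pairs themselves sit far into the
null's bulk). Shallower data reverse the failure: both arms' RMSDs drift
up to the null's 5% quantile and the single-population arm loses its
calls instead. Across depths of 20–60 reads per pair, 2–10 chains,
SIS-only versus diversified initializations and $N$ of 20–40 units we
found no regime in which both arms behave as the idealized description
suggests; more sampling effort sharpens *both* arms. The corresponding
acceptance check asserts both arms and the mixture arm fails; it is left
failing deliberately, as an accurate statement of the procedure's
behaviour at this scale. Users should read a *dominant* call as "the fit
is reproducible after residual subtraction", which is necessary but not
sufficient evidence for a dominant population structure.

## The synthetic-data generator

`simulate_single_population()` and `simulate_mixture_population()` draw
backbones (free ideal chain by default; helix and straight-line backbones
are available for analytic ground truth), covariates with marginals
resembling real 40 KB bins (fragment ends ~ lognormal around 30, GC in
(0.32, 0.64), mappability in (0.82, 1] — all clearing the default filters
by construction), and independent Poisson counts per unordered pair.
Depth is controlled by a single knob: `target_mean` sets $\beta_0$ so the
mean off-diagonal rate hits the target. The default study depth of 60
expected reads per intra-domain pair reflects very deep mammalian Hi-C
(a 40 KB-resolution experiment with hundreds of millions of cis reads);
at this depth an $N = 25$ fit takes well under a minute at default
sampler settings. Every generator is a pure function of its seed.

What the generator does *not* emulate: ligation artifacts, copy-number
variation, unmappable bins inside otherwise usable regions,
domain-boundary insulation patterns, or distance-dependent noise beyond
Poisson. Passing recovery tests on these simulations therefore
demonstrates correctness of the inference machinery under the model's own
assumptions, not robustness to the full messiness of real Hi-C.

## Problem sizes and runtime choices

The test-suite and acceptance studies use $N = 20$–26 loci, 2 chains of
400–2,000 iterations for unit-level checks and the default 3×5,000 for
the headline recovery run, 10–20 replicates for the selection and
dominance studies, and 500 draws for the RMSD null. These sizes were
chosen so the entire stack (including forty full model fits in the AIC
study) completes on a single CPU in well under half an hour.

## Known limitations

* Global scale, rigid motion and handedness are gauge; any downstream use
  of absolute coordinates must pick its own gauge.
* Flat priors make the posterior improper along the gauge directions;
  summaries are gauge-fixed, but very long chains will drift along them.
* Shallow data (mean ≲ 15 reads/pair at $N = 25$) yields visibly
  shrunken long-range distances and under-covering intervals (see above).
* Arrangement proportions are identifiable only for geometrically
  distinguishable candidate sets, and AIC comparisons with *estimated*
  sub-structures are biased toward the consensus model at high depth.
* The two-step dominance call is a reproducibility statistic: it reliably
  confirms dominant structures but over-calls dominance on genuine
  mixtures whose averaged contact pattern admits a stable embedding (see
  the measured operating characteristics above).
* No informative biophysical priors on distances; no joint multi-region
  or whole-genome modelling; at most two sub-regions per mixture.
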