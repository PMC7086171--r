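---
title: "Modelling effective migration surfaces with migsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effective migration surfaces with migsurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsurf)
```

## The problem

In many species, including humans, genetic differentiation grows with
geographic distance ("isolation by distance"), but rarely at a uniform
rate: seas, deserts and mountain ranges slow the effective exchange of
migrants, while historical expansion corridors accelerate it.  `migsurf`
estimates a spatial picture of this heterogeneity: an **effective
migration surface** m and an **effective diversity surface** q defined
over a triangular grid of demes covering the study region.  Both are
visualization constructs, not literal migration counts: areas of high
effective migration are areas where populations are more similar than
their geographic distance alone would predict.

## The model

### Spatial substrate

The region is discretised into a triangular grid (`deme_grid()`): a
regular planar lattice, or an icosahedral geodesic subdivision of the
sphere whose mean edge length is closest to the requested spacing.
Each sampled individual is assigned to its nearest deme
(`assign_demes()`).  After clipping the grid to the region, only the
largest connected component is kept, because resistance distances are
infinite between disconnected fragments.

### Rate surfaces

Each surface is piecewise constant on a Voronoi tessellation with a
random number of tiles (`rate_tess()`).  Tile `j` carries a log10 rate
effect `e_j`; a vertex takes the effect of its nearest tile seed.  The
migration surface has a fixed mean level of 0 — migration rates are
*relative*, and the overall scale is identified jointly through the tile
effects and the likelihood scale sigma^2.  The diversity surface carries
a free mean level `mu_q`, since q is measured in the units of the
observed dissimilarities.

### From rates to expected dissimilarities

Edge conductances are geometric means of the endpoint rates on the
natural scale, `10^((log10_m_u + log10_m_v)/2)` (`rates_on_edges()`).
The expected genetic separation between demes is the **resistance
distance** R of the weighted graph (`resistance_distances()`), computed
through the pseudo-inverse of the weighted Laplacian.  The expected
dissimilarity between individuals from demes a and b is

    Delta(a, b) = (q_a + q_b) / 2 + R(a, b) / 4,     a != b
    Delta(a, a) = q_a

(`expected_dissimilarity()`).  The commute-time constant 1/4 and the
additive within-deme term are fixed conventions of this package's model:
the likelihood scale sigma^2 absorbs overall units but deliberately not
the balance between the q and R contributions, so these constants are
part of the model definition.  They are validated behaviourally — by
parameter recovery on synthetic data — rather than against any external
implementation.

### Likelihood

Let D be the observed matrix of average squared genotype differences
between the n individuals (`observed_dissimilarity()`), computed from p
loci.  With the fixed contrast basis C whose rows are `e_1 - e_{i+1}`,
the projected scatter matrix `S = -1/2 C D C' p` is modelled as Wishart
with p degrees of freedom and scale `Sigma = sigma2 * (-1/2 C Delta* C')`,
where `Delta*` expands the deme-level Delta to individuals (zero
diagonal; same-deme pairs get the deme's q).  The projection removes the
location ambiguity of dissimilarity data; the basis affects the
log-density only through an additive constant that cancels in every MCMC
ratio and Bayes-factor difference, so fixing it keeps logged likelihoods
reproducible.  For q > 0 the implied scale matrix is positive definite
(the q part contributes `1/2 C diag(q) C'`, positive definite because
`C 1 = 0` annihilates the rank-one remainder, and the resistance part is
negative type); non-positive-definite proposals are still flagged with a
log-likelihood of `-Inf` as a numerical safeguard.

### Priors

* tile counts `K_m`, `K_q`: zero-truncated Poisson with mean parameter
  lambda = 10 — a weak preference for around ten tiles per surface;
* tile effects: Normal(0, omega^2) truncated to +/-2 log10 units (a
  10^4-fold dynamic range across a surface);
* omega^2 ~ Uniform(0, 1) per surface;
* `mu_q` ~ Uniform(-6, 6);
* sigma^2 ~ Inverse-Gamma(1, 1);
* tile seeds uniform over the padded bounding box of the grid.

These defaults are this package's own choices; they matter little when p
is large (thousands of loci) because the likelihood is then very sharp,
and they are exercised directly by the prior-recovery tests, which run
the sampler with the likelihood switched off and compare the sampled
tile counts, effects and sigma^2 against the priors.

## The sampler

`migsurf()` runs a reversible-jump Metropolis-Hastings sampler
(`mcmc_step()`) with seven move types: tile-effect update, tile-seed
move, tile birth, tile death, sigma^2 update, omega^2 update, and `mu_q`
update; surface-specific moves pick the migration or diversity surface
uniformly.  Births draw the new seed uniformly over the region and the
new effect from its prior, so the acceptance ratio reduces to the
likelihood ratio times the prior tile-count ratio `lambda / (K + 1)`
(deaths are the exact reverse with ratio `K / lambda`); birth and death
are proposed with equal probability, which the control constructor
enforces.  sigma^2 is conjugate given everything else (the tempered
posterior is Inverse-Gamma), so it is updated by a Gibbs draw.

Proposal scales are effect steps of 0.1 log10 units, seed moves of one
grid spacing, and `mu_q`/omega^2 steps of 0.1; these give acceptance
rates in a workable range across the problem sizes in the test suite and
are configurable in `migsurf_control()`.  Following standard practice
the fit starts with short pilot chains and continues the end state with
the highest posterior log-density.  Initialisation uses a coarse grid
search for the single-tile migration level jointly with a
moment-matched sigma^2 — without it, chains started at arbitrary scale
spend a long time finding the right overall conductance level, which is
only weakly identified through the q-versus-R balance.

Posterior draws are thinned states; each records the per-vertex log10
rates, from which rasters are built on a fixed lattice (default 100x100
cells over the padded bounding box; each cell takes the value of its
nearest vertex, i.e. the grid's Voronoi cells sampled on a lattice).

### Troughs and corridors

`detect_troughs()` realises the consensus rule cellwise: for each raster
cell, `f_low` is the fraction of draws in which the cell lies below that
draw's across-cell mean; cells with `f_low >= 0.95` are troughs and
cells with `1 - f_low >= 0.95` corridors, and connected components of
flagged cells are reported as features.  Normalising per draw by the
across-cell mean makes the rule invariant to the joint scale drift of
the migration level and sigma^2.

### Bayes factors

`log_bayes_factor()` compares the full model against the
uniform-migration null (migration surface constrained to a single tile,
diversity tessellation free).  Marginal likelihoods are estimated by
power posteriors with a temperature ladder `t_k = (k/(K-1))^5` and
trapezoidal thermodynamic integration; the exponent concentrates rungs
near t = 0 where the integrand changes fastest, and each rung continues
from the previous rung's end state.  Power posteriors were preferred
over harmonic-mean style estimators for stability at desk scale.  The
estimator's Monte-Carlo error is reported from lag-1
autocorrelation-corrected rung variances; in practice the spread between
independent ladder runs can exceed this rough estimate, so the
calibration checks use ladders of 24 rungs with 2500-3000 iterations per
rung, at which point independent repetitions of the same comparison
agree to within a couple of log units.

## The synthetic-data generator

`simulate_wf_genotypes()` produces data with the statistical structure
the model assumes, so that every stage is testable without external
data.  It is a forward Wright-Fisher stepping-stone simulation: per
generation, deme allele frequencies mix deterministically along the
edges (per-edge fraction `m_base * 10^((log10_m_u + log10_m_v)/2)`,
matching the model's edge-conductance convention), then drift by
binomial resampling of `2 * deme_size` chromosomes.  Migration acts
before drift — the standard ordering — and a configurable cap on the
per-deme emigration fraction guards against ill-posed migration
matrices.  There is no mutation; frequencies start at Uniform(0.1, 0.9)
per locus, making loci exchangeable replicates.  Genotypes are
Binomial(2, f) draws, and coordinates get Gaussian jitter with sd equal
to 1% of the grid spacing — enough that deme assignment is exercised,
small enough to stay unambiguous.

Default conditions — 100 diploids per deme, 300 generations, base
migration fraction 0.01 per edge — give a realistic regime: local FST
between neighbouring demes of a few percent, smoothly accumulating
differentiation across the grid, and clear but not trivial barrier
signals at depth -1 (a ten-fold migration reduction).  `rate_field()`
plants rectangular barrier or corridor strips with recorded vertex
annotations, and `simulate_model_exact()` inverts the fitted likelihood
directly (a Wishart draw back-transformed through the contrast basis)
for model-exact checks.

What the generator does *not* emulate: linkage disequilibrium between
loci (loci are independent), mutation, selection, ascertainment bias,
long-range admixture events, and non-equilibrium history.  Passing
recovery tests on these data therefore show that the estimator works
when its assumptions hold approximately — they do not certify behaviour
on real panels, where those complications are the norm.

## Panel preparation

`filter_variants()` applies the conventional merge-and-clean rules in a
fixed order: drop non-autosomal and non-SNP records, strand-ambiguous
A/T and G/C pairs, duplicate ids (first copy kept) and SNPs whose allele
pairs conflict between sources; then a one-sided exact Hardy-Weinberg
test; then per-SNP and per-individual missingness thresholds (defaults
1% and 5%).  The HWE test is directional toward *heterozygote excess*:
unresolved strand flips in merged panels inflate heterozygosity, whereas
a heterozygote deficit is the expected signature of population structure
(the Wahlund effect) and must not be filtered.  The exact test uses the
Levene-Haldane conditional distribution, with a mid-P variant available.

`relatedness_prune()` uses the standardized genotype cross-product
(GRM-style) relatedness with greedy removal above the cutoff (default
0.6), dropping the member of each offending pair with more missing data.
`loading_outlier_prune()` removes windows (default +/-100 kb, i.e. a
200 kb window total — the convention adopted here; it is configurable)
around SNPs whose PC loadings, standardised by the per-PC loading
standard deviation, exceed 5 on any of the first 10 components — the
signature of structural variants and long-range LD regions that would
otherwise dominate a component.  `downsample_locales()` caps locales
(identical rounded coordinates) at 50 individuals.

## Evaluation tools

* `pca_decompose()`: genotype PCA with per-SNP mean imputation and
  centring, no variance scaling by default, and a deterministic sign
  convention.
* `expected_distance_from_pcs()`: squared Euclidean distances between
  coordinatewise population medians of the leading k scores (k = 2, 10,
  100 are the conventional comparison points).
* `expected_distance_from_posterior()` / `predict()`: the model's
  posterior expected population distance matrix, averaging each draw's
  sigma2-scaled Delta.
* `fit_correlation()`: Pearson correlation over upper-triangle pairs
  (pairs unweighted).
* `fst_empirical()`: Weir-Cockerham 1984 ratio-of-sums FST.
* `fst_stepping_stone()`: the equilibrium approximation
  `1/(1 + 4 M kappa)`.  kappa is a geometry constant: 1 is the
  many-deme island approximation, and for a finite d-deme island model
  the pairwise between-deme FST definition (which Weir-Cockerham
  estimates) gives `kappa = d/(d-1)`, the value used in the simulation
  checks.
* `partial_mantel()`: partial correlation of genetic distance and a
  same/different language-group indicator controlling geographic
  distance, with joint row/column permutations of the genetic matrix
  and a one-sided upper P-value.  Mantel-type tests are liberal under
  strong spatial autocorrelation; results warrant caution.

## Numerical choices and degenerate inputs

* Resistance distances come from one linear solve of `L + 11'/n` (the
  rank-one shift of the Laplacian); tiny negative values from rounding
  are clipped to zero.  Disconnected graphs are an error.
* The Wishart log-density uses Cholesky factorisations and the
  log-multivariate-gamma function; a failed factorisation of the scale
  matrix yields `-Inf` with an `npd` attribute instead of an error, so
  the sampler simply rejects such proposals.
* Ties in nearest-seed and nearest-deme assignments go to the lowest
  index, making surfaces and assignments reproducible.
* Posterior standard deviations use the sample convention (denominator
  n - 1).
* All randomness flows through R's RNG via a single integer seed;
  chains, simulations and permutation tests are byte-reproducible.

## Design decisions on genuinely open points

* The diversity surface is tessellated independently of the migration
  surface (granularities need not match).
* The migration mean level is fixed at 0 and sigma^2 carries the scale;
  the trough rule's per-draw normalisation makes the reported features
  invariant to this convention.
* Filter order is fixed as listed so that report counts are exactly
  reproducible; the report reconciles with the matrix shapes by
  construction.
* Multi-study allele conflicts are represented by the
  `allele_mismatch` rule on a source-tagged union; actual dataset
  merging is out of scope.

## Problem sizes used by the test suite

The shipped tests run at deliberately modest scales: barrier recovery
uses a 10x5 planar grid (about 50 demes), 4 sampled individuals per
deme and 5000 loci with a 100,000-iteration chain; Bayes-factor
calibration uses a 5x3 grid, 2000 loci and ten replicate seeds per
condition; prior recovery uses 200,000 likelihood-free iterations.
Production analyses would use longer chains (the control accepts the
multi-million-iteration schedules typical of published fits) and finer
grids; the contracts being tested are scale-free.

## Limitations

The model is an equilibrium, time-stationary summary: it cannot
represent populations that overlap spatially while staying
differentiated, long-range admixture, or structure that changed through
time.  Surfaces are identified only relatively, and the positioning of
features in sparsely sampled areas is imprecise.  The Bayes-factor
estimator carries Monte-Carlo error of a few log units at desk scale;
values near zero should not be over-interpreted.
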