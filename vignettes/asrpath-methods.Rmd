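---
title: "Methods: phylogenetic comparative analysis of adult sex ratio and breeding systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of adult sex ratio and breeding systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The adult sex ratio (ASR; the proportion of males among adults) varies
widely across bird species and is entangled with their breeding systems:
mating-system skew, sexual dimorphism, and which sex cares for offspring.
Two causal readings of this entanglement compete. Under the first
(**H1**), demographic asymmetries between the sexes — sex-biased juvenile
and adult mortality and sex-biased age at maturation — shift the ASR,
and the ASR in turn shapes pre-copulatory competition, post-copulatory
competition, and parental care. Under the second (**H2**), the costs of
competition and care fall unevenly on the sexes, driving the demographic
biases, which then produce the ASR. `asrpath` implements the full
comparative pipeline needed to confront these two causal structures with
cross-species data on a phylogeny, and a synthetic-data generator with
known causal ground truth to validate every stage.

# Trait constructions

Demographic biases are log ratios, `log(female/male)`, of juvenile
mortality, adult mortality and age at maturation: zero at parity,
positive when the female value is larger. Sexual size dimorphism keeps
the conventional opposite orientation, `log(male mass/female mass)`.
Plumage dimorphism is the first principal component (correlation matrix,
varimax rotation when more than one component is retained) of five
body-region scores in −2..2; female care is PC1 of brooding and chick
attendance (feeding for altricial-like modes, defence for precocial
species), both oriented so that higher means "more" of the named pole.
Mating-system bias is the male minus female polygamy score (0–4 scales);
the orientation is configurable because published descriptions of this
difference vary, and the sign convention matters only jointly with the
interpretation of regression coefficients. Residual testes mass is the
OLS residual of log10 testes mass on log10 male mass.

Composite indices (demography, pre-copulatory, post-copulatory bias) are
means of z-scored components, with the z-scores computed over the species
entering the specific analysis — sample sizes differ per model, and
standardising over the global table would leak information across
analyses. By default a species needs all components of a composite
(listwise per composite); averaging the available components (at least
two) is available as an option. Where both fledging and hatching sex
ratios exist, fledging is preferred and the source recorded, since
fledging ratios already absorb sex-specific nestling mortality.

# Phylogenetic machinery

All phylogenetic computations run through the Brownian covariance matrix
`C` of a rooted tree (shared root-to-tip path lengths) and Pagel's λ,
which multiplies the off-diagonal of `C` and measures the strength of
phylogenetic signal. λ is estimated by maximising the profile Gaussian
likelihood on [0, 1] with a bounded scalar optimiser (tolerance 1e-6);
boundary maxima are reported as estimates, not errors. For ultrametric
trees the λ-likelihood is evaluated in the eigenbasis of `C` (the
transformed covariance shares C's eigenvectors), which makes each
evaluation linear in the number of species after a single
decomposition; non-ultrametric trees fall back to dense Cholesky
factorisations. The two paths agree to numerical precision and are
cross-checked against a dense grid search in the test suite.

The **unit tree** for a trait rescales internal shared paths by
λ̂/depth and extends terminal branches so every tip sits at depth 1:
its Brownian covariance equals the λ-transform of the original
covariance normalised to unit tip variance. The construction presumes an
ultrametric tree; non-ultrametric inputs are first made ultrametric by
extending terminal branches (with a warning), a pragmatic choice for
perturbed or posterior trees whose branch jitter breaks exact ultrametry.
Felsenstein's independent contrasts are computed on these unit trees
(via `ape::pic`, after deterministic resolution of polytomies into
zero-length branches with tips ordered by label).

# Regression: GLS and the Gibbs animal model

`pgls_fit()` fits `y = Xβ + e`, `e ~ N(0, σ²V(λ))` by full ML (so that
log-likelihoods and AICc are comparable across fixed-effect structures),
with λ either fixed or profiled. `mcmc_phylo_lmm()` fits the Gaussian
animal model `y = Xβ + u + e`, `u ~ N(0, σ²ₐC)`, by blocked Gibbs
sampling in the eigenbasis of the unit-depth `C`, where the phylogenetic
effect's prior is diagonal and one sweep costs O(n). The phylogenetic
variance uses the parameter-expanded working-parameter scheme
(α ~ N(0, 10⁴), scale ~ inverse-gamma with ν = 1, V = 1), which induces
a heavy-tailed, weakly informative marginal prior; the residual variance
prior is inverse-Wishart with V = 1 and ν = 0.002; fixed effects get
diffuse Gaussians. Default chain settings are 75,000 iterations, 7500
burn-in, thinning 40 (1687 retained draws). Reported: posterior means,
central 95% quantile intervals (HPD via a flag), two-sided MCMC p-values
`2·min(Pr(β>0), Pr(β<0))` floored at 2/n_samples, AR-spectral effective
sample sizes, and `lambda_equivalent = σ²ₐ/(σ²ₐ+σ²ₑ)`, the
mixed-model analogue of λ on a unit-depth tree. Proportions such as ASR
are modelled on the raw scale with Gaussian errors, as is usual for
these comparative mixed models.

Repeatability of replicated population measurements is the intraclass
correlation from a REML random-intercept model
(`value ~ 1 + (1|species)`, via lme4), with a parametric-bootstrap
confidence interval (simulate from the fitted model, refit, recompute).

# Imputation

Missing traits are imputed under a multivariate phylogenetic Gaussian
model: stacking the species × trait matrix trait-wise,
`z ~ N(μ ⊗ 1, R_phylo ⊗ C + R_resid ⊗ I)` with `C` at unit depth. The
two among-trait covariance matrices split each trait's variance into a
phylogenetic and an independent part, so each trait has an implied
signal `λ_j = Rp[j,j]/(Rp[j,j]+Re[j,j])`; in the single-trait case the
model is exactly the λ-transform model, which the tests exploit as a
reduction check. Parameters are estimated by ML (log-Cholesky
parameterisation, L-BFGS-B), marginalising the likelihood to the
observed cells; missing cells are filled with their conditional Gaussian
expectations given all observed cells, with predictive SDs from the
conditional variance. The point-estimate completion is the default
(downstream analyses consume point values); stochastic draws can be
taken from the same conditional distribution.

Leave-one-out cross-validation masks each observed cell of a target
trait and correlates held-out with imputed values. The default reuses
the full-data parameter estimates for every mask — fast, but it leaks a
modest optimistic bias through the fitted cross-covariances (visible as
a positive null correlation in small samples). `refit = TRUE`
re-estimates the parameters for every deletion (warm-started from the
full-data fit) and is leak-free; the null-calibration test uses it. The
low-reliability regime reported for near-constant traits (birth sex
ratios cluster tightly around parity, with cross-species variance an
order of magnitude below ASR's) is reproduced in kind by the tests:
traits with tiny cross-species variance cross-validate materially worse
than high-variance traits on the same table, which is why such imputed
traits should be flagged rather than consumed downstream.

# Path analysis and d-separation

Candidate causal structures are DAGs over the composite indices, ASR
and care. The H1 family has `demography → ASR` and ASR driving the
breeding-system traits: variant 1a with no edges among the breeding
traits, 1b with `ASR → precop → care`, 1c with `ASR → care → precop`.
The H2 family mirrors the mediation (breeding traits → demography →
ASR; no edges out of ASR): 2a direct, 2b `precop → care → demography`,
2c `care → precop → demography`. Only the two orderings among breeding
traits named above are published for the mediated variants; the mirrored
constructions here are this package's reconstruction, and user-supplied
DAG edge-list files can replace any of them.

Each DAG's **basis set** contains one conditional-independence claim per
non-adjacent pair, conditioning on the union of the parents of both
nodes; the claim's regression direction is fixed by topological order
(later node regressed on earlier), with deterministic ordering for
reproducibility. The basis set is verified in the tests against an
exhaustive path-blocking d-separation oracle over all DAGs on 3–4 nodes
and a sample of 5-node DAGs. Claims are tested under two frameworks:

* **transform** — every variable is replaced by its contrasts on its own
  λ̂ unit tree; the claim is a regression through the origin of the
  response contrasts on the claim variable's and conditioning set's
  contrasts, with a two-sided t-test on the claim coefficient;
* **residual** — an ML-λ PGLS of the same regression, λ re-estimated in
  each equation's error structure (so λ differs per response).

Claim p-values combine into Fisher's `C = −2Σ ln p`, chi-square with 2k
df under the model. Models are ranked by
`CICc = C + 2qn/(n−1−q)` with `q` = edges + nodes (a constant node
offset cancels in Δ over a fixed node set); `n` is the number of
contrasts in the transform framework and of species in the residual
framework. "Support" requires ΔCICc < 2 and a d-separation p > 0.05.
Saturated models (empty basis set) get C = 0, p = 1 and compete on the
information criterion alone.

In the transform framework each candidate is additionally fitted as a
recursive path model on the contrasts (equation-wise OLS through the
origin, since contrasts have zero expectation; second moments about
zero), with the implied covariance `Σ = (I−B)⁻¹Ψ(I−B)⁻ᵀ`, the ML
discrepancy `F = ln|Σ| − ln|S| + tr(SΣ⁻¹) − p`, `χ² = (n−1)F`, and the
standard indices: TLI and CFI against the independence baseline, RMSEA
`√(max(χ²−df,0)/(df(n−1)))`, SRMR on correlation-scale residuals, and an
AICc built from `χ² + 2q` with the small-sample correction. Because the
d-separation AICc and the SEM AICc answer subtly different questions,
both are emitted (`cicc` and `aicc_sem`). Phylogenetic uncertainty is
handled by replicating the selection across a set of (posterior) trees
and reporting per-model support and top-rank frequencies.

# The synthetic generator

`simulate_tree()` draws pure-birth (Yule) trees rescaled to unit depth.
`simulate_sem_traits()` generates traits in topological order of a
coefficient-bearing DAG, each node the weighted sum of its parents plus
a residual drawn from the λ-transformed Brownian covariance (trait-wise
λ and SD). `simulate_species_records()` inverts the trait
constructions: mortality, maturation and mass pairs carry exactly the
latent log-ratio biases (so the constructions round-trip bit-exactly),
while integer scores (plumage, polygamy, care) discretise noisy copies
of the latent values into equal-probability bins — recoverable to within
a bin, which is what the tests assert. ASR is emitted as a proportion
centred at 0.543 with spread 0.09, the observed cross-species location
and scale for birds; proportions are clipped to their ranges.
`simulate_populations()` draws 2–7 population replicates per species
with the within-species variance set from the target ICC;
`inject_missingness()` masks an exact per-column count of cells,
completely at random, seed-deterministically.

Defaults encode the study conditions exercised end-to-end in the tests
and acceptance script: the H1a structure with all path coefficients 0.5,
λ = 0.7 for every trait, unit residual SDs, ICC target 0.63 with 65
species and 2–7 populations (the repeatability design), and 34% MCAR
missingness on the post-copulatory traits (matching raw-data coverage of
roughly two-thirds for testes mass and under half for extra-pair
paternity). What the generator does *not* emulate: non-Gaussian trait
distributions, measurement error correlated with phylogeny,
non-random (MNAR) missingness, and tree mis-specification beyond
branch-length jitter — so passing recovery tests demonstrate internal
consistency of the machinery, not robustness to those real-data
pathologies.

# Numerical choices and problem sizes

* λ optimisation: `optimize()` on [0, 1], tolerance 1e-6, with explicit
  endpoint comparison (profile likelihoods can be boundary-maximal).
* Eigenvalues of `C` are floored at 1e-10 in the Gibbs sampler; tiny
  ridge terms (1e-10) stabilise Cholesky factorisations of
  observed-cell covariances in the imputation module.
* Zero p-values in Fisher's C are clamped to the smallest positive
  double with a warning; pMCMC is floored at 2/n_samples.
* Degenerate inputs error early with specific messages: constant traits
  (flat λ likelihood), collinear designs (named columns), all-singleton
  groups (undefined within-variance), zero-variance composite
  components (named).
* Tests and the acceptance script use desk-scale problem sizes chosen to
  keep the full suite near two minutes: 500 replicates at 100 tips for
  the d-separation calibration, 100 replicates for model recovery and
  PGLS recovery (n = 200), 50 replicates of the 65-species repeatability
  design, shortened 15k-iteration chains for most MCMC checks with the
  full 75,000-iteration configuration run once.

# Known limitations

Only Pagel's λ among branch-length transforms; Gaussian traits only
(proportions on the raw scale); no latent variables, correlated errors
or cyclic structures in the path models; imputation assumes an
ultrametric-compatible Brownian model and one-hot-coded categorical
covariates are treated as Gaussian. The default LOOCV policy is
optimistically biased in small samples (see above). The mediated H2
variants are reconstructions of unpublished diagrams and should be
replaced by explicit DAG files where the intended structures are known.
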