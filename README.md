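# asrpath

Phylogenetic comparative analysis of adult sex ratio (ASR) variation and
its causal links to demography and breeding systems in birds (or any
clade with comparable trait data).

Species differ enormously in the proportion of males among adults, and
that ratio is bound up with who competes for mates and who cares for
offspring. Two causal structures can generate the same correlations:

* **H1** — sex-biased demography (juvenile/adult mortality, age at
  maturation) sets the ASR, and the ASR then shapes pre-copulatory
  competition, post-copulatory competition and parental care;
* **H2** — the mortality costs of competition and care generate the
  demographic biases, which then produce the ASR.

`asrpath` implements the full pipeline to confront these hypotheses with
cross-species data on a phylogeny:

* **Trait constructions** — log-ratio sex biases `log(female/male)` for
  mortality and maturation, sexual size dimorphism `log(male/female)`,
  plumage and parental-care principal components (varimax), residual
  testes mass, and composite indices as means of z-scored components.
* **Phylogenetic regression, two ways** — ML generalized least squares
  with Pagel's λ profiled in the residual covariance
  `V(λ) = λ·C + (1−λ)·diag(C)`, and a Gibbs-sampled Gaussian animal
  model with parameter-expanded variance priors (default chains: 75,000
  iterations, 7500 burn-in, thin 40), plus VIFs and repeatability (ICC)
  with parametric-bootstrap intervals.
* **Phylogenetic imputation** — multivariate Brownian model with
  trait-specific λ (`z ~ N(μ⊗1, R_phylo⊗C + R_resid⊗I)`), conditional
  Gaussian imputation and leave-one-out cross-validation.
* **Confirmatory path analysis** — candidate DAG sets, Shipley
  d-separation basis sets, claim tests under a trait-transformation
  framework (per-variable λ unit trees + independent contrasts) and a
  residual framework (λ per regression), Fisher's
  `C = −2Σ ln pᵢ`, CICc/AICc ranking, SEM fit indices (TLI, CFI, RMSEA,
  SRMR), and replication over posterior trees.
* **A synthetic-data generator** with known causal ground truth (Yule
  trees, SEM traits with λ-Brownian residuals, invertible raw species
  records, replicated populations at a target ICC, MCAR missingness)
  used throughout the tests.

## Worked example

Simulate a 100-species system under H1a (all path coefficients 0.5,
λ = 0.7), rebuild the derived variables from the raw records, regress
ASR on the demography composite, and rank the six candidate causal
models:

```r
library(asrpath)

spec    <- simulation_spec(n_species = 100, seed = 42)
tree    <- simulate_tree(spec)
records <- simulate_species_records(tree, spec)
derived <- build_derived_table(records)

d <- derived[, c("species", "asr", "demography_bias", "precop_bias", "postcop_bias")]
d$care_bias <- derived$care_pc1

y <- setNames(d$asr, d$species)
X <- matrix(d$demography_bias, ncol = 1,
            dimnames = list(d$species, "demography_bias"))
pgls_fit(y, X, tree)
#> Phylogenetic GLS (lambda ml = 0.571), n = 100, logLik = 155.981, AICc = -303.542
#>                       beta          se         t            p
#> (Intercept)     0.55241770 0.019501942 28.326291 5.406969e-49
#> demography_bias 0.05394012 0.007286159  7.403094 4.652106e-11

ranked <- select_models(candidate_models(TRUE), d, tree, framework = "transform")
ranked[, c("model", "C", "df", "p", "cicc", "cfi", "rmsea", "delta", "supported")]
#>   model    C df        p  cicc   cfi  rmsea delta supported
#> 1    1a 11.0 12 5.30e-01  31.0 0.996 0.0299   0.0      TRUE
#> 2    1b 29.3 12 3.57e-03  49.3 0.881 0.1602  18.3     FALSE
#> 3    1c 43.6 12 1.76e-05  63.7 0.775 0.2206  32.6     FALSE
#> 4    2c 75.3 12 3.28e-11  95.3 0.526 0.3204  64.3     FALSE
#> 5    2b 82.7 12 1.26e-12 102.7 0.477 0.3366  71.7     FALSE
#> 6    2a 88.9 12 8.17e-14 108.9 0.476 0.3368  77.9     FALSE
```

The ASR–demography slope is positive and strongly supported (female
excess in mortality or maturation time shifts the adult population male),
and the generating model 1a is the only candidate that survives the
d-separation test (Fisher's C p = 0.53) and carries all the ΔCICc
support, with clean SEM fit (CFI ≈ 1, RMSEA 0.03). All H2 mirrors are
decisively rejected.

## The analysis workflow

The `analysis/` scripts run the whole study end-to-end on the synthetic
system (261 species, 65 with 2–7 replicate populations, 100
perturbed-branch-length trees), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # trees, raw records, populations, ground truth
Rscript analysis/02_constructs.R      # derived variables and composites
Rscript analysis/03_repeatability.R   # ASR repeatability (ICC + bootstrap CI)
Rscript analysis/04_regressions.R     # PGLS + animal-model regressions, VIF
Rscript analysis/05_imputation.R      # phylogenetic imputation + LOOCV
Rscript analysis/06_path_analysis.R   # both frameworks, 100-tree replication
```

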