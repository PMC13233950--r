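Package: asrpath
Title: Phylogenetic Path Analysis of Adult Sex Ratio and Breeding Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative pipeline linking demographic sex biases, adult sex
    ratio (ASR) and breeding-system traits across species on a phylogeny.
    Builds log-ratio sex-bias variables and composite indices, fits
    phylogenetic regressions by maximum-likelihood generalised least squares
    with Pagel's lambda and by an MCMC Gaussian animal model, imputes missing
    traits under a multivariate phylogenetic Brownian model with
    leave-one-out cross-validation, estimates repeatability of replicated
    population measurements, and performs confirmatory phylogenetic path
    analysis with d-separation tests (Fisher's C), CICc/AICc model ranking,
    structural-equation fit indices and replication over posterior trees.
    Includes a synthetic-data generator with known causal structure for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
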