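#!/usr/bin/env Rscript
## Generate the synthetic study system: a 261-species pure-birth phylogeny,
## raw sex-specific species records whose latent causal structure follows
## the demography -> ASR -> breeding-system hypothesis (H1a, path
## coefficients 0.5, per-trait phylogenetic signal lambda = 0.7), replicated
## ASR measurements for a 65-species subset (2-7 populations each, ICC
## 0.63), and 100 branch-length-perturbed trees standing in for a posterior
## sample. Everything downstream reads these files.

suppressMessages(library(asrpath))

seed <- 20260921L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- simulation_spec(n_species = 261, lambdas = 0.7, icc_target = 0.63,
                        missing_fraction = 0.34, seed = seed)
tree <- simulate_tree(spec)
records <- simulate_species_records(tree, spec)
records <- inject_missingness(records, spec, columns = c("testes_mass", "epp"))

write_newick(tree, file.path(out, "tree.nwk"))
write_trait_table(records, file.path(out, "species_records.tsv"))

## replicated ASR measurements for a subset, the repeatability design
set.seed(seed + 1L)
sub <- sort(sample(records$species, 65))
asr_means <- setNames(records$asr[match(sub, records$species)], sub)
pops <- simulate_populations(asr_means, spec)
write_trait_table(pops, file.path(out, "asr_populations.tsv"))

## posterior-like tree set: lognormal branch-length jitter
set.seed(seed + 2L)
trees <- lapply(1:100, function(i) {
  t2 <- tree
  t2$edge.length <- t2$edge.length * exp(rnorm(length(t2$edge.length), 0, 0.1))
  t2
})
class(trees) <- "multiPhylo"
write_newick(trees, file.path(out, "posterior_trees.nwk"))

gt <- attr(records, "ground_truth")
jsonlite::write_json(
  list(seed = seed, n_species = spec$n_species,
       coefficients = unname(gt$dag$coefficients),
       edges = apply(gt$dag$edges, 1, paste, collapse = ">"),
       lambdas = as.list(gt$lambdas), icc_target = spec$icc_target,
       missing_fraction = spec$missing_fraction),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d species, %d populations for %d species, 100 posterior trees.\n",
            nrow(records), nrow(pops), length(asr_means)))
cat("Ground truth: ", paste(apply(gt$dag$edges, 1, paste, collapse = " -> "),
                            collapse = "; "), " (all coefficients 0.5)\n", sep = "")
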