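## Conditional-independence testing of basis-set claims under the two
## phylogenetic frameworks, Fisher's C, CICc, and candidate-model ranking
## with replication over posterior trees.

#' Per-variable phylogenetic contrasts on trait-specific unit trees
#'
#' For each variable: estimate Pagel's lambda by ML, rescale the tree to
#' the corresponding unit tree, and compute Felsenstein contrasts. All
#' variables share the topology, so contrasts align across variables by
#' internal node.
#'
#' @param data Data frame with a `species` column and numeric variables.
#' @param tree A `phylo` object.
#' @param vars Variables to transform (default: all numeric columns).
#' @return Matrix of contrasts (nodes x variables) with the per-variable
#'   lambda estimates in `attr(, "lambdas")`.
#' @export
transform_contrasts <- function(data, tree, vars = NULL) {
  stopifnot("species" %in% names(data))
  if (is.null(vars))
    vars <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], "species")
  keep <- complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  common <- intersect(tree$tip.label, data$species)
  if (length(common) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  data <- data[match(tree$tip.label, data$species), , drop = FALSE]
  lams <- setNames(numeric(length(vars)), vars)
  Z <- NULL
  for (v in vars) {
    y <- setNames(data[[v]], data$species)
    lf <- fit_lambda_ml(y, tree)
    lams[v] <- lf$lambda
    ut <- unit_tree(tree, lf$lambda)
    cv <- pic_contrasts(y, ut)
    if (is.null(Z)) Z <- matrix(NA_real_, length(cv$values), length(vars),
                                dimnames = list(names(cv$values), vars))
    Z[, v] <- cv$values
  }
  attr(Z, "lambdas") <- lams
  attr(Z, "n_species") <- length(tree$tip.label)
  Z
}

#' Test a single d-separation independence claim
#'
#' Transform framework: regression through the origin of the response
#' variable's contrasts on the contrasts of the claim variable and the
#' conditioning set (each computed on its own lambda unit tree); two-sided
#' t-test on the claim coefficient. Residual framework: ML-lambda PGLS of
#' the response on the same predictors; p-value for the claim coefficient.
#'
#' @param claim A claim from [basis_set()] (`x`, `y`, `conditioning`).
#' @param data Data frame with `species` and the claim variables.
#' @param tree A `phylo` object.
#' @param framework `"transform"` or `"residual"`.
#' @param contrasts Optional precomputed [transform_contrasts()] matrix
#'   (transform framework only; avoids refitting lambda per claim).
#' @return The claim with `p_value` filled in.
#' @export
test_claim <- function(claim, data, tree,
                       framework = c("transform", "residual"),
                       contrasts = NULL) {
  framework <- match.arg(framework)
  vars <- c(claim$y, claim$x, claim$conditioning)
  if (!all(vars %in% names(data))) stop("claim variable(s) missing from data: ",
                                        paste(setdiff(vars, names(data)), collapse = ", "))
  if (framework == "transform") {
    if (is.null(contrasts)) contrasts <- transform_contrasts(data, tree, vars)
    Z <- contrasts
    m <- nrow(Z)
    preds <- c(claim$x, claim$conditioning)
    if (m - 1 < length(preds) + 1) stop("too few contrasts for the number of predictors")
    fit <- lm(Z[, claim$y] ~ 0 + Z[, preds, drop = FALSE])
    sm <- suppressWarnings(summary(fit))$coefficients   # exact fits are legitimate here
    p <- sm[1, 4]
  } else {
    keep <- complete.cases(data[, vars, drop = FALSE])
    d <- data[keep, , drop = FALSE]
    y <- setNames(d[[claim$y]], d$species)
    X <- as.matrix(d[, c(claim$x, claim$conditioning), drop = FALSE])
    rownames(X) <- d$species
    fit <- pgls_fit(y, X, tree, lambda = "ml")
    p <- fit$p[claim$x]
  }
  claim$p_value <- unname(p)
  claim
}

#' Fisher's C statistic for a set of independence-claim p-values
#'
#' `C = -2 * sum(log p_i)`, chi-square with `2k` degrees of freedom under
#' the causal model. Zero p-values are clamped to the smallest positive
#' double with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return List: `C`, `df`, `p`.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0) return(list(C = 0, df = 0L, p = 1))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("zero p-value(s) clamped to the machine minimum")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' C-statistic information criterion corrected for small samples (CICc)
#'
#' `CICc = C + 2 q n / (n - 1 - q)` where `q` is the number of model
#' parameters and `n` the sample size.
#'
#' @param C Fisher's C statistic.
#' @param q Parameter count.
#' @param n Sample size.
#' @return Scalar CICc.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) stop("n must exceed q + 1 for the small-sample correction")
  C + 2 * q * n / (n - 1 - q)
}

#' Fit and rank a set of candidate path models
#'
#' For each candidate DAG: build the d-separation basis set, test every
#' claim under the chosen framework, combine p-values into Fisher's C, and
#' score the model by CICc (and, under the transform framework, the SEM
#' fit indices and the SEM-likelihood AICc as well). Models with an empty
#' basis set (saturated) get C = 0, p = 1 and are compared by information
#' criterion only. Support requires both delta < `delta_threshold` and a
#' d-separation p-value above `alpha`.
#'
#' @param candidates List of `dag_model`s.
#' @param data Data frame with `species` and all model variables.
#' @param tree A `phylo` object.
#' @param framework `"transform"` or `"residual"`.
#' @param alpha Rejection level for the d-separation test.
#' @param delta_threshold Delta-CICc support threshold (default 2).
#' @return Data frame, one row per model: `model`, `C`, `df`, `p`, `q`,
#'   `cicc`, `aicc_sem`, `tli`, `cfi`, `rmsea`, `srmr`, `delta`,
#'   `supported`, ordered by CICc.
#' @export
select_models <- function(candidates, data, tree,
                          framework = c("transform", "residual"),
                          alpha = 0.05, delta_threshold = 2) {
  framework <- match.arg(framework)
  if (length(candidates) < 2) stop("need at least 2 candidate models")
  all_vars <- sort(unique(unlist(lapply(candidates, `[[`, "nodes"))))
  keep <- complete.cases(data[, all_vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  Z <- NULL
  if (framework == "transform") {
    Z <- transform_contrasts(data, tree, all_vars)
    n_eff <- nrow(Z)
  } else {
    n_eff <- length(intersect(data$species, tree$tip.label))
  }
  rows <- lapply(candidates, function(dag) {
    claims <- basis_set(dag)
    pv <- vapply(claims, function(cl) {
      test_claim(cl, data, tree, framework, contrasts = Z)$p_value
    }, numeric(1))
    fc <- fishers_c(pv)
    q <- nrow(dag$edges) + length(dag$nodes)
    ic <- cicc(fc$C, q, n_eff)
    sem <- if (framework == "transform")
      sem_fit(dag, Z) else NULL
    data.frame(model = dag$label, C = fc$C, df = fc$df, p = fc$p, q = q,
               cicc = ic,
               aicc_sem = if (is.null(sem)) NA_real_ else sem$aicc,
               tli = if (is.null(sem)) NA_real_ else sem$tli,
               cfi = if (is.null(sem)) NA_real_ else sem$cfi,
               rmsea = if (is.null(sem)) NA_real_ else sem$rmsea,
               srmr = if (is.null(sem)) NA_real_ else sem$srmr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta <- out$cicc - min(out$cicc)
  out$supported <- out$delta < delta_threshold & out$p > alpha
  out <- out[order(out$cicc), ]
  rownames(out) <- NULL
  attr(out, "n") <- n_eff
  attr(out, "framework") <- framework
  out
}

#' Replicate model selection over a set of (posterior) trees
#'
#' Repeats [select_models()] on each tree and reports, per candidate, the
#' fraction of trees on which it is supported and on which it is top-ranked.
#'
#' @param candidates List of `dag_model`s.
#' @param data Data frame with `species` and all model variables.
#' @param trees A `multiPhylo` or list of `phylo` objects (>= 2).
#' @param framework `"transform"` or `"residual"`.
#' @param seed RNG seed (claims tests are deterministic; the seed fixes any
#'   downstream stochastic use).
#' @return Data frame: `model`, `support_freq`, `top_freq`.
#' @export
tree_uncertainty <- function(candidates, data, trees,
                             framework = c("transform", "residual"),
                             seed = 1L) {
  framework <- match.arg(framework)
  if (length(trees) < 2) stop("need at least 2 trees")
  set.seed(seed)
  labs <- vapply(candidates, `[[`, "", "label")
  supp <- top <- setNames(numeric(length(labs)), labs)
  for (tr in trees) {
    tab <- select_models(candidates, data, tr, framework)
    supp[tab$model[tab$supported]] <- supp[tab$model[tab$supported]] + 1
    top[tab$model[1]] <- top[tab$model[1]] + 1
  }
  data.frame(model = labs,
             support_freq = unname(supp[labs]) / length(trees),
             top_freq = unname(top[labs]) / length(trees),
             stringsAsFactors = FALSE)
}
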