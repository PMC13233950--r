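## Phylogenetic imputation of missing traits under a multivariate Brownian
## model with trait-specific phylogenetic signal.
##
## Model: stacking the species x trait matrix Y trait-wise into z = vec(Y),
##   z ~ N(mu x 1, R_phylo (x) C + R_resid (x) I)
## with C the unit-depth Brownian covariance of the tree. The phylogenetic
## and residual among-trait covariance matrices split each trait's variance,
## giving a per-trait signal lambda_j = Rp[j,j] / (Rp[j,j] + Re[j,j]); in the
## single-trait case this is exactly the lambda-transform model. Missing
## cells are handled by marginalising to the observed pattern; imputation is
## the conditional Gaussian expectation of missing cells given all observed
## cells.

## Internal: stacked covariance over selected cells. cells is a 2-column
## matrix (species index, trait index).
stacked_cov <- function(Rp, Re, C, cells) {
  i <- cells[, 1]; j <- cells[, 2]
  Rp[j, j, drop = FALSE] * C[i, i, drop = FALSE] +
    Re[j, j, drop = FALSE] * (outer(i, i, "==") * 1)
}

## Internal: log-likelihood of observed cells given parameters.
stacked_loglik <- function(z, mu_cells, Rp, Re, C, cells) {
  S <- stacked_cov(Rp, Re, C, cells)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  r <- forwardsolve(t(ch), z - mu_cells)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

## Internal: build parameter vector <-> (mu, Rp, Re) via log-Cholesky.
chol_par <- function(theta, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}
par_chol <- function(R) {
  L <- t(chol(R + diag(1e-10, nrow(R))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

#' Fit the multivariate phylogenetic imputation model
#'
#' Maximum-likelihood fit of the two-matrix phylogenetic Gaussian model
#' (phylogenetic + residual among-trait covariances on a unit-depth tree;
#' see the package vignette) to a trait table with missing cells.
#'
#' @param table Data frame with a `species` column and numeric trait
#'   columns.
#' @param tree A `phylo` object (made unit depth internally).
#' @param traits Character vector of trait columns to model (default: all
#'   numeric columns).
#' @param min_obs Minimum observed species per trait (default 10).
#' @param maxit Optimiser iteration cap.
#' @param init Optional `imputation_model` supplying warm-start parameter
#'   values (used by the leave-one-out refits).
#' @return List of class `imputation_model`: `mu`, `R_phylo`, `R_resid`,
#'   `lambdas`, `loglik`, `traits`, `converged`.
#' @export
fit_imputation_model <- function(table, tree, traits = NULL, min_obs = 10L,
                                 maxit = 500L, init = NULL) {
  stopifnot("species" %in% names(table))
  if (is.null(traits)) {
    traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "species")
  }
  p <- length(traits)
  if (p < 1) stop("no traits to model")
  Y <- as.matrix(table[, traits, drop = FALSE])
  rownames(Y) <- table$species
  common <- intersect(tree$tip.label, table$species)
  if (length(common) < 4) stop("too few species shared between table and tree")
  if (length(common) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  Y <- Y[tree$tip.label, , drop = FALSE]
  nobs <- colSums(!is.na(Y))
  if (any(nobs < min_obs))
    stop("trait(s) observed for fewer than ", min_obs, " species: ",
         paste(traits[nobs < min_obs], collapse = ", "))
  C <- phylo_vcv(tree)
  C <- C / mean(diag(C))
  n <- nrow(Y)
  cells <- which(!is.na(Y), arr.ind = TRUE)[, c(1, 2), drop = FALSE]
  z <- Y[!is.na(Y)]
  ## order cells trait-major to match vec(Y)
  o <- order(cells[, 2], cells[, 1])
  cells <- cells[o, , drop = FALSE]
  z <- Y[cbind(cells[, 1], cells[, 2])]

  S0 <- diag(apply(Y, 2, var, na.rm = TRUE), p)
  cc <- complete.cases(Y)
  if (sum(cc) >= p + 2) {
    S_full <- cov(Y[cc, , drop = FALSE])
    if (all(is.finite(S_full)) && min(eigen(S_full, only.values = TRUE)$values) > 0)
      S0 <- S_full
  }
  mu0 <- colMeans(Y, na.rm = TRUE)
  theta0 <- if (!is.null(init)) {
    c(init$mu[traits], par_chol(init$R_phylo[traits, traits, drop = FALSE]),
      par_chol(init$R_resid[traits, traits, drop = FALSE]))
  } else {
    c(mu0, par_chol(S0 * 0.5), par_chol(diag(diag(S0), p) * 0.5))
  }
  nc <- p * (p + 1) / 2
  unpack <- function(theta) {
    list(mu = theta[seq_len(p)],
         Rp = chol_par(theta[p + seq_len(nc)], p),
         Re = chol_par(theta[p + nc + seq_len(nc)], p))
  }
  negll <- function(theta) {
    pp <- unpack(theta)
    ll <- stacked_loglik(z, pp$mu[cells[, 2]], pp$Rp, pp$Re, C, cells)
    if (!is.finite(ll)) return(1e10)   # keep the bounded optimiser in range
    -ll
  }
  opt <- optim(theta0, negll, method = "L-BFGS-B", control = list(maxit = maxit))
  if (!is.finite(opt$value)) stop("imputation model likelihood did not converge; trace: ", opt$message)
  pp <- unpack(opt$par)
  lam <- diag(pp$Rp) / (diag(pp$Rp) + diag(pp$Re))
  structure(list(mu = setNames(pp$mu, traits),
                 R_phylo = structure(pp$Rp, dimnames = list(traits, traits)),
                 R_resid = structure(pp$Re, dimnames = list(traits, traits)),
                 lambdas = setNames(lam, traits),
                 loglik = -opt$value, traits = traits,
                 converged = opt$convergence == 0),
            class = "imputation_model")
}

#' Impute missing trait cells by conditional Gaussian expectation
#'
#' Fills every missing cell with its conditional expectation given all
#' observed cells under the fitted model; predictive standard deviations
#' come from the conditional variance. Observed cells are returned
#' unchanged.
#'
#' @param model An [fit_imputation_model()] result covering all traits with
#'   missing cells.
#' @param table Data frame with `species` and the model's trait columns.
#' @param tree A `phylo` object.
#' @return List of class `imputation_result`: `completed_table`,
#'   `imputed_mask`, `predictive_sd`.
#' @export
impute <- function(model, table, tree) {
  traits <- model$traits
  Y <- as.matrix(table[, traits, drop = FALSE])
  rownames(Y) <- table$species
  missing_sp <- setdiff(table$species, tree$tip.label)
  if (length(missing_sp)) stop("species absent from tree: ", paste(head(missing_sp, 5), collapse = ", "))
  if (length(setdiff(tree$tip.label, table$species)))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, table$species))
  Y <- Y[tree$tip.label, , drop = FALSE]
  C <- phylo_vcv(tree); C <- C / mean(diag(C))
  completed <- Y
  mask <- is.na(Y)
  sd_out <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  if (any(mask)) {
    obs_cells <- which(!mask, arr.ind = TRUE)
    mis_cells <- which(mask, arr.ind = TRUE)
    zo <- Y[obs_cells]
    mu_o <- model$mu[obs_cells[, 2]]
    mu_m <- model$mu[mis_cells[, 2]]
    Soo <- stacked_cov(model$R_phylo, model$R_resid, C, obs_cells)
    ## cross-covariance missing x observed
    i <- mis_cells[, 1]; j <- mis_cells[, 2]
    k <- obs_cells[, 1]; l <- obs_cells[, 2]
    Smo <- model$R_phylo[j, l, drop = FALSE] * C[i, k, drop = FALSE] +
      model$R_resid[j, l, drop = FALSE] * (outer(i, k, "==") * 1)
    Smm_diag <- diag(model$R_phylo)[j] * diag(C)[i] + diag(model$R_resid)[j]
    ch <- chol(Soo + diag(1e-10, nrow(Soo)))
    w <- backsolve(ch, forwardsolve(t(ch), zo - mu_o))
    completed[mask] <- mu_m + drop(Smo %*% w)
    ## conditional variance: diag(Smm - Smo Soo^-1 Som)
    A <- forwardsolve(t(ch), t(Smo))
    cv <- pmax(Smm_diag - colSums(A^2), 1e-12)
    sd_out[mask] <- sqrt(cv)
  }
  out_table <- data.frame(species = rownames(completed), completed,
                          row.names = NULL, check.names = FALSE)
  structure(list(completed_table = out_table, imputed_mask = mask,
                 predictive_sd = sd_out),
            class = "imputation_result")
}

#' Leave-one-out cross-validation of imputation accuracy
#'
#' For every observed cell of each target trait: mask it, impute it from
#' the remaining observed cells (model parameters are estimated once on the
#' full data and reused, unless `refit = TRUE`), and correlate the imputed
#' with the held-out observed values per trait.
#'
#' @param table Data frame with `species` and trait columns.
#' @param tree A `phylo` object.
#' @param target_traits Traits to cross-validate (default: all modelled).
#' @param model Optional pre-fitted [fit_imputation_model()].
#' @param refit Re-estimate model parameters for every deletion (each refit
#'   warm-started from the full-data fit). Slower but leak-free; the
#'   default reuses the full-data parameters for every mask.
#' @param seed RNG seed (recorded; the procedure is deterministic).
#' @return Named numeric vector of Pearson correlations (NA with a warning
#'   where the held-out values are degenerate).
#' @export
loocv <- function(table, tree, target_traits = NULL, model = NULL,
                  refit = FALSE, seed = 1L) {
  if (is.null(model)) model <- fit_imputation_model(table, tree,
                                                    traits = target_traits_union(table, target_traits))
  traits <- model$traits
  if (is.null(target_traits)) target_traits <- traits
  Y <- as.matrix(table[, traits, drop = FALSE])
  rownames(Y) <- table$species
  if (length(setdiff(tree$tip.label, table$species)))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, table$species))
  Y <- Y[tree$tip.label, , drop = FALSE]
  C <- phylo_vcv(tree); C <- C / mean(diag(C))
  obs_cells <- which(!is.na(Y), arr.ind = TRUE)
  zo <- Y[obs_cells]
  if (refit) {
    ## leak-free variant: re-estimate parameters without each held-out cell
    ## (warm-started from the full-data fit), then impute just that cell
    pred <- rep(NA_real_, length(zo))
    tab_aligned <- data.frame(species = rownames(Y), Y, check.names = FALSE)
    tgt_idx <- which(obs_cells[, 2] %in% match(target_traits, traits))
    for (ii in tgt_idx) {
      t2 <- tab_aligned
      t2[obs_cells[ii, 1], traits[obs_cells[ii, 2]]] <- NA
      m2 <- fit_imputation_model(t2, tree, traits = traits,
                                 min_obs = 3L, init = model)
      r2 <- impute(m2, t2, tree)
      pred[ii] <- as.matrix(r2$completed_table[, traits])[obs_cells[ii, , drop = FALSE]]
    }
  } else {
    mu_o <- model$mu[obs_cells[, 2]]
    S <- stacked_cov(model$R_phylo, model$R_resid, C, obs_cells)
    P <- chol2inv(chol(S + diag(1e-10, nrow(S))))
    resid_z <- zo - mu_o
    ## conditional mean of cell i given the rest from the precision matrix
    pred <- zo - (P %*% resid_z) / diag(P)
  }
  out <- setNames(rep(NA_real_, length(target_traits)), target_traits)
  for (tr in target_traits) {
    jj <- which(obs_cells[, 2] == match(tr, traits))
    if (length(jj) < 3 || sd(zo[jj]) == 0 || sd(pred[jj]) == 0) {
      warning("degenerate held-out values for trait ", tr, "; correlation undefined")
      next
    }
    out[tr] <- cor(zo[jj], pred[jj])
  }
  attr(out, "predictions") <- pred
  out
}

## Internal
target_traits_union <- function(table, target_traits) {
  num <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "species")
  if (is.null(target_traits)) num else union(target_traits, num)
}
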