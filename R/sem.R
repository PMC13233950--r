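## Recursive path-model (SEM) fit on phylogenetic contrasts: equation-wise
## ML, implied covariance by path tracing, likelihood-ratio chi-square and
## the standard incremental/absolute fit indices.

#' Fit a recursive path model to phylogenetic contrasts
#'
#' Each endogenous variable is regressed (through the origin, as contrasts
#' have zero expectation) on its parents; the implied covariance follows
#' from the recursive structure, `Sigma = (I-B)^-1 Psi (I-B)^-T`. Model fit
#' is the ML discrepancy
#' `F = log|Sigma| - log|S| + tr(S Sigma^-1) - p`, `chisq = (n-1) F`, with
#' the independence model as baseline for TLI/CFI; RMSEA, SRMR and an AICc
#' built from `chisq + 2q` complete the report.
#'
#' @param dag A `dag_model` whose nodes name columns of `contrasts`.
#' @param contrasts Matrix of node-aligned contrasts (rows = internal
#'   nodes, columns = variables), e.g. from [transform_contrasts()].
#' @return List of class `sem_fit`: `chisq`, `df_model`, `p`, `tli`,
#'   `cfi`, `rmsea`, `srmr`, `aicc`, `coefficients` (per edge), `n`.
#' @export
sem_fit <- function(dag, contrasts) {
  vars <- dag$nodes
  miss <- setdiff(vars, colnames(contrasts))
  if (length(miss)) stop("contrasts missing for: ", paste(miss, collapse = ", "))
  Z <- contrasts[, vars, drop = FALSE]
  n <- nrow(Z)
  p <- length(vars)
  S <- crossprod(Z) / n          # second moments about zero
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  coefs <- list()
  for (v in vars) {
    pa <- dag_parents(dag, v)
    if (length(pa) == 0) {
      Psi[v, v] <- S[v, v]
    } else {
      Xp <- Z[, pa, drop = FALSE]
      b <- tryCatch(solve(crossprod(Xp), crossprod(Xp, Z[, v])),
                    error = function(e) stop("implied covariance singular in equation for '",
                                             v, "': ", conditionMessage(e)))
      B[v, pa] <- drop(b)
      r <- Z[, v] - Xp %*% b
      Psi[v, v] <- sum(r^2) / n
      coefs[[v]] <- setNames(drop(b), pa)
    }
  }
  IB <- diag(p) - B
  IBi <- solve(IB)
  Sigma <- IBi %*% Psi %*% t(IBi)
  chS <- tryCatch(chol(S), error = function(e) stop("sample covariance of contrasts is singular"))
  chSig <- tryCatch(chol(Sigma), error = function(e) stop("implied covariance singular"))
  ldS <- 2 * sum(log(diag(chS)))
  ldSig <- 2 * sum(log(diag(chSig)))
  Fml <- max(ldSig - ldS + sum(diag(S %*% chol2inv(chSig))) - p, 0)
  chisq <- (n - 1) * Fml
  q <- nrow(dag$edges) + p
  df_model <- p * (p + 1) / 2 - q
  ## baseline (independence) model
  Sig0 <- diag(diag(S), p)
  F0 <- sum(log(diag(S))) - ldS + sum(diag(S) / diag(Sig0)) - p
  chisq0 <- (n - 1) * max(F0, 0)
  df0 <- p * (p - 1) / 2
  tli <- if (df_model > 0 && df0 > 0 && chisq0 / df0 > 1) {
    (chisq0 / df0 - chisq / df_model) / (chisq0 / df0 - 1)
  } else 1
  num <- max(chisq - df_model, 0)
  den <- max(chisq0 - df0, num)
  ## guard: both noncentralities at numerical zero means perfect fit
  cfi <- if (den > 1e-10) 1 - num / den else 1
  rmsea <- if (df_model > 0) sqrt(max(chisq - df_model, 0) / (df_model * (n - 1))) else 0
  dS <- sqrt(diag(S)); dSig <- sqrt(diag(Sigma))
  Rres <- S / tcrossprod(dS) - Sigma / tcrossprod(dSig)
  srmr <- sqrt(mean(Rres[lower.tri(Rres, diag = TRUE)]^2))
  aicc <- chisq + 2 * q + 2 * q * (q + 1) / (n - q - 1)
  structure(list(chisq = chisq, df_model = df_model,
                 p = if (df_model > 0) pchisq(chisq, df_model, lower.tail = FALSE) else 1,
                 tli = min(tli, 1), cfi = cfi, rmsea = rmsea, srmr = srmr,
                 aicc = aicc, coefficients = coefs, n = n),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Path model fit: chisq = %.3f (df = %d, p = %.3f), TLI = %.3f, CFI = %.3f, RMSEA = %.3f, SRMR = %.4f, AICc = %.2f\n",
              x$chisq, x$df_model, x$p, x$tli, x$cfi, x$rmsea, x$srmr, x$aicc))
  invisible(x)
}
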