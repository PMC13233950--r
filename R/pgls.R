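## Phylogenetic generalised least squares with Pagel's lambda.

#' Phylogenetic GLS regression with Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V(lambda))` where `V(lambda)`
#' is the lambda-transformed Brownian covariance of the tree. `lambda` is
#' either fixed or profiled by maximum likelihood on \[0, 1\] jointly with
#' `beta` and `sigma2` (full ML, so that log-likelihoods and AICc are
#' comparable across models with different fixed effects).
#'
#' @param y Named response vector (names = species).
#' @param X Design matrix (rows aligned with `y`); an intercept column is
#'   added if absent.
#' @param tree A `phylo` object.
#' @param lambda `"ml"` (default) or a fixed value in \[0, 1\].
#' @return List of class `gls_fit`: `beta`, `se`, `t`, `p`, `sigma2`,
#'   `lambda`, `loglik`, `aicc`, `n`, `q`.
#' @export
pgls_fit <- function(y, X, tree, lambda = "ml") {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) == 0 || !any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (is.null(names(y))) {
    if (length(y) != ape::Ntip(tree)) stop("unnamed y must match tree tips")
    names(y) <- tree$tip.label
  }
  rownames(X) <- names(y)
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  al <- align_trait(y, tree)
  tree <- al$tree; y <- al$y; X <- X[names(y), , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more coefficients than species")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  C <- phylo_vcv(tree)
  eig <- lambda_eigen(C)
  ml_mode <- identical(lambda, "ml")
  if (ml_mode) {
    f <- function(l) gls_profile(y, X, C, l, eig)$loglik
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    lam <- cand[which.max(vapply(cand, f, numeric(1)))]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be 'ml' or a number in [0, 1]")
    lam <- lambda
  }
  pr <- gls_profile(y, X, C, lam, eig)
  if (!is.finite(pr$loglik))
    stop("GLS likelihood could not be evaluated (singular covariance?)")
  ## SEs from sigma2 * (X' V^-1 X)^-1 with the ML (unbiased-corrected) scale
  covb <- pr$sigma2 * n / (n - p) * chol2inv(chol(pr$XtViX))
  se <- sqrt(diag(covb))
  tval <- pr$beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  q <- p + 1 + as.integer(ml_mode)   # beta, sigma2, lambda if estimated
  aicc <- -2 * pr$loglik + 2 * q + 2 * q * (q + 1) / (n - q - 1)
  structure(list(beta = setNames(pr$beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 t = setNames(tval, colnames(X)),
                 p = setNames(pval, colnames(X)),
                 sigma2 = pr$sigma2, lambda = lam, loglik = pr$loglik,
                 aicc = aicc, n = n, q = q,
                 lambda_mode = if (ml_mode) "ml" else "fixed"),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS (lambda %s = %.3f), n = %d, logLik = %.3f, AICc = %.3f\n",
              x$lambda_mode, x$lambda, x$n, x$loglik, x$aicc))
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the remaining
#' predictors. Intercept columns are ignored. Perfectly collinear columns
#' get `Inf` with a warning.
#'
#' @param X Design matrix or data frame of predictors (>= 2 non-intercept
#'   columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  const <- apply(X, 2, function(c) all(c == c[1]))
  X <- X[, !const, drop = FALSE]
  p <- ncol(X)
  if (p < 2) stop("need at least 2 non-constant predictors")
  out <- setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    out[j] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out))) warning("perfect collinearity: infinite VIF for ",
                                    paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}
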