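## Tree I/O, phylogenetic covariance, Pagel's lambda, unit trees and contrasts.
##
## Trees are `ape::phylo` objects throughout; this file adds validation,
## the lambda machinery used by every downstream regression, and the
## unit-tree construction behind the trait-transformation path framework.

#' Read a phylogeny (or a set of posterior trees) from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates what the rest of the
#' pipeline assumes: unique tip labels and non-negative branch lengths.
#' Zero-length branches are preserved.
#'
#' @param path Path to a Newick file. May contain several trees (one per
#'   line), e.g. a posterior sample used for sensitivity replication.
#' @return A `phylo` object, or a `multiPhylo` list if the file holds more
#'   than one tree.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("Newick parse error in '", path, "': ", conditionMessage(e))
  })
  if (is.null(tr)) stop("Newick parse error: no tree could be read from '", path, "'")
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, validate_tree)
    return(tr)
  }
  validate_tree(tr)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

## Internal: check tip uniqueness and branch lengths.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths; dated/ultrametric branch lengths are required")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths present")
  tree
}

#' Root-to-tip depths of all tips
#' @param tree A `phylo` object.
#' @return Named numeric vector of root-to-tip path lengths.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Is a tree ultrametric (all tips equidistant from the root)?
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on tip-depth spread.
#' @return Logical.
#' @export
tree_is_ultrametric <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(mean(d), .Machine$double.eps)
}

#' Brownian phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j; the
#' diagonal holds root-to-tip distances. This is the covariance of tip values
#' under Brownian motion with unit rate.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted; root it (e.g. ape::root) before computing the covariance")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` returns the Brownian covariance; `lambda = 0`
#' gives a star phylogeny (independent tips).
#'
#' @param V Phylogenetic covariance matrix.
#' @param lambda Signal strength in \[0, 1\].
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

## Internal: eigen machinery for fast repeated lambda likelihood evaluations
## on ultrametric trees. V(lambda) = lambda*C + (1-lambda)*d*I shares C's
## eigenvectors, so each lambda costs O(n) once data are rotated.
lambda_eigen <- function(C) {
  d <- diag(C)
  ultra <- diff(range(d)) <= 1e-8 * max(mean(d), .Machine$double.eps)
  if (!ultra) return(NULL)
  e <- eigen(C, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, depth = mean(d))
}

## Internal: -log restricted/full profile pieces for y ~ X under sigma2*V(lambda).
## Returns list(loglik, beta, sigma2, XtViX) profiled over beta and sigma2 (ML).
gls_profile <- function(y, X, C, lambda, eig = NULL) {
  n <- length(y)
  if (!is.null(eig)) {
    w <- lambda * eig$values + (1 - lambda) * eig$depth
    if (any(w <= 0)) return(list(loglik = -Inf))
    yr <- crossprod(eig$vectors, y)
    Xr <- crossprod(eig$vectors, X)
    XtViX <- crossprod(Xr / w, Xr)
    XtViy <- crossprod(Xr / w, yr)
    ldet <- sum(log(w))
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
    r <- yr - Xr %*% beta
    rss <- sum(r^2 / w)
  } else {
    V <- lambda_transform(C, lambda)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    ldet <- 2 * sum(log(diag(ch)))
    yw <- forwardsolve(t(ch), y)
    Xw <- forwardsolve(t(ch), X)
    XtViX <- crossprod(Xw)
    cb <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cb)) return(list(loglik = -Inf))
    beta <- backsolve(cb, forwardsolve(t(cb), crossprod(Xw, yw)))
    r <- yw - Xw %*% beta
    rss <- sum(r^2)
  }
  sigma2 <- rss / n
  if (!is.finite(sigma2) || sigma2 <= 0) return(list(loglik = -Inf))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + ldet + n)
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2, XtViX = XtViX)
}

#' Maximum-likelihood estimate of Pagel's lambda for a single trait
#'
#' Fits an intercept-only phylogenetic Gaussian model with covariance
#' `sigma2 * lambda_transform(C, lambda)` and profiles the likelihood over
#' the mean and `sigma2`, optimising `lambda` on \[0, 1\] by bounded search.
#' Boundary maxima (0 or 1) are returned as estimates, not errors.
#'
#' @param y Named trait vector (names = species) or vector aligned to
#'   `tree$tip.label`.
#' @param tree A `phylo` object.
#' @param tol Optimiser tolerance on lambda.
#' @return List of class `lambda_fit`: `lambda`, `loglik`, `converged`,
#'   `sigma2`, `mu`.
#' @export
fit_lambda_ml <- function(y, tree, tol = 1e-6) {
  al <- align_trait(y, tree)
  y <- al$y; tree <- al$tree
  n <- length(y)
  if (n < 4) stop("at least 4 species required to estimate lambda")
  if (sd(y) == 0) stop("trait is constant; lambda likelihood is flat")
  C <- phylo_vcv(tree)
  eig <- lambda_eigen(C)
  X <- matrix(1, n, 1)
  f <- function(l) gls_profile(y, X, C, l, eig)$loglik
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  ll <- vapply(cand, f, numeric(1))
  best <- which.max(ll)
  lam <- cand[best]
  pr <- gls_profile(y, X, C, lam, eig)
  structure(list(lambda = lam, loglik = ll[best],
                 converged = is.finite(ll[best]),
                 sigma2 = pr$sigma2, mu = pr$beta[1], n = n),
            class = "lambda_fit")
}

#' Rescale a tree to a unit tree under a given lambda
#'
#' Produces a tree whose Brownian covariance equals the lambda transform of
#' the original covariance divided by the original depth: internal shared
#' paths are multiplied by `lambda / depth` and terminal branches extended so
#' every tip sits at depth 1. The result has unit expected trait variance at
#' each tip, the scale on which phylogenetically independent contrasts for
#' the path analysis are computed. Defined for ultrametric trees;
#' non-ultrametric input is first made ultrametric by extending terminal
#' branches to the maximum depth (with a warning).
#'
#' @param tree A `phylo` object.
#' @param lambda Signal strength in \[0, 1\].
#' @return An ultrametric `phylo` of depth 1.
#' @export
unit_tree <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  validate_tree(tree)
  if (!tree_is_ultrametric(tree)) {
    warning("non-ultrametric tree: terminal branches extended to a common depth before unit-tree rescaling")
    d <- tip_depths(tree)
    term <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
    tree$edge.length[term] <- tree$edge.length[term] + (max(d) - d)
  }
  depth <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length * (lambda / depth)
  d <- tip_depths(tree)
  term <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (1 - d)
  tree
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's standardized contrasts via [ape::pic()]. Polytomies are
#' first resolved deterministically (tips sorted by label, zero-length
#' internal branches).
#'
#' @param y Named trait vector or vector aligned to `tree$tip.label`; must be
#'   complete (prune missing species first).
#' @param tree A `phylo` object.
#' @return List of class `contrast_vector`: `values` (length n-1, named by
#'   internal node id) and `node_ids`.
#' @export
pic_contrasts <- function(y, tree) {
  if (!is.null(names(y)) && anyNA(y[tree$tip.label]))
    stop("missing tip values; prune species with missing data before computing contrasts")
  if (is.null(names(y)) && anyNA(y))
    stop("missing tip values; prune species with missing data before computing contrasts")
  al <- align_trait(y, tree, allow_prune = FALSE)
  y <- al$y; tree <- al$tree
  tree <- resolve_polytomies(tree)
  v <- ape::pic(y, tree)
  structure(list(values = v, node_ids = as.integer(names(v))),
            class = "contrast_vector")
}

## Internal: deterministic polytomy resolution (fixed by tip-label order).
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::multi2di(tree, random = FALSE)
}

## Internal: align a named trait vector with a tree, pruning to the common
## species set (logged) or erroring if pruning is disallowed.
align_trait <- function(y, tree, allow_prune = TRUE) {
  if (is.null(names(y))) {
    if (length(y) != ape::Ntip(tree)) stop("unnamed trait vector must match the number of tips")
    names(y) <- tree$tip.label
  }
  common <- intersect(tree$tip.label, names(y)[!is.na(y)])
  if (length(common) == 0) stop("no species shared between trait vector and tree")
  dropped_tree <- setdiff(tree$tip.label, common)
  dropped_y <- setdiff(names(y), tree$tip.label)
  if (length(dropped_tree) || length(dropped_y)) {
    if (!allow_prune && length(setdiff(tree$tip.label, names(y)))) {
      stop("trait vector does not cover all tips")
    }
    message(sprintf("pruned %d tree tips / dropped %d table species not shared",
                    length(dropped_tree), length(dropped_y)))
    if (length(dropped_tree)) tree <- ape::drop.tip(tree, dropped_tree)
  }
  list(y = y[tree$tip.label], tree = tree)
}
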