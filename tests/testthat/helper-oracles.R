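## Shared fixtures and independent oracles used across the suite.

## Small fixed trees ------------------------------------------------------

two_tip_tree <- function() ape::read.tree(text = "(A:1,B:1);")
three_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

## A reproducible Yule tree of n tips, unit depth.
yule_tree <- function(n, seed = 1) {
  simulate_tree(simulation_spec(n_species = n, seed = seed))
}

## Brownian trait on a tree (unit rate unless sigma given).
rbm <- function(tree, sigma = 1, seed = NULL, lambda = 1) {
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv.phylo(tree)
  V <- C * lambda
  diag(V) <- diag(C)
  y <- drop(crossprod(chol(V), rnorm(nrow(V)))) * sigma
  setNames(y, tree$tip.label)
}

## Dense GLS oracle: beta-hat under covariance V (with intercept).
gls_oracle <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

## Dense profile log-likelihood of the intercept-only lambda model.
lambda_grid_oracle_ll <- function(y, tree, l) {
  C <- ape::vcv.phylo(tree)[names(y), names(y)]
  n <- length(y)
  V <- C * l; diag(V) <- diag(C)
  ch <- chol(V)
  ld <- 2 * sum(log(diag(ch)))
  one <- rep(1, n)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(y * Vi_1) / sum(one * Vi_1)
  r <- y - mu
  s2 <- drop(crossprod(r, backsolve(ch, forwardsolve(t(ch), r)))) / n
  -0.5 * (n * log(2 * pi * s2) + ld + n)
}

## Dense lambda grid-search oracle for the intercept-only model.
lambda_grid_oracle <- function(y, tree, step = 0.001) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(l) lambda_grid_oracle_ll(y, tree, l), numeric(1))
  grid[which.max(ll)]
}

## Exhaustive d-separation oracle by path enumeration (small graphs).
## edges: 2-column character matrix; returns TRUE if x _||_ y | Z.
dsep_oracle <- function(edges, x, y, Z) {
  nodes <- unique(c(edges, x, y, Z))
  desc <- function(v) {
    out <- v
    repeat {
      kids <- unique(edges[edges[, 1] %in% out, 2])
      new <- setdiff(kids, out)
      if (!length(new)) return(out)
      out <- c(out, new)
    }
  }
  ## enumerate all simple undirected paths x..y
  adj <- unique(rbind(edges, edges[, 2:1, drop = FALSE]))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    nxt <- adj[adj[, 1] == v, 2]
    for (w in setdiff(nxt, path)) walk(c(path, w))
  }
  walk(x)
  if (!length(paths)) return(TRUE)
  has_edge <- function(a, b) any(edges[, 1] == a & edges[, 2] == b)
  for (p in paths) {
    if (length(p) == 2) return(FALSE)       # adjacent: never separated
    active <- TRUE
    for (i in 2:(length(p) - 1)) {
      a <- p[i - 1]; v <- p[i]; b <- p[i + 1]
      collider <- has_edge(a, v) && has_edge(b, v)
      if (collider) {
        if (!any(desc(v) %in% Z)) { active <- FALSE; break }
      } else {
        if (v %in% Z) { active <- FALSE; break }
      }
    }
    if (active) return(FALSE)
  }
  TRUE
}

## Enumerate all DAGs on the given nodes (3^choose(n,2) orientations,
## acyclic only). Returns a list of edge matrices.
enumerate_dags <- function(nodes) {
  prs <- t(combn(nodes, 2))
  k <- nrow(prs)
  out <- list()
  for (code in 0:(3^k - 1)) {
    c0 <- code
    em <- matrix(character(0), 0, 2)
    for (i in seq_len(k)) {
      d <- c0 %% 3; c0 <- c0 %/% 3
      if (d == 1) em <- rbind(em, prs[i, ])
      if (d == 2) em <- rbind(em, prs[i, 2:1])
    }
    m <- tryCatch(dag_model(em, nodes = nodes), error = function(e) NULL)
    if (!is.null(m)) out[[length(out) + 1]] <- m
  }
  out
}

## Dense multivariate-normal log density.
mvn_loglik_oracle <- function(z, mu, S) {
  ch <- chol(S)
  r <- forwardsolve(t(ch), z - mu)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

## Effective sample size from the empirical autocorrelation (initial
## positive sequence), independent of the package's AR-based estimate.
ess_safe <- function(x) {
  n <- length(x)
  a <- acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(a)
  max(5, n / (1 + 2 * sum(a[seq_len(cut)])))
}

## Toy raw species records with no missing data.
toy_records <- function(n = 40, seed = 5) {
  spec <- simulation_spec(n_species = n, seed = seed)
  tree <- simulate_tree(spec)
  list(tree = tree, records = simulate_species_records(tree, spec), spec = spec)
}
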