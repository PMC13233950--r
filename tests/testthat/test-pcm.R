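test_that("PGLS with lambda 0 reduces to OLS and intercept-only gives the mean", {
  tr <- yule_tree(40, seed = 1)
  y <- rbm(tr, seed = 1)
  x <- rbm(tr, seed = 2)
  X <- matrix(x, ncol = 1, dimnames = list(names(y), "x"))
  f0 <- pgls_fit(y, X, tr, lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_lt(max(abs(f0$beta - ols)), 1e-10)

  fi <- pgls_fit(y, matrix(numeric(0), length(y), 0,
                           dimnames = list(names(y), NULL)), tr, lambda = 0)
  expect_equal(unname(fi$beta[1]), mean(y), tolerance = 1e-10)
})

test_that("PGLS agrees with the nlme/corPagel oracle at fixed lambda", {
  skip_if_not_installed("nlme")
  tr <- yule_tree(50, seed = 4)
  y <- rbm(tr, seed = 5, lambda = 0.7)
  x <- rbm(tr, seed = 6, lambda = 0.7)
  d <- data.frame(y = y, x = x, sp = names(y), row.names = names(y))
  for (lam in c(0.3, 0.8)) {
    g <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(lam, tr, form = ~sp, fixed = TRUE),
                   method = "ML")
    f <- pgls_fit(y, matrix(x, ncol = 1, dimnames = list(names(y), "x")),
                  tr, lambda = lam)
    expect_lt(max(abs(f$beta - coef(g))), 1e-6)
    expect_lt(abs(f$loglik - as.numeric(logLik(g))), 1e-4)
  }
})

test_that("PGLS profile likelihood at the ML lambda dominates the endpoints", {
  tr <- yule_tree(60, seed = 7)
  for (s in 1:3) {
    y <- rbm(tr, seed = 10 + s, lambda = c(0, 0.5, 1)[s])
    x <- rbm(tr, seed = 20 + s)
    X <- matrix(x, ncol = 1, dimnames = list(names(y), "x"))
    fml <- pgls_fit(y, X, tr, lambda = "ml")
    expect_gte(fml$loglik + 1e-8, pgls_fit(y, X, tr, lambda = 0)$loglik)
    expect_gte(fml$loglik + 1e-8, pgls_fit(y, X, tr, lambda = 1)$loglik)
    ## AICc identity
    q <- fml$q
    expect_equal(fml$aicc,
                 -2 * fml$loglik + 2 * q + 2 * q * (q + 1) / (fml$n - q - 1))
  }
})

test_that("PGLS recovers simulated slope and lambda", {
  n_rep <- 30
  tr <- yule_tree(150, seed = 3)
  C <- ape::vcv.phylo(tr)
  b <- l <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rbm(tr, seed = 1000 + r)
    y <- 0.5 * x + rbm(tr, seed = 2000 + r, lambda = 0.7)
    fit <- pgls_fit(y, matrix(x, ncol = 1, dimnames = list(names(x), "x")), tr)
    b[r] <- fit$beta["x"]; l[r] <- fit$lambda
  }
  expect_lt(abs(mean(b) - 0.5), 0.05)
  expect_lt(abs(mean(l) - 0.7), 0.1)
})

test_that("PGLS names collinear columns", {
  tr <- yule_tree(30, seed = 8)
  x <- rbm(tr, seed = 30)
  X <- cbind(a = x, b = 2 * x)
  rownames(X) <- names(x)
  expect_error(pgls_fit(rbm(tr, seed = 31), X, tr, lambda = 0.5), "collinear")
})

test_that("VIF matches the determinant-minor oracle and flags degeneracy", {
  set.seed(9)
  ## mutually uncorrelated columns (orthogonal to each other and to the
  ## intercept) -> VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100), 20, 5))))[, -1]
  expect_lt(max(abs(vif(Q) - 1)), 1e-8)

  X <- matrix(rnorm(200), 40, 5)
  X[, 2] <- X[, 1] * 0.8 + rnorm(40, 0, 0.3)
  colnames(X) <- paste0("v", 1:5)
  v <- vif(X)
  ## oracle: VIF_j = det(R[-j,-j]) * R_jj-minor ratio
  R <- cor(X)
  oracle <- vapply(1:5, function(j) det(R[-j, -j]) / det(R), numeric(1))
  ## VIF computed on raw (uncentred) regressions differs from the
  ## correlation form by the intercept; compare with centred data
  Xc <- scale(X, scale = FALSE)
  vc <- vif(Xc)
  expect_lt(max(abs(vc - oracle)), 1e-6)

  expect_warning(vd <- vif(cbind(a = X[, 1], b = X[, 1], c = X[, 3])), "collinear")
  expect_true(is.infinite(vd["a"]) || is.infinite(vd["b"]))
})

test_that("MCMC posterior means agree with ML GLS on fixed data", {
  tr <- yule_tree(100, seed = 11)
  x <- rbm(tr, seed = 40)
  y <- 0.5 * x + rbm(tr, seed = 41, lambda = 0.7)
  X <- matrix(x, ncol = 1, dimnames = list(names(x), "x"))
  g <- pgls_fit(y, X, tr)
  mc <- mcmc_phylo_lmm(y, X, tr,
                       config = mcmc_config(n_iter = 15000, burn_in = 1500,
                                            thin = 10, seed = 12))
  mcse <- apply(mc$draws$beta, 2, function(b) sd(b) / sqrt(ess_safe(b)))
  expect_lt(abs(mc$post_mean["x"] - g$beta["x"]),
            2 * mcse["x"] + 0.25 * g$se["x"])
  ## bookkeeping invariants
  expect_equal(mc$n_samples, (15000 - 1500) %/% 10)
  expect_true(all(mc$ci95[, 1] <= mc$post_mean & mc$post_mean <= mc$ci95[, 2]))
  expect_true(all(mc$pmcmc > 0 & mc$pmcmc <= 1))
  expect_true(all(mc$ess <= mc$n_samples + 1))
  ## stationarity on the slope draws
  expect_lt(split_rhat(mc$draws$beta[, "x"]), 1.05)
})

test_that("MCMC credible intervals cover a zero effect at the nominal rate", {
  n_rep <- 60
  tr <- yule_tree(60, seed = 14)
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rbm(tr, seed = 3000 + r)
    y <- rbm(tr, seed = 4000 + r, lambda = 0.5)   # beta1 = 0
    mc <- mcmc_phylo_lmm(y, matrix(x, ncol = 1, dimnames = list(names(x), "x")),
                         tr, config = mcmc_config(n_iter = 4000, burn_in = 500,
                                                  thin = 5, seed = r))
    cover[r] <- mc$ci95["x", 1] <= 0 && 0 <= mc$ci95["x", 2]
  }
  ## binomial 99% band around 0.95 for 60 draws: ~ [0.87, 1]
  expect_gte(mean(cover), 0.86)
})

test_that("MCMC lambda-equivalent tracks the GLS lambda across signal levels", {
  tr <- yule_tree(80, seed = 16)
  lams <- rep(c(0, 0.5, 1), each = 6)
  gl <- ml <- numeric(length(lams))
  for (i in seq_along(lams)) {
    y <- rbm(tr, seed = 5000 + i, lambda = lams[i])
    X <- matrix(rnorm(80), 80, 1, dimnames = list(names(y), "x"))
    gl[i] <- pgls_fit(y, X, tr)$lambda
    mc <- mcmc_phylo_lmm(y, X, tr, config = mcmc_config(n_iter = 3000,
                                                        burn_in = 500,
                                                        thin = 5, seed = i))
    ml[i] <- mc$lambda_equivalent
  }
  expect_gt(cor(gl, ml), 0.8)
})

test_that("repeatability matches the ANOVA closed form on balanced data", {
  set.seed(17)
  k <- 4; g <- 20
  mu <- rnorm(g, 0, 2)
  vals <- rep(mu, each = k) + rnorm(g * k, 0, 1)
  grp <- rep(paste0("s", seq_len(g)), each = k)
  r <- repeatability(vals, grp, n_boot = 0)
  av <- anova(lm(vals ~ grp))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  r_anova <- (msb - msw) / (msb + (k - 1) * msw)
  expect_lt(abs(r$r - r_anova), 1e-6)
  ## groups internally constant -> r = 1
  ## zero within-group variance is numerically degenerate for REML;
  ## convergence chatter is expected
  r1 <- suppressWarnings(repeatability(rep(mu, each = k), grp, n_boot = 0))
  expect_equal(r1$r, 1, tolerance = 1e-6)
})

test_that("repeatability is near zero for permuted labels and affine-invariant", {
  set.seed(18)
  n_rep <- 10
  rs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    vals <- rnorm(120)
    grp <- sample(rep(paste0("s", 1:30), each = 4))
    rs[i] <- repeatability(vals, grp, n_boot = 0)$r
  }
  expect_lte(mean(rs), 0.1)

  k <- 3; g <- 15
  mu <- rnorm(g); vals <- rep(mu, each = k) + rnorm(g * k, 0, 0.5)
  grp <- rep(paste0("s", 1:g), each = k)
  ra <- repeatability(vals, grp, n_boot = 0)$r
  rb <- repeatability(5 * vals - 3, grp, n_boot = 0)$r
  expect_equal(ra, rb, tolerance = 1e-6)

  expect_error(repeatability(rnorm(5), paste0("s", 1:5), n_boot = 0), "singleton")
})
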