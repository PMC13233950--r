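test_that("log-ratio bias is zero at parity, signed with the female excess", {
  expect_equal(log_ratio_bias(0.2, 0.2), 0)
  expect_equal(log_ratio_bias(0.4, 0.2), log(2))
  expect_error(log_ratio_bias(-0.1, 0.2), "positive")
  expect_true(is.na(log_ratio_bias(NA, 0.2)))

  set.seed(1)
  f <- runif(1000, 0.01, 1); m <- runif(1000, 0.01, 1)
  expect_true(all(sign(log_ratio_bias(f, m)) == sign(f - m)))
})

test_that("size dimorphism is male-over-female and antisymmetric", {
  expect_equal(size_dimorphism(100, 100), 0)
  expect_equal(size_dimorphism(110, 100), log(1.1))
  set.seed(2)
  a <- runif(200, 1, 1000); b <- runif(200, 1, 1000)
  expect_equal(size_dimorphism(a, b), -size_dimorphism(b, a))
})

test_that("mating system bias is the male-minus-female score difference", {
  expect_equal(mating_system_bias(4, 0), 4)
  expect_equal(mating_system_bias(2, 2), 0)
  expect_equal(mating_system_bias(0, 3), -3)
  expect_equal(mating_system_bias(0, 3, orientation = "female_minus_male"), 3)
  expect_error(mating_system_bias(5, 0), "0..4")
})

test_that("plumage PCA: degenerate, orthonormal, and varimax-optimal", {
  ## perfectly correlated regions -> PC1 explains everything
  set.seed(3)
  base <- sample(-2:2, 40, replace = TRUE)
  M <- matrix(base, 40, 5)
  colnames(M) <- paste0("r", 1:5)
  res <- plumage_pc1(M)
  expect_equal(res$explained_variance[1], 1, tolerance = 1e-10)

  ## orthonormal rotated loadings, 2 components
  set.seed(4)
  M2 <- matrix(sample(-2:2, 300, replace = TRUE), 60, 5)
  r2 <- plumage_pc1(M2, ncomp = 2)
  expect_lt(max(abs(crossprod(r2$loadings) - diag(2))), 1e-8)

  ## varimax criterion beats random orthogonal rotations
  vcrit <- function(L) sum(apply(L^2, 2, function(c) mean(c^2) - mean(c)^2))
  p0 <- prcomp(scale(M2), center = FALSE)
  A <- p0$rotation[, 1:2] %*% diag(p0$sdev[1:2])
  ours <- vcrit(A %*% varimax(A, normalize = FALSE)$rotmat)
  set.seed(5)
  rand <- replicate(500, {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    vcrit(A %*% R)
  })
  expect_gte(ours + 1e-12, max(rand))

  ## rotation preserves total communality
  expect_equal(sum((A %*% varimax(A, normalize = FALSE)$rotmat)^2), sum(A^2),
               tolerance = 1e-8)

  expect_error(plumage_pc1(matrix(1, 10, 5)), "constant")
  expect_error(plumage_pc1(matrix(3, 10, 5)), "-2..2")
})

test_that("care PC1 is monotone in its inputs and symmetric to column order", {
  ## correlated synthetic grid: attendance within one point of brooding
  g <- expand.grid(brood = 0:4, attend = 0:4)
  g <- g[abs(g$brood - g$attend) <= 1, ]
  res <- care_pc1(g$brood, g$attend, g$attend, rep("altricial", nrow(g)))
  s <- res$scores[, 1]
  expect_equal(unname(which.max(s)), which(g$brood == 4 & g$attend == 4))
  expect_equal(unname(which.min(s)), which(g$brood == 0 & g$attend == 0))
  ## same-sign loadings -> monotone in each input
  expect_true(all(res$loadings[, 1] > 0))
  for (a in 0:4) {
    idx <- which(g$attend == a)
    sub <- s[idx][order(g$brood[idx])]
    expect_true(all(diff(sub) >= -1e-12))
  }

  ## perfectly correlated columns -> 100% explained
  res2 <- care_pc1(g$brood, g$brood, g$brood, rep("altricial", nrow(g)))
  expect_equal(res2$explained_variance[1], 1, tolerance = 1e-10)

  ## swapping columns flips at most the sign of the scores
  resw <- care_pc1(g$attend, g$brood, g$brood, rep("altricial", nrow(g)))
  cc <- cor(res$scores[, 1], resw$scores[, 1])
  expect_equal(abs(cc), 1, tolerance = 1e-8)

  ## precocial species use defence, not feeding
  r3 <- care_pc1(c(1, 2, 3), c(9, 9, 9) * NA, c(1, 2, 3),
                 c("precocial", "precocial", "precocial"))
  expect_equal(attr(r3, "attendance"), c(1, 2, 3))
})

test_that("residual testes mass obeys the OLS identities", {
  set.seed(6)
  mass <- exp(rnorm(50, 5, 1))
  testes <- 10^(-2 + 0.7 * log10(mass) + rnorm(50, 0, 0.2))
  r <- testes_residual(testes, mass)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(abs(cor(r, log10(mass))), 1e-10)

  ## perfect allometry -> all residuals zero
  t2 <- 10^(-1.5 + 0.66 * log10(mass))
  expect_lt(max(abs(testes_residual(t2, mass))), 1e-10)

  ## closed-form normal-equation oracle
  X <- cbind(1, log10(mass))
  b <- solve(t(X) %*% X, t(X) %*% log10(testes))
  expect_lt(max(abs(r - (log10(testes) - X %*% b))), 1e-10)

  expect_error(testes_residual(c(1, 2), c(10, 20)), "3 species")
})

test_that("composite index is a mean of z-scores with the expected bounds", {
  set.seed(7)
  x <- rnorm(30)
  ## identical components -> composite equals the shared z-score
  expect_equal(composite_index(list(a = x, b = x)), drop(scale(x)), ignore_attr = TRUE)
  ## exact cancellation
  z1 <- drop(scale(rnorm(30)))
  expect_lt(max(abs(composite_index(list(a = z1, b = -z1)))), 1e-10)
  ## mean zero, elementwise bounded by the max |z| of the components
  comp <- list(a = rnorm(30), b = rexp(30), c = runif(30))
  ci <- composite_index(comp)
  expect_lt(abs(mean(ci)), 1e-10)
  zmax <- do.call(pmax, lapply(comp, function(v) abs(drop(scale(v)))))
  expect_true(all(abs(ci) <= zmax + 1e-12))
  ## invariant to affine rescaling of a component
  ci2 <- composite_index(list(a = 3 * comp$a - 7, b = comp$b, c = comp$c))
  expect_equal(ci, ci2, tolerance = 1e-12)
  expect_error(composite_index(list(a = rep(1, 30), b = rnorm(30))), "zero-variance")
})

test_that("BSR merge prefers fledging and records provenance", {
  m <- merge_bsr(c(0.5, NA, NA), c(0.6, 0.4, NA))
  expect_equal(m$bsr, c(0.5, 0.4, NA))
  expect_equal(m$bsr_source, c("fledging", "hatching", NA))
})

test_that("derived table round-trips the generator's latent biases", {
  fx <- toy_records(n = 50, seed = 19)
  tab <- build_derived_table(fx$records)
  fl <- attr(fx$records, "field_latents")
  expect_equal(tab$juv_mort_bias, fl$juv_mort_bias, tolerance = 1e-12)
  expect_equal(tab$ad_mort_bias, fl$ad_mort_bias, tolerance = 1e-12)
  expect_equal(tab$mat_bias, fl$mat_bias, tolerance = 1e-12)
  expect_equal(tab$ssd, fl$ssd, tolerance = 1e-12)
  ## composites are centred
  expect_lt(abs(mean(tab$demography_bias, na.rm = TRUE)), 1e-10)
  ## discretized score columns track their latent drivers
  lat <- attr(fx$records, "latent")
  expect_gt(cor(tab$plumage_pc1, lat$precop_bias), 0.7)
  expect_gt(cor(tab$care_pc1, lat$care_bias), 0.7)
})
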