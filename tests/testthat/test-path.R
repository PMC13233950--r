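test_that("candidate model sets encode the two hypotheses", {
  for (pc in c(TRUE, FALSE)) {
    cands <- candidate_models(include_postcop = pc)
    expect_named(cands, c("1a", "1b", "1c", "2a", "2b", "2c"))
    for (m in cands) expect_false(is.null(topological_order(m)))
    ## H2 mirrors: no edge out of ASR
    for (lb in c("2a", "2b", "2c"))
      expect_false(any(cands[[lb]]$edges[, 1] == "asr"))
    ## H1: demography feeds ASR, never the reverse
    for (lb in c("1a", "1b", "1c")) {
      e <- cands[[lb]]$edges
      expect_true(any(e[, 1] == "demography_bias" & e[, 2] == "asr"))
      expect_false(any(e[, 1] == "asr" & e[, 2] == "demography_bias"))
    }
  }
  ## exact 1a edge set without post-copulatory bias
  e1a <- candidate_models(FALSE)[["1a"]]$edges
  got <- sort(paste(e1a[, 1], e1a[, 2], sep = ">"))
  expect_equal(got, sort(c("demography_bias>asr", "asr>precop_bias",
                           "asr>care_bias")))
  ## node count toggles 5 -> 4
  expect_length(candidate_models(TRUE)[["1a"]]$nodes, 5)
  expect_length(candidate_models(FALSE)[["1a"]]$nodes, 4)
})

test_that("DAG construction rejects cycles, self-loops and duplicates", {
  expect_error(dag_model(rbind(c("a", "b"), c("b", "a"))), "cyclic")
  expect_error(dag_model(rbind(c("a", "a"))), "self-loop")
  expect_error(dag_model(rbind(c("a", "b"), c("a", "b"))), "duplicate")
  m <- dag_model(rbind(c("a", "b"), c("b", "c")))
  expect_equal(topological_order(m), c("a", "b", "c"))
})

test_that("basis set reproduces the textbook cases", {
  chain <- dag_model(rbind(c("A", "B"), c("B", "C")))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$x, "A"); expect_equal(bs[[1]]$y, "C")
  expect_equal(bs[[1]]$conditioning, "B")

  full <- dag_model(rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_length(basis_set(full), 0)

  collider <- dag_model(rbind(c("A", "C"), c("B", "C")))
  bs2 <- basis_set(collider)
  expect_length(bs2, 1)
  expect_setequal(c(bs2[[1]]$x, bs2[[1]]$y), c("A", "B"))
  expect_length(bs2[[1]]$conditioning, 0)
})

test_that("every basis-set claim is d-separated: exhaustive sweep over small DAGs", {
  ## all DAGs on 3 and 4 nodes, plus a deterministic sample on 5
  dags3 <- enumerate_dags(c("a", "b", "c"))
  dags4 <- enumerate_dags(c("a", "b", "c", "d"))
  set.seed(1)
  dags5 <- enumerate_dags(c("a", "b", "c", "d", "e")[1:5])
  dags5 <- dags5[sample(length(dags5), 300)]
  for (dg in c(dags3, dags4, dags5)) {
    bs <- basis_set(dg)
    for (cl in bs) {
      expect_true(dsep_oracle(dg$edges, cl$x, cl$y, cl$conditioning),
                  label = sprintf("claim %s _||_ %s | {%s} in DAG {%s}",
                                  cl$x, cl$y, paste(cl$conditioning, collapse = ","),
                                  paste(paste(dg$edges[, 1], dg$edges[, 2], sep = ">"),
                                        collapse = " ")))
    }
    ## claims cover exactly the non-adjacent pairs
    adj <- nrow(dg$edges)
    n <- length(dg$nodes)
    expect_length(bs, choose(n, 2) - adj)
  }
})

test_that("Fisher's C matches its closed form and is order-invariant", {
  f0 <- fishers_c(numeric(0))
  expect_equal(f0$C, 0); expect_equal(f0$p, 1)
  expect_equal(fishers_c(c(1, 1))$C, 0)
  f <- fishers_c(c(0.05, 0.05))
  expect_equal(f$C, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(f$C, 11.98293, tolerance = 1e-5)
  expect_equal(f$df, 4L)
  set.seed(2)
  p <- runif(7)
  expect_equal(fishers_c(p)$C, fishers_c(rev(p))$C)
  expect_warning(fz <- fishers_c(c(0, 0.5)), "clamped")
  expect_true(is.finite(fz$C))
})

test_that("CICc matches its formula and orders by parameter count", {
  expect_equal(cicc(0, 0, 10), 0)
  expect_equal(cicc(5, 3, 67), 5 + 6 * 67 / 63, tolerance = 1e-10)
  expect_equal(cicc(5, 3, 67), 11.38095, tolerance = 1e-5)
  expect_lt(cicc(5, 2, 50), cicc(5, 3, 50))
  expect_error(cicc(5, 10, 11), "exceed")
})

test_that("claim tests reject perfect dependence and are calibrated under the null", {
  tr <- yule_tree(100, seed = 4)
  x <- rbm(tr, seed = 51)
  dat <- data.frame(species = names(x), a = x, b = x)
  cl <- list(x = "a", y = "b", conditioning = character(0))
  for (fw in c("transform", "residual")) {
    p <- test_claim(cl, dat, tr, framework = fw)$p_value
    expect_lt(p, 1e-10)
  }

  ## null calibration (transform framework): p approximately uniform
  n_rep <- 150
  ps <- numeric(n_rep)
  tr2 <- yule_tree(80, seed = 6)
  for (r in seq_len(n_rep)) {
    d2 <- data.frame(species = tr2$tip.label,
                     a = rbm(tr2, seed = 6000 + r, lambda = 0.5),
                     b = rbm(tr2, seed = 9000 + r, lambda = 0.5))
    ps[r] <- test_claim(cl, d2, tr2, framework = "transform")$p_value
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the two frameworks agree on rejection decisions", {
  tr <- yule_tree(80, seed = 8)
  n_rep <- 20
  agree <- logical(n_rep)
  cl <- list(x = "a", y = "b", conditioning = character(0))
  for (r in seq_len(n_rep)) {
    x <- rbm(tr, seed = 300 + r, lambda = 0.7)
    b <- if (r %% 2 == 0) 0.4 else 0        # mix of real and null effects
    y <- b * x + rbm(tr, seed = 600 + r, lambda = 0.7)
    d <- data.frame(species = names(x), a = x, b = y)
    p1 <- test_claim(cl, d, tr, framework = "transform")$p_value
    p2 <- test_claim(cl, d, tr, framework = "residual")$p_value
    agree[r] <- (p1 < 0.05) == (p2 < 0.05)
  }
  expect_gte(mean(agree), 0.9)
})

test_that("saturated SEM fit meets the exact contract", {
  tr <- yule_tree(60, seed = 10)
  d <- data.frame(species = tr$tip.label,
                  a = rbm(tr, seed = 71), b = rbm(tr, seed = 72),
                  c = rbm(tr, seed = 73))
  Z <- transform_contrasts(d, tr)
  sat <- dag_model(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  f <- sem_fit(sat, Z)
  expect_lt(abs(f$chisq), 1e-8)
  expect_equal(f$cfi, 1)
  expect_equal(f$rmsea, 0)
  expect_lt(f$srmr, 1e-8)
})

test_that("SEM chi-square is calibrated under the generating DAG", {
  n_rep <- 40
  cover <- logical(n_rep)
  dag <- dag_model(rbind(c("x", "y"), c("y", "z")), coefficients = c(0.6, 0.6))
  for (r in seq_len(n_rep)) {
    tr <- yule_tree(120, seed = 20 + r)
    spec <- simulation_spec(n_species = 120, dag = dag, lambdas = 0.7,
                            seed = 100 + r)
    d <- simulate_sem_traits(tr, spec)
    Z <- transform_contrasts(d, tr)
    f <- sem_fit(dag, Z)
    band <- qchisq(c(0.025, 0.975), f$df_model)
    cover[r] <- f$chisq >= band[1] & f$chisq <= band[2]
  }
  ## binomial 99% band around 0.95 with 40 draws
  expect_gte(mean(cover), 0.85)
})

test_that("a grossly mis-specified DAG breaches the fit-index thresholds", {
  ## true model x -> y (effect 0.8) omitted entirely
  n_rep <- 10
  breach <- logical(n_rep)
  true_dag <- dag_model(rbind(c("x", "y")), coefficients = 0.8)
  null_dag <- dag_model(matrix(character(0), 0, 2), nodes = c("x", "y"))
  for (r in seq_len(n_rep)) {
    tr <- yule_tree(200, seed = 40 + r)
    spec <- simulation_spec(n_species = 200, dag = true_dag, lambdas = 0.7,
                            residual_sds = 0.6, seed = 200 + r)
    d <- simulate_sem_traits(tr, spec)
    Z <- transform_contrasts(d, tr)
    f <- sem_fit(null_dag, Z)
    breach[r] <- f$cfi < 0.95 && f$rmsea > 0.06
  }
  expect_gte(mean(breach), 0.9)
})

test_that("model selection scores duplicates identically and respects nesting", {
  tr <- yule_tree(60, seed = 50)
  spec <- simulation_spec(n_species = 60, seed = 51)
  d <- simulate_sem_traits(tr, spec)
  names(d) <- sub("^care_bias$", "care_bias", names(d))
  cands <- candidate_models(TRUE)
  dup <- c(cands["1a"], setNames(cands["1a"], "1a_copy"), cands["2a"])
  dup[["1a_copy"]]$label <- "1a_copy"
  tab <- select_models(dup, d, tr, framework = "residual")
  r1 <- tab[tab$model == "1a", ]; r2 <- tab[tab$model == "1a_copy", ]
  expect_equal(r1$C, r2$C); expect_equal(r1$cicc, r2$cicc)
  expect_equal(abs(r1$delta - r2$delta), 0)

  ## adding an edge never increases C (claims become a subset)
  m_small <- dag_model(rbind(c("demography_bias", "asr")),
                       nodes = c("demography_bias", "asr", "precop_bias"))
  m_big <- dag_model(rbind(c("demography_bias", "asr"), c("asr", "precop_bias")),
                     nodes = c("demography_bias", "asr", "precop_bias"))
  d3 <- d[, c("species", "demography_bias", "asr", "precop_bias")]
  Z3 <- transform_contrasts(d3, tr)
  p_small <- vapply(basis_set(m_small), function(cl)
    test_claim(cl, d3, tr, "transform", Z3)$p_value, 1)
  p_big <- vapply(basis_set(m_big), function(cl)
    test_claim(cl, d3, tr, "transform", Z3)$p_value, 1)
  expect_gte(fishers_c(p_small)$C, fishers_c(p_big)$C)
})

test_that("tree replication reports support frequencies in [0, 1]", {
  spec <- simulation_spec(n_species = 50, seed = 61)
  tr <- simulate_tree(spec)
  d <- simulate_sem_traits(tr, spec)
  cands <- candidate_models(TRUE)[c("1a", "2a")]
  ## identical trees -> frequencies replicate the single-tree result
  trees <- rep(list(tr), 3)
  tu <- tree_uncertainty(cands, d, trees, framework = "residual")
  single <- select_models(cands, d, tr, framework = "residual")
  for (i in seq_len(nrow(tu))) {
    expect_true(tu$support_freq[i] %in% c(0, 1))
    expect_equal(tu$support_freq[i] == 1,
                 single$supported[single$model == tu$model[i]])
  }
  ## perturbed branch lengths -> stable top model for strong signal
  set.seed(62)
  ptrees <- lapply(1:5, function(i) {
    t2 <- tr
    t2$edge.length <- t2$edge.length * exp(rnorm(length(t2$edge.length), 0, 0.05))
    t2
  })
  tu2 <- tree_uncertainty(cands, d, ptrees, framework = "residual")
  expect_gte(tu2$top_freq[tu2$model == "1a"], 0.9)
  expect_true(all(tu2$support_freq >= 0 & tu2$support_freq <= 1))
})

test_that("DAG files round-trip through the edge-list format", {
  m <- candidate_models(TRUE)[["1b"]]
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_dag(m, tf)
  m2 <- read_dag(tf, label = "1b")
  expect_equal(m2$edges, m$edges, ignore_attr = TRUE)
  expect_setequal(m2$nodes, m$nodes)
})
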