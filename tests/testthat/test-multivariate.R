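test_that("NMDS embeds exactly embeddable configurations with ~zero stress", {
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  r3 <- nmds(d3, k = 2, n_restarts = 5, seed = 3)
  expect_lt(r3$stress, 1e-6)   # equilateral triangle is exact in 2-D

  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r4 <- nmds(dist(sq), k = 2, n_restarts = 10, seed = 3)
  expect_lt(r4$stress, 1e-4)

  expect_error(nmds(d3, k = 3), "smaller")
  expect_equal(nrow(tidy(r3)), 3)
  expect_equal(glance(r3)$stress, r3$stress)
})

test_that("dispersion test flags degenerate input and detects planted dispersions", {
  dd <- stats::as.dist(matrix(0, 4, 4))
  deg <- dispersion_test(dd, c("a", "a", "b", "b"))
  expect_true(deg$degenerate)
  expect_equal(deg$p_perm, 1)
  expect_true(all(deg$distances$dist_to_centroid == 0))

  # planted sd 1 vs 2 (4-D Gaussian, n = 20 each): reject >= 90% of 100 sims
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(80, sd = 1), 20), matrix(rnorm(80, sd = 2), 20))
    dispersion_test(dist(x), rep(c("a", "b"), each = 20),
                    n_perm = 99, seed = s)$p_perm < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(dispersion_test(dd, c("a", "a", "a", "a")), "two groups")
})

test_that("dispersion distances-to-centroid coincide with the vegan reference", {
  set.seed(15)
  g <- rep(c("a", "b"), each = 10)
  # Euclidean case and a non-Euclidean (Bray-Curtis) case with negative
  # principal-coordinate eigenvalues
  d_eu <- dist(matrix(rnorm(60), 20))
  d_bc <- vegan::vegdist(matrix(rpois(200, 3), 20) + 0.1, "bray")
  for (d in list(d_eu, d_bc)) {
    mine <- dispersion_test(d, g, n_perm = 9, seed = 1)
    ref <- vegan::betadisper(d, g, type = "centroid")
    expect_equal(mine$distances$dist_to_centroid, unname(ref$distances),
                 tolerance = 1e-10)
  }
})

test_that("PERMANOVA reproduces the exact two-pair partition enumeration", {
  # 2+2 samples, within-distance 0, between-distance 1
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- 0
  m[3, 4] <- m[4, 3] <- 0
  res <- permanova(stats::as.dist(m), c("g1", "g1", "g2", "g2"), exact = TRUE)
  expect_equal(res$R2, 1)
  expect_equal(res$ss_resid, 0)
  expect_true(is.infinite(res$pseudo_F))
  expect_equal(res$p_perm, 1 / 3)   # 3 distinct pairings, one as extreme
})

test_that("PERMANOVA matches adonis2 and is scale invariant", {
  set.seed(3)
  d <- dist(t(matrix(rnorm(200), 10, 20)))
  g <- rep(c("a", "b"), each = 10)
  mine <- permanova(d, g, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-12)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-12)
  expect_equal(mine$ss_among + mine$ss_resid, mine$ss_total, tolerance = 1e-8)

  scaled <- permanova(d * 7, g, n_perm = 199, seed = 5)
  expect_equal(scaled$R2, mine$R2, tolerance = 1e-12)
  expect_equal(scaled$p_perm, mine$p_perm)
})

test_that("PERMANOVA R2 under random labels matches its null expectation", {
  # structureless distances, random 2-group labels: E[R2] = (g-1)/(n-1)
  set.seed(8)
  n <- 16
  r2 <- vapply(1:500, function(i) {
    d <- dist(matrix(rnorm(n * 5), n))
    permanova(d, sample(rep(c("a", "b"), each = n / 2)), n_perm = 1,
              seed = i)$R2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.02)
})

test_that("VIF follows its closed form", {
  set.seed(2)
  n <- 200
  v1 <- rnorm(n)
  u <- rnorm(n)
  u <- residuals(lm(u ~ v1))          # exactly orthogonal complement
  v2 <- 0.8 * scale(v1) + sqrt(1 - 0.64) * scale(u)  # empirical cor = 0.8
  v3 <- rnorm(n)
  env <- data.frame(v1 = as.numeric(scale(v1)), v2 = as.numeric(v2), v3 = v3)
  vifs <- vif_scores(env)
  expect_equal(unname(vifs["v1"]), 1 / (1 - 0.64), tolerance = 0.05)
  expect_equal(unname(vifs["v2"]), 1 / (1 - 0.64), tolerance = 0.05)
  expect_lt(vifs["v3"], 1.1)

  dup <- data.frame(a = v1, b = v1)
  expect_equal(unname(vif_scores(dup)), c(Inf, Inf))
})

test_that("constrained ordination recovers a perfect linear response", {
  set.seed(1)
  env <- data.frame(v1 = rnorm(20), v2 = rnorm(20))
  Y <- outer(rnorm(10), env$v1)      # taxa x samples, exact function of v1
  co <- suppressMessages(constrained_ordination(Y, env, n_perm = 99, seed = 2))
  expect_gte(co$constrained_proportion, 0.999)

  # cross-check the constrained proportion against a direct trace computation
  set.seed(4)
  Y2 <- matrix(rnorm(200), 10, 20)
  co2 <- constrained_ordination(Y2, env, n_perm = 99, seed = 2)
  Yc <- scale(t(Y2), scale = FALSE)
  X <- scale(as.matrix(env))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(co2$constrained_proportion,
               sum((H %*% Yc)^2) / sum(Yc^2), tolerance = 1e-8)
  # adding a constraint never decreases the constrained proportion
  env3 <- cbind(env, v3 = rnorm(20))
  co3 <- constrained_ordination(Y2, env3, n_perm = 99, seed = 2)
  expect_gte(co3$constrained_proportion, co2$constrained_proportion - 1e-12)

  expect_error(constrained_ordination(Y2 - 100, env, method = "cca"),
               "non-negative")
})

test_that("marginal tests single out the generating variable, order-independently", {
  set.seed(6)
  n <- 30
  env <- data.frame(driver = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  Y <- outer(rnorm(15), env$driver) + matrix(rnorm(15 * n, sd = 0.2), 15, n)
  p <- marginal_terms_test(Y, env, n_perm = 199, seed = 9)
  expect_lte(p$p[p$variable == "driver"], 0.01)
  expect_gt(min(p$p[p$variable != "driver"]), 0.05)

  # permuting the variable order leaves each variable's p unchanged
  p_rev <- marginal_terms_test(Y, env[, c(3, 1, 2)], n_perm = 199, seed = 9)
  expect_equal(p$p[match(p_rev$variable, p$variable)], p_rev$p)

  # a near-duplicated pair partials each other out: the driver loses its
  # significance once its copy is held as a covariable
  env_dup <- data.frame(driver = env$driver,
                        copy = env$driver + rnorm(n, sd = 0.01))
  p_dup <- marginal_terms_test(Y, env_dup, n_perm = 199, seed = 9)
  expect_true(all(p_dup$p > 0.05))
})
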