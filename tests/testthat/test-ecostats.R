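test_that("CCA eigenvalues match the dense generalized-eigen oracle", {
  set.seed(12)
  for (trial in 1:5) {
    Y <- matrix(rpois(15, 20) + 1, 5, 3)   # 5 samples x 3 variants
    env <- data.frame(temperature_C = c(55, 60, 62, 65, 68),
                      depth_um = c(100, 300, 500, 620, 640))
    res <- ccaOrdination(t(Y), env)
    oracle <- ccaOracle(Y, as.matrix(env))
    expect_equal(unname(res$eigenvalues),
                 oracle$eig[seq_along(res$eigenvalues)], tolerance = 1e-8)
    expect_equal(res$totalInertia, oracle$totalInertia, tolerance = 1e-8)
    expect_equal(res$constrainedInertia, oracle$constrained,
                 tolerance = 1e-8)
  }
})

test_that("single-predictor toy table matches the oracle to 1e-8", {
  Y <- matrix(c(10, 2, 1, 3, 12, 2, 1, 4, 9), 3, 3)
  env <- data.frame(temperature_C = c(55, 60, 65))
  res <- ccaOrdination(t(Y), env, predictors = "temperature_C")
  oracle <- ccaOracle(Y, as.matrix(env))
  expect_equal(unname(res$eigenvalues[1]), oracle$eig[1], tolerance = 1e-8)
})

test_that("inertia decomposition is exact and invariances hold", {
  set.seed(3)
  Y <- matrix(rpois(40, 15) + 1, 8, 5)
  env <- data.frame(temperature_C = seq(55, 69, 2),
                    depth_um = c(200, 600, 300, 500, 150, 640, 420, 330))
  res <- ccaOrdination(t(Y), env)
  m <- res$model
  expect_equal(m$CCA$tot.chi + m$CA$tot.chi, m$tot.chi, tolerance = 1e-8)
  # duplicating every sample leaves the eigenvalues unchanged
  Y2 <- rbind(Y, Y); env2 <- rbind(env, env)
  res2 <- ccaOrdination(t(Y2), env2)
  expect_equal(res2$eigenvalues, res$eigenvalues, tolerance = 1e-10)
  expect_error(ccaOrdination(t(Y), transform(env, depth_um = 1)),
               "degenerate")
})

test_that("shuffled environment explains almost nothing", {
  set.seed(8)
  # strong true gradient structure; the null expectation of the
  # constrained fraction is about q/(n-1), so n is sized to keep it small
  n <- 80
  env <- data.frame(temperature_C = seq(55, 70, length.out = n),
                    depth_um = rep(c(100, 300, 500, 700), n / 4))
  Y <- sapply(1:12, function(v) {
    opt <- 55 + 15 * (v / 12)
    rpois(n, 5 + 40 * exp(-(env$temperature_C - opt)^2 / 8))
  })
  fracs <- replicate(20, {
    envS <- env[sample.int(n), ]
    rownames(envS) <- NULL
    ccaOrdination(t(Y), envS)$explainedFraction
  })
  expect_lt(mean(fracs), 0.05)
  # while the true labels explain far more
  expect_gt(ccaOrdination(t(Y), env)$explainedFraction, 0.2)
})

test_that("ordination cluster test flags planted tight clusters", {
  set.seed(9)
  background <- matrix(rnorm(120, sd = 2), 60, 2)
  cluster <- matrix(rnorm(12, sd = 0.05), 6, 2)
  pts <- rbind(cluster, background)
  res <- ordtestCluster(pts, 1:6, nPerm = 999, seed = 1)
  expect_lte(res$p, 0.005)
  # a random subset of the same cloud is unremarkable
  res2 <- ordtestCluster(background, sample.int(60, 6), nPerm = 199,
                         seed = 2)
  expect_gt(res2$p, 0.05)
  expect_error(ordtestCluster(pts, 1:6, nPerm = 0), "nPerm")
  expect_false(ordtestCluster(pts, 1, nPerm = 99)$testable)
})

test_that("shrinking a planted cluster never increases its p-value", {
  set.seed(10)
  background <- matrix(rnorm(80, sd = 2), 40, 2)
  shape <- matrix(rnorm(10), 5, 2)
  ps <- vapply(c(1, 0.5, 0.2, 0.05), function(scl) {
    pts <- rbind(shape * scl, background)
    ordtestCluster(pts, 1:5, nPerm = 499, seed = 77)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("G statistic follows its closed form", {
  expect_equal(gTest(matrix(c(10, 10, 10, 10), 2))$G, 0)
  tab <- matrix(c(30, 10, 10, 30), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(gTest(tab)$G, 2 * sum(tab * log(tab / E)), tolerance = 1e-10)
  expect_equal(gTest(tab)$df, 1L)
  # equivalence with the 2n * KL formulation on random tables
  set.seed(4)
  for (i in 1:10) {
    tb <- matrix(rpois(12, 20) + 1, 3, 4)
    n <- sum(tb)
    p <- tb / n
    q <- outer(rowSums(tb), colSums(tb)) / n^2
    expect_equal(gTest(tb)$G, 2 * n * sum(p * log(p / q)),
                 tolerance = 1e-10)
  }
  expect_warning(g0 <- gTest(rbind(c(5, 5), c(0, 0), c(2, 8))), "zero")
  expect_equal(g0$df, 1L)
})

test_that("divergent PE responses produce a significant interaction", {
  # PE1 grows 4-fold while PE2 shrinks, deterministic expected counts
  times <- c(0, 2, 4)
  pe1 <- c(200, 450, 800)
  pe2 <- c(800, 550, 400)
  other <- 2000 - pe1 - pe2
  counts <- rbind(PE1 = pe1, PE2 = pe2, other = other)
  colnames(counts) <- times
  res <- perturbationTrend(counts)
  expect_lt(res$interactionP, 0.01)
  expect_equal(res$perPE$direction[1:2], c("up", "down"))
  expect_error(perturbationTrend(counts[, 1, drop = FALSE]), "timepoints")
  # the arcsine ANCOVA mode runs and agrees on direction
  res2 <- perturbationTrend(counts, mode = "ancova")
  expect_equal(res2$perPE$direction[1], "up")
})

test_that("held-constant HFS shares give flat homogeneity slopes", {
  # PE total changes 5-fold; within-PE composition fixed at 50/30/20
  times <- c(0, 2, 4)
  tot <- c(300, 800, 1500)
  counts <- rbind(h1 = round(0.5 * tot), h2 = round(0.3 * tot),
                  lfs = round(0.2 * tot))
  colnames(counts) <- times
  res <- withinPEHomogeneity(counts, c("dominant", "HFS", "LFS"))
  expect_true(all(res$p > 0.3))
  expect_true(all(abs(res$slope) < 0.05))
  expect_true("LFS:HFS" %in% res$component)
})
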