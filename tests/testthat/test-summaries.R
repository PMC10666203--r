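# Summary statistics, weighted distances, adaptive weighting, and
# inverse-regression summary construction.

test_that("count_timeseries extracts observable counts on the time grid", {
  tr <- runViralModel(viralParams(beta_cf = 0, beta_cc = 0, t_end = 3,
                                  delta_death = 0),
                      seed = 1, times = 0:3, width = 9, height = 9)
  stats <- data.frame(statistic_id = "inf", function_id = "count_timeseries",
                      args = "times=0,1,2,3;observable=infected_count",
                      observable_ids = "infected_count")
  s <- computeSummaries(tr, stats)
  expect_equal(unname(s), rep(1, 4))
  expect_equal(names(s), paste0("inf_t", 0:3))

  dead <- data.frame(statistic_id = "d", function_id = "count_timeseries",
                     args = "times=0,3;observable=dead_count",
                     observable_ids = "dead_count")
  expect_equal(unname(computeSummaries(tr, dead)), c(0, 0))

  missing <- data.frame(statistic_id = "m", function_id = "count_timeseries",
                        args = "times=0,7;observable=infected_count",
                        observable_ids = "infected_count")
  expect_error(computeSummaries(tr, missing), "alignment error")
})

test_that("patch radius of a single infected site is sqrt(1/pi)", {
  tr <- runViralModel(viralParams(beta_cf = 0, beta_cc = 0, t_end = 1,
                                  delta_death = 0),
                      seed = 1, times = 0:1, width = 9, height = 9)
  stats <- data.frame(statistic_id = "r",
                      function_id = "patch_radius_timeseries",
                      args = "times=0,1", observable_ids = "patch_radius")
  s <- computeSummaries(tr, stats)
  expect_equal(unname(s), rep(sqrt(1 / pi), 2))
})

test_that("radial profile matches a by-hand site enumeration on a 7x7 grid", {
  m <- matrix(0, 7, 7)
  m[4, 4] <- 1; m[4, 5] <- 1; m[2, 2] <- 1; m[1, 4] <- 1
  got <- radialProfile(m, 3)
  # independent enumeration: centre (4,4), R = 3.5, bin width 3.5/3
  vals <- list(numeric(), numeric(), numeric())
  for (i in 1:7) for (j in 1:7) {
    r <- sqrt((i - 4)^2 + (j - 4)^2)
    if (r >= 3.5) next
    b <- min(floor(r / (3.5 / 3)) + 1, 3)
    vals[[b]] <- c(vals[[b]], m[i, j])
  }
  expect_equal(got, vapply(vals, mean, numeric(1)))
})

test_that("final_fraction reports a state's share of the lattice", {
  tr <- runViralModel(viralParams(beta_cf = 0, beta_cc = 0, t_end = 1,
                                  delta_death = 0),
                      seed = 1, times = 0:1, width = 10, height = 10)
  stats <- data.frame(statistic_id = "frac", function_id = "final_fraction",
                      args = "state=infected", observable_ids = "x")
  expect_equal(unname(computeSummaries(tr, stats)), 1 / 100)
})

test_that("unknown registry functions are rejected", {
  stats <- data.frame(statistic_id = "z", function_id = "no_such_fn",
                      args = "", observable_ids = "x")
  expect_error(computeSummaries(list(), stats), "registry error")
})

test_that("weighted distance satisfies its closed forms and alignment rules", {
  specL2 <- distanceSpec(c(a = 1, b = 1), p = 2, adapt = "none")
  expect_equal(statDistance(c(a = 1, b = 2), c(a = 1, b = 2), specL2), 0)
  expect_equal(statDistance(c(a = 3, b = 4), c(a = 0, b = 0), specL2), 5)
  specL1 <- distanceSpec(c(a = 2, b = 0), p = 1, adapt = "none")
  expect_equal(statDistance(c(a = 1, b = 7), c(a = 0, b = 0), specL1), 2)
  expect_error(statDistance(c(a = 1, b = 2), c(a = 1, x = 2), specL2),
               "alignment error")
})

test_that("distance is a pseudo-metric for p in {1, 2}", {
  set.seed(12)
  for (p in c(1, 2)) {
    w <- setNames(runif(4, 0.1, 2), letters[1:4])
    spec <- distanceSpec(w, p = p, adapt = "none")
    for (i in 1:50) {
      x <- setNames(rnorm(4), letters[1:4])
      y <- setNames(rnorm(4), letters[1:4])
      z <- setNames(rnorm(4), letters[1:4])
      expect_gte(statDistance(x, y, spec), 0)
      expect_equal(statDistance(x, y, spec), statDistance(y, x, spec))
      expect_lte(statDistance(x, z, spec),
                 statDistance(x, y, spec) + statDistance(y, z, spec) + 1e-12)
    }
  }
})

test_that("adaptive weights are reciprocal scales with a zero-scale guard", {
  # exact sd construction: columns with sd 1 and sd 10
  x <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  m <- cbind(s1 = x, s2 = 10 * x)
  expect_equal(unname(adaptWeights(m, "sd")), c(1, 0.1))
  # constant statistic gets weight 0 with a warning
  m2 <- cbind(s1 = x, s2 = rep(3, 3))
  expect_warning(w <- adaptWeights(m2, "mad"), "zero scale")
  expect_equal(unname(w[2]), 0)
})

test_that("mad weights match a direct median-of-absolute-deviations oracle", {
  set.seed(13)
  m <- cbind(a = rlnorm(200), b = rlnorm(200, sdlog = 2))
  w <- adaptWeights(m, "mad")
  oracle <- apply(m, 2, function(x) 1 / median(abs(x - median(x))))
  expect_equal(w, oracle)
})

test_that("adaptive weights are scale-equivariant", {
  set.seed(14)
  m <- cbind(a = rnorm(100), b = rexp(100))
  for (scheme in c("mad", "sd")) {
    w <- adaptWeights(m, scheme)
    m2 <- m; m2[, 1] <- 5 * m2[, 1]
    w2 <- adaptWeights(m2, scheme)
    expect_equal(w2[1], w[1] / 5)
    expect_equal(w2[2], w[2])
  }
})

test_that("regression statistics recover an exact linear relation", {
  set.seed(15)
  s <- cbind(s1 = runif(50), s2 = runif(50), s3 = runif(50))
  theta <- cbind(th = 2 * s[, 1] - 1)
  map <- fitRegressionStatistics(theta, s)
  expect_equal(unname(map$b0), -1, tolerance = 1e-8)
  expect_equal(unname(map$B[1, ]), c(2, 0, 0), tolerance = 1e-8)
})

test_that("duplicated summary columns trigger the ridge fallback", {
  set.seed(16)
  s <- cbind(s1 = runif(60), s2 = runif(60))
  s <- cbind(s, s3 = s[, 1])  # exact duplicate
  theta <- cbind(th = 3 * s[, 1] + rnorm(60, 0, 0.01))
  expect_message(map <- fitRegressionStatistics(theta, s), "ridge")
  sOk <- s[, 1:2]
  mapOk <- fitRegressionStatistics(theta, sOk)
  pred <- map$b0 + map$B %*% t(s)
  predOk <- mapOk$b0 + mapOk$B %*% t(sOk)
  expect_equal(as.numeric(pred), as.numeric(predOk), tolerance = 1e-6)
})

test_that("regression slope agrees with the analytic value on a Gaussian toy", {
  set.seed(17)
  n <- 500
  theta <- rnorm(n)
  s <- theta + rnorm(n, 0, 0.1)
  map <- fitRegressionStatistics(cbind(th = theta), cbind(s = s))
  slopeExpected <- 1 / (1 + 0.1^2)
  se <- sqrt((1 - 1 / (1 + 0.01)) / (n * (1 + 0.01)))
  expect_lt(abs(map$B[1, 1] - slopeExpected), 3 * se)
})

test_that("projected distance is invariant to affine reparameterisation", {
  set.seed(18)
  n <- 80
  theta <- cbind(th = rnorm(n))
  s <- cbind(s1 = theta[, 1] + rnorm(n, 0, 0.2), s2 = rnorm(n))
  mapA <- fitRegressionStatistics(theta, s)
  # affine reparameterisation of the raw statistics
  s2 <- cbind(s1 = 3 * s[, 1] + 1, s2 = -0.5 * s[, 2] + 2)
  mapB <- fitRegressionStatistics(theta, s2)
  specA <- distanceSpec(c(th = 1), adapt = "none", regressionMap = mapA)
  specB <- distanceSpec(c(th = 1), adapt = "none", regressionMap = mapB)
  for (i in 1:20) {
    a <- c(s1 = rnorm(1), s2 = rnorm(1))
    b <- c(s1 = rnorm(1), s2 = rnorm(1))
    a2 <- c(s1 = 3 * a[[1]] + 1, s2 = -0.5 * a[[2]] + 2)
    b2 <- c(s1 = 3 * b[[1]] + 1, s2 = -0.5 * b[[2]] + 2)
    expect_equal(statDistance(a, b, specA), statDistance(a2, b2, specB),
                 tolerance = 1e-8)
  }
})

test_that("observed summaries mirror the simulated statistic layout", {
  obs <- observedSummaries(viralProblem)
  expect_equal(names(obs),
               c(paste0("infected_ts_t", 0:10), paste0("radial10_bin", 1:5)))
  expect_equal(unname(obs[1]), 1)  # one infected cell at t = 0
})
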