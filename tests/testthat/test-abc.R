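# ABC-SMC engine: priors, perturbation kernel, importance weights, epsilon
# schedule, early rejection, and the generation loop's invariants.

test_that("prior sampling matches each declared prior", {
  prob <- toyProblem
  par <- prob@parameters

  # uniform(0, 1)
  par$prior_kind[1] <- "uniform"; par$prior_arg1[1] <- 0
  par$prior_arg2[1] <- 1; prob@parameters <- par
  set.seed(1)
  th <- samplePrior(prob, 1e4)
  expect_lt(abs(mean(th) - 0.5), 3 * sqrt(1 / 12 / 1e4))

  # log10-uniform(1e-2, 1e2): uniform on [-2, 2]
  par$prior_kind[1] <- "log10-uniform"; par$scale[1] <- "log10"
  par$prior_arg1[1] <- 1e-2; par$prior_arg2[1] <- 1e2
  prob@parameters <- par
  set.seed(2)
  th <- samplePrior(prob, 2000)
  ks <- suppressWarnings(ks.test(th, "punif", -2, 2))
  expect_gt(ks$p.value, 0.01)

  # normal(5, 1)
  par$prior_kind[1] <- "normal"; par$scale[1] <- "lin"
  par$prior_arg1[1] <- 5; par$prior_arg2[1] <- 1
  prob@parameters <- par
  set.seed(3)
  th <- samplePrior(prob, 1e4)
  expect_lt(abs(mean(th) - 5), 3 / sqrt(1e4))
})

test_that("perturbation respects degenerate kernels and prior support", {
  prob <- toyProblem
  par <- prob@parameters
  par$prior_kind[1] <- "uniform"; par$prior_arg1[1] <- 0
  par$prior_arg2[1] <- 1; prob@parameters <- par
  prev <- matrix(runif(20), 20, 1)
  w <- rep(1 / 20, 20)
  # zero covariance: particle returned unchanged
  expect_equal(perturbParticle(0.42, prob, prev, w, matrix(0, 1, 1)), 0.42)
  # wide kernel near the boundary: every return stays inside support
  set.seed(4)
  out <- replicate(200, perturbParticle(0.999, prob, prev, w,
                                        matrix(4, 1, 1)))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("kernel covariance follows the weighted previous population", {
  set.seed(5)
  th <- matrix(rnorm(400, sd = 2), ncol = 1)
  w <- runif(400); w <- w / sum(w)
  v <- tissueABC:::weightedCovariance(th, w)[1, 1]
  # oracle: direct weighted variance with unbiasedness correction
  mu <- sum(w * th)
  vOracle <- sum(w * (th - mu)^2) / (1 - sum(w^2))
  expect_equal(v, vOracle, tolerance = 1e-12)
  # proposals drawn with kernel cov 2v have sample variance approx 2v
  set.seed(6)
  prop <- replicate(1e5, 0 + sqrt(2 * v) * rnorm(1))
  expect_lt(abs(var(prop) - 2 * v), 3 * 2 * v * sqrt(2 / 1e5))
})

test_that("importance weights reduce to the one-particle formula", {
  prob <- toyProblem
  par <- prob@parameters
  par$prior_kind[1] <- "uniform"; par$prior_arg1[1] <- -5
  par$prior_arg2[1] <- 5; prob@parameters <- par
  prev <- matrix(1.3, 1, 1)
  cov <- matrix(0.49, 1, 1)
  for (thNew in c(-1, 0.2, 2.4)) {
    w <- importanceWeight(thNew, prob, prev, 1, cov)
    expect_equal(w, dunif(thNew, -5, 5) / dnorm(thNew, 1.3, 0.7),
                 tolerance = 1e-12)
  }
  # the vectorised engine path agrees with the per-particle formula
  ctx <- tissueABC:::buildEngineContext(prob)
  thetas <- matrix(c(-1, 0.2, 2.4), ncol = 1)
  wBatch <- tissueABC:::batchImportanceWeights(ctx, thetas, prev, 1,
                                               chol(cov))
  wRef <- vapply(thetas[, 1], importanceWeight, numeric(1), p = prob,
                 prevThetas = prev, prevWeights = 1, kernelCov = cov)
  expect_equal(wBatch, wRef / sum(wRef), tolerance = 1e-10)
})

test_that("the epsilon rule is the type-1 quantile, clamped non-increasing", {
  expect_equal(nextEpsilon(1:10, 0.5), 5)
  expect_equal(nextEpsilon(rep(3.3, 7), 0.5), 3.3)
  expect_equal(nextEpsilon(1:10, 0.999), 10)
  expect_equal(nextEpsilon(1:10, 0.5, previous = 4), 4)
  expect_error(nextEpsilon(numeric(), 0.5), "empty")
})

test_that("early rejection budgets bind exactly when they should", {
  theta <- log10(c(0.05, 0.2))
  full <- evaluateParticle(theta, viralProblem, seed = 7)
  wide <- evaluateParticle(theta, viralProblem, budget = 1e6, seed = 7)
  expect_identical(full, wide)  # non-binding budget changes nothing
  none <- evaluateParticle(theta, viralProblem, budget = 0, seed = 7)
  expect_true(none$earlyRejected)
  expect_equal(none$distance, Inf)
})

test_that("the engine satisfies its population invariants and reproduces", {
  cfg <- abcConfig(populationSize = 150, maxGenerations = 4, seed = 42)
  s1 <- runABC(toyProblem, cfg, distance = toyDistance)
  s2 <- runABC(toyProblem, cfg, distance = toyDistance)

  expect_equal(nGenerations(s1), 4)
  eps <- epsilonTrajectory(s1)$epsilon
  expect_true(all(diff(eps) <= 0))
  for (g in generations(s1)) {
    pp <- particles(g)
    expect_equal(sum(pp$weight), 1, tolerance = 1e-12)
    expect_true(all(pp$weight >= 0))
    expect_true(all(pp$distance <= g@epsilon))
    expect_gte(g@totalProposals, nrow(pp))
  }
  # generation 1 weights are uniform
  expect_equal(particles(generations(s1)[[1]])$weight, rep(1 / 150, 150))
  # identical seeds give identical runs
  expect_identical(particles(s1), particles(s2))
  expect_identical(particleSummaries(s1), particleSummaries(s2))
})

test_that("a fixed epsilon schedule overrides the adaptive rule", {
  cfg <- abcConfig(populationSize = 100, maxGenerations = 2, seed = 5,
                   epsilonSchedule = c(Inf, 0.5))
  store <- runABC(toyProblem, cfg, distance = toyDistance)
  expect_equal(epsilonTrajectory(store)$epsilon, c(Inf, 0.5))
  expect_true(all(particles(store)$distance <= 0.5))
})

test_that("rejection sampling accepts exactly the ball around the data", {
  rej <- rejectionSample(toyProblem, epsilon = 0.4, n = 200, seed = 8)
  expect_equal(nrow(rej), 200)
  expect_true(all(rej$distance <= 0.4))
  expect_gte(attr(rej, "proposals"), 200)
})

test_that("replicate measurements average summaries before the distance", {
  dir <- file.path(tempdir(), "replicated")
  makeGaussianToy(dir)
  tab <- read.delim(file.path(dir, "measurements.tsv"), sep = "\t",
                    colClasses = "character", check.names = FALSE)
  tab <- rbind(tab, tab)
  tab$replicate_id <- c("r1", "r2")
  tab$value <- c("0.5", "1.5")
  write.table(tab, file.path(dir, "measurements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prob <- parseProblem(file.path(dir, "problem.yaml"))
  expect_equal(unname(observedSummaries(prob)), 1)  # replicates averaged
  ev <- evaluateParticle(0.3, prob, seed = 9)
  # two independent replicate simulations were averaged: with theta = 0.3
  # the summary is 0.3 + mean of two standard-normal draws
  set.seed(9)
  expect_equal(unname(ev$summaries), 0.3 + mean(rnorm(2)), tolerance = 1e-12)
})
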