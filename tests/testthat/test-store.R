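# Result store persistence and posterior diagnostics.

smallStore <- runABC(toyProblem,
                     abcConfig(populationSize = 60, maxGenerations = 3,
                               seed = 33),
                     distance = toyDistance)

test_that("a store survives the file round trip field-by-field", {
  path <- file.path(tempdir(), "store.json")
  saveResultStore(smallStore, path)
  back <- loadResultStore(path)
  expect_equal(back@problemFingerprint, smallStore@problemFingerprint)
  expect_identical(back@observedSummaries, smallStore@observedSummaries)
  expect_equal(length(back@generations), length(smallStore@generations))
  for (i in seq_along(back@generations)) {
    a <- back@generations[[i]]; b <- smallStore@generations[[i]]
    expect_identical(a@particles$weight, b@particles$weight)
    expect_identical(a@particles$distance, b@particles$distance)
    expect_identical(a@particles$theta, b@particles$theta)
    expect_identical(a@epsilon, b@epsilon)
    expect_identical(a@totalProposals, b@totalProposals)
    expect_identical(a@wallSeconds, b@wallSeconds)
    expect_identical(as.numeric(a@summaries), as.numeric(b@summaries))
  }
  expect_identical(back@config$seed, smallStore@config$seed)
})

test_that("ess spans its closed-form extremes", {
  expect_equal(ess(rep(1 / 1000, 1000)), 1000)
  expect_equal(ess(c(1, rep(0, 9))), 1)
  expect_equal(ess(c(0.5, 0.5)), 2)
  expect_error(ess(c(0.5, 0.2)), "domain error")
  set.seed(2)
  for (i in 1:20) {
    w <- runif(50); w <- w / sum(w)
    expect_gte(ess(w), 1)
    expect_lte(ess(w), 50 + 1e-9)
  }
})

test_that("credible intervals reduce to type-1 quantiles for equal weights", {
  set.seed(3)
  x <- rnorm(101)
  ci <- credibleInterval(x, rep(1 / 101, 101), 0.9)
  expect_equal(unname(ci[1, ]),
               unname(quantile(x, c(0.05, 0.95), type = 1)))
  # all mass on one sample: zero-width interval at that value
  w <- c(rep(0, 50), 1, rep(0, 50))
  ci <- credibleInterval(x, w, 0.95)
  expect_equal(unname(ci[1, 1]), x[51])
  expect_equal(unname(ci[1, 2]), x[51])
})

test_that("interval width is non-increasing in narrower levels", {
  set.seed(4)
  x <- rexp(400)
  w <- runif(400); w <- w / sum(w)
  widths <- vapply(c(0.5, 0.8, 0.95, 0.99), function(lv) {
    ci <- credibleInterval(x, w, lv); ci[1, 2] - ci[1, 1]
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("store trajectories copy the per-generation records", {
  tr <- epsilonTrajectory(smallStore)
  expect_equal(nrow(tr), 3)
  expect_true(all(diff(tr$epsilon) <= 0))
  sp <- samplesPerGeneration(smallStore)
  expect_equal(sp$N, rep(60L, 3))
  expect_true(all(sp$total_proposals >= sp$N))
})

test_that("weighted kde2d integrates to one and is maximal at a lone sample", {
  # a single sample: unimodal kernel peaked at the nearest grid node
  k <- kde2d(0, 0, weights = 1, n = 33)
  peak <- which(k$density == max(k$density), arr.ind = TRUE)
  expect_equal(k$x[peak[1]], 0, tolerance = 0.2)
  expect_equal(k$y[peak[2]], 0, tolerance = 0.2)

  set.seed(5)
  x <- rnorm(3000); y <- rnorm(3000)
  k <- kde2d(x, y, n = 64)
  # trapezoid-rule mass
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  wx <- rep(1, 64); wx[c(1, 64)] <- 0.5
  mass <- as.numeric(t(wx) %*% k$density %*% wx) * dx * dy
  expect_equal(mass, 1, tolerance = 1e-3)
  # pointwise agreement with the standard bivariate normal density
  ref <- outer(k$x, k$y, function(a, b) dnorm(a) * dnorm(b))
  expect_lt(max(abs(k$density - ref)), 0.02)
})

test_that("kde2d mass follows the weights across separated clusters", {
  set.seed(6)
  n <- 1000
  x <- c(rnorm(n, -6, 0.5), rnorm(n, 6, 0.5))
  y <- c(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  w <- c(rep(3, n), rep(1, n)); w <- w / sum(w)
  k <- kde2d(x, y, w, n = 96)
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  left <- sum(k$density[k$x < 0, ]) * dx * dy
  right <- sum(k$density[k$x >= 0, ]) * dx * dy
  expect_equal(left / (left + right), 0.75, tolerance = 0.05 * 0.75)
})

test_that("kde2d rejects zero-variance input", {
  expect_error(kde2d(rep(1, 10), 1:10, rep(0.1, 10)), "degenerate-KDE")
})

test_that("the exporter writes every diagnostic table", {
  dir <- file.path(tempdir(), "export")
  exportResultStore(smallStore, dir)
  expect_true(file.exists(file.path(dir, "epsilon_trajectory.tsv")))
  expect_true(file.exists(file.path(dir, "ess.tsv")))
  expect_true(file.exists(file.path(dir, "samples_per_generation.tsv")))
  expect_true(file.exists(file.path(dir, "ci_95.tsv")))
  eps <- read.delim(file.path(dir, "epsilon_trajectory.tsv"))
  expect_equal(nrow(eps), 3)
})
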