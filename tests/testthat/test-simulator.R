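# Lattice simulator: diffusion physics, infection dynamics, the compiled
# run kernel, and the cellular Potts kernel.

test_that("diffusion leaves a uniform field unchanged and checks stability", {
  f <- matrix(3.7, 9, 9)
  expect_equal(diffusionStep(f, D = 0.2, decay = 0, source = 0, dt = 1), f)
  expect_error(diffusionStep(f, D = 1, decay = 0, source = 0, dt = 1),
               "unstable")
})

test_that("zero-flux diffusion conserves mass to machine precision", {
  set.seed(4)
  f <- matrix(runif(30 * 20), 30, 20)
  for (i in 1:50) f2 <- diffusionStep(f, D = 0.24, decay = 0, source = 0,
                                      dt = 1)
  expect_equal(sum(f2), sum(f), tolerance = 1e-14)
})

test_that("diffusion stays non-negative with and without clipping", {
  set.seed(5)
  # inside the convex-combination bound 4*D*dt + decay*dt <= 1: no clipping
  f <- matrix(runif(15 * 15), 15, 15)
  for (i in 1:100) {
    f <- diffusionStep(f, D = 0.15, decay = 0.4, source = 0, dt = 1)
    expect_true(all(f >= 0))
  }
  # outside the bound the update clips at zero
  f <- matrix(runif(15 * 15), 15, 15)
  for (i in 1:100) {
    f <- diffusionStep(f, D = 0.2, decay = 0.9, source = 0, dt = 1)
    expect_true(all(f >= 0))
  }
})

test_that("infection probability follows the two-route hazard", {
  p <- viralParams(beta_cf = 0.3, beta_cc = 0.1, dt = 1, D = 0.2)
  expect_equal(infectionProbability(0, 0, p), 0)
  expect_equal(infectionProbability(0, 2, p), 1 - exp(-0.2))
  expect_equal(infectionProbability(2, 1, p), 1 - exp(-0.7))
  # monotone in both arguments, saturating at 1
  expect_true(all(diff(infectionProbability(seq(0, 50, 1), 0, p)) > 0))
  expect_equal(infectionProbability(1e6, 4, p), 1)
})

test_that("a zero-infected state only decays its field", {
  st <- latticeState(11, 11, infected = NULL,
                     field = matrix(2, 11, 11))
  p <- viralParams(c_decay = 0.5, dt = 0.1, t_end = 1)
  set.seed(1)
  st2 <- viralStep(st, p)
  expect_equal(cellStates(st2), cellStates(st))
  expect_equal(virionField(st2), matrix(2 * (1 - 0.5 * 0.1), 11, 11))
  expect_equal(latticeTime(st2), 0.1)
})

test_that("with zero transmission rates the infected count never grows", {
  p <- viralParams(beta_cf = 0, beta_cc = 0, t_end = 3)
  tr <- runViralModel(p, seed = 2, times = seq(0, 3, 0.5), width = 15,
                      height = 15)
  expect_true(all(diff(tr$counts$infected_count) <= 0))
})

test_that("cell counts are conserved along a trajectory", {
  tr <- runViralModel(viralParams(t_end = 5), seed = 3, times = 0:5,
                      width = 25, height = 25)
  tot <- with(tr$counts, susceptible_count + infected_count + dead_count)
  expect_true(all(tot == 25 * 25))
})

test_that("the kernel is a deterministic function of the seed", {
  p <- viralParams(t_end = 4)
  a <- runViralModel(p, seed = 11, times = 0:4, snapshotTimes = 4)
  b <- runViralModel(p, seed = 11, times = 0:4, snapshotTimes = 4)
  d <- runViralModel(p, seed = 12, times = 0:4, snapshotTimes = 4)
  expect_identical(a$counts, b$counts)
  expect_identical(a$snapshots[[1]]$field, b$snapshots[[1]]$field)
  expect_false(identical(a$counts, d$counts))
})

test_that("t_end = 0 yields only the initial record", {
  tr <- runViralModel(viralParams(t_end = 0), seed = 1, times = 0,
                      width = 9, height = 9)
  expect_equal(nrow(tr$counts), 1)
  expect_equal(tr$counts$infected_count, 1)
  expect_equal(tr$stepsUsed, 0L)
})

test_that("a pure source accumulates n*p_prod*dt of field mass", {
  p <- viralParams(beta_cf = 0, beta_cc = 0, p_prod = 2, c_decay = 0,
                   D = 0.5, delta_death = 0, dt = 0.1, t_end = 1)
  tr <- runViralModel(p, seed = 1, times = 1, snapshotTimes = 1,
                      width = 13, height = 13)
  expect_equal(sum(tr$snapshots[[1]]$field), 10 * 2 * 0.1,
               tolerance = 1e-12)
})

test_that("stepwise R updates and the compiled kernel are bit-compatible", {
  p <- viralParams(t_end = 2)
  set.seed(21)
  st <- latticeState(21, 21)
  for (i in 1:20) st <- viralStep(st, p)
  tr <- runViralModel(p, seed = 21, times = c(0, 2), snapshotTimes = 2,
                      width = 21, height = 21)
  expect_identical(cellStates(st), tr$snapshots[[1]]$cells)
  expect_identical(virionField(st), tr$snapshots[[1]]$field)
})

test_that("virion field stays non-negative over random parameter steps", {
  set.seed(6)
  for (rep in 1:20) {
    p <- viralParams(beta_cf = runif(1), beta_cc = runif(1),
                     p_prod = runif(1, 0, 3), c_decay = runif(1, 0, 5),
                     D = runif(1, 0, 0.24), delta_death = runif(1),
                     dt = 1, t_end = 50)
    st <- latticeState(9, 9, field = matrix(runif(81), 9, 9))
    for (i in 1:50) {
      st <- viralStep(st, p)
      expect_true(all(virionField(st) >= 0))
    }
  }
})

# --- cellular Potts kernel (randomCpm / bruteH live in helper-cpm.R) ---

test_that("cpmHamiltonian matches trivial closed forms", {
  # single 2x2 cell at target volume in J = 0 medium: H = 0
  spin <- matrix(0L, 5, 5); spin[2:3, 2:3] <- 1L
  st <- cpmState(spin, matrix(0, 2, 2), cellType = 1L, targetVolume = 4L,
                 lambdaV = 1)
  expect_equal(cpmHamiltonian(st), 0)
  # one extra site over target with lambda 1: H = 1
  spin[4, 2] <- 1L
  st <- cpmState(spin, matrix(0, 2, 2), cellType = 1L, targetVolume = 4L,
                 lambdaV = 1)
  expect_equal(cpmHamiltonian(st), 1)
})

test_that("cpmHamiltonian equals the brute-force double loop on random states", {
  for (seed in 1:10)
    expect_equal(cpmHamiltonian(randomCpm(seed)), bruteH(randomCpm(seed)))
})

test_that("local energy changes match full recomputation", {
  set.seed(31)
  for (rep in 1:200) {
    st <- randomCpm(sample(1e6, 1))
    r <- sample(8, 1); c <- sample(8, 1)
    off <- tissueABC:::cpmNeighbourOffsets[sample(4, 1), ]
    rr <- r + off[1]; cc <- c + off[2]
    if (rr < 1 || rr > 8 || cc < 1 || cc > 8) next
    s1 <- st@spin[rr, cc]
    if (s1 == st@spin[r, c]) next
    dH <- tissueABC:::cpmDeltaH(st, r, c, s1)
    after <- st
    s0 <- after@spin[r, c]
    after@spin[r, c] <- s1
    if (s0 > 0) after@volume[s0] <- after@volume[s0] - 1L
    if (s1 > 0) after@volume[s1] <- after@volume[s1] + 1L
    expect_equal(dH, bruteH(after) - bruteH(st), tolerance = 1e-12)
  }
})

test_that("a 50-sweep run keeps consistent energy and volume bookkeeping", {
  st <- randomCpm(77)
  H0 <- cpmHamiltonian(st)
  set.seed(78)
  st2 <- cpmStep(st, nSweeps = 50, record = TRUE)
  log <- attr(st2, "attempts")
  expect_gt(nrow(log), 100)
  # incremental updates telescope to the exact final energy
  expect_equal(cpmHamiltonian(st2), H0 + sum(log$dH[log$accepted]),
               tolerance = 1e-9)
  # incrementally tracked volumes equal recounted volumes
  expect_equal(st2@volume,
               tabulate(st2@spin[st2@spin > 0], nbins = length(st2@volume)))
})

test_that("zero-cost moves are always accepted and cold dynamics never climb", {
  # J = 0, lambda = 0: every copy proposal has dH = 0 and must be accepted
  spin <- matrix(sample(0:2, 36, replace = TRUE), 6, 6)
  st <- cpmState(spin, matrix(0, 3, 3), cellType = c(1L, 2L),
                 targetVolume = c(0L, 0L), lambdaV = 0)
  set.seed(9)
  st2 <- cpmStep(st, nSweeps = 2, record = TRUE)
  log <- attr(st2, "attempts")
  expect_true(all(log$accepted))
  expect_true(all(log$dH == 0))
  # near-zero temperature: accepted moves never increase H
  st <- randomCpm(55)
  set.seed(10)
  st3 <- cpmStep(st, nSweeps = 10, temperature = 1e-9, record = TRUE)
  log <- attr(st3, "attempts")
  expect_true(all(log$dH[log$accepted] <= 0))
})
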