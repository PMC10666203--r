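# ABC-SMC inference engine: prior sampling, Gaussian perturbation kernels
# with prior-support redraw, importance weighting, adaptive epsilon
# schedules, early rejection, and the generation loop.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Non-overlapping RNG substream ids: an affine map over a prime modulus
# below sqrt(2^53), injective in the task index within a generation.
.streamModulus <- 94906249
seedStream <- function(seed, generation, task) {
  base <- ((seed %% .streamModulus) * 48271 + generation * 97 + 13) %%
    .streamModulus
  as.integer((base + task * 7919) %% .streamModulus)
}

priorsOf <- function(p) {
  par <- p@parameters[p@parameters$estimate, , drop = FALSE]
  space <- sampleSpace(p)
  lapply(seq_len(nrow(par)), function(i) {
    row <- par[i, ]
    lo <- space$lower[i]; hi <- space$upper[i]
    switch(row$prior_kind,
      uniform = list(
        id = row$parameter_id, lower = lo, upper = hi,
        sample = function(n) stats::runif(n, lo, hi),
        density = function(x) stats::dunif(x, lo, hi)),
      `log10-uniform` = list(
        id = row$parameter_id, lower = lo, upper = hi,
        sample = function(n) stats::runif(n, lo, hi),
        density = function(x) stats::dunif(x, lo, hi)),
      normal = list(
        id = row$parameter_id, lower = -Inf, upper = Inf,
        sample = function(n) stats::rnorm(n, row$prior_arg1, row$prior_arg2),
        density = function(x) stats::dnorm(x, row$prior_arg1, row$prior_arg2)),
      stop("unsupported prior_kind: ", row$prior_kind))
  })
}

#' Draw from the prior
#'
#' Independent draws per estimated parameter from its declared prior, on
#' the sampling scale (log10-uniform priors are sampled uniformly on the
#' log10-transformed bounds). Consumes the R RNG.
#'
#' @param p a [ProblemSpec-class].
#' @param n number of draws.
#' @return Numeric matrix `n x d` with parameter ids as column names.
#' @export
samplePrior <- function(p, n = 1) {
  priors <- priorsOf(p)
  out <- vapply(priors, function(pr) pr$sample(n), numeric(n))
  out <- matrix(out, nrow = n)
  colnames(out) <- vapply(priors, `[[`, character(1), "id")
  out
}

priorDensity <- function(priors, theta) {
  prod(vapply(seq_along(priors), function(i) priors[[i]]$density(theta[i]),
              numeric(1)))
}

inPriorSupport <- function(priors, theta) {
  all(vapply(seq_along(priors), function(i)
    theta[i] >= priors[[i]]$lower && theta[i] <= priors[[i]]$upper,
    logical(1)))
}

# Cholesky factor tolerating zero / semi-definite covariance matrices.
safeCholFactor <- function(cov) {
  cov <- as.matrix(cov)
  if (all(cov == 0)) return(matrix(0, nrow(cov), ncol(cov)))
  tryCatch(chol(cov), error = function(e)
    chol(cov + diag(1e-10 * max(diag(cov)), nrow(cov))))
}

rmvnormChol <- function(cholU) {
  d <- nrow(cholU)
  drop(crossprod(cholU, stats::rnorm(d)))
}

dmvnormCov <- function(x, mean, cov, cholU = safeCholFactor(cov)) {
  d <- length(x)
  if (all(cholU == 0)) return(if (all(x == mean)) Inf else 0)
  z <- backsolve(cholU, x - mean, transpose = TRUE)
  logDet <- 2 * sum(log(diag(cholU)))
  exp(-0.5 * (d * log(2 * pi) + logDet + sum(z^2)))
}

weightedCovariance <- function(thetas, weights) {
  thetas <- as.matrix(thetas)
  mu <- colSums(thetas * weights)
  centred <- sweep(thetas, 2, mu)
  cov <- crossprod(centred * weights, centred)
  # unbiased normalisation for normalised weights
  denom <- 1 - sum(weights^2)
  if (denom > 0) cov <- cov / denom
  (cov + t(cov)) / 2
}

#' Perturb a particle within the prior support
#'
#' Adds multivariate Gaussian kernel noise to a particle. Draws falling
#' outside the prior support are handled by redrawing: a fresh particle is
#' resampled from the previous population by weight and perturbed again,
#' up to `maxTries` proposals in total; exhausting them raises a
#' degenerate-kernel error. A zero kernel covariance returns the particle
#' unchanged.
#'
#' @param theta numeric starting particle (sampling scale).
#' @param p a [ProblemSpec-class] (defines the prior support).
#' @param prevThetas matrix of the previous generation's particles.
#' @param prevWeights their normalised weights.
#' @param kernelCov kernel covariance matrix.
#' @return The perturbed particle.
#' @export
perturbParticle <- function(theta, p, prevThetas, prevWeights, kernelCov,
                            maxTries = 1e4) {
  priors <- priorsOf(p)
  cholU <- safeCholFactor(kernelCov)
  if (all(cholU == 0)) return(theta)
  current <- theta
  for (i in seq_len(maxTries)) {
    prop <- current + rmvnormChol(cholU)
    if (inPriorSupport(priors, prop)) return(prop)
    j <- sample.int(nrow(prevThetas), 1L, prob = prevWeights)
    current <- prevThetas[j, ]
  }
  stop("degenerate-kernel error: ", maxTries,
       " consecutive proposals fell outside the prior support")
}

#' SMC importance weight
#'
#' The standard sequential importance weight
#' `w(theta') = pi(theta') / sum_j w_j K(theta' | theta_j)` with a Gaussian
#' kernel `K`; weights are normalised over the population after all
#' acceptances. Generation 1 uses uniform weights `1/N`.
#'
#' @param theta accepted particle (sampling scale).
#' @param p a [ProblemSpec-class].
#' @param prevThetas,prevWeights previous generation.
#' @param kernelCov kernel covariance.
#' @return Unnormalised weight (non-negative scalar).
#' @export
importanceWeight <- function(theta, p, prevThetas, prevWeights, kernelCov) {
  priors <- priorsOf(p)
  cholU <- safeCholFactor(kernelCov)
  denom <- sum(vapply(seq_len(nrow(prevThetas)), function(j)
    prevWeights[j] * dmvnormCov(theta, prevThetas[j, ], kernelCov, cholU),
    numeric(1)))
  if (denom <= 0)
    stop("numerical-guard error: zero kernel mixture density at proposal")
  priorDensity(priors, theta) / denom
}

#' Next acceptance threshold
#'
#' The alpha-quantile (type 1, the smallest value whose empirical cdf
#' reaches alpha) of the previous generation's accepted distances, clamped
#' to never exceed the previous epsilon.
#'
#' @param distances accepted distances of the previous generation.
#' @param alpha quantile level in (0, 1].
#' @param previous previous epsilon (default `Inf`).
#' @return The new threshold.
#' @export
nextEpsilon <- function(distances, alpha, previous = Inf) {
  if (!length(distances)) stop("empty distance list")
  sorted <- sort(distances)
  k <- min(length(sorted), max(1L, ceiling(alpha * length(sorted))))
  min(sorted[k], previous)
}

# ---------------------------------------------------------------------------
# Model compilation: turn (model document, condition) into a fast simulate
# closure. Dispatch is on the model root's `class` attribute; additional
# simulators can be registered.

simulatorRegistry <- new.env(parent = emptyenv())

#' Register a simulator backend
#'
#' Binds a model-document class (the root element's `class` attribute) to a
#' factory `function(doc, problem)` returning a closure
#' `function(thetaNat, seed, maxSteps)` that simulates a trajectory (a list
#' with `counts`, `snapshots`, `earlyRejected`, `stepsUsed`). `thetaNat`
#' holds the estimated parameters' natural-scale values in table order.
#'
#' @param name model class string.
#' @param factory the factory function.
#' @export
registerSimulator <- function(name, factory) {
  assign(name, factory, envir = simulatorRegistry)
  invisible(name)
}

applyCondition <- function(p, conditionId) {
  doc <- xml2::read_xml(charToRaw(as.character(p@model)))
  con <- p@conditions
  row <- con[match(conditionId, con$condition_id), , drop = FALSE]
  for (cl in setdiff(names(con), "condition_id")) {
    val <- row[[cl]]
    if (nzchar(val)) setTargetValue(doc, cl, val)
  }
  doc
}

readModelParams <- function(doc) {
  nodes <- xml2::xml_find_all(doc, ".//Param")
  vals <- as.numeric(xml2::xml_attr(nodes, "value"))
  stats::setNames(as.list(vals), xml2::xml_attr(nodes, "name"))
}

estimatedFieldNames <- function(p, doc) {
  par <- p@parameters[p@parameters$estimate, , drop = FALSE]
  vapply(par$target_path, function(path) {
    node <- findTargetNode(doc, path)
    if (inherits(node, "xml_missing"))
      stop("mapping error: target path does not resolve: ", path)
    nm <- xml2::xml_attr(node, "name")
    if (is.na(nm)) stop("estimated parameter target has no name attribute: ",
                        path)
    nm
  }, character(1), USE.NAMES = FALSE)
}

statisticTimes <- function(statistics) {
  rec <- numeric(0); snap <- numeric(0)
  for (i in seq_len(nrow(statistics))) {
    args <- parseStatisticArgs(statistics$args[i])
    switch(statistics$function_id[i],
      count_timeseries = ,
      patch_radius_timeseries = rec <- c(rec, args$times),
      radial_profile = snap <- c(snap, args$time),
      final_fraction = NULL)
  }
  list(record = sort(unique(rec)), snapshot = sort(unique(snap)))
}

viralSimulatorFactory <- function(doc, problem) {
  base <- readModelParams(doc)
  lattice <- xml2::xml_find_first(doc, ".//Lattice")
  width <- as.integer(xml2::xml_attr(lattice, "width"))
  height <- as.integer(xml2::xml_attr(lattice, "height"))
  fields <- estimatedFieldNames(problem, doc)
  times <- statisticTimes(problem@statistics)
  parNames <- names(formals(viralParams))
  function(thetaNat, seed = NULL, maxSteps = Inf) {
    pars <- base
    pars[fields] <- thetaNat
    vp <- do.call(viralParams, pars[intersect(names(pars), parNames)])
    tEnd <- max(c(times$record, times$snapshot, 0))
    if (vp$t_end < tEnd) vp$t_end <- tEnd
    runViralModel(vp, seed = seed, times = times$record,
                  snapshotTimes = times$snapshot, maxSteps = maxSteps,
                  width = width, height = height)
  }
}

gaussianSimulatorFactory <- function(doc, problem) {
  base <- readModelParams(doc)
  fields <- estimatedFieldNames(problem, doc)
  times <- statisticTimes(problem@statistics)
  function(thetaNat, seed = NULL, maxSteps = Inf) {
    pars <- base
    pars[fields] <- thetaNat
    withSeed(seed, {
      if (maxSteps < 1)
        return(structure(list(counts = NULL, snapshots = list(),
                              earlyRejected = TRUE, stepsUsed = 0L),
                         class = "viralTrajectory"))
      y <- pars$theta + stats::rnorm(1, 0, pars$sigma)
      tt <- if (length(times$record)) times$record else 0
      list(counts = list(time = tt, y = rep(y, length(tt))),
           snapshots = list(), earlyRejected = FALSE, stepsUsed = 1L)
    })
  }
}

registerSimulator("viral", viralSimulatorFactory)
registerSimulator("gaussian", gaussianSimulatorFactory)

modelClassOf <- function(p) {
  cls <- xml2::xml_attr(xml2::xml_root(p@model), "class")
  if (is.na(cls)) stop("model document root carries no class attribute")
  cls
}

# Engine context: everything the per-particle evaluation needs, compiled
# once per run.
buildEngineContext <- function(p) {
  cls <- modelClassOf(p)
  factory <- get0(cls, envir = simulatorRegistry)
  if (is.null(factory)) stop("no simulator registered for model class '",
                             cls, "'")
  conds <- intersect(p@conditions$condition_id,
                     unique(p@measurements$condition_id))
  multi <- length(conds) > 1L
  sims <- lapply(conds, function(cid) factory(applyCondition(p, cid), p))
  names(sims) <- conds
  reps <- lapply(conds, function(cid) {
    r <- unique(p@measurements$replicate_id[
      p@measurements$condition_id == cid])
    max(1L, sum(nzchar(r)))
  })
  names(reps) <- conds
  obs <- unlist(lapply(conds, function(cid) {
    v <- observedSummaries(p, cid)
    if (multi) names(v) <- paste0(cid, ":", names(v))
    v
  }))
  par <- p@parameters[p@parameters$estimate, , drop = FALSE]
  priors <- priorsOf(p)
  list(problem = p, priors = priors, sims = sims, reps = reps,
       compiledStats = compileStatistics(p@statistics),
       obs = obs, conditions = conds, multi = multi,
       paramIds = par$parameter_id, logScale = par$scale == "log10",
       lower = vapply(priors, `[[`, numeric(1), "lower"),
       upper = vapply(priors, `[[`, numeric(1), "upper"))
}

# Fast in-loop variants of the exported operations, with the prior list and
# kernel Cholesky factor precomputed once per generation.
samplePriorCtx <- function(ctx) {
  vapply(ctx$priors, function(pr) pr$sample(1), numeric(1))
}

fastPerturb <- function(ctx, start, prevThetas, prevWeights, cholU,
                        maxTries = 1e4) {
  if (all(cholU == 0)) return(start)
  d <- length(start)
  cur <- start
  for (i in seq_len(maxTries)) {
    prop <- cur + drop(crossprod(cholU, stats::rnorm(d)))
    if (all(prop >= ctx$lower & prop <= ctx$upper)) return(prop)
    cur <- prevThetas[sample.int(nrow(prevThetas), 1L,
                                 prob = prevWeights), ]
  }
  stop("degenerate-kernel error: ", maxTries,
       " consecutive proposals fell outside the prior support")
}

# Vectorised SMC weights for a whole population: w_i = pi(theta_i) /
# sum_j wprev_j K(theta_i | theta_j), computed through pairwise Mahalanobis
# distances under the kernel Cholesky factor.
batchImportanceWeights <- function(ctx, thetasNew, prevThetas, prevWeights,
                                   cholU) {
  n <- nrow(thetasNew)
  prior <- rep(1, n)
  for (i in seq_along(ctx$priors))
    prior <- prior * ctx$priors[[i]]$density(thetasNew[, i])
  if (all(cholU == 0)) return(prior / sum(prior))
  d <- ncol(thetasNew)
  A <- t(backsolve(cholU, t(thetasNew), transpose = TRUE))
  B <- t(backsolve(cholU, t(prevThetas), transpose = TRUE))
  M <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  logc <- -0.5 * d * log(2 * pi) - sum(log(diag(cholU)))
  den <- drop(exp(logc - 0.5 * pmax(M, 0)) %*% prevWeights)
  w <- prior / den
  w[!is.finite(w)] <- 0
  if (sum(w) > 0) w / sum(w) else rep(1 / n, n)
}

toNaturalScale <- function(ctx, theta) {
  ifelse(ctx$logScale, 10^theta, theta)
}

evalParticleCtx <- function(ctx, theta, spec, budget = Inf) {
  thetaNat <- toNaturalScale(ctx, theta)
  total <- numeric(0)
  cost <- 0L
  for (cid in ctx$conditions) {
    nrep <- ctx$reps[[cid]]
    acc <- NULL
    for (r in seq_len(nrep)) {
      traj <- tryCatch(ctx$sims[[cid]](thetaNat, seed = NULL,
                                       maxSteps = budget),
                       error = function(e) {
                         warning("simulator error, particle rejected: ",
                                 conditionMessage(e), call. = FALSE)
                         NULL
                       })
      if (is.null(traj) || isTRUE(traj$earlyRejected))
        return(list(distance = Inf, summaries = ctx$obs * NA_real_,
                    earlyRejected = !is.null(traj), cost = cost))
      cost <- cost + traj$stepsUsed
      s <- computeSummariesCompiled(traj, ctx$compiledStats)
      acc <- if (is.null(acc)) s else acc + s
    }
    s <- acc / nrep
    if (ctx$multi) names(s) <- paste0(cid, ":", names(s))
    total <- c(total, s)
  }
  list(distance = statDistance(total, ctx$obs, spec), summaries = total,
       earlyRejected = FALSE, cost = cost)
}

#' Evaluate one particle
#'
#' Runs the problem's simulator at a parameter vector (sampling scale),
#' computes the summary statistics (replicate simulations are run
#' independently and their summaries averaged), and returns the weighted
#' distance to the observed summaries. If the simulation would exceed the
#' step budget it is rejected early with distance `Inf` and no (or partial)
#' simulation work; simulator exceptions likewise reject the particle with
#' a warning while the pipeline continues.
#'
#' @param theta parameter vector on the sampling scale.
#' @param p a [ProblemSpec-class].
#' @param spec a [DistanceSpec-class]; defaults to unit weights.
#' @param budget early-rejection budget in simulation steps.
#' @param seed optional seed (global RNG state restored afterwards).
#' @return `list(distance, summaries, earlyRejected, cost)`.
#' @export
evaluateParticle <- function(theta, p, spec = NULL, budget = Inf,
                             seed = NULL) {
  ctx <- buildEngineContext(p)
  if (is.null(spec))
    spec <- distanceSpec(stats::setNames(rep(1, length(ctx$obs)),
                                         names(ctx$obs)), adapt = "none")
  withSeed(seed, evalParticleCtx(ctx, theta, spec, budget))
}

#' Brute-force rejection ABC
#'
#' The reference sampler used to validate the SMC engine: draw from the
#' prior, simulate, accept iff the distance is at most `epsilon`, repeat
#' until `n` acceptances. Returns equally weighted particles.
#'
#' @param p a [ProblemSpec-class].
#' @param epsilon fixed acceptance threshold.
#' @param n number of accepted particles.
#' @param spec a [DistanceSpec-class] (default unit weights).
#' @param seed integer seed.
#' @param maxProposals proposal cap.
#' @return data.frame of accepted particles (sampling scale) with a
#'   `distance` column; attribute `"proposals"` holds the proposal count.
#' @export
rejectionSample <- function(p, epsilon, n, spec = NULL, seed = 1L,
                            maxProposals = 1e6) {
  ctx <- buildEngineContext(p)
  if (is.null(spec))
    spec <- distanceSpec(stats::setNames(rep(1, length(ctx$obs)),
                                         names(ctx$obs)), adapt = "none")
  withSeed(seed, {
    out <- matrix(NA_real_, n, length(ctx$paramIds))
    dist <- numeric(n)
    got <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > maxProposals) stop("rejection sampler exceeded proposal cap")
      theta <- drop(samplePrior(p, 1))
      ev <- evalParticleCtx(ctx, theta, spec)
      if (is.finite(ev$distance) && ev$distance <= epsilon) {
        got <- got + 1L
        out[got, ] <- theta
        dist[got] <- ev$distance
      }
    }
    df <- as.data.frame(out)
    names(df) <- ctx$paramIds
    df$distance <- dist
    attr(df, "proposals") <- tries
    df
  })
}

#' Run ABC-SMC inference
#'
#' The full sequential engine. Generation 1 accepts the first N prior draws
#' (threshold `initialEpsilon`, by default infinite) with uniform weights;
#' every later generation resamples from the previous population by weight,
#' perturbs with a Gaussian kernel (covariance = `kernelScaleFactor` times
#' the weighted empirical covariance of the previous generation, redrawing
#' proposals outside the prior support), simulates, and accepts until N
#' particles meet the generation's threshold; importance weights are then
#' normalised. The threshold is the `epsilonQuantile`-quantile of the
#' previous accepted distances (recomputed under the current generation's
#' adapted statistic weights, clamped to be non-increasing). The run stops
#' once the threshold reaches `minEpsilon`, `maxGenerations` is exhausted,
#' or `maxWalltime` is exceeded (the running generation is finished).
#'
#' With an adaptive distance (`adapt = "mad"` or `"sd"`), generation 1's
#' weights come from a pilot sample of `pilotSize` prior simulations, and
#' are refit at the start of every later generation from the previous
#' generation's accepted summaries. With `useRegressionStatistics = TRUE`
#' an inverse-regression projection is fit on the pilot sample and frozen.
#'
#' The run is fully reproducible: every proposal consumes its own RNG
#' substream derived from `(seed, generation, task index)`.
#'
#' @param p a [ProblemSpec-class].
#' @param config an [ABCConfig-class].
#' @param sampler a [samplerConfig()] (scheduling contract).
#' @param distance optional [DistanceSpec-class]; by default all statistics
#'   get weight 1 and the robust `"mad"` adaptation scheme.
#' @param verbose print one line per generation (t, epsilon, acceptance
#'   rate, ESS, wall seconds).
#' @return A [ResultStore-class].
#' @examples
#' \donttest{
#' toy <- makeGaussianToy(file.path(tempdir(), "toy"))
#' prob <- parseProblem(toy$index)
#' store <- runABC(prob, abcConfig(populationSize = 200, maxGenerations = 4,
#'                                 seed = 7),
#'                 distance = distanceSpec(c(y_obs_t0 = 1), adapt = "none"))
#' epsilonTrajectory(store)
#' }
#' @export
runABC <- function(p, config, sampler = samplerConfig(), distance = NULL,
                   verbose = FALSE) {
  t0 <- Sys.time()
  ctx <- buildEngineContext(p)
  N <- config@populationSize
  d <- length(ctx$paramIds)

  spec <- if (is.null(distance))
    distanceSpec(stats::setNames(rep(1, length(ctx$obs)), names(ctx$obs)),
                 adapt = "mad")
  else distance

  # pilot phase: calibrate adaptive weights / regression projection
  pilotSummaries <- NULL
  if ((spec@adapt != "none" || config@useRegressionStatistics) &&
      config@pilotSize >= 2) {
    nP <- config@pilotSize
    pilotThetas <- matrix(NA_real_, nP, d)
    pilotS <- NULL
    unitSpec <- distanceSpec(stats::setNames(rep(1, length(ctx$obs)),
                                             names(ctx$obs)), adapt = "none")
    for (i in seq_len(nP)) {
      ev <- withSeed(seedStream(config@seed, 0L, i), {
        theta <- drop(samplePrior(p, 1))
        c(evalParticleCtx(ctx, theta, unitSpec, budget = config@simBudget),
          list(theta = theta))
      })
      if (is.null(pilotS))
        pilotS <- matrix(NA_real_, nP, length(ev$summaries),
                         dimnames = list(NULL, names(ev$summaries)))
      pilotThetas[i, ] <- ev$theta
      pilotS[i, ] <- ev$summaries
    }
    ok <- stats::complete.cases(pilotS)
    pilotSummaries <- pilotS[ok, , drop = FALSE]
    if (config@useRegressionStatistics) {
      colnames(pilotThetas) <- ctx$paramIds
      map <- fitRegressionStatistics(pilotThetas[ok, , drop = FALSE],
                                     pilotSummaries)
      spec@regressionMap <- map
      pilotSummaries <- t(apply(pilotSummaries, 1, function(s)
        projectSummaries(map, s)))
      colnames(pilotSummaries) <- ctx$paramIds
    }
    if (spec@adapt != "none") {
      w <- adaptWeights(pilotSummaries, spec@adapt)
      spec@weights <- if (sum(w) > 0) w * length(w) / sum(w) else w
    } else if (config@useRegressionStatistics)
      spec@weights <- stats::setNames(rep(1, ncol(pilotSummaries)),
                                      colnames(pilotSummaries))
  }

  generationsList <- list()
  prev <- NULL
  epsilon <- config@initialEpsilon
  schedule <- config@epsilonSchedule

  for (t in seq_len(config@maxGenerations)) {
    genStart <- Sys.time()
    if (t > 1L) {
      # refit adaptive weights from the previous accepted summaries
      # (projected ones if a regression map is in force), then recompute
      # the previous distances under the new weights so the quantile
      # threshold is taken on a consistent scale
      prevDist <- prev$particles$distance
      if (spec@adapt != "none") {
        # refit weights carry relative importances only: rescaling them to
        # mean 1 keeps the distance scale comparable across generations so
        # the non-increasing threshold clamp does not bind artificially
        w <- adaptWeights(prev$summaries, spec@adapt)
        spec@weights <- if (sum(w) > 0) w * length(w) / sum(w) else w
        prevDist <- vapply(seq_len(N), function(i)
          statDistance(prev$rawSummaries[i, ], ctx$obs,
                       stripAdapt(spec)), numeric(1))
      }
      epsilon <- if (length(schedule) >= t)
        schedule[t] else nextEpsilon(prevDist, config@epsilonQuantile,
                                     previous = epsilon)
      kernelCov <- config@kernelScaleFactor *
        weightedCovariance(prev$thetas, prev$particles$weight)
    } else {
      if (length(schedule) >= 1L) epsilon <- schedule[1L]
      kernelCov <- NULL
    }

    gen <- sampleABCGeneration(ctx, spec, epsilon, N, t, config, sampler,
                               prev, kernelCov)
    wall <- as.numeric(difftime(Sys.time(), genStart, units = "secs"))

    pop <- new("Population", generation = t, epsilon = epsilon,
               particles = gen$particles, summaries = gen$summaries,
               totalProposals = gen$totalProposals, wallSeconds = wall,
               distanceWeights = spec@weights)
    generationsList[[t]] <- pop
    if (verbose)
      message(sprintf(
        "generation %d: epsilon=%.4g acceptance=%.3f ESS=%.1f wall=%.2fs",
        t, epsilon, N / gen$totalProposals,
        ess(gen$particles$weight), wall))

    prev <- list(particles = gen$particles, thetas = gen$thetas,
                 summaries = gen$summaries, rawSummaries = gen$rawSummaries)

    if (epsilon <= config@minEpsilon) break
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) >
        config@maxWalltime) break
  }

  new("ResultStore", problemFingerprint = problemFingerprint(p),
      config = configSnapshot(config),
      observedSummaries = ctx$obs, generations = generationsList)
}

stripAdapt <- function(spec) {
  spec@adapt <- "none"
  spec
}

configSnapshot <- function(config) {
  sapply(slotNames(config), function(s) slot(config, s), simplify = FALSE)
}

# One generation of accepted particles, via the scheduling contract.
sampleABCGeneration <- function(ctx, spec, epsilon, N, t, config, sampler,
                                prev, kernelCov) {
  d <- length(ctx$paramIds)
  cholU <- if (!is.null(kernelCov)) safeCholFactor(kernelCov)

  prevW <- if (t > 1L) prev$particles$weight
  evalTask <- function(streamSeed) {
    withSeed(streamSeed, {
      if (t == 1L) {
        theta <- samplePriorCtx(ctx)
      } else {
        j <- sample.int(N, 1L, prob = prevW)
        theta <- fastPerturb(ctx, prev$thetas[j, ], prev$thetas, prevW,
                             cholU)
      }
      ev <- evalParticleCtx(ctx, theta, spec, budget = config@simBudget)
      list(theta = theta, distance = ev$distance,
           summaries = ev$summaries, cost = ev$cost,
           accepted = is.finite(ev$distance) && ev$distance <= epsilon)
    })
  }

  res <- if (sampler$mode == "static") {
    staticSample(evalTask, N, sampler$nWorkers, t, config@seed)
  } else {
    dynamicSample(evalTask, N, nWorkers = sampler$nWorkers, gen = t,
                  seed = config@seed, latency = sampler$latency,
                  acceptBy = sampler$acceptBy)
  }

  thetas <- do.call(rbind, lapply(res$accepted, `[[`, "theta"))
  colnames(thetas) <- ctx$paramIds
  rawSummaries <- do.call(rbind, lapply(res$accepted, `[[`, "summaries"))
  distances <- vapply(res$accepted, `[[`, numeric(1), "distance")

  if (t == 1L) {
    w <- rep(1 / N, N)
  } else {
    w <- batchImportanceWeights(ctx, thetas, prev$thetas,
                                prev$particles$weight, cholU)
  }

  particles <- as.data.frame(thetas)
  particles$weight <- w
  particles$distance <- distances
  particles$n_attempts <- vapply(res$accepted, function(a)
    if (is.null(a$n_attempts)) 1L else a$n_attempts, integer(1))

  summaries <- rawSummaries
  if (!is.null(spec@regressionMap)) {
    summaries <- t(apply(rawSummaries, 1, function(s)
      projectSummaries(spec@regressionMap, s)))
    colnames(summaries) <- rownames(spec@regressionMap$B)
  }

  list(particles = particles, thetas = thetas, summaries = summaries,
       rawSummaries = rawSummaries, totalProposals = res$totalProposals)
}
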