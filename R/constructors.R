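# User-facing constructors, accessors and show() methods.

#' Create a lattice state
#'
#' @param width,height lattice dimensions (sites; lattice spacing is 1).
#' @param infected integer matrix of 1-based `(row, col)` coordinates to
#'   initialise as infected, or the string `"center"` for the single central
#'   site at `(ceiling(height/2), ceiling(width/2))`.
#' @param field optional initial virion field (defaults to zero).
#' @param time initial model time.
#' @return A [LatticeState-class] object.
#' @examples
#' st <- latticeState(21, 21, infected = "center")
#' table(cellStates(st))
#' @export
latticeState <- function(width, height, infected = "center", field = NULL,
                         time = 0) {
  cells <- matrix(0L, nrow = height, ncol = width)
  if (identical(infected, "center")) {
    cells[ceiling(height / 2), ceiling(width / 2)] <- 1L
  } else if (!is.null(infected)) {
    infected <- rbind(infected)
    cells[cbind(infected[, 1], infected[, 2])] <- 1L
  }
  if (is.null(field)) field <- matrix(0, nrow = height, ncol = width)
  new("LatticeState", cells = cells, field = field, time = as.numeric(time))
}

#' Accessors for lattice states
#'
#' @param object a [LatticeState-class].
#' @return `cellStates` the integer state grid, `virionField` the
#'   concentration grid, `latticeTime` the current model time.
#' @export
cellStates <- function(object) object@cells

#' @rdname cellStates
#' @export
virionField <- function(object) object@field

#' @rdname cellStates
#' @export
latticeTime <- function(object) object@time

setMethod("show", "LatticeState", function(object) {
  d <- dim(object@cells)
  n <- tabulate(object@cells + 1L, nbins = 3L)
  cat(sprintf(
    "LatticeState %dx%d at t=%g | susceptible %d, infected %d, dead %d, virions %.4g\n",
    d[2], d[1], object@time, n[1], n[2], n[3], sum(object@field)
  ))
})

#' Viral-spread model parameters
#'
#' Rates of the two-route infection model: cell-free transmission through a
#' diffusing virion field and direct cell-to-cell transmission through
#' lattice contacts, plus virion production/decay/diffusion, infected-cell
#' death, and the time discretisation.
#'
#' @param beta_cf cell-free infection rate per unit virion concentration per
#'   unit time.
#' @param beta_cc cell-to-cell infection rate per infected 4-neighbour per
#'   unit time.
#' @param p_prod virion production per infected cell per unit time.
#' @param c_decay virion decay rate.
#' @param D virion diffusion coefficient (lattice units^2 per time).
#' @param delta_death infected-cell death rate.
#' @param dt time step; `D * dt` must be `<= 1/4` (explicit-scheme
#'   stability with lattice spacing 1).
#' @param t_end simulation end time.
#' @return A named list of class `viralParams`.
#' @export
viralParams <- function(beta_cf = 0.05, beta_cc = 0.2, p_prod = 1,
                        c_decay = 0.1, D = 0.5, delta_death = 0.05,
                        dt = 0.1, t_end = 10) {
  p <- list(beta_cf = beta_cf, beta_cc = beta_cc, p_prod = p_prod,
            c_decay = c_decay, D = D, delta_death = delta_death,
            dt = dt, t_end = t_end)
  bad <- names(p)[vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x < 0, logical(1))]
  if (length(bad)) stop("viral parameters must be non-negative scalars: ",
                        paste(bad, collapse = ", "))
  if (dt <= 0 || t_end < 0) stop("dt must be > 0 and t_end >= 0")
  if (D * dt > 0.25 + 1e-12)
    stop("explicit diffusion unstable: need D*dt <= 1/4 (dx = 1), got D*dt = ",
         D * dt)
  class(p) <- "viralParams"
  p
}

#' Create a cellular Potts state
#'
#' @param spin integer matrix of cell ids (0 = medium).
#' @param adhesion symmetric adhesion matrix `J`, indexed `(type+1, type+1)`
#'   with medium as type 0 in row/column 1.
#' @param cellType integer vector giving each cell id's type (>= 1).
#' @param targetVolume integer vector of per-cell volume targets.
#' @param lambdaV volume-constraint strength.
#' @param temperature Metropolis temperature (> 0).
#' @return A [CPMState-class] with volumes counted from the spin grid.
#' @export
cpmState <- function(spin, adhesion, cellType, targetVolume, lambdaV = 1,
                     temperature = 1) {
  spin <- matrix(as.integer(spin), nrow = nrow(spin))
  nCells <- length(cellType)
  vol <- tabulate(spin[spin > 0L], nbins = nCells)
  new("CPMState", spin = spin, adhesion = adhesion,
      cellType = as.integer(cellType), volume = as.integer(vol),
      targetVolume = as.integer(targetVolume), lambdaV = lambdaV,
      temperature = temperature)
}

setMethod("show", "CPMState", function(object) {
  cat(sprintf("CPMState %dx%d | %d cells, lambdaV=%g, T=%g, H=%g\n",
              ncol(object@spin), nrow(object@spin), length(object@volume),
              object@lambdaV, object@temperature, cpmHamiltonian(object)))
})

#' Build a distance specification
#'
#' @param weights named non-negative weights, one per statistic component.
#' @param p norm order (1 or 2).
#' @param adapt scale-adaptation scheme applied each generation: `"mad"`
#'   (robust, the default), `"sd"`, or `"none"`.
#' @param regressionMap optional `list(b0, B)` affine projection applied to
#'   both statistic vectors before the norm (see
#'   [fitRegressionStatistics()]).
#' @return A [DistanceSpec-class].
#' @export
distanceSpec <- function(weights, p = 2, adapt = c("mad", "sd", "none"),
                         regressionMap = NULL) {
  adapt <- match.arg(adapt)
  new("DistanceSpec", p = p, weights = weights, adapt = adapt,
      regressionMap = regressionMap)
}

setMethod("show", "DistanceSpec", function(object) {
  cat(sprintf("DistanceSpec: L%d norm, %d statistics, adapt=%s%s\n",
              object@p, length(object@weights), object@adapt,
              if (is.null(object@regressionMap)) "" else ", regression-projected"))
})

#' Build an ABC-SMC configuration
#'
#' @param populationSize accepted particles per generation (N).
#' @param maxGenerations generation cap.
#' @param minEpsilon stop once the next epsilon is at or below this.
#' @param epsilonQuantile alpha in (0,1): the next threshold is the
#'   alpha-quantile (type 1) of the previous accepted distances.
#' @param kernelScaleFactor multiplier on the weighted empirical covariance
#'   of the previous generation for the Gaussian perturbation kernel.
#' @param maxWalltime wall-clock limit in seconds; the running generation is
#'   completed before stopping.
#' @param simBudget early-rejection budget in simulation steps (`Inf`
#'   disables early rejection).
#' @param seed master seed; every random draw in the run derives from it.
#' @param pilotSize prior simulations used to calibrate adaptive distance
#'   weights (and the optional regression map) before generation 1.
#' @param initialEpsilon threshold for generation 1 (default `Inf`:
#'   accept-all calibration).
#' @param useRegressionStatistics fit an inverse-regression summary
#'   projection on the pilot sample and freeze it for the whole run.
#' @param epsilonSchedule optional fixed per-generation thresholds; entries
#'   override the adaptive quantile rule for the corresponding generation.
#' @return An [ABCConfig-class].
#' @export
abcConfig <- function(populationSize = 500, maxGenerations = 10,
                      minEpsilon = 0, epsilonQuantile = 0.5,
                      kernelScaleFactor = 2, maxWalltime = Inf,
                      simBudget = Inf, seed = 1L, pilotSize = 100,
                      initialEpsilon = Inf, useRegressionStatistics = FALSE,
                      epsilonSchedule = numeric()) {
  new("ABCConfig",
      populationSize = as.integer(populationSize),
      maxGenerations = as.integer(maxGenerations),
      minEpsilon = minEpsilon, epsilonQuantile = epsilonQuantile,
      kernelScaleFactor = kernelScaleFactor, maxWalltime = maxWalltime,
      simBudget = simBudget, seed = as.integer(seed),
      pilotSize = as.integer(pilotSize), initialEpsilon = initialEpsilon,
      useRegressionStatistics = useRegressionStatistics,
      epsilonSchedule = as.numeric(epsilonSchedule))
}

setMethod("show", "ABCConfig", function(object) {
  cat(sprintf(
    "ABCConfig: N=%d, maxGen=%d, minEps=%g, alpha=%g, kernel x%g, seed=%d\n",
    object@populationSize, object@maxGenerations, object@minEpsilon,
    object@epsilonQuantile, object@kernelScaleFactor, object@seed))
})

#' Accessors for problem bundles
#'
#' @param object a [ProblemSpec-class].
#' @return the corresponding table (data.frame) or the xml model document.
#' @export
parameterTable <- function(object) object@parameters

#' @rdname parameterTable
#' @export
conditionTable <- function(object) object@conditions

#' @rdname parameterTable
#' @export
measurementTable <- function(object) object@measurements

#' @rdname parameterTable
#' @export
statisticTable <- function(object) object@statistics

#' @rdname parameterTable
#' @export
modelDocument <- function(object) object@model

setMethod("show", "ProblemSpec", function(object) {
  cat(sprintf(
    "ProblemSpec: %d parameters (%d estimated), %d conditions, %d measurements, %d statistics\n",
    nrow(object@parameters), sum(object@parameters$estimate),
    nrow(object@conditions), nrow(object@measurements),
    nrow(object@statistics)))
})

#' Accessors for populations and result stores
#'
#' @param object a [Population-class] or [ResultStore-class].
#' @return `particles()` the particle data.frame; `particleSummaries()` the
#'   per-particle summary matrix; `generations()` the list of populations;
#'   `nGenerations()` their count; `finalPopulation()` the last one.
#' @export
particles <- function(object) {
  if (is(object, "ResultStore")) object <- finalPopulation(object)
  object@particles
}

#' @rdname particles
#' @export
particleSummaries <- function(object) {
  if (is(object, "ResultStore")) object <- finalPopulation(object)
  object@summaries
}

#' @rdname particles
#' @export
generations <- function(object) object@generations

#' @rdname particles
#' @export
nGenerations <- function(object) length(object@generations)

#' @rdname particles
#' @export
finalPopulation <- function(object) {
  if (!length(object@generations)) stop("result store is empty")
  object@generations[[length(object@generations)]]
}

setMethod("show", "Population", function(object) {
  cat(sprintf(
    "Population t=%d: %d particles, epsilon=%.4g, %d proposals, ESS=%.1f\n",
    object@generation, nrow(object@particles), object@epsilon,
    object@totalProposals, ess(object@particles$weight)))
})

setMethod("show", "ResultStore", function(object) {
  cat(sprintf("ResultStore: %d generation(s), problem %s\n",
              length(object@generations),
              substr(object@problemFingerprint, 1, 8)))
  if (length(object@generations)) {
    tr <- epsilonTrajectory(object)
    cat("  epsilon: ", paste(signif(tr$epsilon, 4), collapse = " -> "), "\n")
  }
})
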