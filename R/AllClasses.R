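#' @useDynLib tissueABC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats runif rnorm median sd mad dnorm qnorm quantile setNames
#' @importFrom utils read.delim write.table head tail
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Parsed problem bundle
#'
#' A `ProblemSpec` holds the fully cross-linked content of an on-disk problem
#' bundle: the XML model document plus the parameter, condition, measurement
#' and summary-statistic tables. Objects are created by [parseProblem()]; the
#' slots are reached through the accessors [parameterTable()],
#' [conditionTable()], [measurementTable()], [statisticTable()] and
#' [modelDocument()] rather than `@`.
#'
#' @slot model An `xml2` document with the model definition.
#' @slot parameters data.frame, one row per model parameter (columns
#'   `parameter_id`, `prior_kind`, `prior_arg1`, `prior_arg2`, `scale`,
#'   `estimate`, `nominal_value`, `target_path`).
#' @slot conditions data.frame, one row per experimental condition;
#'   columns beyond `condition_id` are target paths whose cell values
#'   override the model document before simulation.
#' @slot measurements data.frame of observed records (`observable_id`,
#'   `condition_id`, `time`, `value`, optionally `data_ref`, `replicate_id`).
#' @slot statistics data.frame of summary-statistic definitions
#'   (`statistic_id`, `function_id`, `args`, `observable_ids`).
#' @slot directory Directory the bundle was read from (used to resolve
#'   `data_ref` paths); `NA` for purely in-memory problems.
#'
#' @seealso [parseProblem()], [validateProblem()], [mapParameters()]
#' @export
setClass("ProblemSpec",
  representation(
    model = "ANY",
    parameters = "data.frame",
    conditions = "data.frame",
    measurements = "data.frame",
    statistics = "data.frame",
    directory = "character"
  )
)

#' Lattice state of the viral-spread simulator
#'
#' Cell-state grid plus the extracellular virion concentration field. Cell
#' states are coded `0` = susceptible, `1` = infected, `2` = dead.
#'
#' @slot cells integer matrix of cell states.
#' @slot field numeric matrix of virion concentration (same shape,
#'   non-negative).
#' @slot time numeric scalar, current model time.
#'
#' @seealso [latticeState()], [viralStep()], [runViralModel()]
#' @export
setClass("LatticeState",
  representation(cells = "matrix", field = "matrix", time = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@cells) == dim(object@field)))
      msg <- c(msg, "cell grid and virion field must share their shape")
    if (!all(object@cells %in% c(0L, 1L, 2L)))
      msg <- c(msg, "cell states must be 0 (susceptible), 1 (infected) or 2 (dead)")
    if (any(object@field < 0))
      msg <- c(msg, "virion field must be non-negative")
    if (length(object@time) != 1L || object@time < 0)
      msg <- c(msg, "time must be a single non-negative number")
    if (length(msg)) msg else TRUE
  }
)

#' Cellular Potts model state
#'
#' Spin grid (0 = medium, k > 0 = cell id), adhesion matrix indexed by cell
#' type, per-cell volumes with volume-constraint targets, and kinetic
#' parameters for Metropolis boundary-copy dynamics.
#'
#' @slot spin integer matrix of cell ids (0 is medium).
#' @slot adhesion symmetric numeric matrix `J` indexed by type pair; row/col
#'   1 is the medium type.
#' @slot cellType integer vector mapping cell id k to its type (>= 1);
#'   medium is implicitly type 0.
#' @slot volume integer vector, current volume per cell id.
#' @slot targetVolume integer vector, target volume per cell id.
#' @slot lambdaV numeric, volume-constraint strength.
#' @slot temperature numeric, Metropolis temperature.
#'
#' @seealso [cpmState()], [cpmHamiltonian()], [cpmStep()]
#' @export
setClass("CPMState",
  representation(
    spin = "matrix", adhesion = "matrix", cellType = "integer",
    volume = "integer", targetVolume = "integer",
    lambdaV = "numeric", temperature = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!isSymmetric(unname(object@adhesion)))
      msg <- c(msg, "adhesion matrix J must be symmetric")
    ids <- sort(unique(object@spin[object@spin > 0L]))
    if (length(ids) && max(ids) > length(object@volume))
      msg <- c(msg, "volume vector shorter than the largest cell id")
    counted <- tabulate(object@spin[object@spin > 0L], nbins = length(object@volume))
    if (length(object@volume) && !all(counted == object@volume))
      msg <- c(msg, "volume bookkeeping does not match the spin grid")
    if (object@lambdaV < 0) msg <- c(msg, "lambdaV must be >= 0")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Weighted distance specification
#'
#' Per-statistic weights and norm order for comparing simulated to observed
#' summary vectors, with an optional adaptation scheme (robust
#' median-absolute-deviation or standard-deviation scale normalisation,
#' refit each generation) and an optional linear regression map projecting
#' raw statistics onto predicted parameters before the norm is taken.
#'
#' @slot p norm order, 1 or 2.
#' @slot weights named non-negative numeric vector, one entry per statistic.
#' @slot adapt `"none"`, `"mad"` or `"sd"`.
#' @slot regressionMap `NULL`, or `list(b0 =, B =)` with the affine map
#'   `s -> b0 + B %*% s` applied to both vectors before the norm.
#'
#' @seealso [distanceSpec()], [statDistance()], [adaptWeights()]
#' @export
setClass("DistanceSpec",
  representation(p = "numeric", weights = "numeric", adapt = "character",
                 regressionMap = "listOrNULL"),
  validity = function(object) {
    msg <- character()
    if (!object@p %in% c(1, 2)) msg <- c(msg, "norm order p must be 1 or 2")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (length(object@weights) && !any(object@weights > 0))
      msg <- c(msg, "at least one weight must be positive")
    if (!object@adapt %in% c("none", "mad", "sd"))
      msg <- c(msg, "adapt must be one of none, mad, sd")
    if (length(msg)) msg else TRUE
  }
)

#' ABC-SMC engine configuration
#'
#' @slot populationSize integer N >= 2, accepted particles per generation.
#' @slot maxGenerations integer, generation cap.
#' @slot minEpsilon numeric, stop once epsilon falls to or below this.
#' @slot epsilonQuantile numeric in (0,1); the next epsilon is this
#'   empirical quantile (type 1) of the previous generation's accepted
#'   distances.
#' @slot kernelScaleFactor numeric; perturbation kernel covariance is this
#'   factor times the weighted empirical covariance of the previous
#'   generation.
#' @slot maxWalltime numeric seconds; the running generation is finished
#'   before stopping.
#' @slot simBudget numeric; early-rejection budget in simulation steps
#'   (`Inf` disables it).
#' @slot seed integer master seed; all randomness derives from it.
#' @slot pilotSize integer; prior simulations used to initialise adaptive
#'   weights (and the regression map, if requested) before generation 1.
#' @slot initialEpsilon numeric; acceptance threshold of generation 1
#'   (`Inf` = accept-all calibration).
#' @slot useRegressionStatistics logical; fit a Fearnhead-Prangle style
#'   inverse regression on the pilot sample and freeze it.
#' @slot epsilonSchedule numeric; optional fixed per-generation thresholds
#'   overriding the adaptive quantile rule (empty = adaptive).
#'
#' @seealso [abcConfig()], [runABC()]
#' @export
setClass("ABCConfig",
  representation(
    populationSize = "integer", maxGenerations = "integer",
    minEpsilon = "numeric", epsilonQuantile = "numeric",
    kernelScaleFactor = "numeric", maxWalltime = "numeric",
    simBudget = "numeric", seed = "integer", pilotSize = "integer",
    initialEpsilon = "numeric", useRegressionStatistics = "logical",
    epsilonSchedule = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@populationSize < 2L) msg <- c(msg, "populationSize must be >= 2")
    if (object@epsilonQuantile <= 0 || object@epsilonQuantile >= 1)
      msg <- c(msg, "epsilonQuantile must lie in (0, 1)")
    if (object@maxGenerations < 1L) msg <- c(msg, "maxGenerations must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' One ABC-SMC generation
#'
#' A weighted population of accepted particles: parameter draws on the
#' sampling scale, normalised importance weights, distances, summary
#' vectors, and bookkeeping (threshold used, proposals consumed, wall
#' seconds).
#'
#' @slot generation integer t >= 1.
#' @slot epsilon numeric acceptance threshold used for this generation.
#' @slot particles data.frame with one column per estimated parameter
#'   (sampling scale) plus `weight`, `distance` and `n_attempts`.
#' @slot summaries numeric matrix, one row per particle, columns named by
#'   statistic component.
#' @slot totalProposals integer, completed proposals this generation.
#' @slot wallSeconds numeric.
#' @slot distanceWeights numeric, the per-statistic weights in force.
#'
#' @export
setClass("Population",
  representation(
    generation = "integer", epsilon = "numeric", particles = "data.frame",
    summaries = "matrix", totalProposals = "integer",
    wallSeconds = "numeric", distanceWeights = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    w <- object@particles$weight
    if (!is.null(w)) {
      if (abs(sum(w) - 1) > 1e-12) msg <- c(msg, "weights must sum to 1")
      if (any(w < 0)) msg <- c(msg, "weights must be >= 0")
    }
    d <- object@particles$distance
    if (!is.null(d) && is.finite(object@epsilon) && any(d > object@epsilon))
      msg <- c(msg, "all accepted distances must be <= epsilon")
    if (length(msg)) msg else TRUE
  }
)

#' Append-only inference record
#'
#' Everything needed to audit an ABC-SMC run: a fingerprint of the problem
#' bundle, the configuration snapshot, the observed summary vector, and one
#' [Population-class] per generation. Serialises to a single shareable JSON
#' file via [saveResultStore()].
#'
#' @slot problemFingerprint character md5 of the canonically serialised
#'   problem bundle.
#' @slot config list snapshot of the [ABCConfig-class] used.
#' @slot observedSummaries named numeric, the observed statistic vector.
#' @slot generations list of [Population-class] objects, contiguous from 1.
#'
#' @seealso [runABC()], [saveResultStore()], [loadResultStore()]
#' @export
setClass("ResultStore",
  representation(
    problemFingerprint = "character", config = "list",
    observedSummaries = "numeric", generations = "list"
  ),
  validity = function(object) {
    gens <- vapply(object@generations, function(g) g@generation, integer(1))
    if (length(gens) && !identical(gens, seq_along(gens)))
      "generations must be contiguous from 1" else TRUE
  }
)
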