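# Fixture generators: every input needed for tests and demos is produced
# by code, from seeds — a conjugate Gaussian toy with a closed-form
# posterior, a viral-spread recovery problem with known ground truth, and
# a corpus of deliberately broken bundles for the validator.

emptyMeasurements <- function() {
  data.frame(observable_id = character(), condition_id = character(),
             time = numeric(), value = numeric(), data_ref = character(),
             replicate_id = character(), stringsAsFactors = FALSE)
}

measRow <- function(observable, condition, time, value) {
  data.frame(observable_id = observable, condition_id = condition,
             time = time, value = value, data_ref = "", replicate_id = "",
             stringsAsFactors = FALSE)
}

parRow <- function(id, kind, a1, a2, scale, estimate, nominal, path) {
  data.frame(parameter_id = id, prior_kind = kind, prior_arg1 = a1,
             prior_arg2 = a2, scale = scale, estimate = estimate,
             nominal_value = nominal, target_path = path,
             stringsAsFactors = FALSE)
}

statRow <- function(id, fid, args, observables) {
  data.frame(statistic_id = id, function_id = fid, args = args,
             observable_ids = observables, stringsAsFactors = FALSE)
}

#' Conjugate Gaussian toy problem
#'
#' The engine's primary oracle: model `y = theta + noise` with noise sd 1,
#' prior `theta ~ N(0, 1)`, observed `y = 1`. The exact posterior is
#' `N(0.5, 0.5)` (conjugate formula: mean `(tau^-2 mu0 + sigma^-2 y) /
#' (tau^-2 + sigma^-2)`, variance `1 / (tau^-2 + sigma^-2)`), recorded in
#' the returned ground truth.
#'
#' @param dir directory to write the bundle into.
#' @return list with `name`, `dir`, `index` (path to the yaml index),
#'   `groundTruth` (`posteriorMean`, `posteriorVar`), `seed`.
#' @export
makeGaussianToy <- function(dir) {
  model <- xml2::read_xml(paste0(
    '<Model class="gaussian">',
    '<Param name="theta" value="0"/>',
    '<Param name="sigma" value="1"/>',
    "</Model>"))
  parameters <- rbind(
    parRow("theta", "normal", 0, 1, "lin", TRUE, 0,
           "Param[@name='theta']/@value"),
    parRow("sigma", "uniform", NA, NA, "lin", FALSE, 1,
           "Param[@name='sigma']/@value"))
  conditions <- data.frame(condition_id = "c0", stringsAsFactors = FALSE)
  measurements <- measRow("y", "c0", 0, 1)
  statistics <- statRow("y_obs", "count_timeseries",
                        "times=0;observable=y", "y")
  prob <- new("ProblemSpec", model = model, parameters = parameters,
              conditions = conditions, measurements = measurements,
              statistics = statistics, directory = NA_character_)
  index <- writeProblem(prob, dir)
  list(name = "gaussian", dir = dir, index = index,
       groundTruth = list(posteriorMean = 0.5, posteriorVar = 0.5),
       seed = NA_integer_)
}

# Reference synthetic-truth setting of the viral-spread model.
viralTruth <- function() {
  list(beta_cf = 0.05, beta_cc = 0.2, p_prod = 1, c_decay = 0.1, D = 0.5,
       delta_death = 0.05, dt = 0.1, t_end = 10)
}

#' Viral-spread recovery fixture
#'
#' Simulates the two-route viral infection model at the reference setting
#' (`beta_cf = 0.05`, `beta_cc = 0.2`, `p_prod = 1`, `c_decay = 0.1`,
#' `D = 0.5`, `delta_death = 0.05`, `dt = 0.1` on a `width x height`
#' lattice, one central infected cell) for the given seed, and writes the
#' observed data — the infected-count time series at t = 0..10 and a
#' five-bin radial profile of the infected+dead indicator at t = 10
#' (11 + 5 = 16 measurement rows) — as a problem bundle estimating
#' `beta_cf` and `beta_cc` with log10-uniform priors spanning two decades
#' centred on the truth. The observed data come from one stochastic
#' simulator draw, not a noiseless mean, matching the well-specified case
#' the inference faces in practice.
#'
#' @param dir directory to write the bundle into.
#' @param seed seed of the synthetic-truth simulation.
#' @param width,height lattice size.
#' @param estimateDt additionally estimate the step size `dt` with a
#'   log10-uniform(0.01, 1) prior; the required step count then varies
#'   with the parameter draw, which is what the early-rejection budget
#'   acts on. This variant lowers the diffusion coefficient to `D = 0.2`
#'   so the explicit scheme stays stable (`D * dt <= 1/4`) over the whole
#'   dt prior range.
#' @return list with `name`, `dir`, `index`, `groundTruth` (named true
#'   parameter vector), `seed`.
#' @export
makeViralFixture <- function(dir, seed = 1L, width = 50, height = 50,
                             estimateDt = FALSE) {
  truth <- viralTruth()
  if (estimateDt) truth$D <- 0.2
  traj <- runViralModel(do.call(viralParams, truth), seed = seed,
                        times = 0:10, snapshotTimes = 10,
                        width = width, height = height)
  snap <- traj$snapshots[[1]]
  profile <- radialProfile((snap$cells == 1L | snap$cells == 2L) * 1, 5)

  model <- xml2::read_xml(paste0(
    '<Model class="viral">',
    paste0(vapply(names(truth), function(nm) sprintf(
      '<Param name="%s" value="%s"/>', nm, formatNumber(truth[[nm]])),
      character(1)), collapse = ""),
    sprintf('<Lattice width="%d" height="%d"/>', width, height),
    "</Model>"))

  pathOf <- function(nm) sprintf("Param[@name='%s']/@value", nm)
  parameters <- rbind(
    parRow("beta_cf", "log10-uniform", truth$beta_cf / 10,
           truth$beta_cf * 10, "log10", TRUE, truth$beta_cf,
           pathOf("beta_cf")),
    parRow("beta_cc", "log10-uniform", truth$beta_cc / 10,
           truth$beta_cc * 10, "log10", TRUE, truth$beta_cc,
           pathOf("beta_cc")))
  if (estimateDt)
    parameters <- rbind(parameters,
      parRow("dt", "log10-uniform", 0.01, 1, "log10", TRUE, truth$dt,
             pathOf("dt")))
  fixed <- setdiff(names(truth), parameters$parameter_id)
  for (nm in fixed)
    parameters <- rbind(parameters,
      parRow(nm, "uniform", NA, NA, "lin", FALSE, truth[[nm]], pathOf(nm)))

  conditions <- data.frame(condition_id = "c0", stringsAsFactors = FALSE)
  measurements <- rbind(
    measRow("infected_count", "c0", 0:10, traj$counts$infected_count),
    do.call(rbind, lapply(1:5, function(b)
      measRow(paste0("radial_bin", b), "c0", 10, profile[b]))))
  statistics <- rbind(
    statRow("infected_ts", "count_timeseries",
            "times=0,1,2,3,4,5,6,7,8,9,10;observable=infected_count",
            "infected_count"),
    statRow("radial10", "radial_profile", "time=10;nbins=5",
            paste(paste0("radial_bin", 1:5), collapse = ";")))

  prob <- new("ProblemSpec", model = model, parameters = parameters,
              conditions = conditions, measurements = measurements,
              statistics = statistics, directory = NA_character_)
  index <- writeProblem(prob, dir)
  gt <- c(beta_cf = truth$beta_cf, beta_cc = truth$beta_cc)
  if (estimateDt) gt <- c(gt, dt = truth$dt)
  list(name = "viral", dir = dir, index = index, groundTruth = gt,
       seed = as.integer(seed))
}

# Rewrite one tsv table of a bundle through a data.frame transform.
mutateTable <- function(dir, file, fn) {
  path <- file.path(dir, file)
  df <- readTsvTable(path)
  df <- fn(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Corpus of deliberately invalid bundles
#'
#' Builds six problem bundles, each violating exactly one validation rule,
#' for exercising [validateBundle()]: a parameter table lacking the
#' `prior_kind` column (`MISSING_COLUMN`), a measurement referencing an
#' undefined condition (`DANGLING_CONDITION`), inverted uniform prior
#' bounds (`PRIOR_BOUNDS`), a non-positive log10-uniform lower bound
#' (`PRIOR_POSITIVITY`), an unresolvable target path (`PATH_UNRESOLVED`),
#' and an unknown summary-statistic function (`UNKNOWN_STATISTIC`).
#'
#' @param dir parent directory; one sub-directory per bundle.
#' @return list of bundles, each `list(name, dir, index, expectedCode)`.
#' @export
makeInvalidCorpus <- function(dir) {
  defects <- list(
    missing_column = list(code = "MISSING_COLUMN", mutate = function(d)
      mutateTable(d, "parameters.tsv", function(df) {
        df$prior_kind <- NULL; df
      })),
    dangling_condition = list(code = "DANGLING_CONDITION", mutate = function(d)
      mutateTable(d, "measurements.tsv", function(df) {
        df$condition_id[1] <- "c99"; df
      })),
    prior_bounds = list(code = "PRIOR_BOUNDS", mutate = function(d)
      mutateTable(d, "parameters.tsv", function(df) {
        df$prior_kind[1] <- "uniform"
        df$prior_arg1[1] <- "2"; df$prior_arg2[1] <- "1"; df
      })),
    prior_positivity = list(code = "PRIOR_POSITIVITY", mutate = function(d)
      mutateTable(d, "parameters.tsv", function(df) {
        df$prior_kind[1] <- "log10-uniform"; df$scale[1] <- "log10"
        df$prior_arg1[1] <- "0"; df$prior_arg2[1] <- "100"; df
      })),
    unresolved_path = list(code = "PATH_UNRESOLVED", mutate = function(d)
      mutateTable(d, "parameters.tsv", function(df) {
        df$target_path[1] <- "Param[@name='no_such_param']/@value"; df
      })),
    unknown_statistic = list(code = "UNKNOWN_STATISTIC", mutate = function(d)
      mutateTable(d, "statistics.tsv", function(df) {
        df$function_id[1] <- "not_a_registered_function"; df
      }))
  )
  lapply(names(defects), function(nm) {
    sub <- file.path(dir, nm)
    toy <- makeGaussianToy(sub)
    defects[[nm]]$mutate(sub)
    list(name = nm, dir = sub, index = toy$index,
         expectedCode = defects[[nm]]$code)
  })
}
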