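# Result persistence: one shareable JSON file per run (written at full
# 17-significant-digit precision so doubles round-trip bit-exactly), plus a
# tsv exporter for the diagnostic tables.

populationToList <- function(pop, timings = TRUE) {
  list(
    generation = pop@generation,
    epsilon = pop@epsilon,
    particles = as.list(pop@particles),
    particleColumns = names(pop@particles),
    summaries = as.numeric(pop@summaries),
    summaryNames = colnames(pop@summaries),
    nParticles = nrow(pop@particles),
    totalProposals = pop@totalProposals,
    wallSeconds = if (timings) pop@wallSeconds else NA_real_,
    distanceWeights = as.numeric(pop@distanceWeights),
    distanceWeightNames = names(pop@distanceWeights)
  )
}

asNumericSafe <- function(x) suppressWarnings(as.numeric(unlist(x)))

populationFromList <- function(x) {
  particles <- as.data.frame(lapply(x$particles, asNumericSafe),
                             optional = TRUE)
  names(particles) <- unlist(x$particleColumns)
  particles$n_attempts <- as.integer(particles$n_attempts)
  summaries <- matrix(asNumericSafe(x$summaries), nrow = x$nParticles)
  colnames(summaries) <- unlist(x$summaryNames)
  new("Population",
      generation = as.integer(x$generation),
      epsilon = asNumericSafe(x$epsilon),
      particles = particles, summaries = summaries,
      totalProposals = as.integer(x$totalProposals),
      wallSeconds = asNumericSafe(x$wallSeconds),
      distanceWeights = stats::setNames(asNumericSafe(x$distanceWeights),
                                        unlist(x$distanceWeightNames)))
}

#' Save a result store to a single file
#'
#' Serialises a [ResultStore-class] to one JSON file. Numbers are written
#' with full precision, so saving and re-loading reproduces every float
#' bit-identically. With `timings = FALSE` the per-generation wall-clock
#' seconds — the only field that varies between otherwise identical runs —
#' are blanked, making stores from identical `(problem, config, seed,
#' single worker)` runs byte-identical on disk.
#'
#' @param store a [ResultStore-class].
#' @param path output file path.
#' @param timings keep per-generation wall seconds (default `TRUE`).
#' @return `path`, invisibly.
#' @export
saveResultStore <- function(store, path, timings = TRUE) {
  obj <- list(
    format = "tissueABC-store-1",
    problemFingerprint = store@problemFingerprint,
    config = store@config,
    observedSummaries = as.numeric(store@observedSummaries),
    observedNames = names(store@observedSummaries),
    generations = lapply(store@generations, populationToList,
                         timings = timings)
  )
  # I(17) significant digits round-trips IEEE doubles exactly; na = "string"
  # keeps non-finite values (the generation-1 Inf threshold, blanked
  # timings) representable in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "string", pretty = FALSE)
  invisible(path)
}

#' Load a result store
#'
#' @param path a file written by [saveResultStore()].
#' @return A [ResultStore-class] equal field-by-field to the saved one.
#' @export
loadResultStore <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(x$format, "tissueABC-store-1"))
    stop("not a tissueABC result store: ", path)
  cfg <- x$config
  for (nm in c("populationSize", "maxGenerations", "seed", "pilotSize"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  for (nm in c("minEpsilon", "epsilonQuantile", "kernelScaleFactor",
               "maxWalltime", "simBudget", "initialEpsilon"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.numeric(cfg[[nm]])
  if (!is.null(cfg$epsilonSchedule))
    cfg$epsilonSchedule <- as.numeric(unlist(cfg$epsilonSchedule))
  new("ResultStore",
      problemFingerprint = x$problemFingerprint,
      config = cfg,
      observedSummaries = stats::setNames(as.numeric(unlist(x$observedSummaries)),
                                          unlist(x$observedNames)),
      generations = lapply(x$generations, populationFromList))
}

#' Export diagnostic tables from a result store
#'
#' Writes the standard diagnostics as tab-separated files into a
#' directory: `epsilon_trajectory.tsv`, `ess.tsv`,
#' `samples_per_generation.tsv`, `ci_<level>.tsv` (final-generation
#' weighted credible intervals per parameter) and
#' `kde_<p1>_<p2>.csv` (weighted 2-D kernel density grid for the first
#' parameter pair, when there are at least two parameters). Every figure
#' of the usual sampler-diagnostics panel can be drawn from these files
#' with any plotting tool.
#'
#' @param store a [ResultStore-class].
#' @param dir output directory (created if needed).
#' @param level credible level (default 0.95).
#' @return The directory path, invisibly.
#' @export
exportResultStore <- function(store, dir, level = 0.95) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(epsilonTrajectory(store), "epsilon_trajectory.tsv")
  essDf <- data.frame(
    t = vapply(store@generations, function(g) g@generation, integer(1)),
    ess = vapply(store@generations, function(g) ess(g@particles$weight),
                 numeric(1)))
  wt(essDf, "ess.tsv")
  wt(samplesPerGeneration(store), "samples_per_generation.tsv")

  pop <- finalPopulation(store)
  ids <- setdiff(names(pop@particles), c("weight", "distance", "n_attempts"))
  ci <- credibleInterval(as.matrix(pop@particles[ids]),
                         pop@particles$weight, level)
  wt(data.frame(parameter_id = ids, lower = ci[, 1], upper = ci[, 2]),
     paste0("ci_", format(level * 100), ".tsv"))

  if (length(ids) >= 2) {
    k <- kde2d(pop@particles[[ids[1]]], pop@particles[[ids[2]]],
               pop@particles$weight)
    utils::write.table(k$density, file.path(
      dir, paste0("kde_", ids[1], "_", ids[2], ".csv")),
      sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
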