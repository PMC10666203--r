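# Summary statistics: a registry of functions turning raw trajectories (or
# observed measurement records) into named statistic vectors, weighted
# distances with robust adaptive scale normalisation, and inverse-regression
# summary construction.

parseStatisticArgs <- function(str) {
  if (is.na(str) || !nzchar(str)) return(list())
  parts <- strsplit(str, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed args entry: '", p, "'")
    vals <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[trimws(kv[1])]] <- if (!anyNA(num)) num else vals
  }
  out
}

formatStatisticArgs <- function(args) {
  paste(vapply(names(args), function(k)
    paste0(k, "=", paste(formatNumber(args[[k]]), collapse = ",")),
    character(1)), collapse = ";")
}

checkStatisticArgs <- function(functionId, args) {
  need <- function(key, numeric = TRUE, scalar = FALSE) {
    if (is.null(args[[key]]))
      stop("args must define '", key, "'")
    if (numeric && !is.numeric(args[[key]]))
      stop("args entry '", key, "' must be numeric")
    if (scalar && length(args[[key]]) != 1)
      stop("args entry '", key, "' must be a single value")
  }
  switch(functionId,
    count_timeseries = { need("times"); need("observable", numeric = FALSE, scalar = TRUE) },
    patch_radius_timeseries = need("times"),
    radial_profile = {
      need("time", scalar = TRUE); need("nbins", scalar = TRUE)
      if (args$nbins < 1 || args$nbins != round(args$nbins))
        stop("args entry 'nbins' must be a positive integer")
    },
    final_fraction = need("state", numeric = FALSE, scalar = TRUE),
    stop("unknown function_id: ", functionId))
  invisible(TRUE)
}

statisticComponentNames <- function(row) {
  args <- parseStatisticArgs(row$args)
  switch(row$function_id,
    count_timeseries = ,
    patch_radius_timeseries = paste0(row$statistic_id, "_t",
                                     formatNumber(args$times)),
    radial_profile = paste0(row$statistic_id, "_bin", seq_len(args$nbins)),
    final_fraction = row$statistic_id)
}

trajCountsAt <- function(traj, times, column) {
  idx <- match(round(times, 9), round(traj$counts$time, 9))
  if (anyNA(idx))
    stop("alignment error: requested time(s) ",
         paste(times[is.na(idx)], collapse = ", "),
         " not present in the trajectory")
  if (!column %in% names(traj$counts))
    stop("alignment error: observable '", column,
         "' not present in the trajectory")
  traj$counts[[column]][idx]
}

trajSnapshotAt <- function(traj, time) {
  for (s in traj$snapshots)
    if (abs(s$time - time) < 1e-9) return(s)
  stop("alignment error: no snapshot at time ", time)
}

#' Radial profile of a lattice quantity
#'
#' Mean of a matrix over concentric radial bins around the grid centre
#' `((nrow+1)/2, (ncol+1)/2)`. The binned region extends to radius
#' `R = min(nrow, ncol) / 2` with `nbins` equal-width bins; sites at radius
#' `>= R` are excluded.
#'
#' @param mat numeric matrix (an indicator grid or a concentration field).
#' @param nbins number of radial bins.
#' @return Numeric vector of per-bin means, innermost bin first.
#' @examples
#' m <- matrix(0, 7, 7); m[4, 4] <- 1
#' radialProfile(m, 3)
#' @export
radialProfile <- function(mat, nbins) {
  nr <- nrow(mat); nc <- ncol(mat)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  R <- min(nr, nc) / 2
  r <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`))
  bin <- floor(r / (R / nbins)) + 1
  keep <- r < R
  out <- vapply(seq_len(nbins),
                function(b) mean(mat[keep & bin == b]), numeric(1))
  out
}

# The statistic registry. Each entry computes the statistic from a
# simulated trajectory (`sim`) and assembles the observed counterpart from
# measurement records (`obs`).
statisticRegistry <- list(
  count_timeseries = list(
    sim = function(traj, args) trajCountsAt(traj, args$times, args$observable),
    obs = function(meas, args, problem) {
      obsValuesAt(meas, args$observable, args$times, problem)
    }
  ),
  patch_radius_timeseries = list(
    sim = function(traj, args) {
      area <- trajCountsAt(traj, args$times, "infected_count") +
        trajCountsAt(traj, args$times, "dead_count")
      sqrt(area / pi)
    },
    obs = function(meas, args, problem) {
      obsValuesAt(meas, if (is.null(args$observable)) "patch_radius" else
        args$observable, args$times, problem)
    }
  ),
  radial_profile = list(
    sim = function(traj, args) {
      snap <- trajSnapshotAt(traj, args$time)
      mat <- if (identical(args$source, "field")) snap$field else
        (snap$cells == 1L | snap$cells == 2L) * 1
      radialProfile(mat, args$nbins)
    },
    obs = function(meas, args, problem) {
      ids <- meas$observable_id
      refRows <- meas[nzchar(meas$data_ref) &
                        abs(meas$time - args$time) < 1e-9, , drop = FALSE]
      if (nrow(refRows) == 1L) {
        # a single gridded-array reference: compute the profile from it
        radialProfile(readGriddedArray(problem, refRows$data_ref[1]),
                      args$nbins)
      } else {
        vapply(seq_len(args$nbins), function(b) {
          rows <- meas[grepl(paste0("bin", b, "$"), ids) &
                         abs(meas$time - args$time) < 1e-9, , drop = FALSE]
          if (!nrow(rows))
            stop("alignment error: no measurement for radial bin ", b,
                 " at time ", args$time)
          mean(rows$value)
        }, numeric(1))
      }
    }
  ),
  final_fraction = list(
    sim = function(traj, args) {
      last <- traj$counts[nrow(traj$counts), ]
      total <- last$susceptible_count + last$infected_count + last$dead_count
      col <- paste0(args$state, "_count")
      if (!col %in% names(last)) stop("unknown state: ", args$state)
      last[[col]] / total
    },
    obs = function(meas, args, problem) {
      obs <- if (is.null(args$observable))
        paste0(args$state, "_fraction") else args$observable
      rows <- meas[meas$observable_id == obs, , drop = FALSE]
      if (!nrow(rows))
        stop("alignment error: no measurement for observable '", obs, "'")
      mean(rows$value[order(rows$time)][nrow(rows)])
    }
  )
)

obsValuesAt <- function(meas, observable, times, problem) {
  vapply(times, function(tt) {
    rows <- meas[meas$observable_id == observable &
                   abs(meas$time - tt) < 1e-9, , drop = FALSE]
    if (!nrow(rows))
      stop("alignment error: no measurement for observable '", observable,
           "' at time ", tt)
    mean(rows$value)  # replicates averaged
  }, numeric(1))
}

#' Compute summary statistics from a trajectory
#'
#' Applies each row of a statistic table to a simulated trajectory and
#' concatenates the results in table order into one named vector. Registry
#' functions: `count_timeseries` (an observable's counts at a time grid),
#' `patch_radius_timeseries` (equivalent-circle radius `sqrt(area/pi)` of
#' the infected+dead region), `radial_profile` (radial bin means of an
#' indicator grid or field at one time), and `final_fraction` (a cell
#' state's fraction at the last record).
#'
#' @param traj a trajectory as returned by [runViralModel()] (a list with
#'   `counts` and `snapshots`).
#' @param statistics statistic table data.frame (`statistic_id`,
#'   `function_id`, `args`, `observable_ids`), e.g. from
#'   [statisticTable()].
#' @return Named numeric statistic vector; component order is fixed by the
#'   table.
#' @export
computeSummaries <- function(traj, statistics) {
  computeSummariesCompiled(traj, compileStatistics(statistics))
}

# Parse and check a statistic table once; per-simulation evaluation then
# skips all string handling.
compileStatistics <- function(statistics) {
  lapply(seq_len(nrow(statistics)), function(i) {
    row <- statistics[i, ]
    if (!row$function_id %in% names(statisticRegistry))
      stop("registry error: unknown function_id '", row$function_id, "'")
    args <- parseStatisticArgs(row$args)
    checkStatisticArgs(row$function_id, args)
    list(simFun = statisticRegistry[[row$function_id]]$sim, args = args,
         names = statisticComponentNames(row))
  })
}

computeSummariesCompiled <- function(traj, compiled) {
  parts <- lapply(compiled, function(st) {
    vals <- st$simFun(traj, st$args)
    names(vals) <- st$names
    vals
  })
  if (length(parts) == 1L) parts[[1L]] else do.call(c, parts)
}

#' Assemble the observed summary vector of a problem
#'
#' Builds, from the measurement table, the observed counterpart of
#' [computeSummaries()]: same components, same order, with replicate
#' measurements averaged and gridded-array references (`data_ref`)
#' evaluated through the corresponding statistic function.
#'
#' @param p a [ProblemSpec-class].
#' @param conditionId restrict to one condition (default: first).
#' @return Named numeric statistic vector.
#' @export
observedSummaries <- function(p, conditionId = NULL) {
  if (is.null(conditionId)) conditionId <- p@conditions$condition_id[1]
  meas <- p@measurements[p@measurements$condition_id == conditionId, ,
                         drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(nrow(p@statistics))) {
    row <- p@statistics[i, ]
    args <- parseStatisticArgs(row$args)
    checkStatisticArgs(row$function_id, args)
    obsIds <- strsplit(row$observable_ids, ";", fixed = TRUE)[[1]]
    sub <- meas[meas$observable_id %in% obsIds, , drop = FALSE]
    vals <- statisticRegistry[[row$function_id]]$obs(sub, args, p)
    names(vals) <- statisticComponentNames(row)
    out <- c(out, vals)
  }
  out
}

#' Weighted distance between statistic vectors
#'
#' Computes `(sum_i w_i * |sim_i - obs_i|^p)^(1/p)` after checking that the
#' two vectors carry identical component names in identical order. If the
#' specification holds a regression map, both vectors are first projected
#' through `s -> b0 + B s` (the inverse-regression summary construction)
#' and the weights apply in the projected space.
#'
#' @param sim,obs named numeric statistic vectors.
#' @param spec a [DistanceSpec-class].
#' @return Non-negative scalar distance.
#' @export
statDistance <- function(sim, obs, spec) {
  if (!identical(names(sim), names(obs)))
    stop("alignment error: statistic names differ between sim and obs")
  if (!is.null(spec@regressionMap)) {
    sim <- projectSummaries(spec@regressionMap, sim)
    obs <- projectSummaries(spec@regressionMap, obs)
  }
  if (length(spec@weights) != length(sim))
    stop("alignment error: weight vector length ", length(spec@weights),
         " does not match statistic count ", length(sim))
  sum(spec@weights * abs(sim - obs)^spec@p)^(1 / spec@p)
}

projectSummaries <- function(map, s) {
  out <- as.numeric(map$b0 + map$B %*% as.numeric(s))
  names(out) <- rownames(map$B)
  out
}

#' Adaptive per-statistic weights
#'
#' Scale-normalising weights `w_i = 1 / scale_i`, with the scale taken as
#' the median absolute deviation (scheme `"mad"`, robust, the default
#' throughout) or standard deviation (`"sd"`) of statistic `i` across a
#' population of simulated summary vectors. A statistic with zero scale is
#' uninformative this generation: it gets weight 0 and a warning.
#'
#' @param summaries numeric matrix (rows = simulations, columns =
#'   statistics) or a list of equally named vectors.
#' @param scheme `"mad"` or `"sd"`.
#' @return Named non-negative weight vector.
#' @export
adaptWeights <- function(summaries, scheme = c("mad", "sd")) {
  scheme <- match.arg(scheme)
  if (is.list(summaries)) summaries <- do.call(rbind, summaries)
  if (nrow(summaries) < 2) stop("need at least 2 summary vectors")
  scale <- apply(summaries, 2, function(x) {
    if (scheme == "mad") stats::median(abs(x - stats::median(x))) else
      stats::sd(x)
  })
  w <- ifelse(scale > 0, 1 / scale, 0)
  if (any(scale == 0))
    warning("statistic(s) with zero scale get weight 0: ",
            paste(colnames(summaries)[scale == 0], collapse = ", "))
  names(w) <- colnames(summaries)
  w
}

#' Inverse-regression summary construction
#'
#' Fits, on pilot-run samples, one least-squares linear model per parameter
#' regressing the parameter draw on the raw summary vector, and returns the
#' affine map `s -> b0 + B s` whose output (the predicted parameters) is
#' used as the projected summary statistic. Rank-deficient designs fall
#' back to ridge regression with fixed regularisation `1e-8` and a notice.
#'
#' @param thetas numeric matrix of parameter draws (rows = samples).
#' @param summaries numeric matrix of the matching raw summary vectors.
#' @return `list(b0, B)` with `b0` length `ncol(thetas)` and `B` of shape
#'   `ncol(thetas) x ncol(summaries)`; row names follow the parameter
#'   columns.
#' @export
fitRegressionStatistics <- function(thetas, summaries) {
  thetas <- as.matrix(thetas); summaries <- as.matrix(summaries)
  n <- nrow(thetas)
  if (n != nrow(summaries)) stop("thetas and summaries disagree in rows")
  if (n < ncol(thetas) + ncol(summaries) + 1)
    stop("need at least dim(theta) + dim(s) + 1 = ",
         ncol(thetas) + ncol(summaries) + 1, " samples, got ", n)
  X <- cbind(1, summaries)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    message("rank-deficient summary design; ridge fallback (lambda = 1e-8)")
    XtX <- crossprod(X) + diag(1e-8, ncol(X))
    coef <- solve(XtX, crossprod(X, thetas))
  } else {
    coef <- qr.coef(qrX, thetas)
  }
  b0 <- coef[1, ]
  B <- t(coef[-1, , drop = FALSE])
  rownames(B) <- colnames(thetas)
  colnames(B) <- colnames(summaries)
  names(b0) <- colnames(thetas)
  list(b0 = b0, B = B)
}
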