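# Distributed-evaluation contract: static per-worker quotas, dynamic
# on-demand task issue with issue-order acceptance (the unbiasedness rule),
# per-task RNG substreams, and the parallel-efficiency metric. The
# scheduler here is a deterministic in-process emulation of the
# server-worker architecture: workers are modelled as sequential consumers
# with optional injected per-task latency, which is exactly what is needed
# to verify the contract's statistical properties; a real multicore or
# networked backend can be slotted in behind the same interface.

#' Sampler (scheduling) configuration
#'
#' @param mode `"dynamic"` (tasks issued on demand until N acceptances;
#'   minimises wall time) or `"static"` (fixed per-worker acceptance
#'   quotas; minimises CPU time).
#' @param nWorkers number of workers (>= 1).
#' @param latency optional function of a task result returning its
#'   simulated evaluation duration, used by the scheduling emulation.
#' @param acceptBy `"issue"` (default; accept the N accepted particles
#'   with the smallest task-issue indices — latency-independent and
#'   unbiased) or `"completion"` (accept the first N by completion time;
#'   biased when evaluation time correlates with the parameter, provided
#'   for demonstration).
#' @return A list of class `samplerConfig`.
#' @export
samplerConfig <- function(mode = c("dynamic", "static"), nWorkers = 1L,
                          latency = NULL,
                          acceptBy = c("issue", "completion")) {
  mode <- match.arg(mode)
  acceptBy <- match.arg(acceptBy)
  if (nWorkers < 1L) stop("nWorkers must be >= 1")
  structure(list(mode = mode, nWorkers = as.integer(nWorkers),
                 latency = latency, acceptBy = acceptBy),
            class = "samplerConfig")
}

#' @export
print.samplerConfig <- function(x, ...) {
  cat(sprintf("samplerConfig: %s scheduling, %d worker(s), accept by %s\n",
              x$mode, x$nWorkers, x$acceptBy))
  invisible(x)
}

#' Static per-worker acceptance quotas
#'
#' Splits a population of N acceptances into per-worker quotas that sum to
#' N and differ pairwise by at most one; each worker then samples until it
#' has met its quota.
#'
#' @param N population size.
#' @param nWorkers number of workers; must not exceed N.
#' @return Integer vector of quotas, one per worker.
#' @examples
#' staticQuotas(10, 4)   # 3 3 2 2
#' staticQuotas(1000, 48)
#' @export
staticQuotas <- function(N, nWorkers) {
  if (nWorkers < 1L) stop("configuration error: nWorkers must be >= 1")
  if (N < nWorkers) stop("configuration error: N must be >= nWorkers")
  base <- N %/% nWorkers
  rem <- N %% nWorkers
  as.integer(base + (seq_len(nWorkers) <= rem))
}

# Offset keeping static-mode task ids unique across workers within a
# generation (worker w's local task i gets id (w-1)*offset + i).
.staticTaskOffset <- 300000L

staticSample <- function(evalTask, N, nWorkers, gen, seed) {
  quotas <- staticQuotas(N, nWorkers)
  accepted <- vector("list", N)
  got <- 0L
  totalProposals <- 0L
  for (w in seq_len(nWorkers)) {
    need <- quotas[w]
    local <- 0L
    while (need > 0L) {
      local <- local + 1L
      if (local > .staticTaskOffset) stop("static worker exceeded task cap")
      streamSeed <- seedStream(seed, gen, (w - 1L) * .staticTaskOffset + local)
      res <- evalTask(streamSeed)
      totalProposals <- totalProposals + 1L
      if (isTRUE(res$accepted)) {
        got <- got + 1L
        accepted[[got]] <- res
        need <- need - 1L
      }
    }
  }
  list(accepted = accepted, totalProposals = totalProposals)
}

#' Dynamic on-demand sampling
#'
#' Emulates the dynamic scheduling strategy: tasks carry monotone issue
#' indices and non-overlapping RNG substreams derived from
#' `(seed, generation, task index)`; they are assigned on demand to the
#' first free worker. The accepted population consists of the accepted
#' particles with the N smallest issue indices — later acceptances are
#' discarded — which makes the population distribution independent of
#' per-task evaluation latency and hence of the worker count. The
#' alternative `acceptBy = "completion"` rule (first N accepted by
#' completion time) is provided to demonstrate the selection bias that the
#' issue-order rule removes when evaluation time correlates with the
#' parameter.
#'
#' @param evalTask `function(streamSeed)` evaluating one proposal and
#'   returning a list with at least `accepted` (logical); the scheduling
#'   contract does not inspect anything else.
#' @param N number of acceptances required.
#' @param nWorkers workers in the emulation.
#' @param gen generation index (enters the substream derivation).
#' @param seed master seed.
#' @param latency optional `function(result)` giving the task's simulated
#'   duration (defaults to constant 1).
#' @param acceptBy `"issue"` or `"completion"`.
#' @param maxTasks safety cap on issued tasks.
#' @return list with `accepted` (list of N task results, selection-rule
#'   order), `totalProposals` (completed tasks with issue index at most the
#'   Nth accepted task's index), and `taskLog` (data.frame with
#'   `task_index`, `worker`, `start`, `end`, `accepted`, `streamSeed`).
#' @export
dynamicSample <- function(evalTask, N, nWorkers = 1L, gen = 1L, seed = 1L,
                          latency = NULL, acceptBy = c("issue", "completion"),
                          maxTasks = 1e6) {
  acceptBy <- match.arg(acceptBy)
  if (is.null(latency)) latency <- function(res) 1
  clocks <- rep(0, nWorkers)
  results <- list()
  log <- list()
  nAcc <- 0L
  i <- 0L
  repeat {
    i <- i + 1L
    if (i > maxTasks) stop("dynamic sampler exceeded task cap")
    w <- which.min(clocks)
    streamSeed <- seedStream(seed, gen, i)
    res <- evalTask(streamSeed)
    start <- clocks[w]
    end <- start + latency(res)
    clocks[w] <- end
    res$task_index <- i
    res$end <- end
    results[[i]] <- res
    log[[i]] <- data.frame(task_index = i, worker = w, start = start,
                           end = end, accepted = isTRUE(res$accepted),
                           streamSeed = streamSeed)
    if (isTRUE(res$accepted)) nAcc <- nAcc + 1L

    if (acceptBy == "issue") {
      if (nAcc >= N) break
    } else {
      # completion order: stop once the Nth-smallest accepted completion
      # time can no longer be undercut by any not-yet-issued task
      if (nAcc >= N) {
        accEnds <- sort(vapply(Filter(function(r) isTRUE(r$accepted),
                                      results), `[[`, numeric(1), "end"))
        if (accEnds[N] <= min(clocks)) break
      }
    }
  }
  logDf <- do.call(rbind, log)
  accAll <- Filter(function(r) isTRUE(r$accepted), results)
  if (acceptBy == "issue") {
    ord <- order(vapply(accAll, `[[`, integer(1), "task_index"))
    accepted <- accAll[ord][seq_len(N)]
    cutoff <- accepted[[N]]$task_index
    totalProposals <- sum(logDf$task_index <= cutoff)
  } else {
    ord <- order(vapply(accAll, `[[`, numeric(1), "end"))
    accepted <- accAll[ord][seq_len(N)]
    totalProposals <- nrow(logDf)
  }
  list(accepted = accepted, totalProposals = as.integer(totalProposals),
       taskLog = logDf)
}

#' Parallel efficiency
#'
#' `PE = t_single / (t_multi * i)`: the wall time of a single-node run
#' divided by the wall time on `i` nodes times `i`. Equals 1 under perfect
#' scaling.
#'
#' @param tSingle wall time of the single-node run (> 0).
#' @param tMulti wall time of the i-node run (> 0).
#' @param i number of nodes (>= 1).
#' @return The efficiency (dimensionless).
#' @examples
#' parallelEfficiency(100, 25, 4)  # 1: perfect scaling
#' parallelEfficiency(96, 12, 16)  # 0.5
#' @export
parallelEfficiency <- function(tSingle, tMulti, i) {
  if (tSingle <= 0 || tMulti <= 0 || i < 1)
    stop("domain error: times must be positive and i >= 1")
  tSingle / (tMulti * i)
}
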