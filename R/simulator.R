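# Desk-scale stochastic lattice simulator: explicit reaction-diffusion
# virion field, two-route viral infection dynamics, and a cellular Potts
# kernel. The viral step is implemented twice: this readable R version and
# a C++ run kernel (src/viral.cpp) that consumes the R RNG in the identical
# order, so both produce bit-compatible trajectories.

#' One explicit diffusion step
#'
#' Forward-Euler five-point-stencil update of a concentration field with
#' reflecting (zero-flux) boundaries, a source term and linear decay:
#' `f' = f + dt * (D * lap(f) - decay * f) + source * dt`. The zero-flux
#' stencil conserves total mass exactly when source and decay are zero, and
#' the update is provably non-negative whenever
#' `4 * D * dt + decay * dt <= 1` (the updated value is then a convex
#' combination of non-negative terms); outputs are clipped at zero only
#' when that bound is violated.
#'
#' @param field numeric matrix, current concentration (lattice spacing 1).
#' @param D diffusion coefficient; `D * dt <= 1/4` is required (explicit
#'   scheme stability) and checked before any stepping.
#' @param decay linear decay rate.
#' @param source numeric matrix (or scalar) of production per unit time.
#' @param dt time step.
#' @return The updated field matrix.
#' @examples
#' f <- matrix(0, 11, 11); f[6, 6] <- 1
#' f2 <- diffusionStep(f, D = 0.2, decay = 0, source = 0, dt = 1)
#' sum(f2)  # mass conserved
#' @export
diffusionStep <- function(field, D, decay, source, dt) {
  if (D * dt > 0.25 + 1e-12)
    stop("explicit diffusion unstable: need D*dt <= 1/4 (dx = 1), got D*dt = ",
         D * dt)
  nr <- nrow(field); nc <- ncol(field)
  if (length(source) == 1L) source <- matrix(source, nr, nc)
  # reflecting boundaries: out-of-lattice neighbours replicate the edge value
  up    <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- field[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- field[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  lap <- (up + down + left + right) - 4 * field
  out <- field + dt * (D * lap - decay * field) + source * dt
  if (4 * D * dt + decay * dt > 1) out[out < 0] <- 0
  out
}

#' Per-step infection probability of a susceptible cell
#'
#' The two transmission routes contribute a combined hazard
#' `beta_cf * V + beta_cc * n` (cell-free through the local virion
#' concentration, cell-to-cell through infected lattice neighbours); over a
#' step of length `dt` the infection probability is
#' `1 - exp(-(beta_cf * V + beta_cc * n) * dt)`.
#'
#' @param V local virion concentration (>= 0); vectorised.
#' @param nInfected number of infected 4-neighbours; vectorised.
#' @param params a [viralParams()] list.
#' @return Probability in `[0, 1]`.
#' @export
infectionProbability <- function(V, nInfected, params) {
  1 - exp(-(params$beta_cf * V + params$beta_cc * nInfected) * params$dt)
}

countInfectedNeighbours <- function(cells) {
  inf <- (cells == 1L) * 1L
  nr <- nrow(inf); nc <- ncol(inf)
  n <- matrix(0L, nr, nc)
  n[-1L, ] <- n[-1L, ] + inf[-nr, ]
  n[-nr, ] <- n[-nr, ] + inf[-1L, ]
  n[, -1L] <- n[, -1L] + inf[, -nc]
  n[, -nc] <- n[, -nc] + inf[, -1L]
  n
}

#' One synchronous step of the viral-spread model
#'
#' Advances the lattice by `dt`: (i) the virion field diffuses and decays,
#' with production `p_prod` at sites infected before the step; (ii) each
#' susceptible site independently becomes infected with
#' [infectionProbability()], using its post-diffusion local field value and
#' the infected 4-neighbour count of the pre-step configuration; (iii) each
#' pre-step infected site independently dies with probability
#' `1 - exp(-delta_death * dt)`. All hazards are evaluated on the pre-step
#' cell configuration (synchronous update), which makes single-step counts
#' exactly binomial.
#'
#' Random numbers are consumed from the R RNG in a fixed order (infection
#' draws over susceptible sites in column-major order, then death draws
#' over infected sites), matching the compiled run kernel used by
#' [runViralModel()].
#'
#' @param state a [LatticeState-class].
#' @param params a [viralParams()] list.
#' @return The updated [LatticeState-class].
#' @export
viralStep <- function(state, params) {
  cells <- state@cells
  source <- params$p_prod * (cells == 1L)
  field <- diffusionStep(state@field, params$D, params$c_decay, source,
                         params$dt)
  nInf <- countInfectedNeighbours(cells)

  newCells <- cells
  sus <- which(cells == 0L)
  if (length(sus)) {
    # hazard cutoff: per-step infection probabilities below 1e-12 are
    # treated as zero and consume no random draw (keeps the draw order
    # identical to the compiled run kernel)
    h <- (params$beta_cf * field[sus] + params$beta_cc * nInf[sus]) *
      params$dt
    act <- h > 1e-12
    if (any(act)) {
      p <- 1 - exp(-h[act])
      u <- stats::runif(sum(act))
      newCells[sus[act][u < p]] <- 1L
    }
  }
  inf <- which(cells == 1L)
  if (length(inf)) {
    pDeath <- 1 - exp(-params$delta_death * params$dt)
    u <- stats::runif(length(inf))
    newCells[inf[u < pDeath]] <- 2L
  }
  new("LatticeState", cells = newCells, field = field,
      time = state@time + params$dt)
}

#' Run the viral-spread model
#'
#' Simulates the two-route infection model from an initial lattice state to
#' `t_end`, recording cell counts at the requested times and full state
#' snapshots at `snapshotTimes`. The trajectory is a deterministic function
#' of `(params, init, seed)`. Recording happens at the first step whose
#' time reaches each requested time (records at `t = 0` come from the
#' initial state).
#'
#' @param params a [viralParams()] list.
#' @param init a [LatticeState-class]; defaults to an all-susceptible
#'   lattice with one central infected cell.
#' @param seed integer seed (the global RNG state is saved and restored).
#' @param times numeric vector of recording times for the count series.
#' @param snapshotTimes times at which the full cell grid and virion field
#'   are kept.
#' @param maxSteps early-rejection budget: if the run needs more steps than
#'   this, no simulation is performed and the result carries
#'   `earlyRejected = TRUE`.
#' @param width,height lattice size used when `init` is `NULL`.
#' @return A list of class `viralTrajectory` with elements `counts` (a
#'   data.frame `time`, `susceptible_count`, `infected_count`,
#'   `dead_count`), `snapshots` (list of `list(time, cells, field)`),
#'   `earlyRejected`, and `stepsUsed`.
#' @examples
#' tr <- runViralModel(viralParams(t_end = 2), seed = 1, times = 0:2,
#'                     width = 21, height = 21)
#' tr$counts
#' @export
runViralModel <- function(params, init = NULL, seed = 1L,
                          times = seq(0, params$t_end),
                          snapshotTimes = numeric(), maxSteps = Inf,
                          width = 50, height = 50) {
  if (is.null(init)) init <- latticeState(width, height, infected = "center")
  nSteps <- ceiling(params$t_end / params$dt - 1e-9)
  if (nSteps > maxSteps) {
    return(structure(list(counts = NULL, snapshots = list(),
                          earlyRejected = TRUE, stepsUsed = 0L),
                     class = "viralTrajectory"))
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  res <- viral_run_cpp(init@cells, init@field,
                       params[c("beta_cf", "beta_cc", "p_prod", "c_decay",
                                "D", "delta_death", "dt", "t_end")],
                       as.numeric(sort(times)), as.numeric(sort(snapshotTimes)))
  counts <- as.data.frame(res$counts)
  names(counts) <- c("time", "susceptible_count", "infected_count",
                     "dead_count")
  snaps <- lapply(res$snapshots, function(s)
    list(time = s$time, cells = s$cells, field = s$field))
  structure(list(counts = counts, snapshots = snaps, earlyRejected = FALSE,
                 stepsUsed = as.integer(nSteps)),
            class = "viralTrajectory")
}

#' @export
print.viralTrajectory <- function(x, ...) {
  if (x$earlyRejected) {
    cat("viralTrajectory: rejected early (step budget exceeded)\n")
  } else {
    cat(sprintf("viralTrajectory: %d records, %d snapshots, %d steps\n",
                nrow(x$counts), length(x$snapshots), x$stepsUsed))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cellular Potts kernel (Metropolis boundary-copy dynamics)

cpmTypeOf <- function(state, id) {
  ifelse(id == 0L, 0L, state@cellType[id])
}

#' Cellular Potts Hamiltonian
#'
#' The standard CPM energy on a 4-neighbourhood without wraparound:
#' `H = sum over neighbouring site pairs with different spins of
#' J(type_a, type_b) + lambda_V * sum over cells of (v_k - V_T,k)^2`.
#' Each unordered neighbour pair contributes once.
#'
#' @param state a [CPMState-class].
#' @return The energy (numeric scalar).
#' @export
cpmHamiltonian <- function(state) {
  spin <- state@spin
  nr <- nrow(spin); nc <- ncol(spin)
  typeGrid <- matrix(cpmTypeOf(state, spin), nr, nc) + 1L
  Jsum <- 0
  # vertical bonds
  a <- spin[-nr, , drop = FALSE]; b <- spin[-1L, , drop = FALSE]
  ta <- typeGrid[-nr, , drop = FALSE]; tb <- typeGrid[-1L, , drop = FALSE]
  diff <- a != b
  Jsum <- Jsum + sum(state@adhesion[cbind(ta[diff], tb[diff])])
  # horizontal bonds
  a <- spin[, -nc, drop = FALSE]; b <- spin[, -1L, drop = FALSE]
  ta <- typeGrid[, -nc, drop = FALSE]; tb <- typeGrid[, -1L, drop = FALSE]
  diff <- a != b
  Jsum <- Jsum + sum(state@adhesion[cbind(ta[diff], tb[diff])])
  Jsum + state@lambdaV * sum((state@volume - state@targetVolume)^2)
}

cpmNeighbourOffsets <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L),
                              ncol = 2L, byrow = TRUE)

# Local energy change of copying spin `s1` onto site (r, c) holding `s0`.
cpmDeltaH <- function(state, r, c, s1) {
  spin <- state@spin
  s0 <- spin[r, c]
  nr <- nrow(spin); nc <- ncol(spin)
  t0 <- cpmTypeOf(state, s0) + 1L
  t1 <- cpmTypeOf(state, s1) + 1L
  dH <- 0
  for (k in 1:4) {
    rr <- r + cpmNeighbourOffsets[k, 1L]; cc <- c + cpmNeighbourOffsets[k, 2L]
    if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
    sn <- spin[rr, cc]
    tn <- cpmTypeOf(state, sn) + 1L
    if (sn != s0) dH <- dH - state@adhesion[t0, tn]
    if (sn != s1) dH <- dH + state@adhesion[t1, tn]
  }
  lam <- state@lambdaV
  if (s0 > 0L) {
    v <- state@volume[s0]; vt <- state@targetVolume[s0]
    dH <- dH + lam * ((v - 1 - vt)^2 - (v - vt)^2)
  }
  if (s1 > 0L) {
    v <- state@volume[s1]; vt <- state@targetVolume[s1]
    dH <- dH + lam * ((v + 1 - vt)^2 - (v - vt)^2)
  }
  dH
}

#' Monte Carlo sweeps of the cellular Potts model
#'
#' One sweep is `width * height` elementary copy attempts: pick a random
#' site and a random 4-neighbour, propose copying the neighbour's spin onto
#' the site, compute the local energy change, and accept with probability
#' `min(1, exp(-dH / T))`. Proposals whose neighbour falls outside the
#' lattice (no wraparound) or carries the same spin leave the state
#' unchanged. Per-cell volumes are updated incrementally.
#'
#' @param state a [CPMState-class].
#' @param nSweeps number of sweeps.
#' @param temperature Metropolis temperature; defaults to the state's.
#' @param record if `TRUE`, attach an attribute `"attempts"`: a data.frame
#'   with one row per non-trivial attempt (`row`, `col`, `newSpin`, `dH`,
#'   `accepted`) for audit against a full energy recomputation.
#' @return The updated [CPMState-class].
#' @export
cpmStep <- function(state, nSweeps = 1, temperature = state@temperature,
                    record = FALSE) {
  if (temperature <= 0) stop("temperature must be > 0")
  spin <- state@spin
  nr <- nrow(spin); nc <- ncol(spin)
  nAttempts <- nr * nc * nSweeps
  log <- if (record) vector("list", nAttempts) else NULL
  for (a in seq_len(nAttempts)) {
    site <- sample.int(nr * nc, 1L)
    r <- ((site - 1L) %% nr) + 1L
    c <- ((site - 1L) %/% nr) + 1L
    k <- sample.int(4L, 1L)
    rr <- r + cpmNeighbourOffsets[k, 1L]; cc <- c + cpmNeighbourOffsets[k, 2L]
    if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
    s1 <- state@spin[rr, cc]
    s0 <- state@spin[r, c]
    if (s1 == s0) next
    dH <- cpmDeltaH(state, r, c, s1)
    accept <- dH <= 0 || stats::runif(1L) < exp(-dH / temperature)
    if (record)
      log[[a]] <- data.frame(row = r, col = c, oldSpin = s0, newSpin = s1,
                             dH = dH, accepted = accept)
    if (accept) {
      state@spin[r, c] <- s1
      if (s0 > 0L) state@volume[s0] <- state@volume[s0] - 1L
      if (s1 > 0L) state@volume[s1] <- state@volume[s1] + 1L
    }
  }
  if (record)
    attr(state, "attempts") <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  state
}
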