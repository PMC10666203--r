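# Posterior diagnostics: effective sample size, weighted quantiles and
# credible intervals, epsilon / proposal-count trajectories, weighted 2-D
# kernel density estimation, and a weighted two-sample KS test used to
# compare sampler outputs.

#' Effective sample size of an importance-weighted population
#'
#' `ESS = 1 / sum(w_i^2)` for normalised weights: the equivalent number of
#' unweighted samples. Lies in `[1, N]`; `N` for uniform weights, 1 when a
#' single particle carries all mass.
#'
#' @param weights normalised non-negative weight vector (sum 1).
#' @return The effective sample size.
#' @examples
#' ess(rep(1 / 1000, 1000))  # 1000
#' ess(c(0.5, 0.5))          # 2
#' @export
ess <- function(weights) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("domain error: weights must be non-negative and sum to 1")
  1 / sum(weights^2)
}

#' Weighted empirical quantile (type 1)
#'
#' The smallest sample value whose cumulative weight reaches `q`, after
#' sorting by value — the same no-interpolation convention used for the
#' epsilon schedule.
#'
#' @param x sample values.
#' @param w weights (any positive scale; normalised internally).
#' @param q quantile level(s) in `[0, 1]`.
#' @return Quantile value(s).
#' @export
weightedQuantile <- function(x, w, q) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(q, function(qq) x[which(cw >= qq - 1e-12)[1]], numeric(1))
}

#' Weighted credible intervals
#'
#' Equal-tailed weighted posterior intervals: the type-1 weighted quantiles
#' at `(1 - level)/2` and `1 - (1 - level)/2`, per parameter.
#'
#' @param thetas numeric vector or matrix (columns = parameters).
#' @param weights normalised weights.
#' @param level credible level in (0, 1).
#' @return Matrix with one row per parameter and columns `lower`, `upper`.
#' @export
credibleInterval <- function(thetas, weights, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  thetas <- as.matrix(thetas)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- t(apply(thetas, 2, weightedQuantile, w = weights, q = qs))
  colnames(out) <- c("lower", "upper")
  out
}

#' Per-generation trajectories from a result store
#'
#' `epsilonTrajectory` returns the acceptance threshold per generation
#' (non-increasing by construction); `samplesPerGeneration` the proposal
#' counts against the population size.
#'
#' @param store a [ResultStore-class].
#' @return data.frame ordered by generation.
#' @export
epsilonTrajectory <- function(store) {
  if (!length(store@generations)) stop("result store is empty")
  data.frame(
    t = vapply(store@generations, function(g) g@generation, integer(1)),
    epsilon = vapply(store@generations, function(g) g@epsilon, numeric(1)))
}

#' @rdname epsilonTrajectory
#' @export
samplesPerGeneration <- function(store) {
  if (!length(store@generations)) stop("result store is empty")
  data.frame(
    t = vapply(store@generations, function(g) g@generation, integer(1)),
    total_proposals = vapply(store@generations, function(g)
      g@totalProposals, integer(1)),
    N = vapply(store@generations, function(g) nrow(g@particles),
               integer(1)))
}

weightedSd <- function(x, w) {
  mu <- sum(w * x)
  v <- sum(w * (x - mu)^2)
  denom <- 1 - sum(w^2)
  sqrt(if (denom > 0) v / denom else v)
}

#' Weighted two-dimensional kernel density estimate
#'
#' Gaussian-product KDE with per-dimension bandwidth equal to the Silverman
#' factor `n_eff^(-1/6)` (the d = 2 rule) times the weighted standard
#' deviation, with `n_eff` the effective sample size of the weights. On a
#' grid covering about five bandwidths beyond the sample range the density
#' integrates to 1 (trapezoid rule) to within 1e-3. A single sample has no
#' scale and falls back to a unit bandwidth; a zero-variance dimension with
#' more than one sample is an error (use a rug plot instead).
#'
#' @param x,y sample coordinates.
#' @param weights normalised weights (default uniform).
#' @param n grid nodes per dimension.
#' @param lims `c(xmin, xmax, ymin, ymax)`; defaults to the weighted range
#'   extended by five bandwidths.
#' @return list with `x`, `y` (grid node vectors) and `density` (matrix,
#'   rows follow `x`).
#' @export
kde2d <- function(x, y, weights = NULL, n = 64, lims = NULL) {
  m <- length(x)
  if (length(y) != m) stop("x and y must have equal length")
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalised")
  neff <- 1 / sum(weights^2)
  sx <- weightedSd(x, weights)
  sy <- weightedSd(y, weights)
  if (m == 1L) {
    # a lone sample has no scale: fall back to a unit-bandwidth kernel
    sx <- sy <- 1
  } else if (sx == 0 || sy == 0) {
    stop("degenerate-KDE error: zero weighted variance in a dimension; ",
         "consider a rug plot instead")
  }
  h <- neff^(-1 / 6)
  bx <- h * sx
  by <- h * sy
  if (is.null(lims))
    lims <- c(min(x) - 5 * bx, max(x) + 5 * bx,
              min(y) - 5 * by, max(y) + 5 * by)
  gx <- seq(lims[1], lims[2], length.out = n)
  gy <- seq(lims[3], lims[4], length.out = n)
  kx <- outer(gx, x, function(g, s) stats::dnorm(g, s, bx))
  ky <- outer(gy, y, function(g, s) stats::dnorm(g, s, by))
  dens <- kx %*% (weights * t(ky))
  list(x = gx, y = gy, density = dens)
}

#' Weighted two-sample Kolmogorov-Smirnov test
#'
#' Compares two weighted one-dimensional samples through the maximum
#' distance between their weighted empirical cdfs. Significance uses the
#' asymptotic Kolmogorov distribution with the effective sample sizes of
#' the weight vectors in place of the counts.
#'
#' @param x1,x2 sample values.
#' @param w1,w2 weights (default uniform; normalised internally).
#' @return list with `statistic` (D), `nEff1`, `nEff2`, and `p.value`.
#' @export
weightedKS <- function(x1, x2, w1 = NULL, w2 = NULL) {
  if (is.null(w1)) w1 <- rep(1, length(x1))
  if (is.null(w2)) w2 <- rep(1, length(x2))
  w1 <- w1 / sum(w1)
  w2 <- w2 / sum(w2)
  grid <- sort(unique(c(x1, x2)))
  cdf <- function(x, w) {
    ord <- order(x)
    stats::approxfun(x[ord], cumsum(w[ord]), method = "constant",
                     yleft = 0, yright = 1, ties = "ordered")(grid)
  }
  D <- max(abs(cdf(x1, w1) - cdf(x2, w2)))
  n1 <- 1 / sum(w1^2)
  n2 <- 1 / sum(w2^2)
  lambda <- D * sqrt(n1 * n2 / (n1 + n2))
  p <- if (lambda < 0.27) {
    1  # the alternating series is numerically unusable here; cdf ~ 0
  } else {
    k <- 1:100
    max(0, min(1, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(statistic = D, nEff1 = n1, nEff2 = n2, p.value = p)
}
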