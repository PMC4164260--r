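## Dirichlet-process mixture machinery: Chinese-restaurant-process prior
## weights, conjugate normal-inverse-gamma component model with its
## Student-t posterior predictive, and the expected cluster count of the
## DP prior. The sampler works with the collapsed (marginal) representation:
## cluster parameters are integrated out against the base measure, so each
## cluster is summarized by (n, sum, sumsq).

#' Chinese restaurant process prior weights
#'
#' Conditional prior over the cluster assignment of one further observation
#' given current cluster sizes: an existing cluster of size \eqn{n_k}
#' attracts with probability \eqn{n_k/(n+\alpha)}, a new cluster with
#' probability \eqn{\alpha/(n+\alpha)}.
#'
#' @param clusterSizes integer vector of positive cluster sizes (possibly
#'   empty).
#' @param alpha positive concentration parameter.
#' @return numeric probability vector of length \code{length(clusterSizes)+1};
#'   the last entry is the new-cluster mass. Sums to 1.
#' @export
crpWeights <- function(clusterSizes, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number")
  if (length(clusterSizes) && any(clusterSizes < 1))
    stop("cluster sizes must be >= 1")
  n <- sum(clusterSizes)
  c(clusterSizes, alpha) / (n + alpha)
}

#' Absorb one observation into component statistics
#'
#' @param stats a \linkS4class{ComponentStats}.
#' @param x observation.
#' @return updated \linkS4class{ComponentStats}.
#' @export
addPoint <- function(stats, x) {
  new("ComponentStats", n = stats@n + 1, sum = stats@sum + x,
      sumsq = stats@sumsq + x^2)
}

#' Remove one previously added observation
#'
#' Exact inverse of \code{\link{addPoint}}; a component emptied by the
#' removal returns to (0, 0, 0) exactly.
#'
#' @param stats a \linkS4class{ComponentStats}.
#' @param x observation previously added.
#' @return updated \linkS4class{ComponentStats}.
#' @export
removePoint <- function(stats, x) {
  if (stats@n < 1) stop("cannot remove from an empty component")
  n <- stats@n - 1
  if (n == 0) return(new("ComponentStats", n = 0, sum = 0, sumsq = 0))
  new("ComponentStats", n = n, sum = stats@sum - x, sumsq = stats@sumsq - x^2)
}

## Posterior normal-inverse-gamma parameters given component stats.
nigPosterior <- function(stats, base) {
  n <- stats@n
  kn <- base@kappa0 + n
  mun <- (base@kappa0 * base@mu0 + stats@sum) / kn
  an <- base@a0 + n / 2
  bn <- base@b0
  if (n > 0) {
    xbar <- stats@sum / n
    ss <- max(stats@sumsq - n * xbar^2, 0)
    bn <- bn + ss / 2 + base@kappa0 * n * (xbar - base@mu0)^2 / (2 * kn)
  }
  list(mu = mun, kappa = kn, a = an, b = bn)
}

#' Log posterior-predictive density of a component
#'
#' Student-t density of one further observation from a cluster with the
#' given sufficient statistics, the Gaussian likelihood's (mean, variance)
#' integrated against the normal-inverse-gamma posterior. With empty stats
#' this is the prior predictive — the "zero component" responsible for
#' opening new clusters.
#'
#' @param x observation(s).
#' @param stats a \linkS4class{ComponentStats}.
#' @param base a \linkS4class{BaseMeasure}.
#' @return log density value(s).
#' @export
predictiveLogDensity <- function(x, stats, base) {
  validObject(base)
  p <- nigPosterior(stats, base)
  nu <- 2 * p$a
  s2 <- p$b * (p$kappa + 1) / (p$a * p$kappa)
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi * s2) -
    (nu + 1) / 2 * log1p((x - p$mu)^2 / (nu * s2))
}

#' Expected number of clusters under the DP prior
#'
#' \eqn{E[K] = \sum_{i=1}^{n} \alpha/(\alpha+i-1)} for n observations.
#'
#' @param n number of observations (>= 1).
#' @param alpha positive concentration.
#' @return expected cluster count.
#' @export
expectedClusterCount <- function(n, alpha) {
  if (n < 1) stop("n must be >= 1")
  sum(alpha / (alpha + seq_len(n) - 1))
}

#' Simulate sequential CRP partitions
#'
#' Draws \code{nDraws} partitions of \code{n} items by sequential CRP
#' sampling (each item joins an existing cluster with probability
#' proportional to its size, a new one with probability proportional to
#' \code{alpha}). Each draw is returned as its canonical
#' restricted-growth label string encoded base-\code{n} into one integer
#' (label of item i times n^(i-1), summed), suitable for tabulating the
#' partition distribution. Uses R's global RNG stream.
#'
#' @param nDraws number of partitions to draw.
#' @param n number of items per partition (<= 9).
#' @param alpha positive concentration.
#' @return integer vector of length \code{nDraws} of partition codes.
#' @export
simulateCrpPartitions <- function(nDraws, n, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  cpp_crp_codes(as.integer(nDraws), as.integer(n), as.numeric(alpha))
}

#' Data-driven default base measure
#'
#' mu0 = mean intensity, kappa0 = 0.01 (weak prior on the mean), a0 = 2,
#' b0 = intensity variance (or 1 for degenerate constant data).
#'
#' @param x numeric intensities.
#' @return a \linkS4class{BaseMeasure}.
#' @export
defaultBaseMeasure <- function(x) {
  v <- if (length(x) > 1) var(x) else 0
  if (!is.finite(v) || v <= 0) v <- 1
  BaseMeasure(mu0 = mean(x), kappa0 = 0.01, a0 = 2, b0 = v)
}
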