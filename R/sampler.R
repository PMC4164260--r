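## MRF-constrained collapsed Gibbs sampling of the DP mixture labels.
##
## The label conditional at site i multiplies three factors:
##   * the CRP prior weight (cluster size, or alpha for a new cluster),
##   * the MRF smoothness factor exp(-H) with the binary Potts cost
##       H = -lambda * sum_{l in d(i)} w_il * [candidate == S_l]
##     (a new label matches no neighbor, so its factor is exactly 1),
##   * the Student-t posterior predictive of the candidate cluster.
## Sweeps visit the unmasked sites in fixed raster order; empty clusters
## are deleted and labels compacted immediately. The hot loop lives in
## src/sampler.cpp; siteConditional() below is an independent R rendering
## of the same conditional used for verification.

#' Create a sampler state from an image
#'
#' Sites are initialized over-segmented, into \code{initClusters}
#' equal-frequency intensity bins (deterministic). Single-site collapsed
#' Gibbs merges redundant clusters easily but cannot split a large cluster
#' in one move, so starting over-segmented lets the chain find the cluster
#' count from above; it also yields the expected convergence profile
#' (many reassignments early, stabilizing below 1\% of sites).
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param alpha DP concentration (> 0).
#' @param lambda MRF smoothness weight (>= 0; 0 = unconstrained).
#' @param base a \linkS4class{BaseMeasure}, or \code{NULL} for data-driven
#'   defaults.
#' @param connectivity neighborhood connectivity, 4 or 8.
#' @param initClusters number of initial intensity-quantile clusters
#'   (capped at the number of sites).
#' @return a \linkS4class{SamplerState}.
#' @export
makeSamplerState <- function(image, alpha = 1, lambda = 1, base = NULL,
                             connectivity = 4L, initClusters = 20L) {
  stopifnot(is(image, "IntensityImage"))
  m <- brainMask(image)
  g <- gridGraph(dim(image), connectivity = connectivity, mask = m)
  x <- if (is.null(m)) as.vector(pixels(image)) else pixels(image)[m]
  if (length(x) == 0) stop("image has no unmasked sites")
  if (is.null(base)) base <- defaultBaseMeasure(x)
  K0 <- max(1L, min(as.integer(initClusters), length(x)))
  lab <- if (K0 == 1L) rep(0L, length(x)) else
    as.integer(cut(rank(x, ties.method = "first"), K0)) - 1L
  compN <- as.numeric(tabulate(lab + 1L, nbins = K0))
  compSum <- vapply(seq_len(K0) - 1L, function(k) sum(x[lab == k]), 0)
  compSumsq <- vapply(seq_len(K0) - 1L, function(k) sum(x[lab == k]^2), 0)
  new("SamplerState", x = as.numeric(x), labels = lab,
      compN = compN, compSum = compSum, compSumsq = compSumsq,
      alpha = as.numeric(alpha), lambda = as.numeric(lambda),
      base = base, graph = g)
}

setMethod("nClusters", "SamplerState",
          function(object) length(object@compN))

#' Binary (Potts) MRF cost of a candidate label at a site
#'
#' \eqn{H = -\lambda \sum_{l \in \partial(i)} \omega_{il}
#' \delta(\mathrm{candidate}, S_l)}; always <= 0, and 0 when the candidate
#' matches no neighbor, so \eqn{\exp(-H) \ge 1} rewards agreement.
#'
#' @param labels integer vector of per-site labels (0-based), or a
#'   \linkS4class{SamplerState}.
#' @param site 1-based site index.
#' @param candidate candidate label (0-based).
#' @param lambda smoothness weight >= 0.
#' @param graph a \linkS4class{NeighborhoodGraph} (taken from the state if
#'   \code{labels} is a \linkS4class{SamplerState}).
#' @return the scalar cost H.
#' @export
binaryCost <- function(labels, site, candidate, lambda, graph = NULL) {
  if (is(labels, "SamplerState")) {
    graph <- labels@graph
    labels <- labels@labels
  }
  if (lambda < 0) stop("lambda must be >= 0")
  nb <- neighborsOf(graph, site)
  -lambda * sum(nb$w * (labels[nb$nbr] == candidate), na.rm = TRUE)
}

#' Quadratic MRF cost over continuous cluster parameters
#'
#' \eqn{\sum_{l \in \partial(i)} \| \theta_{cand} - \theta_l \|^2}: the
#' continuous-parameter alternative to \code{\link{binaryCost}}. Provided
#' for completeness; the default pipeline uses the binary cost.
#'
#' @param thetaValues per-site parameter values.
#' @param site 1-based site index.
#' @param candidateTheta candidate parameter value.
#' @param graph a \linkS4class{NeighborhoodGraph}.
#' @return the scalar cost.
#' @export
quadraticCost <- function(thetaValues, site, candidateTheta, graph) {
  nb <- neighborsOf(graph, site)
  sum((candidateTheta - thetaValues[nb$nbr])^2)
}

#' Full conditional label distribution at one site
#'
#' Removes the site's observation from its cluster (deleting the cluster
#' and compacting labels if it empties), then returns the normalized
#' probability vector over the K remaining clusters plus a new one:
#' entry k proportional to \eqn{n_k \exp(-H_k) t(x_i | \mathrm{stats}_k)},
#' the last entry proportional to \eqn{\alpha \, t(x_i | \emptyset)}.
#'
#' @param state a \linkS4class{SamplerState}.
#' @param site 1-based site index.
#' @return probability vector of length K+1 (sums to 1).
#' @export
siteConditional <- function(state, site) {
  stopifnot(is(state, "SamplerState"))
  validObject(state)
  x <- state@x
  lab <- state@labels
  if (site < 1 || site > length(x)) stop("site outside the state")
  cur <- lab[site]
  n <- state@compN; s <- state@compSum; ss <- state@compSumsq
  n[cur + 1L] <- n[cur + 1L] - 1
  s[cur + 1L] <- s[cur + 1L] - x[site]
  ss[cur + 1L] <- ss[cur + 1L] - x[site]^2
  if (n[cur + 1L] <= 0) {
    keep <- -(cur + 1L)
    n <- n[keep]; s <- s[keep]; ss <- ss[keep]
    lab[lab > cur] <- lab[lab > cur] - 1L
  }
  lab[site] <- NA_integer_
  K <- length(n)
  logw <- numeric(K + 1)
  for (k in seq_len(K)) {
    st <- new("ComponentStats", n = n[k], sum = s[k],
              sumsq = max(ss[k], if (n[k] > 0) s[k]^2 / n[k] else 0))
    logw[k] <- log(n[k]) -
      binaryCost(lab, site, k - 1L, state@lambda, state@graph) +
      predictiveLogDensity(x[site], st, state@base)
  }
  logw[K + 1] <- log(state@alpha) +
    predictiveLogDensity(x[site], ComponentStats(), state@base)
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' One Gibbs sweep over all sites
#'
#' Visits every site in raster order, resampling its label from
#' \code{\link{siteConditional}}'s distribution; deletes emptied clusters.
#' Uses R's global RNG stream (seed with \code{set.seed} for
#' reproducibility).
#'
#' @param state a \linkS4class{SamplerState}.
#' @return list with the updated \code{state} and \code{nChanged}, the
#'   number of sites whose cluster membership changed.
#' @export
gibbsSweep <- function(state) {
  stopifnot(is(state, "SamplerState"))
  g <- state@graph
  res <- cpp_gibbs_sweep(state@x, g@offsets, g@nbr - 1L, g@w,
                         state@labels, state@alpha, state@lambda,
                         state@base@mu0, state@base@kappa0,
                         state@base@a0, state@base@b0)
  state@labels <- res$labels
  state@compN <- res$compN
  state@compSum <- res$compSum
  state@compSumsq <- res$compSumsq
  list(state = state, nChanged = res$nChanged)
}

#' Convergence rule on the assignment-change trace
#'
#' The chain is considered stable once the number of assignments changed
#' per sweep stays below 1\% of the total number of sites for
#' \code{window} consecutive sweeps.
#'
#' @param trace a \linkS4class{SamplerTrace} or an integer vector of
#'   per-sweep change counts.
#' @param nSites total number of sites.
#' @param window number of consecutive qualifying sweeps required.
#' @param fraction stability threshold as a fraction of \code{nSites}.
#' @return logical.
#' @export
hasConverged <- function(trace, nSites, window = 3L, fraction = 0.01) {
  if (is(trace, "SamplerTrace")) trace <- trace@nChanged
  if (window < 1L) stop("window must be >= 1")
  n <- length(trace)
  if (n < window) return(FALSE)
  all(trace[(n - window + 1L):n] < fraction * nSites)
}

#' Run the MRF-constrained DP mixture sampler
#'
#' Initializes all sites in one cluster and sweeps until
#' \code{\link{hasConverged}} or \code{maxIterations} (whichever first),
#' returning the terminal label field and the full per-iteration trace.
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param alpha DP concentration.
#' @param lambda MRF smoothness weight.
#' @param base optional \linkS4class{BaseMeasure}.
#' @param maxIterations sweep cap.
#' @param window convergence window (consecutive stable sweeps).
#' @param connectivity 4 or 8.
#' @param seed optional integer seed (calls \code{set.seed}).
#' @param earlyStop if \code{FALSE}, always run \code{maxIterations}
#'   sweeps (useful for trace analysis).
#' @param initClusters number of initial intensity-quantile clusters.
#' @return list with \code{labels} (a \linkS4class{LabelField}, \code{NA}
#'   at masked-out pixels), \code{trace} (a \linkS4class{SamplerTrace})
#'   and \code{state} (the terminal \linkS4class{SamplerState}).
#' @export
runSampler <- function(image, alpha = 1, lambda = 1, base = NULL,
                       maxIterations = 200L, window = 3L,
                       connectivity = 4L, seed = NULL, earlyStop = TRUE,
                       initClusters = 20L) {
  if (!is.null(seed)) set.seed(seed)
  state <- makeSamplerState(image, alpha = alpha, lambda = lambda,
                            base = base, connectivity = connectivity,
                            initClusters = initClusters)
  g <- state@graph
  res <- cpp_run_sampler(state@x, g@offsets, g@nbr - 1L, g@w,
                         state@labels, state@alpha, state@lambda,
                         state@base@mu0, state@base@kappa0,
                         state@base@a0, state@base@b0,
                         as.integer(maxIterations), as.integer(window),
                         0.01, isTRUE(earlyStop))
  state@labels <- res$labels
  state@compN <- res$compN
  state@compSum <- res$compSum
  state@compSumsq <- res$compSumsq
  labMat <- matrix(NA_integer_, dim(image)[1], dim(image)[2])
  labMat[!is.na(g@siteIndex)] <- res$labels[g@siteIndex[!is.na(g@siteIndex)]]
  trace <- new("SamplerTrace",
               iteration = seq_along(res$nClusters),
               nClusters = as.integer(res$nClusters),
               nChanged = as.integer(res$nChanged))
  list(labels = LabelField(labMat), trace = trace, state = state)
}

#' Fraction of discordant neighbor pairs in a label field
#'
#' The proportion of neighboring site pairs carrying different labels — a
#' direct readout of how strongly the MRF term smooths the segmentation
#' (it decreases as lambda grows).
#'
#' @param labels a \linkS4class{LabelField} or integer label matrix.
#' @param connectivity 4 or 8.
#' @return fraction in [0, 1].
#' @export
discordantPairFraction <- function(labels, connectivity = 4L) {
  lab <- if (is(labels, "LabelField")) labels4(labels) else labels
  g <- gridGraph(dim(lab), connectivity = connectivity, mask = !is.na(lab))
  v <- lab[!is.na(lab)]
  from <- rep(seq_len(g@nSites), diff(g@offsets))
  disc <- v[from] != v[g@nbr]
  sum(disc) / length(disc)
}
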