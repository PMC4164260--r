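# Independent oracles used across the suite. Everything here is written
# against the model definitions directly (explicit loops, quadrature,
# enumeration), never by calling the package's own fast paths.

# Student-t posterior predictive via stats::dt on raw cluster values:
# posterior parameters recomputed from the raw data (not from sufficient
# statistics) and the density evaluated through the location-scale t.
oracleStudentPredictive <- function(x, values, mu0, kappa0, a0, b0) {
  n <- length(values)
  kn <- kappa0 + n
  mun <- (kappa0 * mu0 + sum(values)) / kn
  an <- a0 + n / 2
  bn <- b0 + 0.5 * sum((values - mean(c(values)))^2) * (n > 0) +
    if (n > 0) kappa0 * n * (mean(values) - mu0)^2 / (2 * kn) else 0
  if (n == 0) bn <- b0
  nu <- 2 * an
  scale <- sqrt(bn * (kn + 1) / (an * kn))
  stats::dt((x - mun) / scale, df = nu) / scale
}

# Fully numeric marginal-likelihood route: f(x | data) as the ratio of two
# 2-D quadratures of Normal likelihood x normal-inverse-gamma prior over
# (mu, log variance). Independent of all posterior-update algebra; the
# integrand is log-stabilized around a rough (mu, v) reference point.
quadraturePredictive <- function(x, values, mu0, kappa0, a0, b0) {
  logMarginal <- function(obs) {
    n <- length(obs)
    logJoint <- function(mu, lv) {   # includes the dv = v dlv Jacobian
      v <- exp(lv)
      -sum((obs - mu)^2) / (2 * v) - n / 2 * log(2 * pi * v) +
        stats::dnorm(mu, mu0, sqrt(v / kappa0), log = TRUE) +
        a0 * log(b0) - lgamma(a0) - (a0 + 1) * lv - b0 / v + lv
    }
    muhat <- (kappa0 * mu0 + sum(obs)) / (kappa0 + n)
    vhat <- (b0 + 0.5 * sum((obs - muhat)^2)) / (a0 + n / 2 + 1)
    ref <- logJoint(muhat, log(vhat))
    outer_f <- function(lvv) {
      vapply(lvv, function(lv) {
        stats::integrate(function(mu)
          exp(vapply(mu, logJoint, 0, lv = lv) - ref),
          -Inf, Inf, rel.tol = 1e-10)$value
      }, 0)
    }
    val <- stats::integrate(outer_f, log(vhat) - 35, log(vhat) + 35,
                            rel.tol = 1e-10)$value
    ref + log(val)
  }
  exp(logMarginal(c(values, x)) - logMarginal(values))
}

# Brute-force site conditional on a tiny grid: explicit loops multiplying
# the CRP prior weight, the Potts factor exp(-H) with a literal
# delta-function neighbor loop, and the Student-t predictive on raw values.
# clusterValues: list of numeric vectors, one per cluster (0-based labels).
oracleSiteConditional <- function(x, labelsMat, site, alpha, lambda,
                                  mu0, kappa0, a0, b0) {
  nr <- nrow(labelsMat); nc <- ncol(labelsMat)
  rc <- c((site - 1) %% nr + 1, (site - 1) %/% nr + 1)
  xi <- x[rc[1], rc[2]]
  lab <- labelsMat
  lab[rc[1], rc[2]] <- NA
  used <- sort(unique(as.vector(lab[!is.na(lab)])))
  # compact exactly as the sampler does: drop gaps, shift higher labels down
  relab <- lab
  for (idx in seq_along(used)) relab[lab == used[idx]] <- idx - 1L
  K <- length(used)
  nTot <- sum(!is.na(relab))
  w <- numeric(K + 1)
  for (k in seq_len(K)) {
    vals <- x[!is.na(relab) & relab == (k - 1L)]
    H <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- rc[1] + d[1]; cc <- rc[2] + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !is.na(relab[rr, cc]) && relab[rr, cc] == (k - 1L))
        H <- H - lambda * 1
    }
    w[k] <- length(vals) / (nTot + alpha) * exp(-H) *
      oracleStudentPredictive(xi, vals, mu0, kappa0, a0, b0)
  }
  w[K + 1] <- alpha / (nTot + alpha) *
    oracleStudentPredictive(xi, numeric(0), mu0, kappa0, a0, b0)
  w / sum(w)
}

# All set partitions of 1..n as canonical restricted-growth strings.
allPartitionsRGS <- function(n) {
  out <- list()
  recurse <- function(prefix, maxLab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in 0:(maxLab + 1))
      recurse(c(prefix, lab), max(maxLab, lab))
  }
  recurse(integer(0), -1L)
  out
}

# Exact CRP/Ewens probability of one canonical partition (label vector):
# alpha^K * prod((size_k - 1)!) / (alpha * (alpha+1) * ... * (alpha+n-1))
ewensProbability <- function(rgs, alpha) {
  sizes <- table(rgs)
  n <- length(rgs)
  exp(length(sizes) * log(alpha) + sum(lgamma(as.numeric(sizes))) -
        sum(log(alpha + 0:(n - 1))))
}

# Encode a canonical label vector the same way cpp_crp_codes does
rgsCode <- function(rgs, n) sum(rgs * n^(seq_along(rgs) - 1))

# From-scratch recomputation of per-cluster sufficient statistics
recomputeStats <- function(x, labels0) {
  K <- max(labels0) + 1L
  list(n = vapply(seq_len(K) - 1L, function(k) sum(labels0 == k), 0),
       s = vapply(seq_len(K) - 1L, function(k) sum(x[labels0 == k]), 0),
       ss = vapply(seq_len(K) - 1L, function(k) sum(x[labels0 == k]^2), 0))
}

# Total variation of an image (sum of absolute 4-neighbor differences)
totalVariation <- function(P) {
  sum(abs(P[-1, ] - P[-nrow(P), ])) + sum(abs(P[, -1] - P[, -ncol(P)]))
}

# Small random sampler state on a full grid for property tests
randomState <- function(nr, nc, K, alpha = 1, lambda = 1, seed = 1) {
  set.seed(seed)
  img <- IntensityImage(matrix(rnorm(nr * nc, 100, 30), nr, nc))
  st <- makeSamplerState(img, alpha = alpha, lambda = lambda,
                         initClusters = K)
  st
}
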