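# MRF-constrained collapsed Gibbs sampler: cost functions, the single-site
# conditional against a brute-force oracle and against the compiled path,
# sweep bookkeeping, the convergence rule, and exact recovery on a
# separable instance.

test_that("binary Potts cost counts matching neighbors", {
  st <- randomState(3, 3, K = 3, lambda = 0.5, seed = 21)
  lab <- st@labels
  # center site of the 3x3 full grid is site 5 (column-major)
  nb <- neighborsOf(st@graph, 5)
  expect_length(nb$nbr, 4)
  for (cand in 0:2) {
    matches <- sum(lab[nb$nbr] == cand)
    expect_equal(binaryCost(st, 5, cand, lambda = 0.5), -0.5 * matches)
  }
  # candidate matching no neighbor: H = 0 so exp(-H) = 1
  expect_equal(binaryCost(st, 5, 99L, lambda = 0.5), 0)
  expect_equal(exp(-binaryCost(st, 5, 99L, lambda = 0.5)), 1)
  # lambda = 0: H = 0 for every candidate
  for (cand in 0:2) expect_equal(binaryCost(st, 5, cand, lambda = 0), 0)
  # a hand-built case: 2 of 4 unit-weight neighbors match, lambda = 0.5
  labs <- c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L)
  g <- gridGraph(c(3, 3))
  expect_equal(binaryCost(labs, 5, 0L, lambda = 0.5, graph = g), -1)
})

test_that("quadratic cost matches a naive double loop", {
  g <- gridGraph(c(4, 4))
  set.seed(22)
  theta <- rnorm(16)
  for (site in c(1, 6, 16)) {
    cand <- rnorm(1)
    naive <- 0
    for (l in seq_len(16)) {
      if (l %in% neighborsOf(g, site)$nbr)
        naive <- naive + (cand - theta[l])^2
    }
    expect_equal(quadraticCost(theta, site, cand, g), naive)
  }
  expect_equal(quadraticCost(rep(2, 16), 6, 2, g), 0)
  # one neighbor at distance d contributes d^2
  th <- rep(7, 16)
  nb1 <- neighborsOf(g, 1)$nbr
  th[nb1[1]] <- 7 - 3
  expect_equal(quadraticCost(th, 1, 7, g), 3^2)
})

test_that("site conditional matches the brute-force oracle on 2x2 grids", {
  set.seed(23)
  for (rep in 1:8) {
    P <- matrix(rnorm(4, 10, 4), 2, 2)
    img <- IntensityImage(P)
    alpha <- runif(1, 0.3, 3); lambda <- runif(1, 0, 2)
    base <- BaseMeasure(mu0 = 10, kappa0 = 0.4, a0 = 2, b0 = 3)
    st <- makeSamplerState(img, alpha = alpha, lambda = lambda,
                           base = base, initClusters = sample(1:3, 1))
    labMat <- matrix(st@labels, 2, 2)
    for (site in 1:4) {
      got <- siteConditional(st, site)
      want <- oracleSiteConditional(P, labMat, site, alpha, lambda,
                                    mu0 = 10, kappa0 = 0.4, a0 = 2, b0 = 3)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("R and compiled site conditionals agree", {
  st <- randomState(5, 4, K = 4, alpha = 1.3, lambda = 0.8, seed = 24)
  g <- st@graph
  for (site in c(1, 7, 13, 20)) {
    rWay <- siteConditional(st, site)
    cWay <- dpmrf:::cpp_site_conditional(
      st@x, g@offsets, g@nbr - 1L, g@w, st@labels, site - 1L,
      st@alpha, st@lambda, st@base@mu0, st@base@kappa0,
      st@base@a0, st@base@b0)
    expect_equal(rWay, as.numeric(cWay), tolerance = 1e-12)
  }
})

test_that("lambda = 0 reduces the conditional to the plain DP mixture", {
  set.seed(25)
  for (rep in 1:10) {
    st0 <- randomState(4, 4, K = 3, alpha = 2, lambda = 0, seed = 30 + rep)
    stBig <- st0; stBig@lambda <- 0
    # plain-MDP reference: CRP weight times predictive, no neighborhood term
    site <- sample(16, 1)
    plain <- local({
      x <- st0@x; lab <- st0@labels
      cur <- lab[site]
      n <- st0@compN; s <- st0@compSum; ss <- st0@compSumsq
      n[cur + 1] <- n[cur + 1] - 1
      s[cur + 1] <- s[cur + 1] - x[site]
      ss[cur + 1] <- ss[cur + 1] - x[site]^2
      if (n[cur + 1] <= 0) { n <- n[-(cur + 1)]; s <- s[-(cur + 1)]; ss <- ss[-(cur + 1)] }
      K <- length(n)
      w <- numeric(K + 1)
      for (k in seq_len(K)) {
        stK <- new("ComponentStats", n = n[k], sum = s[k],
                   sumsq = max(ss[k], s[k]^2 / n[k]))
        w[k] <- n[k] * exp(predictiveLogDensity(x[site], stK, st0@base))
      }
      w[K + 1] <- st0@alpha *
        exp(predictiveLogDensity(x[site], ComponentStats(), st0@base))
      w / sum(w)
    })
    expect_lt(max(abs(siteConditional(st0, site) - plain)), 1e-12)
  }
})

test_that("a new cluster draws no MRF boost", {
  # the *unnormalized* new-cluster mass is lambda-free: compare the ratio
  # of new-cluster to a fixed-size term across lambdas via binaryCost
  st <- randomState(4, 4, K = 3, lambda = 1, seed = 26)
  site <- 6
  # H for a brand-new label is 0 at any lambda
  expect_equal(binaryCost(st, site, 999L, lambda = 1), 0)
  expect_equal(binaryCost(st, site, 999L, lambda = 10), 0)
})

test_that("gibbs sweep keeps stats consistent and is seed-reproducible", {
  img <- IntensityImage(matrix(c(rnorm(50, 0, 1), rnorm(50, 20, 1)), 10, 10))
  st <- makeSamplerState(img, alpha = 1, lambda = 0.7, initClusters = 6)
  set.seed(27)
  res <- gibbsSweep(st)
  expect_true(validObject(res$state))
  expect_lte(res$nChanged, length(st@x))
  # incremental stats equal from-scratch recomputation exactly
  rec <- recomputeStats(res$state@x, res$state@labels)
  expect_identical(as.numeric(rec$n), res$state@compN)
  expect_equal(rec$s, res$state@compSum, tolerance = 1e-12)
  expect_equal(rec$ss, res$state@compSumsq, tolerance = 1e-12)
  # determinism
  set.seed(27)
  res2 <- gibbsSweep(st)
  expect_identical(res$state@labels, res2$state@labels)
  expect_identical(res$nChanged, res2$nChanged)
})

test_that("degenerate constant images keep the state valid", {
  img <- IntensityImage(matrix(5, 6, 6))
  st <- makeSamplerState(img, alpha = 50, lambda = 0.5, initClusters = 4)
  set.seed(28)
  for (i in 1:3) {
    res <- gibbsSweep(st)
    st <- res$state
    expect_true(validObject(st))
    expect_equal(sum(st@compN), 36)
  }
})

test_that("the convergence rule implements 'below 1% of sites'", {
  expect_true(hasConverged(c(500, 50, 3, 2, 2), nSites = 400, window = 3))
  expect_false(hasConverged(c(500, 50, 5), nSites = 400, window = 3))
  expect_false(hasConverged(c(500, 50, 4), nSites = 400, window = 3))  # 4 is not < 4
  expect_true(hasConverged(rep(0, 3), nSites = 10, window = 3))
  expect_false(hasConverged(c(0, 0), nSites = 10, window = 3))
  expect_error(hasConverged(c(1, 2), nSites = 10, window = 0), "window")
})

test_that("run sampler recovers a two-plateau image exactly for any lambda", {
  P <- matrix(0, 12, 12); P[, 7:12] <- 50
  img <- IntensityImage(P)
  for (lam in c(0, 0.5, 2)) {
    fit <- runSampler(img, alpha = 1, lambda = lam, seed = 31)
    expect_equal(nClusters(fit$labels), 2L)
    lab <- labels4(fit$labels)
    expect_equal(length(unique(lab[P == 0])), 1L)
    expect_equal(length(unique(lab[P == 50])), 1L)
    expect_true(lab[1, 1] != lab[1, 12])
  }
})

test_that("run sampler traces match stepwise sweeps and are deterministic", {
  img <- IntensityImage(matrix(rnorm(100, 50, 20), 10, 10))
  fit1 <- runSampler(img, seed = 32, maxIterations = 15, earlyStop = FALSE)
  fit2 <- runSampler(img, seed = 32, maxIterations = 15, earlyStop = FALSE)
  expect_identical(labels4(fit1$labels), labels4(fit2$labels))
  expect_identical(fit1$trace@nChanged, fit2$trace@nChanged)
  expect_length(fit1$trace@iteration, 15)
  # same RNG stream stepped manually one sweep at a time
  set.seed(32)
  st <- makeSamplerState(img)
  ks <- integer(15)
  for (i in 1:15) {
    res <- gibbsSweep(st)
    st <- res$state
    ks[i] <- length(st@compN)
  }
  expect_identical(ks, fit1$trace@nClusters)
  expect_identical(st@labels[st@graph@siteIndex[!is.na(st@graph@siteIndex)]],
                   as.integer(labels4(fit1$labels)))
})

test_that("masked-out sites are excluded from sampling and labeled NA", {
  msk <- matrix(TRUE, 8, 8); msk[1:3, 1:3] <- FALSE
  img <- IntensityImage(matrix(rnorm(64, 10, 2), 8, 8), mask = msk)
  fit <- runSampler(img, seed = 33)
  expect_true(all(is.na(labels4(fit$labels)[!msk])))
  expect_true(all(!is.na(labels4(fit$labels)[msk])))
})
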