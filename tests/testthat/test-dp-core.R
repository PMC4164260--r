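# DP mixture machinery: CRP weights, sufficient-statistic bookkeeping,
# Student-t predictive against quadrature, expected cluster count, and
# exchangeability of the induced partition distribution.

test_that("CRP weights follow the sequential conditional prior", {
  expect_equal(crpWeights(integer(0), alpha = 1), 1.0)
  expect_equal(crpWeights(c(2, 1), alpha = 1), c(0.5, 0.25, 0.25))
  set.seed(1)
  for (i in 1:20) {
    sizes <- sample(1:10, sample(1:6, 1), replace = TRUE)
    a <- runif(1, 0.1, 5)
    w <- crpWeights(sizes, a)
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
    expect_equal(w[length(w)], a / (sum(sizes) + a))
    # permuting the size list permutes the weights
    p <- sample(seq_along(sizes))
    expect_equal(crpWeights(sizes[p], a)[seq_along(sizes)],
                 w[seq_along(sizes)][p])
  }
  expect_error(crpWeights(c(0, 2), 1), ">= 1")
  expect_error(crpWeights(c(1, 2), -1), "positive")
})

test_that("add/remove point are exact inverses and match from-scratch stats", {
  s <- ComponentStats()
  s1 <- addPoint(s, 2.0)
  expect_equal(c(s1@n, s1@sum, s1@sumsq), c(1, 2, 4))
  expect_equal(removePoint(s1, 2.0), s)
  vals <- c(1, 2, 3)
  s3 <- Reduce(addPoint, vals, ComponentStats())
  ref <- ComponentStats(vals)
  expect_equal(c(s3@n, s3@sum, s3@sumsq), c(ref@n, ref@sum, ref@sumsq))
  set.seed(2)
  xs <- rnorm(10, 5, 2)
  st <- Reduce(addPoint, xs, ComponentStats())
  st <- removePoint(st, xs[4])
  ref <- ComponentStats(xs[-4])
  expect_equal(st@sum, ref@sum)
  expect_equal(st@sumsq, ref@sumsq)
  expect_error(removePoint(ComponentStats(), 1), "empty")
})

test_that("prior predictive integrates to 1 and is symmetric about mu0", {
  base <- BaseMeasure(mu0 = 3, kappa0 = 0.5, a0 = 2.5, b0 = 4)
  dens <- function(x) exp(predictiveLogDensity(x, ComponentStats(), base))
  expect_equal(stats::integrate(dens, -Inf, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  for (d in c(0.3, 1.7, 6)) {
    expect_equal(predictiveLogDensity(3 + d, ComponentStats(), base),
                 predictiveLogDensity(3 - d, ComponentStats(), base))
  }
})

test_that("posterior predictive matches 2-D quadrature of the NIG integrand", {
  set.seed(3)
  for (i in 1:6) {
    vals <- rnorm(sample(1:6, 1), mean = runif(1, -2, 4), sd = runif(1, 0.5, 2))
    x <- runif(1, -4, 6)
    mu0 <- runif(1, -1, 1); k0 <- runif(1, 0.1, 2)
    a0 <- runif(1, 1.5, 4); b0 <- runif(1, 0.5, 3)
    base <- BaseMeasure(mu0, k0, a0, b0)
    got <- exp(predictiveLogDensity(x, ComponentStats(vals), base))
    want <- quadraturePredictive(x, vals, mu0, k0, a0, b0)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("expected cluster count matches the harmonic-sum formula and CRP draws", {
  expect_equal(expectedClusterCount(1, 2.5), 1)
  expect_equal(expectedClusterCount(3, 1), 11 / 6)
  # Monte-Carlo: mean cluster count over sequential CRP draws
  set.seed(4)
  nDraws <- 4000; n <- 12; alpha <- 1.5
  ks <- replicate(nDraws, {
    sizes <- integer(0)
    for (i in seq_len(n)) {
      pick <- sample.int(length(sizes) + 1L, 1, prob = crpWeights(sizes, alpha))
      if (pick > length(sizes)) sizes <- c(sizes, 1L)
      else sizes[pick] <- sizes[pick] + 1L
    }
    length(sizes)
  })
  se <- sd(ks) / sqrt(nDraws)
  expect_lt(abs(mean(ks) - expectedClusterCount(n, alpha)), 3 * se)
})

test_that("sequential CRP sampling is exchangeable (small-n partition check)", {
  # n = 5, alpha = 1: empirical distribution over the 52 set partitions
  # against the exact Ewens probabilities
  set.seed(5)
  n <- 5; alpha <- 1; nDraws <- 30000
  codes <- simulateCrpPartitions(nDraws, n, alpha)
  parts <- allPartitionsRGS(n)
  expect_length(parts, 52)
  exact <- vapply(parts, ewensProbability, 0, alpha = alpha)
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  codeKey <- vapply(parts, rgsCode, 0, n = n)
  emp <- tabulate(match(codes, codeKey), nbins = length(parts)) / nDraws
  tv <- 0.5 * sum(abs(emp - exact))
  expect_lt(tv, 0.02)
})

test_that("base measure validation rejects bad hyperparameters", {
  expect_error(BaseMeasure(kappa0 = 0), "kappa0")
  expect_error(BaseMeasure(a0 = -1), "a0")
  expect_error(BaseMeasure(b0 = 0), "b0")
})
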