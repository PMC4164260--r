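# Anisotropic diffusion: coefficient forms, neighbor gradients, the
# explicit update against a term-by-term oracle, and the scheme's
# conservation / maximum-principle / edge-preservation properties.

test_that("diffusion coefficient matches both closed forms", {
  expect_equal(diffusionCoefficient(0, q = 3, "exponential"), 1)
  expect_equal(diffusionCoefficient(0, q = 3, "rational"), 1)
  expect_equal(diffusionCoefficient(1, q = 1, "exponential"), exp(-1))
  expect_equal(diffusionCoefficient(1, q = 1, "rational"), 0.5)
  x <- seq(0, 10, by = 0.25)
  for (v in c("exponential", "rational")) {
    cx <- diffusionCoefficient(x, q = 2, v)
    expect_true(all(cx > 0 & cx <= 1))
    expect_true(all(diff(cx) < 0))
  }
  expect_error(diffusionCoefficient(1, q = -1), "positive")
})

test_that("neighbor gradients follow the 4-neighborhood definition", {
  img <- IntensityImage(matrix(5, 3, 3))
  expect_true(all(neighborGradients(img, c(2, 2)) == 0))

  P <- matrix(0, 3, 3); P[2, 2] <- 8
  img <- IntensityImage(P)
  g <- neighborGradients(img, c(2, 2))
  expect_length(g, 4)
  expect_true(all(g == -8))
  expect_length(neighborGradients(img, c(1, 1)), 2)
  expect_length(neighborGradients(img, c(1, 2)), 3)
  expect_error(neighborGradients(img, c(4, 1)), "outside")

  # masked neighbors are dropped
  msk <- matrix(TRUE, 3, 3); msk[1, 2] <- FALSE
  img2 <- IntensityImage(P, mask = msk)
  expect_length(neighborGradients(img2, c(2, 2)), 3)
})

test_that("one diffusion step matches a scalar term-by-term evaluation", {
  P <- matrix(0, 3, 3); P[2, 2] <- 8
  params <- DiffusionParams(q = 1, dt = 0.25, nSteps = 1)
  out <- pixels(diffuseStep(IntensityImage(P), params))

  # independent loop oracle: I_s + (dt/4) sum_p c(|I_p - I_s|)(I_p - I_s)
  expected <- P
  for (r in 1:3) for (cc in 1:3) {
    acc <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr >= 1 && rr <= 3 && c2 >= 1 && c2 <= 3) {
        g <- P[rr, c2] - P[r, cc]
        acc <- acc + exp(-abs(g)^2) * g
      }
    }
    expected[r, cc] <- P[r, cc] + 0.25 / 4 * acc
  }
  expect_equal(out, expected, tolerance = 1e-14)
  # the center explicitly: 8 - (0.25/4) * 4 * exp(-64) * 8
  expect_equal(out[2, 2], 8 - 0.25 * exp(-64) * 8)
})

test_that("constant images are exact fixed points", {
  img <- IntensityImage(matrix(42, 6, 5))
  params <- DiffusionParams(q = 2, dt = 0.25, nSteps = 1)
  expect_identical(pixels(diffuseStep(img, params)), pixels(img))
})

test_that("pixel sum is conserved and the maximum principle holds", {
  set.seed(7)
  img <- IntensityImage(matrix(runif(30 * 20, 0, 100), 30, 20))
  params <- DiffusionParams(q = 8, dt = 0.25, nSteps = 1)
  cur <- img
  for (i in 1:25) {
    nxt <- diffuseStep(cur, params)
    expect_lt(abs(sum(pixels(nxt)) - sum(pixels(img))) / sum(pixels(img)),
              1e-9)
    expect_gte(min(pixels(nxt)), min(pixels(img)) - 1e-12)
    expect_lte(max(pixels(nxt)), max(pixels(img)) + 1e-12)
    cur <- nxt
  }
  # with a mask, masked-out pixels never change and the sum still holds
  msk <- matrix(TRUE, 10, 10); msk[3:5, 3:5] <- FALSE
  set.seed(8)
  img2 <- IntensityImage(matrix(runif(100, 0, 50), 10, 10), mask = msk)
  out2 <- diffuseStep(img2, params)
  expect_identical(pixels(out2)[!msk], pixels(img2)[!msk])
  expect_lt(abs(sum(pixels(out2)) - sum(pixels(img2))), 1e-9 * sum(pixels(img2)))
})

test_that("diffuse composes steps and nSteps = 0 is the identity", {
  set.seed(9)
  img <- IntensityImage(matrix(runif(64, 0, 10), 8, 8))
  p0 <- DiffusionParams(q = 1, dt = 0.2, nSteps = 0)
  expect_identical(pixels(diffuse(img, p0)), pixels(img))
  p2 <- DiffusionParams(q = 1, dt = 0.2, nSteps = 2)
  p1 <- DiffusionParams(q = 1, dt = 0.2, nSteps = 1)
  expect_equal(pixels(diffuse(img, p2)),
               pixels(diffuseStep(diffuseStep(img, p1), p1)))
})

test_that("total variation is non-increasing on a noisy step image", {
  set.seed(10)
  P <- matrix(0, 24, 24); P[, 13:24] <- 100
  P <- P + matrix(rnorm(24 * 24, 0, 5), 24, 24)
  img <- IntensityImage(P)
  params <- DiffusionParams(q = 15, dt = 0.25, nSteps = 1)
  tv <- totalVariation(pixels(img))
  for (i in 1:20) {
    img <- diffuseStep(img, params)
    tvNew <- totalVariation(pixels(img))
    expect_lte(tvNew, tv + 1e-9)
    tv <- tvNew
  }
})

test_that("strong edges pass less flux than weak ones", {
  mk <- function(contrast) {
    P <- matrix(0, 10, 10); P[, 6:10] <- contrast
    IntensityImage(P)
  }
  params <- DiffusionParams(q = 10, dt = 0.25, nSteps = 1)
  fluxAcross <- function(contrast) {
    out <- pixels(diffuseStep(mk(contrast), params))
    sum(abs(out[, 5] - 0)) / contrast  # relative plateau erosion
  }
  expect_gt(fluxAcross(2), fluxAcross(200))
})

test_that("invalid diffusion parameters are rejected", {
  expect_error(DiffusionParams(q = 1, dt = 0.3), "stability")
  expect_error(DiffusionParams(q = 0), "positive")
})
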