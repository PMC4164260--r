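## Synthetic co-registered multimodal tumor phantoms with exact ground
## truth. The geometry is deliberately analytic (concentric disks on a
## two-tissue brain disk): ground truth is known pixel-exactly, which is
## what the pipeline's contracts need; anatomical realism is not the goal.
## Noise is Rician — the magnitude-MR noise model sqrt((A+n1)^2 + n2^2)
## with independent zero-mean Gaussians n1, n2.

#' Construct a PhantomSpec
#'
#' Default class means (background, tissue1, tissue2, edema, core), on a
#' 0-255 scale: FLAIR (10, 90, 150, 230, 230) — edema and core equally
#' bright, so the brightest FLAIR cluster is the whole tumor; T1C
#' (10, 90, 150, 150, 240) — the core enhances, edema matches tissue2
#' (edema does not enhance on T1C). All distinct means are at least
#' 4 sigma apart at the default noise level (sigma = 5\% of the dynamic
#' range, i.e. 11.5-12 units).
#'
#' @param shape grid dimensions, default 128 x 128.
#' @param flairMeans,t1cMeans class means per modality (length 5, order
#'   background, tissue1, tissue2, edema, core).
#' @param coreRadius,edemaRadius tumor radii in pixels (core < edema).
#' @param center tumor center (row, col); default the grid center.
#' @param noiseSigma Rician sigma as a fraction of the modality's dynamic
#'   range.
#' @param seed integer RNG seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(shape = c(128L, 128L),
                        flairMeans = c(background = 10, tissue1 = 90,
                                       tissue2 = 150, edema = 230,
                                       core = 230),
                        t1cMeans = c(background = 10, tissue1 = 90,
                                     tissue2 = 150, edema = 150,
                                     core = 240),
                        coreRadius = 12, edemaRadius = 24,
                        center = NULL, noiseSigma = 0.05, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape + 1) / 2
  new("PhantomSpec", shape = shape,
      flairMeans = as.numeric(flairMeans), t1cMeans = as.numeric(t1cMeans),
      coreRadius = as.numeric(coreRadius),
      edemaRadius = as.numeric(edemaRadius), center = as.numeric(center),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Add Rician noise to an image
#'
#' Replaces each pixel A by \eqn{\sqrt{(A+n_1)^2 + n_2^2}} with
#' \eqn{n_1, n_2} independent N(0, sigma^2) draws — the magnitude-MR noise
#' model (Rayleigh where the signal is 0, near-Gaussian where A >> sigma).
#' Uses R's global RNG stream. \code{sigma = 0} returns the input exactly.
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param sigma noise standard deviation (absolute intensity units).
#' @return the noisy \linkS4class{IntensityImage}.
#' @export
addRicianNoise <- function(image, sigma) {
  stopifnot(is(image, "IntensityImage"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  P <- pixels(image)
  n1 <- matrix(rnorm(length(P), 0, sigma), nrow(P), ncol(P))
  n2 <- matrix(rnorm(length(P), 0, sigma), nrow(P), ncol(P))
  IntensityImage(sqrt((P + n1)^2 + n2^2), mask = brainMask(image),
                 spacing = pixelSpacing(image))
}

## Class index map: 1 bg, 2 tissue1, 3 tissue2, 4 edema, 5 core.
phantomClassMap <- function(spec) {
  nr <- spec@shape[1]; nc <- spec@shape[2]
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dCenter <- sqrt((r - (nr + 1) / 2)^2 + (cc - (nc + 1) / 2)^2)
  brainR <- 0.46 * min(nr, nc)
  dTumor <- sqrt((r - spec@center[1])^2 + (cc - spec@center[2])^2)
  cls <- matrix(1L, nr, nc)
  cls[dCenter <= brainR & r <= nr / 2] <- 2L
  cls[dCenter <= brainR & r > nr / 2] <- 3L
  cls[dTumor <= spec@edemaRadius] <- 4L
  cls[dTumor <= spec@coreRadius] <- 5L
  cls
}

#' Generate a co-registered multimodal phantom
#'
#' Builds the noiseless piecewise-constant class image per modality, the
#' exact ground-truth masks (core disk, edema ring, and their union), then
#' applies Rician noise, FLAIR first and T1C second, from a single stream
#' seeded with \code{spec@seed} (so the two modalities get independent
#' noise and the phantom is bit-reproducible).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{Phantom}.
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  cls <- phantomClassMap(spec)
  truth <- composeTumorMasks(core = cls == 5L, edema = cls == 4L)
  build <- function(means) {
    P <- matrix(means[cls], spec@shape[1], spec@shape[2])
    IntensityImage(P)
  }
  flair0 <- build(spec@flairMeans)
  t1c0 <- build(spec@t1cMeans)
  set.seed(spec@seed)
  sigF <- spec@noiseSigma * diff(range(spec@flairMeans))
  sigT <- spec@noiseSigma * diff(range(spec@t1cMeans))
  new("Phantom", flair = addRicianNoise(flair0, sigF),
      t1c = addRicianNoise(t1c0, sigT), truth = truth, spec = spec)
}
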