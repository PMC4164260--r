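## Perona-Malik anisotropic diffusion on the 4-neighborhood grid.
##
## Explicit scheme: I_s <- I_s + (dt/4) * sum_p c(|I_p - I_s|) (I_p - I_s),
## the sum running over the up/down/left/right neighbors that exist and are
## inside the mask; missing neighbors contribute zero flux (zero-flux
## boundary). The fixed 1/4 normalization makes every edge's flux appear
## once with each sign, so the pixel sum is conserved exactly and constant
## images are fixed points. dt <= 1/4 gives the discrete maximum principle.

#' Diffusion coefficient c(x)
#'
#' Edge-stopping function of the gradient magnitude: 1 at zero gradient,
#' strictly decreasing, near 0 for gradients well above the contrast
#' parameter \code{q} so diffusion halts across strong edges.
#'
#' @param x nonnegative gradient magnitude(s).
#' @param q positive contrast parameter.
#' @param variant \code{"exponential"} for \eqn{\exp(-(x/q)^2)},
#'   \code{"rational"} for \eqn{1/(1+(x/q)^2)}.
#' @return values in (0, 1].
#' @export
diffusionCoefficient <- function(x, q,
                                 variant = c("exponential", "rational")) {
  variant <- match.arg(variant)
  if (length(q) != 1L || !is.finite(q) || q <= 0)
    stop("q must be a single positive number")
  if (any(x < 0)) stop("gradient magnitudes must be >= 0")
  r2 <- (x / q)^2
  if (variant == "exponential") exp(-r2) else 1 / (1 + r2)
}

## Shifted copies of P with replicate padding; gradient to a replicated
## border cell is 0 so boundaries are naturally zero-flux.
shiftUp    <- function(P) P[c(1L, seq_len(nrow(P) - 1L)), , drop = FALSE]
shiftDown  <- function(P) P[c(seq_len(nrow(P))[-1L], nrow(P)), , drop = FALSE]
shiftLeft  <- function(P) P[, c(1L, seq_len(ncol(P) - 1L)), drop = FALSE]
shiftRight <- function(P) P[, c(seq_len(ncol(P))[-1L], ncol(P)), drop = FALSE]

#' Intensity differences to the existing 4-neighbors of a site
#'
#' Returns \eqn{I_p - I_s} for each neighbor p of \code{site} in the order
#' up, down, left, right, dropping neighbors that fall outside the grid or
#' outside the mask.
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param site integer (row, col), 1-based.
#' @return named numeric vector of gradients (length 2..4).
#' @export
neighborGradients <- function(image, site) {
  P <- pixels(image)
  r <- site[1]; cc <- site[2]
  if (r < 1 || r > nrow(P) || cc < 1 || cc > ncol(P))
    stop("site outside the image grid")
  m <- brainMask(image)
  inside <- function(rr, ccc) {
    rr >= 1 && rr <= nrow(P) && ccc >= 1 && ccc <= ncol(P) &&
      (is.null(m) || m[rr, ccc])
  }
  out <- c(up = NA_real_, down = NA_real_, left = NA_real_,
           right = NA_real_)
  off <- list(up = c(-1L, 0L), down = c(1L, 0L), left = c(0L, -1L),
              right = c(0L, 1L))
  for (nm in names(off)) {
    rr <- r + off[[nm]][1]; ccc <- cc + off[[nm]][2]
    if (inside(rr, ccc)) out[nm] <- P[rr, ccc] - P[r, cc]
  }
  out[!is.na(out)]
}

#' One explicit anisotropic-diffusion step
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param params a \linkS4class{DiffusionParams}.
#' @return the diffused \linkS4class{IntensityImage} (same shape, mask and
#'   spacing).
#' @export
diffuseStep <- function(image, params) {
  stopifnot(is(image, "IntensityImage"), is(params, "DiffusionParams"))
  validObject(params)
  P <- pixels(image)
  m <- brainMask(image)
  flux <- matrix(0, nrow(P), ncol(P))
  shifts <- list(shiftUp, shiftDown, shiftLeft, shiftRight)
  for (sh in shifts) {
    g <- sh(P) - P
    if (!is.null(m)) {
      valid <- m & sh(m)
      g[!valid] <- 0
    }
    flux <- flux + diffusionCoefficient(abs(g), params@q, params@variant) * g
  }
  out <- P + (params@dt / 4) * flux
  if (!is.null(m)) out[!m] <- P[!m]
  IntensityImage(out, mask = m, spacing = pixelSpacing(image))
}

#' Anisotropic diffusion for nSteps steps
#'
#' Applies \code{\link{diffuseStep}} \code{nSteps} times; \code{nSteps = 0}
#' returns the input unchanged (the initial condition of the diffusion PDE).
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param params a \linkS4class{DiffusionParams}; if \code{NULL}, defaults
#'   are derived from the image by \code{\link{defaultDiffusionParams}}.
#' @return the diffused \linkS4class{IntensityImage}.
#' @export
diffuse <- function(image, params = NULL) {
  if (is.null(params)) params <- defaultDiffusionParams(image)
  validObject(params)
  for (i in seq_len(params@nSteps)) image <- diffuseStep(image, params)
  image
}

#' Default diffusion parameters for an image
#'
#' q = 10\% of the image dynamic range (within the mask), dt = 0.25,
#' 10 steps, exponential coefficient. These are configuration defaults, not
#' quantities estimated from data.
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param nSteps number of steps.
#' @param variant coefficient variant.
#' @return a \linkS4class{DiffusionParams}.
#' @export
defaultDiffusionParams <- function(image, nSteps = 10L,
                                   variant = "exponential") {
  P <- pixels(image)
  if (!is.null(brainMask(image))) P <- P[brainMask(image)]
  rng <- diff(range(P))
  if (rng <= 0) rng <- 1
  DiffusionParams(q = 0.1 * rng, dt = 0.25, nSteps = nSteps,
                  variant = variant)
}
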