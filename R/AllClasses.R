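#' @import methods
#' @importFrom stats var rnorm
#' @importFrom utils write.table
#' @useDynLib dpmrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' 2-D intensity image with optional brain mask
#'
#' Container for a single-channel MR slice: a matrix of real intensities in
#' arbitrary MR units, an optional logical mask (\code{TRUE} = inside brain),
#' and the physical pixel spacing in mm (informational only). The grid
#' convention used throughout the package is row-major with pixel (1,1) at
#' the top-left; images and label fields share it.
#'
#' @slot pixels numeric matrix of finite intensities.
#' @slot mask \code{NULL} or a logical matrix of the same shape.
#' @slot spacing numeric of length 2, (row, col) pixel size in mm.
#' @export
setClass("IntensityImage",
  representation(pixels = "matrix", mask = "matrixOrNULL", spacing = "numeric"),
  prototype(mask = NULL, spacing = c(1, 1)))

setValidity("IntensityImage", function(object) {
  msgs <- character()
  if (!is.numeric(object@pixels))
    msgs <- c(msgs, "pixels must be a numeric matrix")
  nbad <- sum(!is.finite(object@pixels))
  if (nbad > 0)
    msgs <- c(msgs, sprintf("pixels contain %d non-finite value(s)", nbad))
  if (!is.null(object@mask)) {
    if (!is.logical(object@mask))
      msgs <- c(msgs, "mask must be logical")
    if (!identical(dim(object@mask), dim(object@pixels)))
      msgs <- c(msgs, "mask and pixels must have identical shape")
  }
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be two positive numbers")
  if (length(msgs)) msgs else TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels numeric matrix of intensities.
#' @param mask optional logical matrix (\code{TRUE} = inside brain).
#' @param spacing numeric length-2 pixel spacing in mm.
#' @return an \linkS4class{IntensityImage}.
#' @export
IntensityImage <- function(pixels, mask = NULL, spacing = c(1, 1)) {
  storage.mode(pixels) <- "double"
  new("IntensityImage", pixels = pixels, mask = mask,
      spacing = as.numeric(spacing))
}

#' Segmentation label field
#'
#' Integer cluster labels on the image grid. In-use labels are the contiguous
#' integers \code{0..nClusters-1}; the constructor compacts arbitrary
#' nonnegative labels to this form (distinct values mapped to 0,1,... in
#' increasing order). Masked-out sites carry \code{NA}.
#'
#' @slot labels integer matrix (\code{NA} at masked-out sites).
#' @slot nClusters number of distinct labels in use.
#' @export
setClass("LabelField",
  representation(labels = "matrix", nClusters = "integer"))

setValidity("LabelField", function(object) {
  lab <- object@labels
  u <- sort(unique(lab[!is.na(lab)]))
  if (length(u) && !identical(as.integer(u), seq_len(length(u)) - 1L))
    return("labels must be contiguous integers 0..nClusters-1")
  if (object@nClusters != length(u))
    return("nClusters does not match the number of distinct labels")
  TRUE
})

#' Construct a LabelField, compacting labels
#'
#' @param labels integer matrix of nonnegative labels (\code{NA} allowed for
#'   masked sites).
#' @return a \linkS4class{LabelField} with labels compacted to
#'   \code{0..nClusters-1}.
#' @export
LabelField <- function(labels) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[!is.na(labels)]))
  if (length(u)) {
    remap <- match(labels, u) - 1L
    dim(remap) <- dim(labels)
    labels <- remap
  }
  new("LabelField", labels = labels, nClusters = length(u))
}

#' Anisotropic-diffusion parameters
#'
#' @slot q positive contrast parameter controlling the extent of diffusion:
#'   gradients well below \code{q} are smoothed, gradients well above are
#'   preserved as edges.
#' @slot dt explicit time step; must be <= 1/4 for stability of the
#'   4-neighborhood scheme.
#' @slot nSteps number of diffusion steps.
#' @slot variant \code{"exponential"} for \eqn{c(x)=\exp(-(x/q)^2)} or
#'   \code{"rational"} for \eqn{c(x)=1/(1+(x/q)^2)}.
#' @export
setClass("DiffusionParams",
  representation(q = "numeric", dt = "numeric", nSteps = "integer",
                 variant = "character"))

setValidity("DiffusionParams", function(object) {
  msgs <- character()
  if (length(object@q) != 1L || !is.finite(object@q) || object@q <= 0)
    msgs <- c(msgs, "q must be a single positive number")
  if (length(object@dt) != 1L || !is.finite(object@dt) ||
      object@dt <= 0 || object@dt > 0.25)
    msgs <- c(msgs, "dt must be in (0, 0.25] for scheme stability")
  if (object@nSteps < 0L)
    msgs <- c(msgs, "nSteps must be >= 0")
  if (!object@variant %in% c("exponential", "rational"))
    msgs <- c(msgs, "variant must be 'exponential' or 'rational'")
  if (length(msgs)) msgs else TRUE
})

#' Construct DiffusionParams
#'
#' @param q positive contrast parameter (same units as the image).
#' @param dt time step in (0, 0.25].
#' @param nSteps nonnegative integer number of steps.
#' @param variant \code{"exponential"} or \code{"rational"}.
#' @return a \linkS4class{DiffusionParams}.
#' @export
DiffusionParams <- function(q, dt = 0.25, nSteps = 10L,
                            variant = c("exponential", "rational")) {
  variant <- match.arg(variant)
  new("DiffusionParams", q = as.numeric(q), dt = as.numeric(dt),
      nSteps = as.integer(nSteps), variant = variant)
}

#' Normal-inverse-gamma base measure
#'
#' Conjugate base measure G0 over per-cluster (mean, variance):
#' variance ~ InvGamma(a0, b0), mean | variance ~ N(mu0, variance/kappa0).
#' With it the cluster-predictive density is a closed-form Student-t.
#'
#' @slot mu0 prior mean of cluster means.
#' @slot kappa0 prior strength (pseudo-count) on the mean.
#' @slot a0 inverse-gamma shape.
#' @slot b0 inverse-gamma scale.
#' @export
setClass("BaseMeasure",
  representation(mu0 = "numeric", kappa0 = "numeric",
                 a0 = "numeric", b0 = "numeric"))

setValidity("BaseMeasure", function(object) {
  ok <- function(v) length(v) == 1L && is.finite(v)
  if (!ok(object@mu0)) return("mu0 must be a finite number")
  if (!ok(object@kappa0) || object@kappa0 <= 0) return("kappa0 must be > 0")
  if (!ok(object@a0) || object@a0 <= 0) return("a0 must be > 0")
  if (!ok(object@b0) || object@b0 <= 0) return("b0 must be > 0")
  TRUE
})

#' Construct a BaseMeasure
#'
#' @param mu0,kappa0,a0,b0 normal-inverse-gamma hyperparameters.
#' @return a \linkS4class{BaseMeasure}.
#' @export
BaseMeasure <- function(mu0 = 0, kappa0 = 0.01, a0 = 2, b0 = 1) {
  new("BaseMeasure", mu0 = as.numeric(mu0), kappa0 = as.numeric(kappa0),
      a0 = as.numeric(a0), b0 = as.numeric(b0))
}

#' Sufficient statistics of one mixture component
#'
#' @slot n number of assigned observations.
#' @slot sum sum of assigned intensities.
#' @slot sumsq sum of squared assigned intensities.
#' @export
setClass("ComponentStats",
  representation(n = "numeric", sum = "numeric", sumsq = "numeric"),
  prototype(n = 0, sum = 0, sumsq = 0))

setValidity("ComponentStats", function(object) {
  if (object@n < 0) return("n must be >= 0")
  if (object@n == 0 && (object@sum != 0 || object@sumsq != 0))
    return("empty component must have sum = sumsq = 0")
  if (object@n > 0 && object@sumsq < object@sum^2 / object@n - 1e-8)
    return("sumsq must be >= sum^2/n")
  TRUE
})

#' Construct ComponentStats
#'
#' @param values optional numeric vector of observations to absorb.
#' @return a \linkS4class{ComponentStats}.
#' @export
ComponentStats <- function(values = numeric()) {
  new("ComponentStats", n = length(values), sum = sum(values),
      sumsq = sum(values^2))
}

#' Undirected neighborhood graph on the pixel grid
#'
#' Adjacency of the unmasked grid sites in compressed sparse form: the
#' neighbors of site \code{i} (1-based, raster order over unmasked sites)
#' are \code{nbr[(offsets[i]+1):offsets[i+1]]} with matching edge weights.
#' Symmetric, no self-loops.
#'
#' @slot nSites number of (unmasked) sites.
#' @slot offsets integer length \code{nSites+1}, cumulative neighbor counts.
#' @slot nbr integer vector of 1-based neighbor site indices.
#' @slot w numeric edge weights aligned with \code{nbr}.
#' @slot dims grid dimensions.
#' @slot siteIndex integer matrix mapping grid cells to site indices
#'   (\code{NA} where masked out).
#' @export
setClass("NeighborhoodGraph",
  representation(nSites = "integer", offsets = "integer", nbr = "integer",
                 w = "numeric", dims = "integer", siteIndex = "matrix"))

setValidity("NeighborhoodGraph", function(object) {
  if (length(object@offsets) != object@nSites + 1L)
    return("offsets must have length nSites+1")
  if (length(object@nbr) != length(object@w))
    return("nbr and w must align")
  if (length(object@nbr) != object@offsets[length(object@offsets)])
    return("offsets must end at length(nbr)")
  if (any(object@nbr < 1L | object@nbr > object@nSites))
    return("neighbor indices out of range")
  TRUE
})

#' State of the collapsed Gibbs sampler
#'
#' Holds the label of every unmasked site, the per-cluster sufficient
#' statistics (kept incrementally, always equal to a from-scratch
#' recomputation), the data, and the model hyperparameters.
#'
#' @slot x per-site intensities (raster order over unmasked sites).
#' @slot labels per-site 0-based cluster labels, contiguous \code{0..K-1}.
#' @slot compN,compSum,compSumsq per-cluster sufficient statistics.
#' @slot alpha Dirichlet-process concentration.
#' @slot lambda MRF smoothness weight (0 = unconstrained).
#' @slot base \linkS4class{BaseMeasure}.
#' @slot graph \linkS4class{NeighborhoodGraph}.
#' @export
setClass("SamplerState",
  representation(x = "numeric", labels = "integer",
                 compN = "numeric", compSum = "numeric", compSumsq = "numeric",
                 alpha = "numeric", lambda = "numeric",
                 base = "BaseMeasure", graph = "NeighborhoodGraph"))

setValidity("SamplerState", function(object) {
  if (length(object@labels) != length(object@x))
    return("labels and x must align")
  if (length(object@x) != object@graph@nSites)
    return("x must have one entry per graph site")
  if (object@alpha <= 0) return("alpha must be > 0")
  if (object@lambda < 0) return("lambda must be >= 0")
  K <- length(object@compN)
  if (length(object@labels)) {
    if (any(object@labels < 0L | object@labels >= K))
      return("labels out of component range")
    tab <- tabulate(object@labels + 1L, nbins = K)
    if (!all(tab == object@compN))
      return("component counts do not match labels")
    if (any(tab == 0))
      return("empty components must be deleted and labels compacted")
    sums <- vapply(seq_len(K) - 1L,
                   function(k) sum(object@x[object@labels == k]), 0)
    if (max(abs(sums - object@compSum)) > 1e-6 * (1 + max(abs(sums))))
      return("component sums do not match data")
  }
  TRUE
})

#' Per-iteration sampler trace
#'
#' Records, for each Gibbs sweep, the number of clusters in use and the
#' number of sites whose assignment changed — the data behind
#' cluster-count/assignment-change convergence plots and the stopping rule.
#'
#' @slot iteration,nClusters,nChanged integer vectors of equal length.
#' @export
setClass("SamplerTrace",
  representation(iteration = "integer", nClusters = "integer",
                 nChanged = "integer"))

setValidity("SamplerTrace", function(object) {
  n <- length(object@iteration)
  if (length(object@nClusters) != n || length(object@nChanged) != n)
    return("trace columns must align")
  if (any(object@nChanged < 0L)) return("nChanged must be >= 0")
  TRUE
})

#' Tumor-compartment masks
#'
#' Binary masks on the image grid for the enhancing tumor core (GTV, from
#' T1C), the edema, and the whole tumor (CTV = GTV + edema). Core and edema
#' are disjoint and their union is the whole-tumor mask.
#'
#' @slot core,edema,whole logical matrices of identical shape.
#' @export
setClass("TumorMasks",
  representation(core = "matrix", edema = "matrix", whole = "matrix"))

setValidity("TumorMasks", function(object) {
  if (!is.logical(object@core) || !is.logical(object@edema) ||
      !is.logical(object@whole))
    return("masks must be logical matrices")
  if (!identical(dim(object@core), dim(object@edema)) ||
      !identical(dim(object@core), dim(object@whole)))
    return("masks must share one shape")
  if (any(object@core & object@edema))
    return("core and edema must be disjoint")
  if (!identical(object@whole, object@core | object@edema))
    return("whole must equal core | edema")
  TRUE
})

#' Segmentation accuracy report
#'
#' Pixel confusion counts of a result mask against ground truth, with the
#' four derived overlap scores. A score whose denominator is zero is
#' reported as \code{NaN} (explicitly undefined).
#'
#' @slot tp,tn,fp,fn pixel counts.
#' @slot dsc,jaccard,sensitivity,specificity scores in [0,1] or \code{NaN}.
#' @export
setClass("MetricsReport",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric", dsc = "numeric", jaccard = "numeric",
                 sensitivity = "numeric", specificity = "numeric"))

#' Synthetic multimodal phantom specification
#'
#' Defines a co-registered FLAIR/T1C slice pair: a concentric-disk tumor
#' (core inside an edema ring) on a two-tissue brain disk over dark
#' background, degraded by Rician noise. Class means are given per modality
#' for (background, tissue1, tissue2, edema, core).
#'
#' @slot shape grid dimensions (rows, cols).
#' @slot flairMeans,t1cMeans named numeric length 5 class means.
#' @slot coreRadius,edemaRadius tumor radii in pixels, core < edema.
#' @slot center tumor center (row, col).
#' @slot noiseSigma Rician sigma as a fraction of the modality's dynamic
#'   range (max class mean - min class mean).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", flairMeans = "numeric",
                 t1cMeans = "numeric", coreRadius = "numeric",
                 edemaRadius = "numeric", center = "numeric",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@shape) != 2L || any(object@shape < 8L))
    msgs <- c(msgs, "shape must be two dimensions >= 8")
  for (nm in c("flairMeans", "t1cMeans")) {
    v <- slot(object, nm)
    if (length(v) != 5L || any(!is.finite(v)))
      msgs <- c(msgs, sprintf("%s must be 5 finite class means", nm))
  }
  if (object@coreRadius <= 0 || object@coreRadius >= object@edemaRadius)
    msgs <- c(msgs, "need 0 < coreRadius < edemaRadius")
  if (object@edemaRadius > min(object@shape) / 2)
    msgs <- c(msgs, "edemaRadius must be <= min(shape)/2")
  if (object@noiseSigma < 0)
    msgs <- c(msgs, "noiseSigma must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic co-registered phantom
#'
#' @slot flair,t1c \linkS4class{IntensityImage} pair.
#' @slot truth ground-truth \linkS4class{TumorMasks}.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("Phantom",
  representation(flair = "IntensityImage", t1c = "IntensityImage",
                 truth = "TumorMasks", spec = "PhantomSpec"))
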