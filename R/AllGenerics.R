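#' Extract the pixel matrix
#' @param object an object with pixel data.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' Extract the brain mask
#' @param object an object carrying an optional mask.
#' @return logical matrix or \code{NULL}.
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))

#' Pixel spacing in mm
#' @param object an \linkS4class{IntensityImage}.
#' @return numeric length 2.
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' Label matrix of a segmentation
#' @param object a \linkS4class{LabelField}.
#' @return integer matrix.
#' @export
setGeneric("labels4", function(object) standardGeneric("labels4"))

#' Number of clusters in use
#' @param object a \linkS4class{LabelField} or \linkS4class{SamplerState}.
#' @return integer.
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' Tumor-core mask
#' @param object a \linkS4class{TumorMasks}.
#' @return logical matrix.
#' @export
setGeneric("coreMask", function(object) standardGeneric("coreMask"))

#' Edema mask slot
#' @param object a \linkS4class{TumorMasks}.
#' @return logical matrix.
#' @export
setGeneric("edemaMaskOf", function(object) standardGeneric("edemaMaskOf"))

#' Whole-tumor (CTV) mask
#' @param object a \linkS4class{TumorMasks}.
#' @return logical matrix.
#' @export
setGeneric("wholeMask", function(object) standardGeneric("wholeMask"))

setMethod("pixels", "IntensityImage", function(object) object@pixels)
setMethod("brainMask", "IntensityImage", function(object) object@mask)
setMethod("pixelSpacing", "IntensityImage", function(object) object@spacing)
#' @export
setMethod("dim", "IntensityImage", function(x) dim(x@pixels))

setMethod("labels4", "LabelField", function(object) object@labels)
setMethod("nClusters", "LabelField", function(object) object@nClusters)
#' @export
setMethod("dim", "LabelField", function(x) dim(x@labels))

setMethod("coreMask", "TumorMasks", function(object) object@core)
setMethod("edemaMaskOf", "TumorMasks", function(object) object@edema)
setMethod("wholeMask", "TumorMasks", function(object) object@whole)

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IntensityImage %dx%d, range [%.4g, %.4g], spacing %g x %g mm",
              d[1], d[2], min(object@pixels), max(object@pixels),
              object@spacing[1], object@spacing[2]))
  if (!is.null(object@mask))
    cat(sprintf(", %d/%d pixels in mask", sum(object@mask), prod(d)))
  cat("\n")
})

setMethod("show", "LabelField", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelField %dx%d, %d cluster(s)\n", d[1], d[2],
              object@nClusters))
})

setMethod("show", "TumorMasks", function(object) {
  cat(sprintf("TumorMasks %dx%d: core %d px, edema %d px, whole %d px\n",
              nrow(object@core), ncol(object@core), sum(object@core),
              sum(object@edema), sum(object@whole)))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", as.integer(object@tp),
              as.integer(object@tn), as.integer(object@fp),
              as.integer(object@fn)))
  cat(sprintf("  DSC=%.4f Jaccard=%.4f Sens=%.4f Spec=%.4f\n",
              object@dsc, object@jaccard, object@sensitivity,
              object@specificity))
})

setMethod("show", "SamplerTrace", function(object) {
  n <- length(object@iteration)
  cat(sprintf("SamplerTrace: %d iteration(s)", n))
  if (n > 0)
    cat(sprintf(", final K=%d, final changed=%d",
                object@nClusters[n], object@nChanged[n]))
  cat("\n")
})

setMethod("show", "SamplerState", function(object) {
  cat(sprintf(
    "SamplerState: %d sites, %d cluster(s), alpha=%g, lambda=%g\n",
    length(object@x), length(object@compN), object@alpha, object@lambda))
})

setMethod("show", "Phantom", function(object) {
  d <- object@spec@shape
  cat(sprintf(
    "Phantom %dx%d: core r=%g, edema r=%g, noise sigma=%g, seed=%d\n",
    d[1], d[2], object@spec@coreRadius, object@spec@edemaRadius,
    object@spec@noiseSigma, object@spec@seed))
})

#' Coerce a sampler trace to a data.frame
#'
#' @param x a \linkS4class{SamplerTrace}.
#' @param ... ignored.
#' @return data.frame with columns iteration, nClusters, nChanged.
#' @export
as.data.frame.SamplerTrace <- function(x, ...) {
  data.frame(iteration = x@iteration, nClusters = x@nClusters,
             nChanged = x@nChanged)
}
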