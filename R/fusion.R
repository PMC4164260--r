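## Multimodal fusion: per-modality segmentations become compartment masks.
## The T1C tumor cluster is the enhancing core (GTV); edema is the FLAIR
## tumor region minus the T1C one, and the whole tumor (CTV) is their union.

#' Extract the tumor cluster from a segmentation
#'
#' \code{brightest_mean}: the cluster with the highest mean intensity
#' inside the brain mask (ties broken toward the lowest label index) —
#' motivated by tumor enhancement appearing as the brightest class.
#' Clusters smaller than \code{minFraction} of the in-mask pixels are not
#' eligible: a terminal Gibbs sample routinely carries one or two transient
#' single-pixel clusters, and a tumor selector must not return one of
#' those. If no cluster reaches the size floor the filter is dropped.
#' \code{seeded}: the cluster containing a user-given pixel.
#'
#' @param labels a \linkS4class{LabelField}.
#' @param image the matching \linkS4class{IntensityImage}.
#' @param strategy \code{"brightest_mean"} or \code{"seeded"}.
#' @param seedPixel (row, col) of the seed, required for \code{"seeded"}.
#' @param minFraction minimum cluster size for \code{brightest_mean},
#'   as a fraction of the labeled pixels.
#' @return logical mask of the selected cluster (\code{FALSE} at masked-out
#'   pixels).
#' @export
selectTargetCluster <- function(labels, image,
                                strategy = c("brightest_mean", "seeded"),
                                seedPixel = NULL, minFraction = 0.001) {
  strategy <- match.arg(strategy)
  stopifnot(is(labels, "LabelField"), is(image, "IntensityImage"))
  if (!identical(dim(labels), dim(image)))
    stop("labels and image must share one shape")
  lab <- labels4(labels)
  P <- pixels(image)
  if (strategy == "brightest_mean") {
    if (labels@nClusters == 0L) stop("label field has no clusters")
    ks <- seq_len(labels@nClusters) - 1L
    sizes <- vapply(ks, function(k) sum(!is.na(lab) & lab == k), 0)
    means <- vapply(ks, function(k) mean(P[!is.na(lab) & lab == k]), 0)
    eligible <- sizes >= minFraction * sum(sizes)
    if (!any(eligible)) eligible <- rep(TRUE, length(ks))
    means[!eligible] <- -Inf
    target <- which.max(means) - 1L  # which.max takes the first maximum
  } else {
    if (is.null(seedPixel) || length(seedPixel) != 2L)
      stop("seeded strategy needs seedPixel = c(row, col)")
    target <- lab[seedPixel[1], seedPixel[2]]
    if (is.na(target))
      stop("seed pixel lies outside the brain mask")
  }
  out <- !is.na(lab) & lab == target
  dim(out) <- dim(lab)
  out
}

#' Edema mask from the two modality segmentations
#'
#' The set difference of the FLAIR tumor region minus the T1C tumor
#' region: \eqn{V_{edema} = \{x \in V_{FLAIR} \mid x \notin V_{T1C}\}}.
#'
#' @param flairTumor logical whole-tumor mask from FLAIR.
#' @param t1cTumor logical core mask from T1C.
#' @return logical edema mask, disjoint from \code{t1cTumor}.
#' @export
edemaMask <- function(flairTumor, t1cTumor) {
  if (!identical(dim(flairTumor), dim(t1cTumor)))
    stop("masks must share one shape")
  flairTumor & !t1cTumor
}

#' Compose the tumor-compartment masks
#'
#' @param core logical tumor-core (GTV) mask.
#' @param edema logical edema mask, disjoint from \code{core}.
#' @return a \linkS4class{TumorMasks} with \code{whole = core | edema}
#'   (CTV = GTV + edema).
#' @export
composeTumorMasks <- function(core, edema) {
  if (!identical(dim(core), dim(edema)))
    stop("masks must share one shape")
  if (any(core & edema))
    stop("core and edema masks overlap")
  new("TumorMasks", core = core, edema = edema, whole = core | edema)
}

#' Composite label image of the tumor compartments
#'
#' 0 = background, 1 = edema (gray), 2 = tumor core (white) — the encoding
#' used in the saved composite masks.
#'
#' @param masks a \linkS4class{TumorMasks}.
#' @return integer matrix with values 0/1/2.
#' @export
compositeLabels <- function(masks) {
  stopifnot(is(masks, "TumorMasks"))
  out <- matrix(0L, nrow(masks@core), ncol(masks@core))
  out[masks@edema] <- 1L
  out[masks@core] <- 2L
  out
}
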