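## Image and mask I/O. Formats: NIfTI-1 (.nii / .nii.gz) via RNifti and
## grayscale PNG via the png package. Grid convention: matrices are
## (row, col), pixel (1,1) top-left, identical for images and label fields.
## PNG intensities are scaled by 255 on read so an 8-bit pixel value v reads
## back as intensity v exactly; NIfTI stores floating point losslessly.

hasExt <- function(path, exts) {
  low <- tolower(path)
  any(vapply(exts, function(e) endsWith(low, e), logical(1)))
}

#' Load a 2-D intensity image
#'
#' Reads a grayscale PNG or a NIfTI volume. For a 3-D NIfTI volume,
#' \code{sliceIndex} (1-based) selects an axial slice along the third axis.
#' NIfTI pixel dimensions set the spacing; PNG spacing is 1 mm.
#'
#' @param path file path (.png, .nii or .nii.gz).
#' @param sliceIndex 1-based axial slice for 3-D NIfTI input.
#' @return an \linkS4class{IntensityImage}.
#' @export
loadImage <- function(path, sliceIndex = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path)
  if (hasExt(path, c(".nii", ".nii.gz"))) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ",
                                             conditionMessage(e)))
    arr <- as.array(img)
    pd <- RNifti::pixdim(img)
    if (length(dim(arr)) == 3L) {
      if (is.null(sliceIndex))
        stop("3-D NIfTI input: sliceIndex is required")
      if (sliceIndex < 1L || sliceIndex > dim(arr)[3])
        stop(sprintf("sliceIndex %d out of range 1..%d",
                     sliceIndex, dim(arr)[3]))
      arr <- arr[, , sliceIndex]
    } else if (length(dim(arr)) != 2L) {
      stop("only 2-D or 3-D NIfTI images are supported")
    }
    spacing <- if (length(pd) >= 2) as.numeric(pd[1:2]) else c(1, 1)
  } else if (hasExt(path, ".png")) {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG file: ",
                                             conditionMessage(e)))
    if (length(dim(raw)) == 3L) {
      if (dim(raw)[3] >= 3 &&
          (max(abs(raw[, , 1] - raw[, , 2])) > 0 ||
           max(abs(raw[, , 1] - raw[, , 3])) > 0))
        stop("PNG must be grayscale")
      raw <- raw[, , 1]
    }
    arr <- raw * 255
    spacing <- c(1, 1)
  } else {
    stop("unsupported image format (use .png, .nii or .nii.gz): ", path)
  }
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop(sprintf("image contains %d non-finite voxel(s)", nbad))
  IntensityImage(matrix(as.numeric(arr), nrow(arr), ncol(arr)),
                 spacing = spacing)
}

#' Save a 2-D intensity image
#'
#' NIfTI output stores values losslessly as double; PNG output clamps to
#' [0, 255] and quantizes to 8 bits.
#'
#' @param image an \linkS4class{IntensityImage}.
#' @param path output path (.png, .nii or .nii.gz).
#' @return invisibly, \code{path}.
#' @export
saveImage <- function(image, path) {
  stopifnot(is(image, "IntensityImage"))
  p <- pixels(image)
  if (hasExt(path, c(".nii", ".nii.gz"))) {
    nim <- RNifti::asNifti(p)
    RNifti::pixdim(nim) <- pixelSpacing(image)
    RNifti::writeNifti(nim, path, datatype = "double")
  } else if (hasExt(path, ".png")) {
    png::writePNG(pmin(pmax(p, 0), 255) / 255, path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

asLabelMatrix <- function(mask) {
  if (is(mask, "LabelField")) {
    m <- labels4(mask)
    m[is.na(m)] <- 0L
  } else if (is.logical(mask)) {
    m <- mask * 1L
    dim(m) <- dim(mask)
  } else {
    m <- mask
    storage.mode(m) <- "integer"
  }
  m
}

#' Save a label field or binary mask
#'
#' Integer labels are written exactly: NIfTI as int16, PNG as 8-bit gray
#' (label value = pixel value, so at most 256 labels fit a PNG). Masked-out
#' (\code{NA}) sites are written as 0.
#'
#' @param mask a \linkS4class{LabelField}, logical mask, or integer matrix.
#' @param path output path (.png, .nii or .nii.gz).
#' @return invisibly, \code{path}.
#' @export
saveMask <- function(mask, path) {
  m <- asLabelMatrix(mask)
  if (any(m < 0L)) stop("labels must be nonnegative")
  if (hasExt(path, c(".nii", ".nii.gz"))) {
    RNifti::writeNifti(RNifti::asNifti(m + 0), path, datatype = "int16")
  } else if (hasExt(path, ".png")) {
    if (max(m) > 255L)
      stop("more than 256 labels cannot be stored in an 8-bit PNG")
    png::writePNG(m / 255, path)
  } else {
    stop("unsupported mask format: ", path)
  }
  invisible(path)
}

#' Load a label field
#'
#' Inverse of \code{\link{saveMask}}: values are rounded to integers and
#' compacted into a \linkS4class{LabelField}.
#'
#' @param path input path (.png, .nii or .nii.gz).
#' @return a \linkS4class{LabelField}.
#' @export
loadMask <- function(path) {
  img <- loadImage(path)
  p <- pixels(img)
  LabelField(matrix(as.integer(round(p)), nrow(p), ncol(p)))
}
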