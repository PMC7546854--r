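#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Scalar volumetric image
#'
#' A 3D scalar image with anisotropic voxel spacing. The data array is stored
#' with axis order (z, y, x); \code{spacing} and \code{origin} follow the same
#' order and are in millimetres. Voxel centers sit at integer 0-based
#' coordinates, so the voxel (iz, iy, ix) is at world position
#' \code{origin + c(iz, iy, ix) * spacing}.
#'
#' @slot data numeric 3D array, axis order (z, y, x)
#' @slot spacing mm per voxel along (z, y, x); all entries > 0
#' @slot origin world-frame mm offset of voxel (0, 0, 0)
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("Volume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (z, y, x)")
  if (any(dim(d) < 2L)) return("each axis must have at least 2 voxels")
  if (!all(is.finite(d))) return("intensities must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (z, y, x)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (z, y, x)")
  TRUE
})

#' Binary segmentation mask
#'
#' Shares the geometry contract of \code{\linkS4class{Volume}}; values are
#' restricted to \{0, 1\}.
#' @export
setClass("Mask", contains = "Volume")

setValidity("Mask", function(object) {
  if (!all(object@data %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' Construct a Volume
#'
#' @param data numeric 3D array, axis order (z, y, x)
#' @param spacing mm per voxel along (z, y, x)
#' @param origin world mm offset of the first voxel
#' @return a \code{\linkS4class{Volume}}
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a binary Mask
#'
#' @inheritParams Volume
#' @return a \code{\linkS4class{Mask}}
#' @export
Mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("Mask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Sampling grid of continuous source coordinates
#'
#' One continuous source-space coordinate tuple per output pixel/voxel, in
#' column order (x, y) for 2D grids and (x, y, z) for 3D grids. Coordinates
#' may lie outside the source extent; the samplers treat out-of-support
#' contributions as zero.
#'
#' @slot points numeric matrix, one row per output element
#' @slot shape output dimensions: (ny, nx) in 2D, (nz, ny, nx) in 3D; rows of
#'   \code{points} follow R's column-major order over \code{shape}
#' @export
setClass("SamplingGrid",
  representation(points = "matrix", shape = "integer")
)

setValidity("SamplingGrid", function(object) {
  nc <- ncol(object@points)
  if (!nc %in% c(2L, 3L)) return("points must have 2 or 3 columns")
  if (length(object@shape) != nc)
    return("shape length must match the point dimensionality")
  if (nrow(object@points) != prod(object@shape))
    return("one coordinate tuple per output element is required")
  TRUE
})

#' Non-rigid displacement field on a coarse control lattice
#'
#' Per-voxel displacements in voxel units, parameterised by a coarse lattice
#' of control displacements (cubic Keys interpolation) and optionally cached
#' as a dense per-voxel field. The identity transform has all-zero
#' displacements. Component order along the 4th array dimension is
#' (dz, dy, dx), matching the (z, y, x) storage convention.
#'
#' @slot control 4D array (ncz, ncy, ncx, 3) of control displacements in
#'   voxels; may be empty when only a dense field is available
#' @slot controlSpacing control-point spacing in voxels along (z, y, x)
#' @slot dense optional cached dense field, 4D array (nz, ny, nx, 3)
#' @slot shape target image shape (nz, ny, nx)
#' @export
setClass("DisplacementField",
  representation(control = "array", controlSpacing = "numeric",
                 dense = "arrayOrNULL", shape = "integer"),
  prototype(control = array(0, c(0, 0, 0, 3)), controlSpacing = c(2, 8, 8),
            dense = NULL, shape = integer(0))
)

setValidity("DisplacementField", function(object) {
  hasControl <- length(object@control) > 0
  if (hasControl) {
    dc <- dim(object@control)
    if (length(dc) != 4L || dc[4] != 3L)
      return("control must be a (ncz, ncy, ncx, 3) array")
    if (any(object@controlSpacing <= 0))
      return("control spacing must be positive")
  }
  if (!is.null(object@dense)) {
    dd <- dim(object@dense)
    if (length(dd) != 4L || dd[4] != 3L)
      return("dense must be a (nz, ny, nx, 3) array")
    if (length(object@shape) == 3L && !all(dd[1:3] == object@shape))
      return("dense field shape must match the target shape")
  }
  if (!hasControl && is.null(object@dense))
    return("a field needs a control lattice or a dense array")
  TRUE
})

#' Per-region deep feature vectors
#'
#' Multiscale convolutional features of an image partitioned into regions;
#' one column per region.
#'
#' @slot blocks numeric matrix (feature dim x N regions)
#' @slot geometry list describing the partition (mode, per-region index
#'   ranges)
#' @export
setClass("FeatureBlocks",
  representation(blocks = "matrix", geometry = "list")
)

setValidity("FeatureBlocks", function(object) {
  if (ncol(object@blocks) < 1L) return("at least one region is required")
  if (nrow(object@blocks) < 1L) return("feature vectors must be non-empty")
  if (!all(is.finite(object@blocks))) return("features must be finite")
  TRUE
})

#' Registration configuration
#'
#' Tunable parameters of the pairwise unsupervised registration: the warp
#' mode, control-lattice resolution, similarity-network depth and region
#' partition, and the optimisation budget.
#'
#' @export
setClass("RegistrationConfig",
  representation(mode = "character", controlSpacing = "numeric",
                 featureLevels = "integer", blockPartition = "integer",
                 maxIters = "integer", tolerance = "numeric",
                 learningRate = "numeric", momentum = "numeric",
                 seed = "integer", smoothnessWeight = "numeric",
                 channelsBase = "integer", translationInit = "logical",
                 headInit = "character", dropDegenerateBlocks = "logical")
)

setValidity("RegistrationConfig", function(object) {
  if (!object@mode %in% c("3d", "2d")) return("mode must be '3d' or '2d'")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@featureLevels < 1L) return("featureLevels must be >= 1")
  if (any(object@blockPartition < 1L))
    return("blockPartition must be >= 1 per axis")
  if (object@smoothnessWeight < 0) return("smoothnessWeight must be >= 0")
  if (!object@headInit %in% c("zero", "random"))
    return("headInit must be 'zero' or 'random'")
  TRUE
})

#' Result of a pairwise registration
#'
#' @slot field the estimated \code{\linkS4class{DisplacementField}}
#' @slot warped the moving image resampled into the fixed geometry
#' @slot lossTrace per-iteration loss values
#' @slot iterations number of optimisation iterations run
#' @slot converged whether the relative-loss stopping rule fired
#' @slot initialLoss loss of the identity field, for reference
#' @export
setClass("RegistrationResult",
  representation(field = "DisplacementField", warped = "Volume",
                 lossTrace = "numeric", iterations = "integer",
                 converged = "logical", initialLoss = "numeric")
)

#' Corresponding anatomical landmarks in two frames
#'
#' World-mm coordinates (columns z, y, x) of the same anatomical points in
#' the moving and fixed frames; used to quantify registration error.
#' @export
setClass("LandmarkSet",
  representation(moving = "matrix", fixed = "matrix")
)

setValidity("LandmarkSet", function(object) {
  if (nrow(object@moving) != nrow(object@fixed))
    return("moving and fixed must hold equal landmark counts")
  if (nrow(object@moving) < 1L) return("at least one landmark is required")
  if (ncol(object@moving) != 3L || ncol(object@fixed) != 3L)
    return("landmarks must be (z, y, x) mm coordinates")
  TRUE
})

#' Construct a LandmarkSet
#' @param moving,fixed n x 3 matrices of world-mm (z, y, x) coordinates
#' @export
LandmarkSet <- function(moving, fixed) {
  new("LandmarkSet", moving = as.matrix(moving), fixed = as.matrix(fixed))
}

#' Ablative margin assessment result
#'
#' @slot minMarginMM minimal ablative margin in mm, floored at 0
#' @slot surfaceDistancesMM signed mm distance from every tumour-surface
#'   voxel to the ablation-zone boundary (negative outside the ablation zone)
#' @slot group "A" when the minimal margin is at or below the safety
#'   threshold, "B" otherwise
#' @slot covered whether the tumour lies entirely inside the ablation zone
#' @slot thresholdMM the safety threshold used for grouping (default 5 mm)
#' @export
setClass("MarginResult",
  representation(minMarginMM = "numeric", surfaceDistancesMM = "numeric",
                 group = "character", covered = "logical",
                 thresholdMM = "numeric")
)

setValidity("MarginResult", function(object) {
  if (object@minMarginMM < 0) return("minMarginMM must be >= 0")
  expected <- max(0, min(object@surfaceDistancesMM))
  if (abs(object@minMarginMM - expected) > 1e-9)
    return("minMarginMM must equal max(0, min(surfaceDistancesMM))")
  if (object@covered != all(object@surfaceDistancesMM >= 0))
    return("covered must reflect all surface distances being >= 0")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @describeIn Volume-class extract the intensity array
#' @param x a Volume
#' @export
volData <- function(x) x@data

#' @describeIn Volume-class voxel spacing in mm (z, y, x)
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn Volume-class world origin in mm (z, y, x)
#' @export
volOrigin <- function(x) x@origin

#' @rdname RegistrationResult-class
#' @param x a RegistrationResult
#' @export
lossTrace <- function(x) x@lossTrace

#' @rdname RegistrationResult-class
#' @export
resultField <- function(x) x@field

#' @rdname RegistrationResult-class
#' @export
warpedVolume <- function(x) x@warped

#' @rdname MarginResult-class
#' @param x a MarginResult
#' @export
minMargin <- function(x) x@minMarginMM

#' @rdname MarginResult-class
#' @export
marginGroup <- function(x) x@group

#' @rdname MarginResult-class
#' @export
isCovered <- function(x) x@covered

#' @rdname MarginResult-class
#' @export
surfaceDistances <- function(x) x@surfaceDistancesMM

#' @rdname FeatureBlocks-class
#' @param x a FeatureBlocks
#' @export
featureMatrix <- function(x) x@blocks

# ---- show methods ----------------------------------------------------------

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d (z, y, x)\n", d[1], d[2], d[3]))
  cat("  spacing (mm):", paste(format(object@spacing), collapse = " x "), "\n")
  cat("  intensity range:",
      paste(format(range(object@data), digits = 4), collapse = " .. "), "\n")
})

setMethod("show", "DisplacementField", function(object) {
  cat("DisplacementField\n")
  if (length(object@control) > 0)
    cat("  control lattice:", paste(dim(object@control)[1:3], collapse = " x "),
        "at spacing", paste(object@controlSpacing, collapse = "/"), "voxels\n")
  if (!is.null(object@dense)) {
    mags <- sqrt(rowSums(matrix(object@dense, ncol = 3)^2))
    cat("  dense field:", paste(dim(object@dense)[1:3], collapse = " x "),
        sprintf("; |u| mean %.3f max %.3f voxels\n", mean(mags), max(mags)))
  }
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult:", object@iterations, "iterations,",
      if (object@converged) "converged" else "budget exhausted", "\n")
  cat(sprintf("  loss %.5f (identity %.5f)\n",
              min(object@lossTrace), object@initialLoss))
})

setMethod("show", "MarginResult", function(object) {
  cat(sprintf("MarginResult: min margin %.2f mm, group %s (threshold %g mm), %s\n",
              object@minMarginMM, object@group, object@thresholdMM,
              if (object@covered) "tumour covered" else "tumour not covered"))
})

setMethod("show", "FeatureBlocks", function(object) {
  cat("FeatureBlocks:", ncol(object@blocks), "regions x",
      nrow(object@blocks), "features\n")
})
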