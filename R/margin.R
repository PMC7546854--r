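# Ablative margin quantification: signed surface distances between the
# (warped) tumour boundary and the ablation-zone boundary, computed with a
# spacing-aware exact Euclidean distance transform.

# foreground voxels with at least one face-adjacent (6-connectivity)
# background neighbour; voxels on the volume faces count as boundary
boundaryVoxels <- function(a) {
  d <- dim(a)
  fg <- a == 1
  hasBg <- array(FALSE, d)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  for (ax in 1:3) {
    n <- d[ax]
    for (s in c(-1L, 1L)) {
      idx <- seq_len(n) + s
      edge <- idx < 1L | idx > n
      idx <- pad(idx, n)
      nb <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      nb <- array(nb, d)
      edgeArr <- slice.index(a, ax)
      edgeArr <- if (s == -1L) edgeArr == 1L else edgeArr == n
      hasBg <- hasBg | (nb == 0) | edgeArr
    }
  }
  fg & hasBg
}

#' Warp a binary mask through a displacement field
#'
#' The mask is resampled through the field with linear (tent-kernel)
#' interpolation and thresholded at 0.5. An identity field returns the input
#' mask exactly; a uniform integer-voxel translation translates it exactly.
#'
#' @param mask a \code{\linkS4class{Mask}} in the moving geometry
#' @param field a \code{\linkS4class{DisplacementField}} mapping fixed-frame
#'   coordinates to moving-frame coordinates
#' @return the warped \code{Mask} in the fixed geometry
#' @export
warpMask <- function(mask, field) {
  stopifnot(is(mask, "Mask"))
  shape <- if (length(field@shape) == 3L) field@shape else dim(mask@data)
  if (length(field@shape) == 3L && !is.null(field@dense) &&
      !all(dim(field@dense)[1:3] == dim(mask@data)))
    stop("geometry mismatch: field does not match the mask geometry")
  grid <- fieldToGrid(field, shape)
  v <- cppSamplePoints3D(as.numeric(mask@data), dim(mask@data), grid@points)
  Mask(array(as.numeric(v >= 0.5), shape), mask@spacing, mask@origin)
}

#' Minimal ablative margin from tumour and ablation masks
#'
#' For every tumour boundary voxel the Euclidean mm distance (spacing-aware)
#' to the nearest ablation-zone boundary voxel center is computed and signed:
#' positive where the tumour boundary lies inside the ablation zone, negative
#' where the tumour protrudes outside it. The minimal margin is the smallest
#' signed distance floored at 0 (a breached margin reports 0 mm), matching
#' the convention that the ablative margin is the shortest distance from the
#' tumour edge to the ablation-zone edge.
#'
#' @param tumor,ablation non-empty \code{\linkS4class{Mask}}s sharing
#'   geometry (the tumour warped into the post-ablation frame)
#' @param thresholdMM safety threshold for grouping (default 5 mm)
#' @return a \code{\linkS4class{MarginResult}}
#' @export
minimalMargin <- function(tumor, ablation, thresholdMM = 5) {
  stopifnot(is(tumor, "Mask"), is(ablation, "Mask"))
  checkGeometry(tumor, ablation, "tumor and ablation masks")
  if (sum(tumor@data) == 0) stop("validation error: empty tumor mask")
  if (sum(ablation@data) == 0) stop("validation error: empty ablation mask")
  sp <- tumor@spacing
  dims <- dim(tumor@data)
  ab <- boundaryVoxels(ablation@data)
  tb <- which(boundaryVoxels(tumor@data))
  edt <- cppEDTFromSeeds(as.vector(ab), as.integer(dims), sp)
  d <- edt[tb]
  inside <- ablation@data[tb] == 1
  signed <- ifelse(inside, d, -d)
  minM <- max(0, min(signed))
  new("MarginResult", minMarginMM = minM, surfaceDistancesMM = signed,
      group = classifyMargin(minM, thresholdMM), covered = all(signed >= 0),
      thresholdMM = thresholdMM)
}

#' Classify a minimal margin into safety groups
#'
#' Group A when the margin is at or below the threshold (insufficient safety
#' margin, inclusive boundary), group B when it exceeds it.
#'
#' @param minMarginMM nonnegative minimal margin in mm
#' @param thresholdMM threshold, default 5 mm
#' @return "A" or "B"
#' @export
classifyMargin <- function(minMarginMM, thresholdMM = 5) {
  if (any(minMarginMM < 0)) stop("validation error: margin must be >= 0")
  ifelse(minMarginMM <= thresholdMM, "A", "B")
}

#' Theoretical safety-margin contour
#'
#' Morphological dilation of the tumour by a spacing-aware Euclidean ball of
#' the requested mm radius: a voxel belongs to the contour region iff its
#' center lies within \code{marginMM} of a tumour voxel center. For margins
#' smaller than the finest voxel dimension the effective radius is raised to
#' that dimension, so the output always strictly contains the tumour (at
#' most a 1-voxel shell in the limit).
#'
#' @param tumor a non-empty \code{\linkS4class{Mask}}
#' @param marginMM dilation radius in mm (> 0), default 5
#' @return the dilated \code{Mask}
#' @export
theoreticalMarginContour <- function(tumor, marginMM = 5) {
  stopifnot(is(tumor, "Mask"))
  if (marginMM <= 0) stop("validation error: marginMM must be > 0")
  if (sum(tumor@data) == 0) stop("validation error: empty tumor mask")
  edt <- cppEDTFromSeeds(as.vector(tumor@data == 1), as.integer(dim(tumor@data)),
                         tumor@spacing)
  rEff <- max(marginMM, min(tumor@spacing))
  Mask(array(as.numeric(edt <= rEff + 1e-9), dim(tumor@data)),
       tumor@spacing, tumor@origin)
}

#' Margin sufficiency after registration
#'
#' Chains \code{\link{warpMask}} (when a field is supplied),
#' \code{\link{minimalMargin}} and \code{\link{classifyMargin}}; the safety
#' margin is achieved iff the minimal margin exceeds the threshold (group B).
#'
#' @param tumor tumour mask in the moving (pre-ablation) geometry
#' @param ablation ablation-zone mask in the fixed geometry
#' @param field optional displacement field from registration
#' @param marginMM safety threshold, default 5 mm
#' @return list with the \code{\linkS4class{MarginResult}} (\code{margin})
#'   and the logical \code{achieved}
#' @export
marginSufficiency <- function(tumor, ablation, field = NULL, marginMM = 5) {
  if (!is.null(field)) tumor <- warpMask(tumor, field)
  mr <- minimalMargin(tumor, ablation, thresholdMM = marginMM)
  list(margin = mr, achieved = mr@group == "B")
}
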