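#' Identity sampling grid
#'
#' @param shape output dimensions: (ny, nx) for a 2D grid or (nz, ny, nx)
#'   for a 3D grid
#' @return a \code{\linkS4class{SamplingGrid}} whose point for every output
#'   element is its own 0-based coordinate
#' @export
identityGrid <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) {
    ny <- shape[1]; nx <- shape[2]
    pts <- cbind(x = rep(0:(nx - 1), each = ny),
                 y = rep(0:(ny - 1), times = nx))
  } else if (length(shape) == 3L) {
    nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
    pts <- cbind(x = rep(0:(nx - 1), each = nz * ny),
                 y = rep(rep(0:(ny - 1), each = nz), times = nx),
                 z = rep(0:(nz - 1), times = ny * nx))
  } else stop("shape must have length 2 or 3")
  new("SamplingGrid", points = pts, shape = shape)
}

#' Number of control lattice nodes needed to cover a shape
#' @keywords internal
latticeDims <- function(shape, controlSpacing) {
  pmax(2L, as.integer(ceiling((shape - 1) / controlSpacing)) + 1L)
}

#' Identity (all-zero) displacement field
#'
#' @param shape target image shape (nz, ny, nx)
#' @param controlSpacing control-point spacing in voxels along (z, y, x)
#' @export
identityField <- function(shape, controlSpacing = c(2, 8, 8)) {
  shape <- as.integer(shape)
  nd <- latticeDims(shape, controlSpacing)
  new("DisplacementField", control = array(0, c(nd, 3)),
      controlSpacing = as.numeric(controlSpacing), dense = NULL, shape = shape)
}

#' Materialise the dense per-voxel displacement field
#'
#' Interpolates the control lattice with the cubic Keys kernel (edge
#' replication). A cached dense field is returned as-is.
#'
#' @param field a \code{\linkS4class{DisplacementField}}
#' @param shape target shape; defaults to the field's own shape
#' @return a (nz, ny, nx, 3) array of voxel-unit displacements (dz, dy, dx)
#' @export
denseField <- function(field, shape = NULL) {
  if (is.null(shape)) shape <- field@shape
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("a target shape (nz, ny, nx) is required")
  if (!is.null(field@dense)) {
    if (!all(dim(field@dense)[1:3] == shape))
      stop("geometry mismatch: cached dense field does not match shape")
    return(field@dense)
  }
  nd <- dim(field@control)[1:3]
  need <- latticeDims(shape, field@controlSpacing)
  if (any(nd < need))
    stop("geometry mismatch: control lattice does not cover the output shape")
  cppLatticeToDense(field@control, nd, shape, field@controlSpacing)
}

#' Generate the sampling grid of a displacement field
#'
#' The grid point for output voxel i is its own coordinate plus the
#' interpolated displacement at i; a zero field yields the identity grid.
#'
#' @param field a \code{\linkS4class{DisplacementField}}
#' @param shape output shape (nz, ny, nx)
#' @return a \code{\linkS4class{SamplingGrid}} with (x, y, z) points
#' @export
fieldToGrid <- function(field, shape = NULL) {
  if (is.null(shape)) shape <- field@shape
  shape <- as.integer(shape)
  dense <- denseField(field, shape)
  g <- identityGrid(shape)
  g@points[, "x"] <- g@points[, "x"] + as.vector(dense[, , , 3])
  g@points[, "y"] <- g@points[, "y"] + as.vector(dense[, , , 2])
  g@points[, "z"] <- g@points[, "z"] + as.vector(dense[, , , 1])
  g
}

asPoints <- function(grid, d) {
  if (is(grid, "SamplingGrid")) {
    if (ncol(grid@points) != d) stop("grid dimensionality mismatch")
    list(pts = grid@points, shape = grid@shape)
  } else if (is.matrix(grid) && ncol(grid) == d) {
    list(pts = grid, shape = NULL)
  } else stop("grid must be a SamplingGrid or an n x ", d, " point matrix")
}

#' Bilinear (tent-kernel) image sampling with border-zero handling
#'
#' Samples a 2D image at continuous (x, y) coordinates using the separable
#' tent kernel: the output value is the kernel-weighted sum of source pixels,
#' and coordinates outside the source contribute zero. Sampling at integer
#' coordinates reproduces the source exactly. The operation is differentiable
#' with respect to the grid coordinates (see \code{\link{sampleGradient}}).
#'
#' @param source numeric matrix (ny, nx); x indexes columns, y rows, both
#'   0-based at pixel centers
#' @param grid a \code{\linkS4class{SamplingGrid}} with 2-column points, or
#'   an n x 2 matrix of (x, y) coordinates
#' @return a matrix shaped like the grid, or a vector for a bare point matrix
#' @export
bilinearSample <- function(source, grid) {
  stopifnot(is.matrix(source))
  p <- asPoints(grid, 2L)
  v <- cppSamplePoints2D(as.numeric(source), dim(source), p$pts)
  if (!is.null(p$shape)) matrix(v, p$shape[1], p$shape[2]) else v
}

#' Trilinear volume sampling with border-zero handling
#'
#' 3D extension of \code{\link{bilinearSample}} with a separable 3-axis tent
#' kernel.
#'
#' @param source a \code{\linkS4class{Volume}} or 3D array (z, y, x)
#' @param grid a \code{\linkS4class{SamplingGrid}} with 3-column (x, y, z)
#'   points, or an n x 3 matrix
#' @return a \code{Volume}/array shaped like the grid, or a vector for a bare
#'   point matrix
#' @export
trilinearSample <- function(source, grid) {
  isVol <- is(source, "Volume")
  a <- if (isVol) source@data else source
  stopifnot(length(dim(a)) == 3L)
  p <- asPoints(grid, 3L)
  v <- cppSamplePoints3D(as.numeric(a), dim(a), p$pts)
  if (is.null(p$shape)) return(v)
  out <- array(v, p$shape)
  if (isVol) Volume(out, source@spacing, source@origin) else out
}

#' Gradient of sampled values with respect to grid coordinates
#'
#' Returns the upstream-weighted analytic derivative of
#' \code{bilinearSample}/\code{trilinearSample} output with respect to each
#' grid coordinate (the tent kernel's subgradient is used at integer
#' coordinates).
#'
#' @param source matrix (2D) or array/Volume (3D)
#' @param grid point matrix or SamplingGrid
#' @param upstream upstream gradient, one value per grid point (default 1)
#' @return n x 2 or n x 3 matrix of d(output)/d(coordinate)
#' @export
sampleGradient <- function(source, grid, upstream = NULL) {
  if (is(source, "Volume")) source <- source@data
  d <- length(dim(source))
  p <- asPoints(grid, if (d == 2L) 2L else 3L)
  if (is.null(upstream)) upstream <- rep(1, nrow(p$pts))
  if (d == 2L)
    cppSampleGrad2D(as.numeric(source), dim(source), p$pts, upstream)
  else
    cppSampleGrad3D(as.numeric(source), dim(source), p$pts, upstream)
}
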