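#' Read a NIfTI-1 volume
#'
#' Reads a scalar 3D NIfTI image into a \code{\linkS4class{Volume}}. Geometry
#' is taken from the NIfTI affine; only axis-aligned affines are supported.
#' Axes stored with a negative world direction are flipped so that array
#' index order always increases with world coordinate.
#'
#' @param path path to a .nii or .nii.gz file
#' @param mask logical; read as a binary \code{\linkS4class{Mask}}
#' @return a \code{Volume} (or \code{Mask}) with data in (z, y, x) axis order
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("unsupported dimensionality in '", path, "': expected a 3D image, got ",
         length(dim(a)), "D")
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
    stop("only axis-aligned affines are supported; '", path,
         "' has an oblique orientation")
  scales <- diag(rot)
  if (any(abs(scales) <= 0)) stop("degenerate affine in '", path, "'")
  orig <- aff[1:3, 4]
  # flip axes with negative direction so spacing is positive
  for (ax in 1:3) {
    if (scales[ax] < 0) {
      idx <- rev(seq_len(dim(a)[ax]))
      a <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                  a[, , idx, drop = FALSE])
      orig[ax] <- orig[ax] + scales[ax] * (dim(a)[ax] - 1)
      scales[ax] <- -scales[ax]
    }
  }
  # NIfTI stores (x, y, z); internal order is (z, y, x)
  a <- aperm(a, c(3, 2, 1))
  storage.mode(a) <- "double"
  spacing <- rev(scales)
  origin <- rev(orig)
  if (mask) Mask(a, spacing, origin) else Volume(a, spacing, origin)
}

#' Write a volume as NIfTI-1
#'
#' Masks are written as uint8 in \{0, 1\}; other volumes as float32. The
#' round trip preserves data, spacing and origin to float32 precision.
#'
#' @param volume a \code{\linkS4class{Volume}} or \code{\linkS4class{Mask}}
#' @param path output path (.nii or .nii.gz)
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  a <- aperm(volume@data, c(3, 2, 1))  # back to (x, y, z)
  sp <- rev(volume@spacing)
  orig <- rev(volume@origin)
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- sp
  aff <- rbind(cbind(diag(sp), orig), c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is(volume, "Mask")) "uint8" else "float")
  invisible(path)
}

#' Write a displacement field as a multi-component NIfTI
#'
#' The dense field (voxel-unit displacements, components dz/dy/dx) is stored
#' as a 4D image whose 4th dimension indexes the component.
#' @param field a \code{\linkS4class{DisplacementField}} with a known shape
#' @param path output path
#' @export
writeField <- function(field, path) {
  dense <- denseField(field)
  a <- aperm(dense, c(3, 2, 1, 4))
  img <- RNifti::asNifti(a, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

sameGeometry <- function(a, b) {
  all(dim(a@data) == dim(b@data)) &&
    all(abs(a@spacing - b@spacing) < 1e-6)
}

checkGeometry <- function(a, b, what = "images") {
  if (!sameGeometry(a, b))
    stop("geometry mismatch: ", what, " must share shape and spacing")
  invisible(TRUE)
}
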