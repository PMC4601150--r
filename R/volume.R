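#' 3-D scalar image volume with anisotropic voxel spacing
#'
#' Lightweight container for an angiographic volume: a 3-D numeric array plus
#' the physical voxel spacing (mm per axis) and the world position (mm) of the
#' centre of voxel `[1, 1, 1]`. Axis 3 is the axial / slice direction; axes 1
#' and 2 are in-plane. All package functions take distances in mm and convert
#' to voxels internally using the spacing.
#'
#' @param values numeric 3-D array of intensities.
#' @param spacing numeric length-3, mm per voxel along each array axis
#'   (in-plane x, in-plane y, slice z). Must be positive.
#' @param origin numeric length-3, world mm coordinate of voxel `[1,1,1]`
#'   centre. Defaults to `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(0, c(8, 8, 4)), spacing = c(0.5, 0.5, 0.75))
#' dim(vol$values)
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values")
  if (any(!is.finite(values))) stop("volume intensities must be finite")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

# world mm -> (fractional) 1-based voxel index
world_to_voxel <- function(vol, pos_mm) {
  pos_mm <- matrix(pos_mm, ncol = 3)
  sweep(sweep(pos_mm, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

# 1-based voxel index -> world mm (voxel centre)
voxel_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# physical extent (mm) of the grid, from first to last voxel centre
volume_extent <- function(vol) (dim(vol$values) - 1) * vol$spacing

#' Read / write a volume as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry the voxel spacing through `pixdim`. World origin is kept at the
#' package convention (voxel `[1,1,1]` centre at `origin`).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an [image_volume()].
#' @return `read_volume()` returns an [image_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(RNifti::niftiHeader(img), "pixdim")[2:4]
  if (is.null(sp) || any(!is.finite(sp)) || any(sp <= 0))
    sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Trilinear interpolation of volume intensities at world positions
#'
#' Positions outside the grid return `NA`.
#'
#' @param vol an [image_volume()].
#' @param pos_mm n x 3 matrix of world positions (mm).
#' @return numeric vector of length n.
#' @keywords internal
interp_trilinear <- function(vol, pos_mm) {
  v <- world_to_voxel(vol, pos_mm)
  d <- dim(vol$values)
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  out <- rep(NA_real_, nrow(v))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol$values[cbind(i, j, k)]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx
  c10 <- at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx
  c01 <- at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx
  c11 <- at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}
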