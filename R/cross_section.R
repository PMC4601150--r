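#' Resample a 2-D plane perpendicular to a vessel tangent
#'
#' Trilinearly interpolates the volume on a square grid lying in the plane
#' through `origin` orthogonal to `tangent`. The in-plane axes are chosen
#' deterministically: the tangent is crossed with the world axis most
#' orthogonal to it, then orthonormalized, so repeated calls with the same
#' inputs give identical output. Grid points outside the volume are `NA`.
#'
#' @param volume an [image_volume()].
#' @param origin world mm position on the plane (the centerline point).
#' @param tangent direction normal to the plane (need not be unit length).
#' @param fov_mm side length of the sampled square (mm).
#' @param step_mm in-plane pixel pitch (mm).
#' @return numeric matrix with attributes `step_mm`, `origin`, `axes`
#'   (2 x 3 matrix of the in-plane unit vectors) and `center_px`.
#' @export
resample_plane <- function(volume, origin, tangent, fov_mm, step_mm) {
  tn <- sqrt(sum(tangent^2))
  if (!is.finite(tn) || tn == 0) stop("degenerate tangent vector")
  t1 <- tangent / tn
  e <- diag(3)[, which.min(abs(t1))]      # world axis most orthogonal to t1
  u <- c(t1[2] * e[3] - t1[3] * e[2],
         t1[3] * e[1] - t1[1] * e[3],
         t1[1] * e[2] - t1[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t1[2] * u[3] - t1[3] * u[2],
         t1[3] * u[1] - t1[1] * u[3],
         t1[1] * u[2] - t1[2] * u[1])
  offs <- seq(-fov_mm / 2, fov_mm / 2, by = step_mm)
  n <- length(offs)
  grid <- expand.grid(a = offs, b = offs)
  pts <- cbind(origin[1] + grid$a * u[1] + grid$b * v[1],
               origin[2] + grid$a * u[2] + grid$b * v[2],
               origin[3] + grid$a * u[3] + grid$b * v[3])
  img <- matrix(interp_trilinear(volume, pts), n, n)
  structure(img, step_mm = step_mm, origin = origin,
            axes = rbind(u, v), center_px = c((n + 1) / 2, (n + 1) / 2))
}

#' Segment the vessel lumen on a cross-section image
#'
#' Threshold-plus-curvature-regularization segmentation of one cross-section:
#' pixels inside the intensity band (at or above LT, and at or below UT for
#' CTA — hyperintense calcified plaque is excluded from the lumen) form the
#' candidate region; the connected component containing the seed is kept and
#' its boundary regularized by morphological closing/opening with a disc whose
#' radius grows with `curvature_scale` (scale 10 maps to a 1-pixel disc),
#' which closes single-pixel noise holes and smooths the contour the way a
#' curvature term in a level-set evolution would.
#'
#' @param image_2d matrix from [resample_plane()].
#' @param thresholds a [threshold_set()].
#' @param seed_point length-2 pixel index (row, col); defaults to the image
#'   centre (the centerline pierces the plane there).
#' @param curvature_scale smoothing strength; larger = smoother boundary.
#' @return logical matrix (the lumen mask). If the seed lies out of band the
#'   mask is empty with attribute `seed_out_of_band = TRUE`.
#' @export
segment_cross_section <- function(image_2d, thresholds, seed_point = NULL,
                                  curvature_scale = 10) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (is.null(seed_point)) {
    sp <- attr(image_2d, "center_px")
    seed_point <- if (is.null(sp)) (dim(image_2d) + 1) / 2 else sp
  }
  seed_point <- as.integer(round(seed_point))
  band <- !is.na(image_2d) & image_2d >= thresholds$LT
  if (!is.na(thresholds$UT)) band <- band & image_2d <= thresholds$UT

  # tolerate a seed a pixel or two off the lumen: snap to the nearest in-band
  # pixel within a small window
  if (!band[seed_point[1], seed_point[2]]) {
    d <- dim(band)
    win <- 3L
    ri <- max(1, seed_point[1] - win):min(d[1], seed_point[1] + win)
    ci <- max(1, seed_point[2] - win):min(d[2], seed_point[2] + win)
    sub <- band[ri, ci, drop = FALSE]
    if (!any(sub)) {
      out <- matrix(FALSE, d[1], d[2])
      attr(out, "seed_out_of_band") <- TRUE
      return(out)
    }
    w <- which(sub, arr.ind = TRUE)
    best <- which.min((ri[w[, 1]] - seed_point[1])^2 +
                        (ci[w[, 2]] - seed_point[2])^2)
    seed_point <- c(ri[w[best, 1]], ci[w[best, 2]])
  }

  comp_of_seed <- function(m) {
    lab <- EBImage::bwlabel(m * 1)
    id <- lab[seed_point[1], seed_point[2]]
    if (id == 0) matrix(FALSE, nrow(m), ncol(m)) else lab == id
  }
  mask <- comp_of_seed(band)

  r <- max(1L, as.integer(round(curvature_scale / 10)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  sm <- EBImage::opening(EBImage::closing(mask * 1, brush), brush)
  sm <- EBImage::fillHull(sm) > 0
  # plaque pixels must never enter the lumen mask, even after closing
  if (!is.na(thresholds$UT)) sm <- sm & !(!is.na(image_2d) & image_2d > thresholds$UT)
  if (sm[seed_point[1], seed_point[2]]) mask <- comp_of_seed(sm)
  attr(mask, "seed_out_of_band") <- FALSE
  mask
}

#' Area and shortest diameter of a binary cross-section mask
#'
#' Area is the pixel count times the pixel area. The shortest diameter is the
#' minimum Feret (caliper) width of the pixel region: the mask's convex-hull
#' pixel centres are projected on directions swept in 1 degree steps and the
#' projected pixel footprint is added, giving the exact width of the pixel
#' union in each direction.
#'
#' @param mask logical matrix.
#' @param in_plane_spacing pixel pitch, scalar or length-2 (mm).
#' @param angle_step_deg caliper angular step (default 1 degree).
#' @return named list: `area_mm2`, `diameter_mm`.
#' @examples
#' px <- 0.1
#' xs <- seq(-2.5, 2.5, by = px)
#' disc <- outer(xs, xs, function(a, b) a^2 + b^2 <= 2^2)
#' measure_mask(disc, px)  # area ~ 12.57 mm^2, diameter ~ 4.0 mm
#' @export
measure_mask <- function(mask, in_plane_spacing, angle_step_deg = 1) {
  if (!any(mask)) stop("cannot measure an empty mask")
  sp <- rep(in_plane_spacing, length.out = 2)
  area <- sum(mask) * prod(sp)
  pix <- which(mask, arr.ind = TRUE)
  pts <- cbind(pix[, 1] * sp[1], pix[, 2] * sp[2])
  hull <- if (nrow(pts) > 2) pts[grDevices::chull(pts), , drop = FALSE] else pts
  th <- seq(0, pi - 1e-9, by = angle_step_deg * pi / 180)
  ct <- cos(th); st <- sin(th)
  proj <- hull %*% rbind(ct, st)                 # hull points x angles
  spread <- apply(proj, 2, max) - apply(proj, 2, min)
  footprint <- abs(ct) * sp[1] + abs(st) * sp[2] # projected pixel extent
  list(area_mm2 = area, diameter_mm = min(spread + footprint))
}
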