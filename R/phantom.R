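#' Specify a synthetic artery for a vascular phantom
#'
#' An artery is a tube swept along a smooth 3-D path with a baseline radius
#' and optional focal narrowings (stenoses), each a smooth cosine-taper dip in
#' the radius profile. Child branches attach at a stated arc-length, creating
#' bifurcations with analytically known positions.
#'
#' @param path numeric n x 3 matrix of control points (world mm). The curve is
#'   interpolated through them (cubic spline for n > 2, linear for n = 2). By
#'   convention the first point lies on the aorta surface.
#' @param radius_mm baseline lumen radius (mm), > 0.
#' @param stenoses data frame with columns `center_mm` (arc-length of the dip
#'   centre), `depth` (fractional radius reduction in `[0, 1)`) and `width_mm`
#'   (full width of the cosine taper). May be empty.
#' @param branches list of child `artery_spec` objects, each carrying an
#'   `attach_mm` attribute (arc-length on this artery where the child roots).
#' @param intensity lumen intensity; `NA` inherits the aorta's value.
#' @return An object of class `artery_spec`.
#' @export
artery_spec <- function(path, radius_mm, stenoses = NULL, branches = list(),
                        intensity = NA_real_) {
  path <- as.matrix(path)
  if (ncol(path) != 3L || nrow(path) < 2L)
    stop("`path` must be an n x 3 matrix with n >= 2")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive")
  if (is.null(stenoses))
    stenoses <- data.frame(center_mm = numeric(), depth = numeric(),
                           width_mm = numeric())
  stopifnot(all(c("center_mm", "depth", "width_mm") %in% names(stenoses)))
  if (any(stenoses$depth < 0 | stenoses$depth >= 1))
    stop("stenosis `depth` must lie in [0, 1)")
  if (any(stenoses$width_mm <= 0)) stop("stenosis `width_mm` must be positive")
  structure(
    list(path = path, radius_mm = radius_mm,
         stenoses = tibble::as_tibble(stenoses), branches = branches,
         intensity = intensity),
    class = "artery_spec"
  )
}

#' Attach a child branch to an artery at a given arc-length
#'
#' @param parent,child `artery_spec` objects.
#' @param attach_mm arc-length (mm) on `parent` where `child` roots.
#' @return `parent` with the child appended to its branch list.
#' @export
add_branch <- function(parent, child, attach_mm) {
  attr(child, "attach_mm") <- attach_mm
  parent$branches <- c(parent$branches, list(child))
  parent
}

#' Specify a synthetic angiographic phantom
#'
#' The phantom emulates a contrast-filled renal vascular tree: an axis-aligned
#' aorta-like cylinder (axis along array axis 3) with arteries branching off
#' it, embedded in a uniform background, optionally with hyperintense
#' calcified-plaque blobs (CTA only) and additive Gaussian noise. CTA-like
#' voxels are 0.5 x 0.5 x 0.75 mm and MRA-like voxels 0.7 x 0.7 x 2.0 mm
#' (in-plane x, in-plane y, slice).
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per axis; positive.
#' @param aorta list with `center` (x, y world mm of the cylinder axis),
#'   `radius_mm`, `intensity`.
#' @param arteries list of [artery_spec()] objects.
#' @param background_intensity scalar background value.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none).
#' @param plaques data frame with columns `x_mm`, `y_mm`, `z_mm`, `radius_mm`,
#'   `intensity` (spherical blobs painted over the scene); intensities must
#'   exceed the lumen intensity.
#' @param seed integer seed for the noise stream.
#' @param voxelization `"partial"` (default): each voxel takes the
#'   partial-volume average of the scene over a supersampled subgrid, the way
#'   a scanner integrates signal over its voxel; `"binary"`: a voxel takes the
#'   lumen value when its centre lies inside a structure. Partial volume is
#'   essential at MRA-like slice thickness, where a severe stenosis is
#'   thinner than one voxel: a binary grid would break the lumen into
#'   disconnected voxels, which no scanner does.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing, aorta, arteries,
                         background_intensity = 50, noise_sd = 0,
                         plaques = NULL, seed = 1L,
                         voxelization = c("partial", "binary")) {
  voxelization <- match.arg(voxelization)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive on all axes")
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2))
  stopifnot(is.list(aorta), all(c("center", "radius_mm", "intensity") %in% names(aorta)))
  if (aorta$radius_mm <= 0) stop("aorta radius must be positive")
  if (is.null(plaques))
    plaques <- data.frame(x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                          radius_mm = numeric(), intensity = numeric())
  lum <- aorta$intensity
  if (nrow(plaques) > 0 && any(plaques$intensity <= lum))
    stop("plaque intensity must exceed the lumen intensity")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
         aorta = aorta, arteries = arteries,
         background_intensity = background_intensity, noise_sd = noise_sd,
         plaques = tibble::as_tibble(plaques), seed = as.integer(seed),
         voxelization = voxelization),
    class = "phantom_spec"
  )
}

# densify an artery path: returns list(points = m x 3 mm, s = arc-length mm)
densify_path <- function(path, step_mm) {
  chord <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  total <- chord[length(chord)]
  m <- max(2L, ceiling(total / step_mm) + 1L)
  t_out <- seq(0, total, length.out = m)
  pts <- if (nrow(path) > 2) {
    sapply(1:3, function(j) stats::spline(chord, path[, j], xout = t_out)$y)
  } else {
    sapply(1:3, function(j) stats::approx(chord, path[, j], xout = t_out)$y)
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(points = pts, s = s)
}

arc_length_of <- function(art, step_mm = 0.25) {
  d <- densify_path(art$path, step_mm)
  d$s[length(d$s)]
}

# radius profile r(s): baseline minus cosine-taper dips
radius_at <- function(art, s) {
  r <- rep(art$radius_mm, length(s))
  if (nrow(art$stenoses) > 0) {
    for (i in seq_len(nrow(art$stenoses))) {
      st <- art$stenoses[i, ]
      u <- abs(s - st$center_mm)
      dip <- ifelse(u <= st$width_mm / 2,
                    st$depth * 0.5 * (1 + cos(2 * pi * (s - st$center_mm) / st$width_mm)),
                    0)
      r <- r * (1 - dip)
    }
  }
  r
}

# paint a swept tube into `vol` (modified in place by value semantics);
# returns the updated array
paint_tube <- function(values, spacing, origin, art, intensity, step_mm) {
  d <- dim(values)
  dense <- densify_path(art$path, step_mm)
  r_s <- radius_at(art, dense$s)
  xs <- origin[1] + (seq_len(d[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * spacing[3]
  for (i in seq_along(dense$s)) {
    p <- dense$points[i, ]
    r <- r_s[i]
    ix <- which(abs(xs - p[1]) <= r)
    iy <- which(abs(ys - p[2]) <= r)
    iz <- which(abs(zs - p[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - p[1])^2
    dy2 <- (ys[iy] - p[2])^2
    dz2 <- (zs[iz] - p[3])^2
    box <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    if (any(box)) {
      sub <- values[ix, iy, iz, drop = FALSE]
      sub[box] <- intensity
      values[ix, iy, iz] <- sub
    }
  }
  values
}

# block-average an array by integer factors per axis (partial-volume downsample)
block_mean <- function(a, f) {
  for (ax in 1:3) {
    if (f[ax] == 1L) next
    d <- dim(a)
    a <- aperm(a, c(ax, setdiff(1:3, ax)))
    da <- dim(a)
    dim(a) <- c(f[ax], da[1] / f[ax], da[2], da[3])
    a <- colMeans(a)
    inv <- order(c(ax, setdiff(1:3, ax)))
    a <- aperm(a, inv)
  }
  a
}

# analytic truth for one artery: per-segment extremes from the radius profile
artery_truth <- function(art, artery_id, ds = 0.05) {
  len <- arc_length_of(art)
  if (nrow(art$stenoses) > 0 &&
      any(art$stenoses$center_mm < 0 | art$stenoses$center_mm > len))
    stop("stenosis centre lies outside the artery path length")
  attach_s <- vapply(art$branches, function(b) attr(b, "attach_mm"), numeric(1))
  if (length(attach_s) && any(attach_s < 0 | attach_s > len))
    stop("branch attachment lies outside the artery path length")
  seg_truth <- function(s_from, s_to, seg_art, seg_idx) {
    s <- seq(s_from, s_to, by = ds)
    r <- radius_at(seg_art, s)
    min_d <- 2 * min(r); max_d <- 2 * max(r)
    tibble::tibble(
      artery = artery_id, segment = seg_idx,
      min_d = min_d, max_d = max_d,
      min_a = pi * (min_d / 2)^2, max_a = pi * (max_d / 2)^2,
      dred = (1 - min_d / max_d) * 100,
      ared = (1 - (min_d / max_d)^2) * 100
    )
  }
  first_bif <- if (length(attach_s)) min(attach_s) else NA_real_
  out <- seg_truth(0, if (is.na(first_bif)) len else first_bif, art, 1L)
  if (!is.na(first_bif)) {
    # candidates at the first bifurcation: parent continuation + attached child
    child <- art$branches[[which.min(attach_s)]]
    cand <- list(
      parent = list(art = art, from = first_bif,
                    to = min(c(attach_s[attach_s > first_bif], len)),
                    r = art$radius_mm),
      child = list(art = child, from = 0,
                   to = {
                     ca <- vapply(child$branches, function(b) attr(b, "attach_mm"), numeric(1))
                     cl <- arc_length_of(child)
                     if (length(ca)) min(c(ca, cl)) else cl
                   },
                   r = child$radius_mm)
    )
    big <- cand[[which.max(vapply(cand, function(cc) cc$r, numeric(1)))]]
    out <- dplyr::bind_rows(out, seg_truth(big$from, big$to, big$art, 2L))
  }
  attr(out, "bifurcation_mm") <- attach_s
  out
}

#' Generate a synthetic angiographic volume with known stenosis geometry
#'
#' Voxelizes the phantom scene (a voxel is lumen when its centre lies inside
#' the aorta cylinder or inside a swept artery tube), paints plaques over it,
#' and adds seeded zero-mean Gaussian noise. The ground-truth diameter/area
#' extremes per segment are computed analytically from the radius profiles
#' before voxelization, so they are exact regardless of grid resolution.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (an [image_volume()]) and `truth`
#'   (tibble: artery, segment, `min_d`, `max_d`, `min_a`, `max_a` in mm / mm^2,
#'   `dred`, `ared` in percent; bifurcation arc-lengths as attribute
#'   `bifurcation_mm`).
#' @examples
#' art <- artery_spec(rbind(c(10, 0, 7.5), c(40, 0, 7.5)), radius_mm = 2.5,
#'                    stenoses = data.frame(center_mm = 15, depth = 0.5,
#'                                          width_mm = 8))
#' ph <- generate_phantom(phantom_spec(
#'   grid_shape = c(96, 48, 20), voxel_spacing = c(0.5, 0.5, 0.75),
#'   aorta = list(center = c(0, 0), radius_mm = 9, intensity = 300),
#'   arteries = list(art), background_intensity = 50,
#'   seed = 7))
#' ph$truth
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  # centre the grid so the aorta axis can sit at negative x if desired
  origin <- attr(spec, "origin")
  if (is.null(origin)) origin <- c(
    spec$aorta$center[1] - spec$aorta$radius_mm - 5 * sp[1],
    -(d[2] - 1) * sp[2] / 2,
    0
  )

  truth <- dplyr::bind_rows(lapply(seq_along(spec$arteries), function(i) {
    artery_truth(spec$arteries[[i]], i)  # validates stenoses/branches too
  }))

  # paint the scene on a grid; for partial-volume mode this is a supersampled
  # subgrid whose block means become the voxel values
  if (spec$voxelization == "partial") {
    f <- pmax(1L, as.integer(ceiling(sp / 0.35)))
  } else {
    f <- c(1L, 1L, 1L)
  }
  gd <- d * f
  gsp <- sp / f
  gorigin <- origin - sp / 2 + gsp / 2  # sub-centres tile each voxel

  values <- array(spec$background_intensity, dim = gd)
  xs <- gorigin[1] + (seq_len(gd[1]) - 1) * gsp[1]
  ys <- gorigin[2] + (seq_len(gd[2]) - 1) * gsp[2]
  # aorta cylinder along axis 3
  in_plane <- outer((xs - spec$aorta$center[1])^2,
                    (ys - spec$aorta$center[2])^2, "+") <= spec$aorta$radius_mm^2
  values[rep(in_plane, gd[3])] <- spec$aorta$intensity

  step <- min(gsp) / 2
  paint_recursive <- function(values, art) {
    intens <- if (is.na(art$intensity)) spec$aorta$intensity else art$intensity
    values <- paint_tube(values, gsp, gorigin, art, intens, step)
    for (b in art$branches) values <- paint_recursive(values, b)
    values
  }
  for (art in spec$arteries) values <- paint_recursive(values, art)

  if (nrow(spec$plaques) > 0) {
    zs <- gorigin[3] + (seq_len(gd[3]) - 1) * gsp[3]
    for (i in seq_len(nrow(spec$plaques))) {
      pl <- spec$plaques[i, ]
      ix <- which(abs(xs - pl$x_mm) <= pl$radius_mm)
      iy <- which(abs(ys - pl$y_mm) <= pl$radius_mm)
      iz <- which(abs(zs - pl$z_mm) <= pl$radius_mm)
      if (!length(ix) || !length(iy) || !length(iz)) next
      box <- outer(outer((xs[ix] - pl$x_mm)^2, (ys[iy] - pl$y_mm)^2, "+"),
                   (zs[iz] - pl$z_mm)^2, "+") <= pl$radius_mm^2
      sub <- values[ix, iy, iz, drop = FALSE]
      sub[box] <- pl$intensity
      values[ix, iy, iz] <- sub
    }
  }

  if (any(f > 1L)) values <- block_mean(values, f)

  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
                              stats::rnorm(length(values), 0, spec$noise_sd))
    values <- values + array(noise, dim = d)
  }

  list(volume = image_volume(values, sp, origin), truth = truth)
}

#' Standard ROI placements for a phantom
#'
#' Places aorta ROIs on the aorta axis (swept across every slice, so the
#' reference-slice search can scan them) and background ROIs in the phantom
#' corners, mimicking the manual psoas/vertebral placements used on clinical
#' scans. Counts follow the modality convention: 4 background ROIs for CTA,
#' 3 for MRA.
#'
#' @param spec a [phantom_spec()].
#' @param volume the generated [image_volume()] (for the grid geometry).
#' @param modality `"CTA"` or `"MRA"`.
#' @return list with elements `aorta` and `background`, both [roi_set()]s.
#' @export
phantom_roi_sets <- function(spec, volume, modality = c("CTA", "MRA")) {
  modality <- match.arg(modality)
  d <- dim(volume$values)
  aorta <- roi_set(
    tibble::tibble(x_mm = spec$aorta$center[1], y_mm = spec$aorta$center[2],
                   slice = NA_integer_,
                   radius_mm = spec$aorta$radius_mm * 0.6),
    target = "aorta"
  )
  # background ROIs in the far field on the artery side (clear of the aorta
  # cylinder and of the artery tube), mid-stack
  ext <- volume_extent(volume)
  lo <- volume$origin
  xs <- lo[1] + c(0.70, 0.92, 0.70, 0.92) * ext[1]
  ys <- lo[2] + c(0.12, 0.12, 0.88, 0.88) * ext[2]
  n_bg <- if (modality == "CTA") 4L else 3L
  background <- roi_set(
    tibble::tibble(x_mm = xs[seq_len(n_bg)], y_mm = ys[seq_len(n_bg)],
                   slice = as.integer(round(d[3] / 2)),
                   radius_mm = 2.5),
    target = if (modality == "CTA") "psoas" else "vertebral"
  )
  list(aorta = aorta, background = background)
}
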