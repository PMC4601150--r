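#' Pairwise fuzzy affinity between two voxel intensities
#'
#' Trapezoidal in-band membership applied to the dimmer of the two voxels:
#' a voxel at or below the lower threshold (or, for CTA, above the upper
#' threshold) has membership 0; membership rises linearly to 1 at the contrast
#' value and stays 1 up to the upper threshold. The affinity of a voxel pair
#' is the minimum of the two memberships, so it is symmetric, 1 when both
#' voxels sit at the contrast value, 0 when either lies out of band, and
#' monotone non-decreasing in the dimmer intensity within the band.
#'
#' @param intensity_a,intensity_b voxel intensities (vectorized).
#' @param thresholds a [threshold_set()].
#' @return affinity in `[0, 1]`.
#' @examples
#' ts <- threshold_set(300, 60, "MRA")
#' affinity(300, 300, ts)  # 1
#' affinity(100, 300, ts)  # 0: below LT = 140
#' @export
affinity <- function(intensity_a, intensity_b, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  g <- function(v) {
    m <- pmin(pmax((v - thresholds$LT) /
                     (thresholds$aorta_value - thresholds$LT), 0), 1)
    m[v <= thresholds$LT] <- 0
    if (!is.na(thresholds$UT)) m[v > thresholds$UT] <- 0
    m
  }
  pmin(g(intensity_a), g(intensity_b))
}

#' Competing seeds for fuzzy-connectedness segmentation
#'
#' @param seeds data frame with columns `label` (positive integer; distinct
#'   labels compete, e.g. aorta vs renal artery vs adjacent vein), `i`, `j`,
#'   `k` (1-based voxel indices).
#' @return object of class `seed_set`.
#' @export
seed_set <- function(seeds) {
  seeds <- tibble::as_tibble(seeds)
  stopifnot(all(c("label", "i", "j", "k") %in% names(seeds)))
  if (nrow(seeds) == 0) stop("a seed_set needs at least one seed")
  if (any(seeds$label < 1)) stop("seed labels must be positive integers")
  structure(seeds, class = c("seed_set", class(seeds)))
}

#' Seeds given in world mm coordinates
#'
#' @param volume an [image_volume()].
#' @param pos data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @return a [seed_set()] at the nearest voxel centres.
#' @export
seed_set_mm <- function(volume, pos) {
  v <- round(world_to_voxel(volume, as.matrix(pos[, c("x_mm", "y_mm", "z_mm")])))
  d <- dim(volume$values)
  v[, 1] <- pmin(pmax(v[, 1], 1), d[1])
  v[, 2] <- pmin(pmax(v[, 2], 1), d[2])
  v[, 3] <- pmin(pmax(v[, 3], 1), d[3])
  seed_set(tibble::tibble(label = pos$label, i = v[, 1], j = v[, 2], k = v[, 3]))
}

#' Competing fuzzy-connectedness segmentation
#'
#' Assigns every voxel to the seed label with the greatest max-min path
#' strength: the strength of a path is the minimum [affinity()] along its
#' edges (6-connected), and a voxel's connectivity to a seed is the maximum
#' strength over all paths. Voxels whose best strength is 0 stay unlabelled.
#' Ties between labels are resolved deterministically: equal path strength
#' falls back to the smaller spacing-aware geodesic distance (mm) from the
#' seed, then to earlier queue insertion, so competition inside a uniformly
#' bright tree splits at the mm-midline between seeds.
#'
#' @param volume an [image_volume()].
#' @param seeds a [seed_set()]; every seed must lie inside the `[LT, UT]`
#'   intensity band (an error is raised if all of them are out of band; single
#'   out-of-band seeds are dropped).
#' @param thresholds a [threshold_set()].
#' @return An object of class `label_volume`: list with `labels` (integer 3-D
#'   array, 0 = unassigned), `strength` (best path strength per voxel),
#'   `spacing`, `origin`.
#' @export
fuzzy_connectedness_segment <- function(volume, seeds, thresholds) {
  stopifnot(inherits(volume, "image_volume"), inherits(seeds, "seed_set"),
            inherits(thresholds, "threshold_set"))
  d <- dim(volume$values)
  if (any(seeds$i < 1 | seeds$i > d[1] | seeds$j < 1 | seeds$j > d[2] |
          seeds$k < 1 | seeds$k > d[3]))
    stop("seed position outside the volume")
  idx0 <- (seeds$i - 1L) + (seeds$j - 1L) * d[1] + (seeds$k - 1L) * d[1] * d[2]
  ut <- if (is.na(thresholds$UT)) Inf else thresholds$UT
  res <- fc_segment_cpp(volume$values, dim(volume$values), volume$spacing,
                        as.integer(idx0), as.integer(seeds$label),
                        thresholds$LT, ut, thresholds$aorta_value)
  structure(
    list(labels = res$labels, strength = res$strength,
         spacing = volume$spacing, origin = volume$origin),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat(sprintf("<label_volume> %s voxels labelled (%d labels)\n",
              format(sum(tab)), length(tab)))
  invisible(x)
}

#' Write a label volume as NIfTI (integer codes)
#'
#' @param labels a `label_volume`.
#' @param path output path.
#' @export
write_label_volume <- function(labels, path) {
  vol <- image_volume(array(as.numeric(labels$labels), dim(labels$labels)),
                      labels$spacing, labels$origin)
  write_volume(vol, path)
}

# binary mask of one label
label_mask <- function(labels, label = NULL) {
  if (is.null(label)) labels$labels > 0 else labels$labels == label
}
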