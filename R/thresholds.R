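#' A set of circular regions of interest in the axial plane
#'
#' ROIs are discs in the axial (slice) plane, given by an in-plane world
#' centre, a slice index and a radius in mm. A ROI with `slice = NA` is a
#' "swept" placement: it is evaluated on every slice, which is how the
#' reference-slice search scans the aorta.
#'
#' @param rois data frame with columns `x_mm`, `y_mm`, `slice` (1-based index
#'   or `NA`), `radius_mm`.
#' @param target what the ROIs sample: `"aorta"`, `"psoas"` (CTA background)
#'   or `"vertebral"` (MRA background).
#' @return An object of class `roi_set` (a tibble with a `target` attribute).
#' @export
roi_set <- function(rois, target = c("aorta", "psoas", "vertebral")) {
  target <- match.arg(target)
  rois <- tibble::as_tibble(rois)
  stopifnot(all(c("x_mm", "y_mm", "slice", "radius_mm") %in% names(rois)))
  if (nrow(rois) == 0) stop("a roi_set needs at least one ROI")
  if (any(rois$radius_mm <= 0)) stop("ROI radius must be positive")
  structure(rois, target = target, class = c("roi_set", class(rois)))
}

#' Read / write ROI sets as JSON
#'
#' @param path JSON file path.
#' @param rois a [roi_set()].
#' @return `read_roi_set()` returns a [roi_set()].
#' @export
read_roi_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_set(tibble::as_tibble(obj$rois), target = obj$target)
}

#' @rdname read_roi_set
#' @export
write_roi_set <- function(rois, path) {
  jsonlite::write_json(
    list(target = attr(rois, "target"), rois = as.data.frame(rois)),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

# voxel values inside one disc ROI on one slice
roi_values <- function(volume, x_mm, y_mm, slice, radius_mm) {
  d <- dim(volume$values)
  if (slice < 1 || slice > d[3]) stop("ROI slice index outside the volume")
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  inside <- outer((xs - x_mm)^2, (ys - y_mm)^2, "+") <= radius_mm^2
  if (!any(inside)) stop("ROI lies outside the volume grid")
  volume$values[, , slice][inside]
}

# per-slice ROI statistic for a roi_set on a given slice
roi_slice_stat <- function(volume, rois, slice, stat) {
  vals <- lapply(seq_len(nrow(rois)), function(i) {
    sl <- if (is.na(rois$slice[i])) slice else rois$slice[i]
    roi_values(volume, rois$x_mm[i], rois$y_mm[i], sl, rois$radius_mm[i])
  })
  stat(unlist(vals))
}

#' Locate the aorta reference slice
#'
#' Scans the axial slices and returns the index of the slice on which the
#' aorta-ROI mean intensity is greatest (the cross-section with the strongest
#' contrast filling). Ties are broken towards the smallest slice index.
#'
#' @param volume an [image_volume()].
#' @param aorta_rois a [roi_set()] with target `"aorta"`; ROIs with
#'   `slice = NA` are evaluated on every candidate slice.
#' @return integer slice index.
#' @export
locate_reference_slice <- function(volume, aorta_rois) {
  stopifnot(inherits(aorta_rois, "roi_set"))
  if (nrow(aorta_rois) == 0) stop("empty ROI set")
  d <- dim(volume$values)
  candidates <- if (all(!is.na(aorta_rois$slice))) {
    sort(unique(aorta_rois$slice))
  } else {
    seq_len(d[3])
  }
  means <- vapply(candidates, function(sl) {
    rr <- aorta_rois[is.na(aorta_rois$slice) | aorta_rois$slice == sl, ,
                     drop = FALSE]
    roi_slice_stat(volume, rr, sl, mean)
  }, numeric(1))
  candidates[which.max(means)]  # which.max returns the first maximum
}

# shared recipe: mean of the per-slice ROI maxima at the reference slice and
# the slices 10 mm proximal / distal (offset rounded to the nearest slice,
# clamped at the volume ends with a warning)
three_slice_max_mean <- function(volume, aorta_rois, offset_mm = 10) {
  ref <- locate_reference_slice(volume, aorta_rois)
  d3 <- dim(volume$values)[3]
  off <- max(1L, as.integer(round(offset_mm / volume$spacing[3])))
  slices <- ref + c(-off, 0L, off)
  if (any(slices < 1L | slices > d3)) {
    warning("10 mm offset slice falls outside the volume; clamped to the ends")
    slices <- pmin(pmax(slices, 1L), d3)
  }
  maxima <- vapply(slices, function(sl)
    roi_slice_stat(volume, aorta_rois, sl, max), numeric(1))
  list(value = mean(maxima), slices = slices)
}

#' Contrast (aorta) intensity value
#'
#' The contrast value is the mean of three per-slice aorta-ROI maxima: at the
#' reference slice (greatest ROI mean) and at the slices 10 mm proximal and
#' distal to it.
#'
#' @inheritParams locate_reference_slice
#' @param offset_mm proximal/distal offset, default 10 mm.
#' @return scalar intensity.
#' @export
compute_contrast_value <- function(volume, aorta_rois, offset_mm = 10) {
  three_slice_max_mean(volume, aorta_rois, offset_mm)$value
}

#' Background intensity value
#'
#' Mean over ROIs of the per-ROI mean intensity, sampled in non-contrast-filled
#' tissue: 4 psoas ROIs for CTA, 3 vertebral ROIs for MRA. In strict mode the
#' ROI count is validated against the modality convention.
#'
#' @param volume an [image_volume()].
#' @param background_rois a [roi_set()] with target `"psoas"` or `"vertebral"`.
#' @param strict validate the ROI count (4 for psoas, 3 for vertebral)?
#' @return scalar intensity.
#' @export
compute_background_value <- function(volume, background_rois, strict = TRUE) {
  stopifnot(inherits(background_rois, "roi_set"))
  target <- attr(background_rois, "target")
  if (target == "aorta") stop("background ROIs must target psoas or vertebral")
  expected <- if (target == "psoas") 4L else 3L
  if (strict && nrow(background_rois) != expected)
    stop(sprintf("strict mode: %s background needs %d ROIs, got %d",
                 target, expected, nrow(background_rois)))
  per_roi <- vapply(seq_len(nrow(background_rois)), function(i) {
    r <- background_rois[i, ]
    sl <- if (is.na(r$slice)) stop("background ROIs need explicit slices") else r$slice
    mean(roi_values(volume, r$x_mm, r$y_mm, sl, r$radius_mm))
  }, numeric(1))
  mean(per_roi)
}

#' Lower segmentation threshold
#'
#' `LT = (aorta + 2 * background) / 3`: one third of the way from the
#' background value towards the contrast value. This convex combination is the
#' grey level separating contrast-filled lumen from surrounding tissue for
#' both CTA and MRA.
#'
#' @param aorta_value contrast intensity (see [compute_contrast_value()]).
#' @param background_value background intensity
#'   (see [compute_background_value()]).
#' @return scalar threshold.
#' @examples
#' compute_lower_threshold(300, 60)  # 140
#' @export
compute_lower_threshold <- function(aorta_value, background_value) {
  if (!is.finite(aorta_value) || !is.finite(background_value))
    stop("threshold inputs must be finite")
  (aorta_value + 2 * background_value) / 3
}

#' Upper segmentation threshold (CTA only)
#'
#' Mean of the per-slice aorta maxima at the reference slice and 10 mm
#' proximal/distal — the same numeric recipe as the contrast value, kept as a
#' distinct operation because the upper threshold exists only for CTA (where
#' calcified plaques exceed the attenuation of contrast-mixed blood) and the
#' two values diverge if the ROI placements differ.
#'
#' @inheritParams compute_contrast_value
#' @param modality `"CTA"` or `"MRA"`; calling in MRA mode is an error.
#' @return scalar threshold.
#' @export
compute_upper_threshold <- function(volume, aorta_rois,
                                    modality = c("CTA", "MRA"),
                                    offset_mm = 10) {
  modality <- match.arg(modality)
  if (modality == "MRA") stop("the upper threshold is undefined for MRA")
  three_slice_max_mean(volume, aorta_rois, offset_mm)$value
}

#' Segmentation threshold set
#'
#' Bundles the contrast value, background value, lower threshold and (CTA)
#' upper threshold, with provenance (the slices used).
#'
#' @param aorta_value,background_value scalar intensities.
#' @param modality `"CTA"` or `"MRA"`; MRA has no upper threshold.
#' @param UT upper threshold; computed values override the default
#'   (`NA` for MRA).
#' @param provenance optional list recorded alongside (slice indices etc.).
#' @return An object of class `threshold_set` with fields `aorta_value`,
#'   `background_value`, `LT`, `UT`, `modality`.
#' @export
threshold_set <- function(aorta_value, background_value,
                          modality = c("CTA", "MRA"), UT = NA_real_,
                          provenance = list()) {
  modality <- match.arg(modality)
  LT <- compute_lower_threshold(aorta_value, background_value)
  if (modality == "MRA") UT <- NA_real_
  if (!is.na(UT) && UT < aorta_value)
    stop("the upper threshold must be >= the contrast value")
  if (background_value < aorta_value &&
      !(background_value <= LT && LT <= aorta_value))
    stop("LT must lie between the background and contrast values")
  structure(
    list(aorta_value = aorta_value, background_value = background_value,
         LT = LT, UT = UT, modality = modality, provenance = provenance),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %s: aorta %.4g, background %.4g, LT %.4g%s\n",
              x$modality, x$aorta_value, x$background_value, x$LT,
              if (is.na(x$UT)) "" else sprintf(", UT %.4g", x$UT)))
  invisible(x)
}

#' Estimate the full threshold set from ROI statistics
#'
#' Convenience wrapper running [locate_reference_slice()],
#' [compute_contrast_value()], [compute_background_value()] and (for CTA)
#' [compute_upper_threshold()].
#'
#' @inheritParams compute_background_value
#' @param aorta_rois aorta [roi_set()].
#' @param modality `"CTA"` or `"MRA"`.
#' @return a [threshold_set()].
#' @export
estimate_thresholds <- function(volume, aorta_rois, background_rois,
                                modality = c("CTA", "MRA"), strict = TRUE) {
  modality <- match.arg(modality)
  tsm <- three_slice_max_mean(volume, aorta_rois)
  bg <- compute_background_value(volume, background_rois, strict = strict)
  ut <- if (modality == "CTA") tsm$value else NA_real_
  threshold_set(tsm$value, bg, modality = modality, UT = ut,
                provenance = list(reference_slices = tsm$slices))
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds a [threshold_set()].
#' @param path JSON file path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(obj$aorta_value, obj$background_value, modality = obj$modality,
                UT = if (is.null(obj$UT) || is.na(obj$UT)) NA_real_ else obj$UT,
                provenance = obj$provenance)
}
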