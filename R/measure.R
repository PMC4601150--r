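#' Relative diameter / area reduction
#'
#' `dred(MinD, MaxD) = (1 - MinD/MaxD) * 100` percent, and identically for
#' areas. Values are clamped to `[0, 100]` with a warning when measurement
#' noise makes the minimum exceed the maximum.
#'
#' @param min_d,max_d minimum and maximum diameter (mm); `max_d` must be > 0.
#' @param min_a,max_a minimum and maximum area (mm^2); `max_a` must be > 0.
#' @return percentage in `[0, 100]`.
#' @examples
#' dred(2.5, 5.0)  # 50
#' ared(4.9, 19.6) # 75
#' @export
dred <- function(min_d, max_d) {
  if (any(!is.finite(max_d)) || any(max_d <= 0))
    stop("`max_d` must be positive")
  out <- (1 - min_d / max_d) * 100
  if (any(out < 0 | out > 100)) {
    warning("minimum exceeds maximum; reduction clamped to [0, 100]")
    out <- pmin(pmax(out, 0), 100)
  }
  out
}

#' @rdname dred
#' @export
ared <- function(min_a, max_a) {
  if (any(!is.finite(max_a)) || any(max_a <= 0))
    stop("`max_a` must be positive")
  out <- (1 - min_a / max_a) * 100
  if (any(out < 0 | out > 100)) {
    warning("minimum exceeds maximum; reduction clamped to [0, 100]")
    out <- pmin(pmax(out, 0), 100)
  }
  out
}

#' Profile a vessel segment with perpendicular cross-sections
#'
#' Walks the segment centerline at a fixed arc-length step, resamples the
#' plane orthogonal to the local tangent at each position, segments the lumen
#' and measures area and shortest diameter. Every position is flagged
#' eligible for the maximum search unless it lies (i) less than 10 mm from
#' the aorta or (ii) within 5 mm of a bounding bifurcation; minima are always
#' searched over all positions.
#'
#' @param volume an [image_volume()].
#' @param segment a `vessel_segment` from [define_segments()].
#' @param thresholds a [threshold_set()].
#' @param step_mm arc-length sampling step (default 0.5 mm, about the finest
#'   voxel pitch of a CTA acquisition).
#' @param fov_mm cross-section field of view; default adapts to the local
#'   radius estimate.
#' @param plane_step_mm in-plane pixel pitch; default a quarter of the finest
#'   voxel spacing (fine enough that caliper widths are not pixel-limited).
#' @param curvature_scale passed to [segment_cross_section()].
#' @param aorta_clearance_mm,bifurcation_clearance_mm eligibility distances
#'   (defaults 10 mm and 5 mm).
#' @param tip_clearance_mm positions closer than this to a free (non-
#'   bifurcation, non-aortic) end of the centerline are marked invalid: the
#'   extracted centerline stops where the label ends, and planes there cut the
#'   partial end of the segmentation rather than a full lumen cross-section.
#' @return A `segment_profile`: tibble with one row per position (`arc_mm`,
#'   `dist_aorta_mm`, `x`, `y`, `z`, `diameter_mm`, `area_mm2`, `valid`,
#'   `max_eligible`) with the segment metadata as attributes. If every
#'   cross-section is empty the attribute `measurable` is `FALSE`.
#' @export
profile_segment <- function(volume, segment, thresholds, step_mm = 0.5,
                            fov_mm = NULL, plane_step_mm = NULL,
                            curvature_scale = 10,
                            aorta_clearance_mm = 10,
                            bifurcation_clearance_mm = 5,
                            tip_clearance_mm = 3) {
  stopifnot(inherits(segment, "vessel_segment"), step_mm > 0)
  if (nrow(segment) < 2) stop("a segment needs at least 2 centerline nodes")
  if (is.null(plane_step_mm)) plane_step_mm <- min(volume$spacing) / 4
  if (is.null(fov_mm)) {
    r <- segment$radius_mm
    fov_mm <- max(8, 6 * stats::median(r[is.finite(r)], na.rm = TRUE))
    if (!is.finite(fov_mm)) fov_mm <- 12
  }

  s0 <- segment$arc_mm[1]
  s1 <- segment$arc_mm[nrow(segment)]
  arcs <- seq(s0, s1, by = step_mm)
  ip <- function(col) stats::approx(segment$arc_mm, segment[[col]],
                                    xout = arcs, rule = 2)$y
  px <- ip("x"); py <- ip("y"); pz <- ip("z")
  tx <- ip("tx"); ty <- ip("ty"); tz <- ip("tz")
  da <- ip("dist_aorta_mm")
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  tx <- tx / tn; ty <- ty / tn; tz <- tz / tn

  start_bif <- attr(segment, "start_bif_mm")
  end_bif <- attr(segment, "end_bif_mm")

  res <- lapply(seq_along(arcs), function(i) {
    img <- resample_plane(volume, c(px[i], py[i], pz[i]), c(tx[i], ty[i], tz[i]),
                          fov_mm = fov_mm, step_mm = plane_step_mm)
    m <- segment_cross_section(img, thresholds, curvature_scale = curvature_scale)
    if (!any(m)) return(c(NA_real_, NA_real_))
    mm <- measure_mask(m, plane_step_mm)
    c(mm$diameter_mm, mm$area_mm2)
  })
  res <- do.call(rbind, res)

  near_bif <- rep(FALSE, length(arcs))
  if (is.finite(start_bif))
    near_bif <- near_bif | abs(arcs - start_bif) < bifurcation_clearance_mm
  if (is.finite(end_bif))
    near_bif <- near_bif | abs(arcs - end_bif) < bifurcation_clearance_mm

  # the distal end is a free tip when no bifurcation bounds the segment there
  near_tip <- if (is.na(end_bif)) {
    s1 - arcs < tip_clearance_mm
  } else rep(FALSE, length(arcs))

  out <- tibble::tibble(
    arc_mm = arcs, dist_aorta_mm = da, x = px, y = py, z = pz,
    diameter_mm = res[, 1], area_mm2 = res[, 2],
    valid = is.finite(res[, 1]) & !near_tip,
    max_eligible = is.finite(res[, 1]) & !near_tip &
      da >= aorta_clearance_mm & !near_bif
  )
  structure(out,
            segment = attr(segment, "segment"),
            artery = attr(segment, "artery"),
            start_bif_mm = start_bif, end_bif_mm = end_bif,
            step_mm = step_mm, measurable = any(out$valid),
            class = c("segment_profile", class(out)))
}

#' Summarize a segment profile into the four extremes and the reductions
#'
#' `MinD`/`MinA` are the minima over all valid positions (located
#' independently, possibly at different positions); `MaxD`/`MaxA` are the
#' maxima over eligible positions only. When the eligibility rules leave no
#' position (e.g. very short distances between branches), the maxima fall back
#' to all valid positions — the automated counterpart of reading the value
#' visually — and `fallback_used` is set. `Dred`/`Ared` follow from
#' [dred()] / [ared()].
#'
#' @param profile a `segment_profile`.
#' @return one-row tibble of class `segment_summary`: `artery`, `segment`,
#'   `min_d`, `min_a`, `max_d`, `max_a`, `dred`, `ared`, `fallback_used`,
#'   `measurable`, `n_positions`. A profile with no valid cross-section yields
#'   `measurable = FALSE` with `NA` measures (not an error).
#' @export
summarize_segment <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  val <- profile[profile$valid, ]
  if (nrow(val) == 0) {
    return(tibble::new_tibble(tibble::tibble(
      artery = attr(profile, "artery") %||% NA_integer_,
      segment = attr(profile, "segment") %||% NA_integer_,
      min_d = NA_real_, min_a = NA_real_, max_d = NA_real_, max_a = NA_real_,
      dred = NA_real_, ared = NA_real_,
      fallback_used = NA, measurable = FALSE, n_positions = 0L
    ), class = "segment_summary"))
  }
  elig <- profile[profile$max_eligible, ]
  fallback <- nrow(elig) == 0
  if (fallback) elig <- val
  min_d <- min(val$diameter_mm); min_a <- min(val$area_mm2)
  max_d <- max(elig$diameter_mm); max_a <- max(elig$area_mm2)
  tibble::new_tibble(tibble::tibble(
    artery = attr(profile, "artery") %||% NA_integer_,
    segment = attr(profile, "segment") %||% NA_integer_,
    min_d = min_d, min_a = min_a, max_d = max_d, max_a = max_a,
    dred = suppressWarnings(dred(min_d, max_d)),
    ared = suppressWarnings(ared(min_a, max_a)),
    fallback_used = fallback, measurable = TRUE, n_positions = nrow(val)
  ), class = "segment_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure every segment of an artery in one call
#'
#' Convenience wrapper: [define_segments()] on the centerline, then
#' [profile_segment()] + [summarize_segment()] per segment.
#'
#' @inheritParams profile_segment
#' @param tree a `centerline_tree`.
#' @param artery_id identifier stored in the output.
#' @param ... passed to [profile_segment()].
#' @return list with `profiles` (list of `segment_profile`) and `summary`
#'   (tibble, one row per segment).
#' @export
measure_artery <- function(volume, tree, thresholds, artery_id = 1L, ...) {
  segs <- define_segments(tree, artery_id = artery_id)
  profiles <- lapply(segs, function(s)
    profile_segment(volume, s, thresholds, ...))
  summary <- dplyr::bind_rows(lapply(profiles, summarize_segment))
  list(profiles = profiles, summary = summary)
}
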