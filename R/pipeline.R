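#' Pipeline run configuration
#'
#' Collects the fixed constants of a measurement run: the modality (which
#' decides whether an upper threshold is used), the arc-length sampling step,
#' the cross-section curvature scale, the maximum-eligibility clearances
#' (10 mm from the aorta, 5 mm from bifurcations), the summarization
#' approaches, the reader-merge mode, the AUC confidence-interval method and
#' the seed.
#'
#' @param modality `"CTA"` or `"MRA"`.
#' @param step_mm arc-length step for profiling (mm).
#' @param curvature_scale cross-section smoothing scale.
#' @param aorta_clearance_mm,bifurcation_clearance_mm eligibility distances.
#' @param approaches subset of `c("First", "Tightest", "Main")`.
#' @param merge_mode reader-merge mode (see [merge_readers()]).
#' @param ci_method AUC CI method (see [roc_auc()]).
#' @param seed integer seed for any randomness in the run.
#' @param paths named list of input/output paths (`volume`, `aorta_rois`,
#'   `background_rois`, `seeds`, `out_dir`).
#' @return object of class `run_config`.
#' @export
run_config <- function(modality = c("CTA", "MRA"), step_mm = 0.5,
                       curvature_scale = 10, aorta_clearance_mm = 10,
                       bifurcation_clearance_mm = 5,
                       approaches = c("First", "Tightest", "Main"),
                       merge_mode = "recompute", ci_method = "delong",
                       seed = 1L, paths = list()) {
  modality <- match.arg(modality)
  stopifnot(step_mm > 0, aorta_clearance_mm > 0, bifurcation_clearance_mm > 0)
  structure(list(modality = modality, step_mm = step_mm,
                 curvature_scale = curvature_scale,
                 aorta_clearance_mm = aorta_clearance_mm,
                 bifurcation_clearance_mm = bifurcation_clearance_mm,
                 approaches = approaches, merge_mode = merge_mode,
                 ci_method = ci_method, seed = as.integer(seed),
                 paths = paths),
            class = "run_config")
}

#' Validate a pipeline input bundle before any computation
#'
#' Consistency report for a volume, its ROI sets and seed points: positive
#' spacing, finite intensities, ROIs inside the grid, seed positions within
#' the physical extent (catching mm/voxel mix-ups: positions exceeding the
#' physical extent but lying within the voxel counts are flagged as likely
#' given in voxels).
#'
#' @param volume an [image_volume()].
#' @param rois list of [roi_set()]s (optional).
#' @param seeds_mm data frame with `label`, `x_mm`, `y_mm`, `z_mm` (optional).
#' @return tibble report: `check`, `item`, `ok`, `message`; an empty failure
#'   list means the bundle is consistent.
#' @export
validate_inputs <- function(volume, rois = list(), seeds_mm = NULL) {
  rep_row <- function(check, item, ok, message = "") {
    tibble::tibble(check = check, item = item, ok = ok, message = message)
  }
  out <- rep_row("spacing", "volume", all(volume$spacing > 0),
                 "voxel spacing must be positive")
  out <- dplyr::bind_rows(out, rep_row(
    "intensities", "volume", all(is.finite(volume$values)),
    "volume intensities must be finite"))
  d <- dim(volume$values)
  lo <- volume$origin
  hi <- volume$origin + volume_extent(volume)
  for (nm in names(rois)) {
    rs <- rois[[nm]]
    for (i in seq_len(nrow(rs))) {
      inside <- rs$x_mm[i] - rs$radius_mm[i] >= lo[1] - volume$spacing[1] &&
        rs$x_mm[i] + rs$radius_mm[i] <= hi[1] + volume$spacing[1] &&
        rs$y_mm[i] - rs$radius_mm[i] >= lo[2] - volume$spacing[2] &&
        rs$y_mm[i] + rs$radius_mm[i] <= hi[2] + volume$spacing[2] &&
        (is.na(rs$slice[i]) || (rs$slice[i] >= 1 && rs$slice[i] <= d[3]))
      out <- dplyr::bind_rows(out, rep_row(
        "roi-bounds", sprintf("%s[%d]", nm, i), inside,
        if (inside) "" else sprintf("ROI %d of %s extends outside the volume",
                                    i, nm)))
    }
  }
  if (!is.null(seeds_mm)) {
    for (i in seq_len(nrow(seeds_mm))) {
      p <- c(seeds_mm$x_mm[i], seeds_mm$y_mm[i], seeds_mm$z_mm[i])
      inside <- all(p >= lo) && all(p <= hi)
      looks_voxel <- !inside && all(p >= 0) && all(p <= d)
      msg <- if (inside) "" else if (looks_voxel)
        "position exceeds the physical extent but fits the voxel counts: mm/voxel mix-up?"
      else "seed position outside the volume"
      out <- dplyr::bind_rows(out, rep_row(
        "seed-bounds", sprintf("seed[%d]", i), inside, msg))
    }
  }
  out
}

#' Run the full measurement pipeline on a phantom
#'
#' Orchestrates phantom generation, ROI placement, threshold estimation,
#' competing fuzzy-connectedness segmentation (aorta seed vs artery seed),
#' centerline extraction rooted at the aorta junction, segment definition,
#' cross-section profiling and summarization, writing every intermediate
#' artifact plus a run manifest to `out_dir`. Identical config and seed give
#' identical outputs.
#'
#' @param config a [run_config()]; `config$paths$out_dir` receives the
#'   artifacts (created if missing; `NULL` skips writing).
#' @param phantom a [phantom_spec()], e.g. [demo_phantom_spec()]; its
#'   `junction_mm` attribute roots the centerline.
#' @return list: `volume`, `truth`, `thresholds`, `labels`, `tree`,
#'   `profiles`, `summary` (per-segment tibble), `manifest`.
#' @export
run_pipeline <- function(config, phantom = demo_phantom_spec(
  modality = config$modality, seed = config$seed)) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  ph <- generate_phantom(phantom)
  vol <- ph$volume

  rois <- phantom_roi_sets(phantom, vol, modality = config$modality)
  thr <- estimate_thresholds(vol, rois$aorta, rois$background,
                             modality = config$modality)

  junction <- attr(phantom, "junction_mm")
  if (is.null(junction)) stop("the phantom spec must carry a junction_mm attribute")
  aorta_center <- c(phantom$aorta$center, junction[3])
  artery_dir <- junction - aorta_center
  artery_dir <- artery_dir / sqrt(sum(artery_dir^2))
  # competing seeds: a line of seeds along the aorta axis (generous seeding of
  # the large structure, the usual practice with competing seeds) and one
  # artery seed at one aorta radius beyond the wall, so the strength-tie
  # mm-midline falls near the junction
  z_ext <- vol$origin[3] + c(0, volume_extent(vol)[3])
  z_line <- seq(z_ext[1] + 2, z_ext[2] - 2, by = 10)
  seed_pos <- dplyr::bind_rows(
    tibble::tibble(label = 1L, x_mm = phantom$aorta$center[1],
                   y_mm = phantom$aorta$center[2], z_mm = z_line),
    tibble::tibble(
      label = 2L,
      x_mm = junction[1] + 1.4 * phantom$aorta$radius_mm * artery_dir[1],
      y_mm = junction[2] + 1.4 * phantom$aorta$radius_mm * artery_dir[2],
      z_mm = junction[3] + 1.4 * phantom$aorta$radius_mm * artery_dir[3]
    )
  )
  seeds <- seed_set_mm(vol, seed_pos)
  labels <- fuzzy_connectedness_segment(vol, seeds, thr)

  tree <- extract_centerline(labels, root_hint = junction, label = 2L)
  segs <- define_segments(tree)
  profiles <- lapply(segs, function(s)
    profile_segment(vol, s, thr, step_mm = config$step_mm,
                    curvature_scale = config$curvature_scale,
                    aorta_clearance_mm = config$aorta_clearance_mm,
                    bifurcation_clearance_mm = config$bifurcation_clearance_mm))
  summary <- dplyr::bind_rows(lapply(profiles, summarize_segment))

  manifest <- list(
    package_version = as.character(utils::packageVersion("stenometry")),
    config = unclass(config)[setdiff(names(unclass(config)), "paths")],
    seed = config$seed,
    thresholds = list(LT = thr$LT, UT = thr$UT,
                      aorta = thr$aorta_value, background = thr$background_value),
    truth = as.data.frame(ph$truth),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out_dir <- config$paths$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_thresholds(thr, file.path(out_dir, "thresholds.json"))
    write_label_volume(labels, file.path(out_dir, "labels.nii.gz"))
    write_centerline(tree, file.path(out_dir, "centerline.json"))
    for (i in seq_along(profiles)) {
      utils::write.csv(tibble::as_tibble(profiles[[i]]),
                       file.path(out_dir, sprintf("profile_segment%d.csv", i)),
                       row.names = FALSE)
    }
    utils::write.csv(summary, file.path(out_dir, "segment_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }

  list(volume = vol, truth = ph$truth, thresholds = thr, labels = labels,
       tree = tree, profiles = profiles, summary = summary,
       manifest = manifest)
}
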