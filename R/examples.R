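#' Bundled worked-example cohort records
#'
#' A synthetic per-kidney record table for a 47-patient (94-kidney) referral
#' cohort, constructed so the three cohort filters have visible work to do:
#' one patient lacks a modality, twelve kidneys carry a positive functional
#' reference (one of them non-measurable on MRA), and eleven further kidneys
#' are non-measurable. Running [filter_cohort()] on it yields a 68-kidney
#' analysis set with 11 positives (16.2 %) and 57 negatives (83.8 %) — the
#' accounting structure typical of a renal-artery referral cohort.
#'
#' @return per-kidney tibble suitable for [filter_cohort()].
#' @export
example_cohort_records <- function() {
  n_patients <- 47L
  rec <- tidyr::expand_grid(patient = seq_len(n_patients),
                            side = c("L", "R")) |>
    dplyr::mutate(kidney = dplyr::row_number(),
                  has_cta = TRUE, has_mra = TRUE, has_ref = TRUE,
                  measurable_cta = TRUE, measurable_mra = TRUE,
                  cer = "negative", ctest = NA_character_)
  # patient 47: CTA incomplete -> whole patient excluded
  rec$has_cta[rec$patient == 47L] <- FALSE
  # positive functional reference: left kidneys of patients 1-12;
  # two of them intermediate on renography, resolved positive by the
  # captopril test
  pos <- rec$side == "L" & rec$patient <= 12L
  rec$cer[pos] <- "positive"
  inter_pos <- rec$side == "L" & rec$patient %in% c(3L, 7L)
  rec$cer[inter_pos] <- "intermediate"
  rec$ctest[inter_pos] <- "positive"
  # four further intermediates resolved negative
  inter_neg <- rec$side == "R" & rec$patient %in% c(20L, 25L, 30L, 35L)
  rec$cer[inter_neg] <- "intermediate"
  rec$ctest[inter_neg] <- "negative"
  # non-measurable vessels: the positive left kidney of patient 1 (MRA) and
  # eleven negative kidneys in patients without positives
  rec$measurable_mra[rec$patient == 1L & rec$side == "L"] <- FALSE
  nm <- rec$side == "L" & rec$patient %in% 13:23
  rec$measurable_cta[nm & rec$patient <= 18L] <- FALSE
  rec$measurable_mra[nm & rec$patient >= 19L] <- FALSE
  rec
}

#' Bundled worked-example measurability table
#'
#' Long per-segment reader-measurability flags for a two-modality study with
#' 104 measurable first segments and 99 second segments on CTA (96 and 72 of
#' them measurable by both readers) and 92 / 68 on MRA (83 / 46 by both) —
#' the counts [measurability_stats()] turns into both-reader percentages
#' (92, 73, 90 and 68 %).
#'
#' @return tibble with columns `unit`, `modality`, `segment`, `reader`,
#'   `measurable`.
#' @export
example_measurability_counts <- function() {
  blocks <- tibble::tribble(
    ~modality, ~segment, ~n_any, ~n_both,
    "CTA", 1L, 104L, 96L,
    "CTA", 2L, 99L, 72L,
    "MRA", 1L, 92L, 83L,
    "MRA", 2L, 68L, 46L
  )
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    tidyr::expand_grid(unit = seq_len(b$n_any), reader = 1:2) |>
      dplyr::mutate(modality = b$modality, segment = b$segment,
                    measurable = unit <= b$n_both | reader == 1L)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(unit = paste(modality, segment, unit, sep = "_")) |>
    dplyr::select(unit, modality, segment, reader, measurable)
}

#' Demonstration phantom: a stenosed renal artery off an aorta
#'
#' A CTA-like (default) or MRA-like phantom with one renal artery leaving an
#' aorta-like cylinder, carrying a single focal stenosis of chosen depth at
#' 20 mm from the aorta. Used throughout the examples, tests and the
#' acceptance analysis.
#'
#' @param depth fractional diameter reduction of the stenosis (0-1).
#' @param modality `"CTA"` (0.5 x 0.5 x 0.75 mm voxels) or `"MRA"`
#'   (0.7 x 0.7 x 2.0 mm).
#' @param radius_mm baseline artery radius.
#' @param length_mm artery length from the aorta surface.
#' @param noise_sd additive noise SD.
#' @param seed noise seed.
#' @return a [phantom_spec()].
#' @export
demo_phantom_spec <- function(depth = 0.5, modality = c("CTA", "MRA"),
                              radius_mm = 2.5, length_mm = 45,
                              noise_sd = 0, seed = 1L) {
  modality <- match.arg(modality)
  sp <- if (modality == "CTA") c(0.5, 0.5, 0.75) else c(0.7, 0.7, 2.0)
  aorta_r <- 9
  # artery leaves the aorta wall at the origin along +x, at mid-stack height
  z_extent <- if (modality == "CTA") 45 else 48
  nz <- round(z_extent / sp[3]) + 1
  z_mid <- (nz - 1) / 2 * sp[3]
  x0 <- aorta_r  # aorta axis at x = 0, wall at x = aorta_r
  # the artery lies in an axial-slice plane (as renal arteries do in a
  # coronally planned stack) with a sub-voxel in-plane offset and a gentle
  # in-plane tilt, so the tube surface never aligns with the voxel grid; the
  # tube radius stays exact because truth is analytic
  y0 <- 0.17
  path <- rbind(c(x0 - 1, y0, z_mid),
                c(x0 + length_mm / 2, y0 + 1.5, z_mid),
                c(x0 + length_mm, y0 + 3, z_mid))
  sten <- data.frame(center_mm = 21, depth = depth, width_mm = 8)
  if (depth == 0) sten <- sten[0, ]
  art <- artery_spec(path, radius_mm = radius_mm, stenoses = sten)
  nx <- round((aorta_r + length_mm + 8 + aorta_r + 3) / sp[1]) + 1
  ny <- round(30 / sp[2]) + 1
  spec <- phantom_spec(
    grid_shape = c(nx, ny, nz), voxel_spacing = sp,
    aorta = list(center = c(0, 0), radius_mm = aorta_r, intensity = 300),
    arteries = list(art), background_intensity = 50,
    noise_sd = noise_sd, seed = seed
  )
  attr(spec, "origin") <- c(-aorta_r - 2, -15, 0)
  # where the (tilted) path crosses the aorta wall at x = aorta_r
  attr(spec, "junction_mm") <- c(x0, y0 + 3 / (length_mm + 1), z_mid)
  spec
}
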