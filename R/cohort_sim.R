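#' Specify a synthetic reader-study cohort
#'
#' Describes a simulated study in which every kidney's renal arteries are
#' measured by two blinded readers on two modalities (CTA and MRA), and a
#' binary functional reference (renography plus captopril test) is generated
#' from the true stenosis severity through a saturating probability model.
#' Defaults mirror a realistic referral cohort: two kidneys per patient, about
#' one kidney in six with an accessory artery, segment-level true diameter
#' reductions spread widely over 0-100 %, and a reference that turns positive
#' around a 60 % diameter reduction.
#'
#' @param n_kidneys number of kidneys (2 per patient); must be > 0.
#' @param p_accessory probability a kidney has a second (accessory) artery.
#' @param severity function `n -> n` true diameter reductions (percent) per
#'   segment; default `100 * rbeta(n, 1.5, 1.5)` (mean 50, SD 26).
#' @param baseline_d_mm mean and SD of the healthy (maximum) lumen diameter.
#' @param reader_noise_sd additive reader noise SD: `d` on diameters (mm),
#'   `a` on areas (mm^2). Used when `dred_noise_sd` is `NULL`.
#' @param dred_noise_sd when set, reader and modality noise act directly on
#'   the Dred percentage (Gaussian, unclamped) and the absolute measures are
#'   derived from the noisy percentage — the parametrization used to study
#'   agreement statistics with known variance components.
#' @param modality_bias named vector (CTA, MRA): systematic offset of each
#'   modality, on the same scale as the active noise model.
#' @param modality_noise_sd modality-specific noise SD (same scale).
#' @param ref_midpoint,ref_slope the probability of a positive reference is
#'   `plogis((true_dred - ref_midpoint) / ref_slope)` evaluated at the
#'   kidney's worst segment.
#' @param f_intermediate fraction of kidneys whose renography alone is
#'   intermediate and needs the captopril test to resolve.
#' @param p_reader_miss per-reader probability a segment is judged
#'   non-measurable, by modality and segment (`cta1`, `cta2`, `mra1`, `mra2`).
#' @param p_no_seg2 probability an artery has no measurable second segment at
#'   all (no second bifurcation).
#' @param seed integer seed; identical specs with identical seeds generate
#'   identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_kidneys = 94,
                        p_accessory = 0.17,
                        severity = function(n) 100 * stats::rbeta(n, 1.5, 1.5),
                        baseline_d_mm = c(mean = 5.5, sd = 0.7),
                        reader_noise_sd = c(d = 0.35, a = 2.0),
                        dred_noise_sd = NULL,
                        modality_bias = c(CTA = 0, MRA = 0),
                        modality_noise_sd = c(CTA = 0, MRA = 0),
                        ref_midpoint = 60, ref_slope = 8,
                        f_intermediate = 0.07,
                        p_reader_miss = c(cta1 = 0.04, cta2 = 0.15,
                                          mra1 = 0.05, mra2 = 0.25),
                        p_no_seg2 = 0.1,
                        seed = 1L) {
  if (n_kidneys <= 0) stop("`n_kidneys` must be positive")
  stopifnot(p_accessory >= 0, p_accessory <= 1,
            f_intermediate >= 0, f_intermediate <= 1,
            all(p_reader_miss >= 0), all(p_reader_miss <= 1),
            all(reader_noise_sd >= 0), all(modality_noise_sd >= 0),
            ref_slope > 0)
  structure(
    list(n_kidneys = as.integer(n_kidneys), p_accessory = p_accessory,
         severity = severity, baseline_d_mm = baseline_d_mm,
         reader_noise_sd = reader_noise_sd, dred_noise_sd = dred_noise_sd,
         modality_bias = modality_bias, modality_noise_sd = modality_noise_sd,
         ref_midpoint = ref_midpoint, ref_slope = ref_slope,
         f_intermediate = f_intermediate, p_reader_miss = p_reader_miss,
         p_no_seg2 = p_no_seg2, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic two-reader / two-modality measurement cohort
#'
#' One row per kidney x artery x segment x modality x reader. Absolute
#' measures are derived from the true geometry (circular lumen: area =
#' pi (d/2)^2) with additive noise per the active noise model; the reference
#' is a latent significance draw from the severity model, reported directly
#' by renography except in the intermediate fraction, where the captopril
#' test reports it instead.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `patient`, `side`, `kidney`, `artery`,
#'   `segment`, `modality`, `reader`, `measurable`, `min_d`, `min_a`,
#'   `max_d`, `max_a`, `dred`, `ared`, `true_dred`, `cer`, `ctest`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    nk <- spec$n_kidneys
    kidneys <- tibble::tibble(
      kidney = seq_len(nk),
      patient = (kidney + 1L) %/% 2L,
      side = ifelse(kidney %% 2L == 1L, "L", "R"),
      n_arteries = 1L + stats::rbinom(nk, 1L, spec$p_accessory)
    )

    arteries <- kidneys |>
      dplyr::rowwise() |>
      dplyr::reframe(kidney = kidney, patient = patient, side = side,
                     artery = seq_len(n_arteries)) |>
      dplyr::mutate(
        accessory = artery > 1L,
        base_d = pmax(2, stats::rnorm(dplyr::n(),
                                      spec$baseline_d_mm["mean"] -
                                        2 * accessory,
                                      spec$baseline_d_mm["sd"])),
        has_seg2 = stats::runif(dplyr::n()) > spec$p_no_seg2
      )

    segments <- arteries |>
      dplyr::rowwise() |>
      dplyr::reframe(kidney = kidney, patient = patient, side = side,
                     artery = artery, base_d = base_d,
                     segment = seq_len(1L + has_seg2)) |>
      dplyr::mutate(true_dred = spec$severity(dplyr::n()))

    # latent hemodynamic significance per kidney, from the worst segment
    ref <- segments |>
      dplyr::group_by(kidney) |>
      dplyr::summarise(worst = max(true_dred), .groups = "drop") |>
      dplyr::mutate(
        p_pos = stats::plogis((worst - spec$ref_midpoint) / spec$ref_slope),
        latent = stats::rbinom(dplyr::n(), 1L, p_pos) == 1L,
        intermediate = stats::runif(dplyr::n()) < spec$f_intermediate,
        cer = dplyr::case_when(intermediate ~ "intermediate",
                               latent ~ "positive",
                               TRUE ~ "negative"),
        ctest = dplyr::if_else(intermediate,
                               dplyr::if_else(latent, "positive", "negative"),
                               NA_character_)
      )

    grid <- tidyr::expand_grid(segments, modality = c("CTA", "MRA"),
                               reader = 1:2)
    miss_key <- paste0(tolower(grid$modality), grid$segment)
    p_miss <- unname(spec$p_reader_miss[miss_key])
    grid$measurable <- stats::runif(nrow(grid)) >= p_miss

    n <- nrow(grid)
    if (is.null(spec$dred_noise_sd)) {
      true_min_d <- grid$base_d * (1 - grid$true_dred / 100)
      noise <- function(sd) stats::rnorm(n, 0, sd)
      bias_d <- unname(spec$modality_bias[grid$modality])
      mod_sd <- unname(spec$modality_noise_sd[grid$modality])
      grid$min_d <- pmax(0, true_min_d + bias_d + noise(mod_sd) +
                           noise(spec$reader_noise_sd["d"]))
      grid$max_d <- pmax(0.5, grid$base_d + bias_d + noise(mod_sd) +
                           noise(spec$reader_noise_sd["d"]))
      true_min_a <- pi * (true_min_d / 2)^2
      true_max_a <- pi * (grid$base_d / 2)^2
      grid$min_a <- pmax(0, true_min_a + noise(spec$reader_noise_sd["a"]))
      grid$max_a <- pmax(0.2, true_max_a + noise(spec$reader_noise_sd["a"]))
      grid$dred <- pmin(pmax((1 - grid$min_d / grid$max_d) * 100, 0), 100)
      grid$ared <- pmin(pmax((1 - grid$min_a / grid$max_a) * 100, 0), 100)
    } else {
      # direct Dred-scale noise with known variance components (unclamped)
      bias <- unname(spec$modality_bias[grid$modality])
      mod_sd <- unname(spec$modality_noise_sd[grid$modality])
      grid$dred <- grid$true_dred + bias + stats::rnorm(n, 0, mod_sd) +
        stats::rnorm(n, 0, spec$dred_noise_sd)
      grid$ared <- 100 * (1 - (1 - grid$dred / 100)^2)
      grid$max_d <- grid$base_d
      grid$min_d <- grid$base_d * (1 - grid$dred / 100)
      grid$max_a <- pi * (grid$base_d / 2)^2
      grid$min_a <- pi * (pmax(grid$min_d, 0) / 2)^2
    }

    grid |>
      dplyr::left_join(ref[, c("kidney", "cer", "ctest")], by = "kidney") |>
      dplyr::select(patient, kidney, side, artery, segment, modality, reader,
                    measurable, min_d, min_a, max_d, max_a, dred, ared,
                    true_dred, cer, ctest) |>
      dplyr::arrange(kidney, artery, segment, modality, reader)
  })
}
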