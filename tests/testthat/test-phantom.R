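test_that("analytic truth matches circular geometry for a straight stenosed tube", {
  art <- artery_spec(rbind(c(0, 0, 0), c(40, 0, 0)), radius_mm = 2.5,
                     stenoses = data.frame(center_mm = 20, depth = 0.5,
                                           width_mm = 8))
  tr <- stenometry:::artery_truth(art, 1L)
  expect_equal(tr$min_d, 2.5, tolerance = 1e-6)
  expect_equal(tr$max_d, 5.0)
  expect_equal(tr$dred, 50, tolerance = 1e-4)
  expect_equal(tr$ared, 75, tolerance = 1e-4)
  # circular cross-sections: Ared = 100 (1 - (1 - Dred/100)^2) exactly
  expect_equal(tr$ared, 100 * (1 - (1 - tr$dred / 100)^2), tolerance = 1e-10)
  expect_equal(tr$min_a, pi * (tr$min_d / 2)^2)

  # identity case: no stenosis
  art0 <- artery_spec(rbind(c(0, 0, 0), c(40, 0, 0)), radius_mm = 2.5)
  tr0 <- stenometry:::artery_truth(art0, 1L)
  expect_equal(tr0$dred, 0)
  expect_equal(tr0$min_d, tr0$max_d)
})

test_that("invalid phantom specifications are rejected with messages", {
  art_bad <- artery_spec(rbind(c(0, 0, 0), c(10, 0, 0)), radius_mm = 2,
                         stenoses = data.frame(center_mm = 50, depth = 0.5,
                                               width_mm = 4))
  spec <- phantom_spec(c(16, 16, 8), c(1, 1, 1),
                       aorta = list(center = c(0, 0), radius_mm = 3,
                                    intensity = 300),
                       arteries = list(art_bad))
  expect_error(generate_phantom(spec), "outside the artery path length")
  expect_error(artery_spec(rbind(c(0, 0, 0), c(10, 0, 0)), radius_mm = 2,
                           stenoses = data.frame(center_mm = 5, depth = 1.2,
                                                 width_mm = 4)),
               "depth")
  expect_error(phantom_spec(c(16, 16, 8), c(1, -1, 1),
                            aorta = list(center = c(0, 0), radius_mm = 3,
                                         intensity = 300),
                            arteries = list()),
               "positive")
  # plaque must be brighter than lumen
  expect_error(phantom_spec(c(16, 16, 8), c(1, 1, 1),
                            aorta = list(center = c(0, 0), radius_mm = 3,
                                         intensity = 300),
                            arteries = list(),
                            plaques = data.frame(x_mm = 0, y_mm = 0, z_mm = 0,
                                                 radius_mm = 1, intensity = 200)),
               "plaque")
})

test_that("identical spec and seed reproduce bit-identical noisy volumes", {
  spec <- tiny_phantom_spec(noise_sd = 10, seed = 42)
  v1 <- generate_phantom(spec)$volume
  v2 <- generate_phantom(spec)$volume
  expect_identical(v1$values, v2$values)
  v3 <- generate_phantom(tiny_phantom_spec(noise_sd = 10, seed = 43))$volume
  expect_false(identical(v1$values, v3$values))
})

test_that("voxelized lumen volume converges to the analytic tube volume", {
  tube_vol <- function(sp) {
    art <- artery_spec(rbind(c(-14, 0.21, 0.13), c(14, 0.21, 0.13)),
                       radius_mm = 2.3)
    d <- round(c(32, 12, 12) / sp) + 1
    spec <- phantom_spec(d, rep(sp, 3),
                         aorta = list(center = c(-40, 0), radius_mm = 1,
                                      intensity = 300),
                         arteries = list(art), background_intensity = 0)
    attr(spec, "origin") <- c(-16, -6, -6)
    ph <- generate_phantom(spec)
    # partial-volume values are lumen fractions scaled to [bg, lumen]
    frac <- ph$volume$values / 300
    sum(frac) * prod(ph$volume$spacing)
  }
  # swept-sphere tube = cylinder plus two hemispherical end caps
  analytic <- pi * 2.3^2 * 28 + 4 / 3 * pi * 2.3^3
  err <- vapply(c(1.0, 0.5), function(sp) abs(tube_vol(sp) - analytic),
                numeric(1))
  expect_lt(err[2], err[1])                 # finer grid, smaller error
  expect_lt(err[2] / analytic, 0.02)
})

test_that("cohort generator honours its zero-noise and saturating-link contracts", {
  # zero reader noise: the two readers agree exactly
  co <- generate_cohort(cohort_spec(n_kidneys = 12,
                                    reader_noise_sd = c(d = 0, a = 0),
                                    seed = 5))
  w <- tidyr::pivot_wider(co[, c("kidney", "artery", "segment", "modality",
                                 "reader", "min_d", "max_a")],
                          names_from = reader, values_from = c(min_d, max_a))
  expect_equal(w$min_d_1, w$min_d_2)
  expect_equal(w$max_a_1, w$max_a_2)

  # steep reference link: severities far from the midpoint get deterministic labels
  spec <- cohort_spec(n_kidneys = 60, p_accessory = 0, p_no_seg2 = 1,
                      severity = function(n) sample(c(10, 90), n, replace = TRUE),
                      ref_midpoint = 50, ref_slope = 0.1,
                      f_intermediate = 0, seed = 9)
  co2 <- generate_cohort(spec)
  per_kid <- dplyr::distinct(co2[, c("kidney", "true_dred", "cer")])
  expect_true(all(per_kid$cer[per_kid$true_dred == 90] == "positive"))
  expect_true(all(per_kid$cer[per_kid$true_dred == 10] == "negative"))

  expect_error(cohort_spec(n_kidneys = 0), "positive")
})

test_that("cohort positive fraction matches the severity model within 3 SE", {
  spec <- cohort_spec(n_kidneys = 1000, p_accessory = 0, p_no_seg2 = 1,
                      severity = function(n) 100 * stats::rbeta(n, 1.5, 1.5),
                      ref_midpoint = 60, ref_slope = 8,
                      f_intermediate = 0.07, seed = 21)
  co <- generate_cohort(spec)
  per_kid <- dplyr::distinct(co[, c("kidney", "true_dred", "cer", "ctest")])
  labels <- resolve_reference(per_kid$cer, per_kid$ctest)
  p_hat <- mean(labels == "positive")
  p_model <- mean(stats::plogis((per_kid$true_dred - 60) / 8))
  se <- sqrt(p_model * (1 - p_model) / nrow(per_kid))
  expect_lt(abs(p_hat - p_model), 3 * se)
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  spec <- tiny_phantom_spec(modality = "MRA")
  vol <- cached("mra_tiny_vol", generate_phantom(spec))$volume
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(array(back$values, dim(vol$values)), vol$values,
               tolerance = 1e-6, ignore_attr = TRUE)
  unlink(path)
})
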