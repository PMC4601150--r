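seg_row <- function(min_d, max_d = 5, min_a = pi * (min_d / 2)^2,
                    max_a = pi * (max_d / 2)^2) {
  tibble::tibble(min_d = min_d, min_a = min_a, max_d = max_d, max_a = max_a,
                 dred = (1 - min_d / max_d) * 100,
                 ared = (1 - min_a / max_a) * 100)
}

test_that("reader merging averages absolute measures and passes single readers through", {
  r1 <- seg_row(2); r2 <- seg_row(3)
  m <- merge_readers(r1, r2)
  expect_equal(m$min_d, 2.5)
  expect_equal(m$max_d, 5)
  expect_equal(m$dred, dred(2.5, 5))        # recomputed from the averages
  expect_equal(m$n_readers, 2L)
  # single-reader rule
  expect_equal(merge_readers(r1, NULL)$min_d, 2)
  expect_equal(merge_readers(NULL, r2)$min_d, 3)
  # idempotence and symmetry
  expect_equal(merge_readers(r1, r1)$dred, r1$dred)
  expect_equal(merge_readers(r1, r2)$dred, merge_readers(r2, r1)$dred)
  # both absent: non-measurable, no exception
  none <- merge_readers(NULL, NULL)
  expect_false(none$measurable)
  # percentage-averaging alternative
  mp <- merge_readers(r1, r2, mode = "average_pct")
  expect_equal(mp$dred, (r1$dred + r2$dred) / 2)
})

test_that("the three approaches pick their candidates as defined", {
  # one artery, one segment: every approach returns it
  k1 <- dplyr::bind_cols(tibble::tibble(artery = 1L, segment = 1L,
                                        measurable = TRUE), seg_row(2))
  for (ap in c("First", "Tightest", "Main"))
    expect_equal(summarize_kidney(k1, ap)$dred, k1$dred)

  # accessory artery with a tighter first-segment stenosis than the main artery
  kid <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(artery = 1L, segment = 1L, measurable = TRUE),
                     seg_row(3.0, 5.0)),   # main artery, Dred 40
    dplyr::bind_cols(tibble::tibble(artery = 1L, segment = 2L, measurable = TRUE),
                     seg_row(3.5, 5.0)),   # Dred 30
    dplyr::bind_cols(tibble::tibble(artery = 2L, segment = 1L, measurable = TRUE),
                     seg_row(0.6, 3.0))    # accessory, Dred 80
  )
  expect_equal(summarize_kidney(kid, "Tightest")$dred, 80)
  expect_equal(summarize_kidney(kid, "Main")$dred, 40)      # larger MaxD artery
  expect_equal(summarize_kidney(kid, "First")$dred, 80)     # first segments incl. accessory
  expect_equal(summarize_kidney(kid, "Main")$artery, 1L)

  # empty candidate set: non-measurable
  kid_nm <- kid; kid_nm$measurable <- FALSE
  expect_false(summarize_kidney(kid_nm, "First")$measurable)
})

test_that("Tightest dominates First and Main across a simulated cohort", {
  co <- generate_cohort(cohort_spec(n_kidneys = 100, seed = 17))
  kr <- kidney_results(co)
  w <- tidyr::pivot_wider(kr[, c("kidney", "modality", "approach", "dred")],
                          names_from = approach, values_from = dred)
  expect_true(all(w$Tightest >= w$First - 1e-9, na.rm = TRUE))
  expect_true(all(w$Tightest >= w$Main - 1e-9, na.rm = TRUE))
})

test_that("the functional reference resolves via the captopril test only when intermediate", {
  expect_equal(resolve_reference("positive", NA), "positive")
  expect_equal(resolve_reference("negative", NA), "negative")
  expect_equal(resolve_reference("intermediate", "positive"), "positive")
  expect_equal(resolve_reference("intermediate", "negative"), "negative")
  expect_equal(resolve_reference(c("positive", "intermediate"),
                                 c(NA, "negative")),
               c("positive", "negative"))
  expect_error(resolve_reference("intermediate", NA), "captopril")
  expect_error(resolve_reference("maybe", NA), "invalid")
})

test_that("cohort filtering applies its three rules on a toy cohort", {
  toy <- tibble::tibble(
    patient = c(1, 1, 2, 2, 3, 3),
    side = rep(c("L", "R"), 3),
    kidney = 1:6,
    has_cta = TRUE, has_mra = TRUE, has_ref = TRUE,
    measurable_cta = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    measurable_mra = TRUE,
    cer = c("negative", "negative", "positive", "negative",
            "positive", "negative"),
    ctest = NA_character_
  )
  fc <- filter_cohort(toy)
  # patient 1 keeps both (negative); patient 2 keeps the positive left only;
  # patient 3 loses the non-measurable positive AND its contralateral
  expect_setequal(fc$analysis$kidney, c(1, 2, 3))
  expect_equal(sum(fc$analysis$label == "positive"), 1)
  expect_equal(sum(fc$analysis$label == "negative"), 2)

  # nothing to drop: filter is the identity, and idempotent
  all_neg <- toy
  all_neg$cer <- "negative"; all_neg$measurable_cta <- TRUE
  fc2 <- filter_cohort(all_neg)
  expect_equal(nrow(fc2$analysis), 6)
  fc3 <- filter_cohort(fc2$analysis)
  expect_equal(nrow(fc3$analysis), nrow(fc2$analysis))
})

test_that("the bundled worked example reproduces the printed cohort percentages", {
  fc <- filter_cohort(example_cohort_records())
  n <- nrow(fc$analysis)
  pos <- sum(fc$analysis$label == "positive")
  expect_equal(n, 68)
  expect_equal(pos, 11)
  expect_equal(round(100 * pos / n, 1), 16.2)
  expect_equal(round(100 * (n - pos) / n, 1), 83.8)
  # filtering the analysis set again removes nothing
  again <- filter_cohort(fc$analysis)
  expect_equal(nrow(again$analysis), 68)
})

test_that("measurability statistics compute both-reader percentages per modality and segment", {
  ms <- measurability_stats(example_measurability_counts())
  get <- function(mod, seg, col)
    ms[[col]][ms$modality == mod & ms$segment == seg]
  expect_equal(get("CTA", 1, "n_any"), 104)
  expect_equal(get("CTA", 1, "n_both"), 96)
  expect_equal(get("CTA", 1, "pct_both"), 92)
  expect_equal(get("CTA", 2, "pct_both"), 73)
  expect_equal(get("MRA", 1, "pct_both"), 90)
  # empty group: percentage reported missing
  empty <- tibble::tibble(unit = "a", modality = "CTA", segment = 1L,
                          reader = 1:2, measurable = FALSE)
  ms0 <- measurability_stats(empty)
  expect_true(is.na(ms0$pct_both))
})
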