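#' Merge the two readers' measurements of one segment
#'
#' The morphological measures are the element-wise mean of the two readers'
#' four absolute measures, with the relative reductions recomputed from the
#' averaged `MinD`/`MaxD` and `MinA`/`MaxA` so the merged record stays
#' internally consistent (set `mode = "average_pct"` to average the readers'
#' percentages instead, for sensitivity checks). When only one reader judged
#' the segment measurable, that reader's measurements pass through unchanged.
#'
#' @param r1,r2 one-row data frames with columns `min_d`, `min_a`, `max_d`,
#'   `max_a` (and optionally `dred`, `ared`), or `NULL` when that reader did
#'   not measure the segment.
#' @param mode `"recompute"` (default) or `"average_pct"`.
#' @return one-row tibble with the merged measures and `n_readers`; `NULL`
#'   input on both sides yields a non-measurable row (`measurable = FALSE`).
#' @export
merge_readers <- function(r1, r2, mode = c("recompute", "average_pct")) {
  mode <- match.arg(mode)
  present <- function(r) !is.null(r) && nrow(r) == 1 && is.finite(r$min_d)
  p1 <- present(r1); p2 <- present(r2)
  if (!p1 && !p2) {
    return(tibble::tibble(min_d = NA_real_, min_a = NA_real_,
                          max_d = NA_real_, max_a = NA_real_,
                          dred = NA_real_, ared = NA_real_,
                          n_readers = 0L, measurable = FALSE))
  }
  if (p1 && p2) {
    out <- tibble::tibble(
      min_d = (r1$min_d + r2$min_d) / 2, min_a = (r1$min_a + r2$min_a) / 2,
      max_d = (r1$max_d + r2$max_d) / 2, max_a = (r1$max_a + r2$max_a) / 2,
      n_readers = 2L, measurable = TRUE
    )
    if (mode == "average_pct") {
      out$dred <- (r1$dred + r2$dred) / 2
      out$ared <- (r1$ared + r2$ared) / 2
    } else {
      out$dred <- suppressWarnings(dred(out$min_d, out$max_d))
      out$ared <- suppressWarnings(ared(out$min_a, out$max_a))
    }
    return(out[, c("min_d", "min_a", "max_d", "max_a", "dred", "ared",
                   "n_readers", "measurable")])
  }
  r <- if (p1) r1 else r2
  dd <- if ("dred" %in% names(r)) r$dred else suppressWarnings(dred(r$min_d, r$max_d))
  aa <- if ("ared" %in% names(r)) r$ared else suppressWarnings(ared(r$min_a, r$max_a))
  tibble::tibble(min_d = r$min_d, min_a = r$min_a, max_d = r$max_d,
                 max_a = r$max_a, dred = dd, ared = aa,
                 n_readers = 1L, measurable = TRUE)
}

#' Merge readers across a whole cohort table
#'
#' Tidy verb applying the [merge_readers()] rule per
#' kidney x artery x segment x modality group of a long cohort table (as
#' produced by [generate_cohort()]).
#'
#' @param cohort long cohort tibble with a `reader` column and `measurable`
#'   flags.
#' @param mode passed to [merge_readers()].
#' @return tibble with one row per kidney x artery x segment x modality.
#' @export
merge_cohort_readers <- function(cohort, mode = c("recompute", "average_pct")) {
  mode <- match.arg(mode)
  keys <- intersect(c("patient", "kidney", "side", "artery", "segment",
                      "modality", "true_dred", "cer", "ctest"), names(cohort))
  merged <- cohort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_readers = sum(measurable & is.finite(min_d)),
      dred_avg = mean(dred[measurable & is.finite(min_d)]),
      ared_avg = mean(ared[measurable & is.finite(min_d)]),
      dplyr::across(c(min_d, min_a, max_d, max_a),
                    ~ mean(.x[measurable & is.finite(min_d)])),
      .groups = "drop"
    ) |>
    dplyr::mutate(measurable = n_readers > 0L)
  if (mode == "average_pct") {
    merged$dred <- merged$dred_avg
    merged$ared <- merged$ared_avg
  } else {
    merged$dred <- ifelse(merged$max_d > 0,
                          pmin(pmax((1 - merged$min_d / merged$max_d) * 100, 0), 100),
                          NA_real_)
    merged$ared <- ifelse(merged$max_a > 0,
                          pmin(pmax((1 - merged$min_a / merged$max_a) * 100, 0), 100),
                          NA_real_)
  }
  merged$dred_avg <- merged$ared_avg <- NULL
  merged
}

#' Summarize one kidney under a measurement approach
#'
#' The candidate segments are: all first segments of the kidney's arteries
#' (`"First"`), all segments (`"Tightest"`), or both segments of the main
#' artery — the artery with the largest maximum diameter (`"Main"`). The
#' chosen segment is the candidate with the largest `Dred`; ties go to the
#' larger `Ared`, then to segment 1 before segment 2.
#'
#' @param kidney_df merged per-segment tibble for one kidney and one modality
#'   (columns `artery`, `segment`, `min_d`, `min_a`, `max_d`, `max_a`,
#'   `dred`, `ared`, `measurable`).
#' @param approach `"First"`, `"Tightest"` or `"Main"`.
#' @return one-row tibble (`approach`, `artery`, `segment`, `min_d`, `min_a`,
#'   `dred`, `ared`, `measurable`); an empty candidate set yields a
#'   non-measurable row.
#' @export
summarize_kidney <- function(kidney_df, approach = c("First", "Tightest", "Main")) {
  approach <- match.arg(approach)
  meas <- kidney_df[kidney_df$measurable & is.finite(kidney_df$dred), ,
                    drop = FALSE]
  cand <- switch(approach,
    First = meas[meas$segment == 1L, , drop = FALSE],
    Tightest = meas,
    Main = {
      if (nrow(meas) == 0) meas else {
        per_art <- meas |>
          dplyr::group_by(artery) |>
          dplyr::summarise(big_d = max(max_d), n_meas = dplyr::n(),
                           .groups = "drop") |>
          dplyr::arrange(dplyr::desc(big_d), dplyr::desc(n_meas), artery)
        meas[meas$artery == per_art$artery[1], , drop = FALSE]
      }
    }
  )
  if (nrow(cand) == 0) {
    return(tibble::tibble(approach = approach, artery = NA_integer_,
                          segment = NA_integer_, min_d = NA_real_,
                          min_a = NA_real_, dred = NA_real_, ared = NA_real_,
                          measurable = FALSE))
  }
  cand <- cand |>
    dplyr::arrange(dplyr::desc(dred), dplyr::desc(ared), segment)
  tibble::tibble(approach = approach, artery = cand$artery[1],
                 segment = cand$segment[1], min_d = cand$min_d[1],
                 min_a = cand$min_a[1], dred = cand$dred[1],
                 ared = cand$ared[1], measurable = TRUE)
}

#' Per-kidney results for a whole cohort under one or more approaches
#'
#' Merges readers ([merge_cohort_readers()]) and applies
#' [summarize_kidney()] per kidney x modality x approach.
#'
#' @param cohort long cohort tibble (see [generate_cohort()]).
#' @param approaches character subset of `c("First", "Tightest", "Main")`.
#' @param mode reader-merge mode.
#' @return tibble with one row per kidney x modality x approach.
#' @export
kidney_results <- function(cohort,
                           approaches = c("First", "Tightest", "Main"),
                           mode = c("recompute", "average_pct")) {
  mode <- match.arg(mode)
  merged <- merge_cohort_readers(cohort, mode = mode)
  keys <- intersect(c("patient", "kidney", "side", "modality", "cer", "ctest"),
                    names(merged))
  units <- dplyr::distinct(merged[, keys, drop = FALSE])
  meas <- merged[merged$measurable & is.finite(merged$dred), , drop = FALSE]

  pick_best <- function(df, ap) {
    picked <- df |>
      dplyr::arrange(dplyr::desc(dred), dplyr::desc(ared), segment) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE) |>
      dplyr::mutate(approach = ap, measurable = TRUE)
    # kidneys with an empty candidate set are reported non-measurable
    missing <- dplyr::anti_join(units, picked, by = keys)
    if (nrow(missing) > 0) {
      missing$approach <- ap
      missing$artery <- NA_integer_; missing$segment <- NA_integer_
      missing$min_d <- NA_real_; missing$min_a <- NA_real_
      missing$dred <- NA_real_; missing$ared <- NA_real_
      missing$measurable <- FALSE
      picked <- dplyr::bind_rows(picked, missing)
    }
    picked[, c(keys, "approach", "artery", "segment", "min_d", "min_a",
               "dred", "ared", "measurable")]
  }

  out <- list()
  if ("First" %in% approaches)
    out$First <- pick_best(meas[meas$segment == 1L, , drop = FALSE], "First")
  if ("Tightest" %in% approaches)
    out$Tightest <- pick_best(meas, "Tightest")
  if ("Main" %in% approaches) {
    main <- meas |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "artery")))) |>
      dplyr::summarise(big_d = max(max_d), n_meas = dplyr::n(),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(big_d), dplyr::desc(n_meas), artery) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE)
    mm <- dplyr::semi_join(meas, main[, c(keys, "artery")],
                           by = c(keys, "artery"))
    out$Main <- pick_best(mm, "Main")
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "approach"))))
}

#' Resolve the functional reference label
#'
#' Renography alone decides positive/negative; an intermediate renography
#' result is resolved by the captopril test.
#'
#' @param cer character vector in `{"positive", "intermediate", "negative"}`.
#' @param ctest character vector in `{"positive", "negative"}` or `NA`;
#'   required wherever `cer` is intermediate.
#' @return character vector in `{"positive", "negative"}`.
#' @examples
#' resolve_reference("positive", NA)               # "positive"
#' resolve_reference("intermediate", "negative")   # "negative"
#' @export
resolve_reference <- function(cer, ctest = NA_character_) {
  ctest <- rep(ctest, length.out = length(cer))
  bad_cer <- !cer %in% c("positive", "intermediate", "negative")
  if (any(bad_cer)) stop("invalid renography result: ", cer[bad_cer][1])
  inter <- cer == "intermediate"
  if (any(inter & (is.na(ctest) | !ctest %in% c("positive", "negative"))))
    stop("an intermediate renography result requires a captopril test result")
  out <- cer
  out[inter] <- ctest[inter]
  out
}

#' Apply the study's cohort filters
#'
#' Three rules, applied in order with explicit accounting: (1) drop kidneys of
#' patients lacking any of the three investigations (both modalities and the
#' functional reference); (2) drop kidneys whose vessels are non-measurable on
#' either modality; (3) drop kidneys contralateral to a positive-labelled
#' kidney — including positives that were themselves dropped as
#' non-measurable, since the functional reference cannot lateralize disease in
#' such patients. Solitary kidneys are never excluded by rule 3.
#'
#' @param records per-kidney tibble with columns `patient`, `side`, `kidney`,
#'   `has_cta`, `has_mra`, `has_ref`, `measurable_cta`, `measurable_mra`,
#'   `cer`, `ctest` (or a pre-resolved `label` column).
#' @return list of class `cohort_filter`: `analysis` (the retained kidneys,
#'   with `label`) and `accounting` (tibble of steps, drops and remaining
#'   counts).
#' @export
filter_cohort <- function(records) {
  stopifnot(all(c("patient", "side", "kidney") %in% names(records)))
  if (!"label" %in% names(records))
    records$label <- resolve_reference(records$cer, records$ctest)

  acc <- tibble::tibble(step = "input", dropped = 0L,
                        remaining = nrow(records))
  complete <- records$has_cta & records$has_mra & records$has_ref
  bad_patients <- unique(records$patient[!complete])
  s1 <- records[!records$patient %in% bad_patients, , drop = FALSE]
  acc <- dplyr::add_row(acc, step = "incomplete investigations",
                        dropped = nrow(records) - nrow(s1),
                        remaining = nrow(s1))

  measurable <- s1$measurable_cta & s1$measurable_mra
  s2 <- s1[measurable, , drop = FALSE]
  acc <- dplyr::add_row(acc, step = "non-measurable vessels",
                        dropped = nrow(s1) - nrow(s2), remaining = nrow(s2))

  # positives among kidneys that survived step 1 (a positive dropped as
  # non-measurable still invalidates its contralateral side)
  pos <- s1[s1$label == "positive", c("patient", "side")]
  contra <- mapply(function(p, sd) {
    any(pos$patient == p & pos$side != sd)
  }, s2$patient, s2$side)
  s3 <- s2[!contra, , drop = FALSE]
  acc <- dplyr::add_row(acc, step = "contralateral to positive",
                        dropped = nrow(s2) - nrow(s3), remaining = nrow(s3))

  structure(list(analysis = tibble::as_tibble(s3), accounting = acc),
            class = "cohort_filter")
}

#' @export
print.cohort_filter <- function(x, ...) {
  print(x$accounting)
  pos <- sum(x$analysis$label == "positive")
  n <- nrow(x$analysis)
  cat(sprintf("analysis set: %d kidneys, %d positive (%.1f %%)\n",
              n, pos, 100 * pos / n))
  invisible(x)
}

#' Measurability statistics per modality and segment
#'
#' For each modality x segment: how many vessel segments were judged
#' measurable by at least one reader, how many by both, and the both-reader
#' percentage (rounded to integer percent). Groups with no measurable
#' segment report `NA`.
#'
#' @param measurements long tibble with columns `modality`, `segment`,
#'   `reader`, `measurable` and unit keys (`kidney`, `artery` or `unit`).
#' @return tibble: `modality`, `segment`, `n_any`, `n_both`, `pct_both`.
#' @export
measurability_stats <- function(measurements) {
  keys <- intersect(c("unit", "patient", "kidney", "side", "artery"),
                    names(measurements))
  if (!length(keys)) stop("no unit key column found")
  measurements |>
    dplyr::group_by(modality, segment,
                    dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_meas = sum(measurable), .groups = "drop") |>
    dplyr::group_by(modality, segment) |>
    dplyr::summarise(
      n_any = sum(n_meas >= 1L),
      n_both = sum(n_meas >= 2L),
      pct_both = ifelse(n_any > 0, round(100 * n_both / n_any), NA_real_),
      .groups = "drop"
    )
}
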