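#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Descriptive statistics
#'
#' Arithmetic mean and sample standard deviation (denominator `n - 1`).
#'
#' @param values numeric vector, non-empty; `NA`s dropped.
#' @return tibble with `mean`, `sd` (`NA` when n < 2) and `n`.
#' @export
descriptives <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no values to describe")
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 n = length(values))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference plus/minus exactly twice the sample standard deviation
#' (denominator `n - 1`) — the 2-SD convention, not 1.96.
#'
#' @param differences numeric vector of paired differences (n >= 2 after
#'   dropping `NA`).
#' @return object of class `loa`: list with `mean_difference`, `loa_low`,
#'   `loa_high`, `sd`, `n`.
#' @examples
#' limits_of_agreement(c(-1, 1))  # mean 0, limits -2.83 / +2.83
#' @export
limits_of_agreement <- function(differences) {
  d <- differences[is.finite(differences)]
  if (length(d) < 2) stop("limits of agreement need at least 2 differences")
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_difference = m, loa_low = m - 2 * s,
                 loa_high = m + 2 * s, sd = s, n = length(d)),
            class = "loa")
}

#' @export
print.loa <- function(x, ...) {
  cat(sprintf("mean difference %.3g (95 %% limits of agreement %.3g; %.3g), n = %d\n",
              x$mean_difference, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.loa <- function(x, ...) {
  tibble::tibble(mean_difference = x$mean_difference, loa_low = x$loa_low,
                 loa_high = x$loa_high, sd = x$sd, n = x$n)
}

#' Two-way random-effects intraclass correlation
#'
#' Single-measure absolute-agreement ICC treating both cases and raters as
#' random effects — ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE +
#' k (MSC - MSE) / n) from the two-way ANOVA mean squares, with the standard
#' F-based 95 % confidence limits. The average-measures form ICC(2,k) is
#' available via `type = "agreement_k"`.
#'
#' @param ratings numeric matrix, cases in rows and raters in columns, or a
#'   data frame with columns `case`, `rater`, `value`. Cases with any missing
#'   rater are dropped (agreement is computed from units judged measurable by
#'   all raters).
#' @param type `"agreement_1"` (single measures, default) or `"agreement_k"`.
#' @param conf_level confidence level, default 0.95.
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `k`, mean squares, `type`. Zero total variance yields `NA` ICC.
#' @export
icc_two_way_random <- function(ratings, type = c("agreement_1", "agreement_k"),
                               conf_level = 0.95) {
  type <- match.arg(type)
  if (is.data.frame(ratings) && all(c("case", "rater", "value") %in% names(ratings))) {
    ratings <- ratings |>
      tidyr::pivot_wider(id_cols = "case", names_from = "rater",
                         values_from = "value") |>
      dplyr::select(-"case") |>
      as.matrix()
  }
  X <- as.matrix(ratings)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2) stop("ICC needs at least 2 cases and 2 raters")
  m <- mean(X)
  ri <- rowMeans(X); cj <- colMeans(X)
  MSR <- k * sum((ri - m)^2) / (n - 1)
  MSC <- n * sum((cj - m)^2) / (k - 1)
  SSE <- sum((sweep(sweep(X, 1, ri), 2, cj) + m)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  tot_var <- sum((X - m)^2)
  if (tot_var == 0) {
    out <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE, type = type,
                conf_level = conf_level)
    return(structure(out, class = "icc_result"))
  }

  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  if (icc1 >= 1 - 1e-12) {
    lo1 <- hi1 <- 1
  } else {
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  if (type == "agreement_k") {
    step_up <- function(r) r * k / (1 + (k - 1) * r)
    icc_v <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
    ci <- sort(step_up(c(lo1, hi1)))
  } else {
    icc_v <- icc1
    ci <- sort(c(lo1, hi1))
  }
  structure(list(icc = icc_v, ci_low = max(-1, ci[1]), ci_high = min(1, ci[2]),
                 n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE, type = type,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %s = %.3f (%.0f %% CI %.3f-%.3f), n = %d cases, %d raters\n",
              if (x$type == "agreement_1") "(2,1)" else "(2,k)",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n = x$n, k = x$k, type = x$type)
}

#' @export
glance.icc_result <- function(x, ...) tidy(x)

#' Inter-observer / inter-method agreement bundle
#'
#' Limits of agreement of the paired differences `x - y` together with the
#' two-way random-effects ICC of the pair — the structure used to report
#' reader and modality agreement.
#'
#' @param x,y paired measurements (same cases); incomplete pairs dropped.
#' @param conf_level confidence level for the ICC limits.
#' @return object of class `agreement_result`.
#' @export
agreement <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  loa <- limits_of_agreement(x[ok] - y[ok])
  icc <- icc_two_way_random(cbind(x[ok], y[ok]), conf_level = conf_level)
  structure(list(loa = loa, icc = icc, n = sum(ok)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  print(x$loa); print(x$icc)
  invisible(x)
}

#' @export
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(mean_difference = x$loa$mean_difference,
                 loa_low = x$loa$loa_low, loa_high = x$loa$loa_high,
                 icc = x$icc$icc, icc_ci_low = x$icc$ci_low,
                 icc_ci_high = x$icc$ci_high, n = x$n)
}

# midrank-based DeLong placements; scores oriented so higher = more positive
delong_placements <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve and area under it
#'
#' The curve is the empirical trapezoidal ROC; its area equals the
#' Mann-Whitney statistic (ties count one half). The 95 % confidence interval
#' uses the DeLong placement variance by default (`ci_method = "hanley"`
#' switches to the Hanley-McNeil approximation). Orient the score so that
#' higher means more diseased: relative reductions already do, absolute
#' minimum diameter/area must be inverted (`direction = "lower_worse"`).
#'
#' @param scores numeric measurement per case.
#' @param labels binary reference: logical, 0/1, or `"positive"`/`"negative"`.
#' @param direction `"higher_worse"` (default) or `"lower_worse"`.
#' @param ci_method `"delong"` or `"hanley"`.
#' @param conf_level confidence level.
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`, and `curve` (tibble of FPR/TPR, monotone from (0,0) to (1,1)).
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
roc_auc <- function(scores, labels, direction = c("higher_worse", "lower_worse"),
                    ci_method = c("delong", "hanley"), conf_level = 0.95) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  positive <- to_positive(labels)
  ok <- is.finite(scores) & !is.na(positive)
  scores <- scores[ok]; positive <- positive[ok]
  if (!any(positive) || all(positive))
    stop("ROC needs both a positive and a negative class")
  s <- if (direction == "lower_worse") -scores else scores
  pl <- delong_placements(s, positive)
  n1 <- sum(positive); n0 <- sum(!positive)

  # empirical curve at decreasing thresholds
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!positive] >= t), numeric(1))
  curve <- tibble::tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))

  if (ci_method == "delong") {
    v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  } else {
    a <- pl$auc
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
      (n1 * n0)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = pl$auc,
                 ci_low = max(0, pl$auc - z * sqrt(v)),
                 ci_high = min(1, pl$auc + z * sqrt(v)),
                 se = sqrt(v), n_pos = n1, n_neg = n0, curve = curve,
                 direction = direction, ci_method = ci_method),
            class = "roc_result")
}

to_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  tolower(as.character(labels)) %in% c("positive", "pos", "1", "true")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95 %% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Paired comparison of two AUROCs (DeLong test)
#'
#' Both scores must be measured on the same cases against the same reference.
#' The covariance of the two areas is estimated from the DeLong placements
#' and the difference tested with a two-sided normal statistic. Identical (or
#' rank-identical) scores give a difference of 0 and p = 1.
#'
#' @param scores_a,scores_b paired measurements.
#' @param labels binary reference (see [roc_auc()]).
#' @param direction_a,direction_b orientation per score.
#' @return tibble: `auc_a`, `auc_b`, `diff`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels,
                               direction_a = "higher_worse",
                               direction_b = "higher_worse") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired AUC comparison needs equal-length inputs")
  positive <- to_positive(labels)
  ok <- is.finite(scores_a) & is.finite(scores_b) & !is.na(positive)
  sa <- scores_a[ok]; sb <- scores_b[ok]; positive <- positive[ok]
  if (!any(positive) || all(positive))
    stop("ROC needs both a positive and a negative class")
  if (direction_a == "lower_worse") sa <- -sa
  if (direction_b == "lower_worse") sb <- -sb
  pa <- delong_placements(sa, positive)
  pb <- delong_placements(sb, positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  v <- stats::var(pa$v10 - pb$v10) / n1 + stats::var(pa$v01 - pb$v01) / n0
  d <- pa$auc - pb$auc
  if (v <= 0 || !is.finite(v)) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, diff = d, z = z, p_value = p)
}

#' AUROC of every measure under every approach against the reference
#'
#' Tidy wrapper producing the measure x approach (x modality) AUROC table from
#' per-kidney results: relative reductions score higher-is-worse, absolute
#' minima lower-is-worse.
#'
#' @param results per-kidney tibble from [kidney_results()], containing
#'   `label` (or `cer`/`ctest` to resolve), `modality`, `approach` and the
#'   measure columns.
#' @param measures which measures to evaluate.
#' @param ci_method passed to [roc_auc()].
#' @return tibble: `modality`, `approach`, `measure`, `auc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
auroc_table <- function(results,
                        measures = c("min_d", "min_a", "dred", "ared"),
                        ci_method = "delong") {
  if (!"label" %in% names(results))
    results$label <- resolve_reference(results$cer, results$ctest)
  results |>
    dplyr::filter(measurable) |>
    dplyr::group_by(modality, approach) |>
    dplyr::group_modify(function(g, key) {
      dplyr::bind_rows(lapply(measures, function(m) {
        dir <- if (m %in% c("min_d", "min_a")) "lower_worse" else "higher_worse"
        r <- roc_auc(g[[m]], g$label, direction = dir, ci_method = ci_method)
        dplyr::bind_cols(tibble::tibble(measure = m), glance(r))
      }))
    }) |>
    dplyr::ungroup()
}
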