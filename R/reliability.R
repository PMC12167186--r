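# Agreement and reliability between automated and reference (manual)
# quantification: one-way random single-measure ICC(1,1) with F-based 95%
# CIs, Deming errors-in-variables regression, Spearman rank correlation,
# paired Wilcoxon with percentile-bootstrap CIs, and the four-way
# agreement/disagreement categorization of measurement decisions.

.complete_pairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' One-way random, single-measure intraclass correlation ICC(1,1)
#'
#' Absolute-agreement reliability between two raters (here: manual reader and
#' algorithm) under the one-way random-effects model. With k = 2 measurements
#' per subject, ICC = (MSB - MSW) / (MSB + (k - 1) MSW), where MSB and MSW
#' are the between- and within-subject mean squares of the one-way ANOVA.
#' The confidence interval and the p-value (H0: ICC = 0) come from the
#' standard F-based formulation: F = MSB/MSW on (n - 1, n (k - 1)) degrees of
#' freedom. Values below 0.5 indicate poor reliability, 0.5-0.75 moderate,
#' 0.75-0.9 good, and above 0.9 excellent.
#'
#' @param manual,auto Paired measurements (same units); incomplete pairs are
#'   dropped.
#' @param alpha CI significance level (default 0.05 for a 95% CI).
#' @return List of class `mq_icc`: `icc`, `ci95` (lo, hi), `p_value`,
#'   `n_pairs`, `msb`, `msw`.
#' @export
icc_1_1 <- function(manual, auto, alpha = 0.05) {
  p <- .complete_pairs(manual, auto)
  n <- p$n; k <- 2L
  if (n < 3) stop("ICC requires at least 3 complete pairs", call. = FALSE)
  dat <- cbind(p$x, p$y)
  subj_means <- rowMeans(dat)
  grand <- mean(dat)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((dat - subj_means)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw == 0) {
    warning("zero variance in both directions; ICC undefined, reporting 0",
            call. = FALSE)
    return(structure(list(icc = 0, ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, n_pairs = n,
                          msb = msb, msw = msw), class = "mq_icc"))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw == 0) {
    # perfect agreement: degenerate F
    return(structure(list(icc = icc, ci95 = c(icc, icc), p_value = 0,
                          n_pairs = n, msb = msb, msw = msw),
                     class = "mq_icc"))
  }
  fobs <- msb / msw
  df1 <- n - 1; df2 <- n * (k - 1)
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  pval <- stats::pf(fobs, df1, df2, lower.tail = FALSE)
  structure(list(icc = icc, ci95 = ci, p_value = pval, n_pairs = n,
                 msb = msb, msw = msw), class = "mq_icc")
}

#' @export
print.mq_icc <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f [%.3f, %.3f], p = %.3g, n = %d\n",
              x$icc, x$ci95[1], x$ci95[2], x$p_value, x$n_pairs))
  invisible(x)
}

#' Deming errors-in-variables regression
#'
#' Closed-form linear fit allowing measurement error on both axes, with error
#' variance ratio `delta` = var(error in y) / var(error in x); `delta = 1`
#' (the default) is orthogonal regression, symmetric under swapping the axes
#' (the slope maps to its reciprocal). A slope near 1 with intercept near 0
#' indicates concordance between the two measurement methods.
#'
#' @param x,y Paired measurements (x: reference, y: test).
#' @param delta Error variance ratio (> 0).
#' @return List of class `mq_deming`: `slope`, `intercept`, `delta`, `n`.
#' @export
deming_fit <- function(x, y, delta = 1) {
  p <- .complete_pairs(x, y)
  if (p$n < 3) stop("Deming regression requires at least 3 pairs", call. = FALSE)
  stopifnot(delta > 0)
  x <- p$x; y <- p$y
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0 && syy == 0)
    stop("zero variance on both axes; Deming fit undefined", call. = FALSE)
  if (sxy == 0) {
    # degenerate orientation: vertical or horizontal principal axis
    slope <- if (syy >= delta * sxx) Inf else 0
  } else {
    slope <- (syy - delta * sxx +
                sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept, delta = delta, n = p$n),
            class = "mq_deming")
}

#' @export
print.mq_deming <- function(x, ...) {
  cat(sprintf("Deming fit (delta = %g): y = %.4f x + %.4f (n = %d)\n",
              x$delta, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-rank tie handling; p-value from the asymptotic
#' t approximation (ties-safe).
#'
#' @param x,y Paired measurements.
#' @return List: `rho`, `p_value`, `n`; `rho` is `NA` (with a warning) when
#'   either column is constant.
#' @export
spearman_rho <- function(x, y) {
  p <- .complete_pairs(x, y)
  if (p$n < 3) stop("Spearman correlation requires at least 3 pairs", call. = FALSE)
  if (stats::var(p$x) == 0 || stats::var(p$y) == 0) {
    warning("constant column; Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = p$n))
  }
  ct <- suppressWarnings(stats::cor.test(p$x, p$y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = p$n)
}

#' Compare paired medians with Wilcoxon test and bootstrap CIs
#'
#' Reports the medians of both arms, the median of the paired differences
#' (auto - manual), the two-sided paired Wilcoxon signed-rank p-value, and
#' seeded percentile-bootstrap 95% confidence intervals: pairs are resampled
#' for each arm's median, differences are resampled for the
#' median-of-differences interval.
#'
#' @param manual,auto Paired measurements (ms).
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed RNG seed for the bootstrap (local; does not disturb the
#'   global RNG state).
#' @param conf Confidence level (default 0.95).
#' @return List of class `mq_median_comparison` with `median_auto`,
#'   `median_manual`, `median_of_differences`, `wilcoxon_p`, `ci_auto`,
#'   `ci_manual`, `ci_difference`, `n`, `degenerate`.
#' @export
compare_medians <- function(manual, auto, B = 10000L, seed = 1L, conf = 0.95) {
  p <- .complete_pairs(manual, auto)
  if (p$n < 5) stop("median comparison requires at least 5 pairs", call. = FALSE)
  manual <- p$x; auto <- p$y; n <- p$n
  d <- auto - manual
  degenerate <- all(d == 0)
  wp <- if (degenerate) 1 else
    suppressWarnings(stats::wilcox.test(auto, manual, paired = TRUE,
                                        exact = FALSE, correct = TRUE))$p.value
  lo <- (1 - conf) / 2; hi <- 1 - lo
  boots <- with_local_seed(seed, {
    bm <- ba <- bd <- numeric(B)
    for (b in seq_len(B)) {
      i <- sample.int(n, n, replace = TRUE)   # resample pairs
      bm[b] <- stats::median(manual[i])
      ba[b] <- stats::median(auto[i])
      j <- sample.int(n, n, replace = TRUE)   # resample differences
      bd[b] <- stats::median(d[j])
    }
    list(bm = bm, ba = ba, bd = bd)
  })
  structure(list(
    median_auto = stats::median(auto),
    median_manual = stats::median(manual),
    median_of_differences = stats::median(d),
    wilcoxon_p = wp,
    ci_auto = unname(stats::quantile(boots$ba, c(lo, hi))),
    ci_manual = unname(stats::quantile(boots$bm, c(lo, hi))),
    ci_difference = unname(stats::quantile(boots$bd, c(lo, hi))),
    n = n, degenerate = degenerate
  ), class = "mq_median_comparison")
}

#' @export
print.mq_median_comparison <- function(x, ...) {
  cat(sprintf("medians: auto %.1f [%.1f, %.1f] vs manual %.1f [%.1f, %.1f]\n",
              x$median_auto, x$ci_auto[1], x$ci_auto[2],
              x$median_manual, x$ci_manual[1], x$ci_manual[2]))
  cat(sprintf("median of differences %.2f [%.2f, %.2f], Wilcoxon p = %.3g (n = %d)\n",
              x$median_of_differences, x$ci_difference[1], x$ci_difference[2],
              x$wilcoxon_p, x$n))
  invisible(x)
}

#' Categorize agreement between automated and manual measurement decisions
#'
#' Each (exam, sequence, segment) cell falls into one of four top-level
#' categories: positive agreement (both measured), negative agreement (both
#' absent), human-only (manual present, automated omitted — subdivided by
#' the automated omission reason), and algorithm-only (automated present,
#' manual absent). Counts sum to the number of rows.
#'
#' @param table Data frame with columns `manual_value`, `auto_value`
#'   (NA = absent) and `auto_omission_reason` (used for human-only rows).
#' @return List of class `mq_agreement`: `n`, the four category counts, and
#'   `human_only_reasons` (named count vector).
#' @export
categorize_agreement <- function(table) {
  n <- nrow(table)
  if (n == 0L)
    return(structure(list(n = 0L, positive_agreement = 0L,
                          negative_agreement = 0L, human_only = 0L,
                          algorithm_only = 0L,
                          human_only_reasons = integer(0)),
                     class = "mq_agreement"))
  has_m <- is.finite(table$manual_value)
  has_a <- is.finite(table$auto_value)
  human_only <- has_m & !has_a
  reasons <- table$auto_omission_reason[human_only]
  reasons[is.na(reasons) | reasons == ""] <- "unspecified"
  structure(list(
    n = n,
    positive_agreement = sum(has_m & has_a),
    negative_agreement = sum(!has_m & !has_a),
    human_only = sum(human_only),
    algorithm_only = sum(!has_m & has_a),
    human_only_reasons = if (length(reasons)) table(reasons) else integer(0)
  ), class = "mq_agreement")
}

#' @export
print.mq_agreement <- function(x, ...) {
  pct <- function(k) if (x$n) sprintf("%.1f%%", 100 * k / x$n) else "-"
  cat(sprintf("agreement over %d cells: positive %d (%s), negative %d (%s), human-only %d (%s), algorithm-only %d (%s)\n",
              x$n, x$positive_agreement, pct(x$positive_agreement),
              x$negative_agreement, pct(x$negative_agreement),
              x$human_only, pct(x$human_only),
              x$algorithm_only, pct(x$algorithm_only)))
  if (length(x$human_only_reasons)) {
    cat("human-only reasons:\n")
    for (r in names(x$human_only_reasons))
      cat(sprintf("  %s: %d\n", r, x$human_only_reasons[[r]]))
  }
  invisible(x)
}

#' Build an agreement table from measurement tables
#'
#' Outer-joins automated and manual measurement tables on
#' (exam_id, sequence_id, segment).
#'
#' @param auto Data frame with columns exam_id, sequence_id, segment,
#'   mean_ms (NA when omitted) and reason.
#' @param manual Data frame with columns exam_id, sequence_id, segment,
#'   value_ms.
#' @return Data frame with `manual_value`, `auto_value`,
#'   `auto_omission_reason` per cell.
#' @export
agreement_table <- function(auto, manual) {
  a <- data.frame(exam_id = auto$exam_id, sequence_id = auto$sequence_id,
                  segment = auto$segment, auto_value = auto$mean_ms,
                  auto_omission_reason = ifelse(is.na(auto$mean_ms),
                                                auto$reason, NA_character_),
                  stringsAsFactors = FALSE)
  m <- data.frame(exam_id = manual$exam_id, sequence_id = manual$sequence_id,
                  segment = manual$segment, manual_value = manual$value_ms,
                  stringsAsFactors = FALSE)
  merge(m, a, by = c("exam_id", "sequence_id", "segment"), all = TRUE)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
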