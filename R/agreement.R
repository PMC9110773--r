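#' Paired method-vs-reference series
#'
#' One mass value per subject for a method under evaluation and for the
#' reference (e.g. necropsy weight). Subjects with a missing method value
#' are excluded before construction.
#'
#' @param predicted Method values in g.
#' @param reference Reference values in g (same length, >= 3).
#' @param subject_ids Optional identifiers (defaults to 1..n).
#' @return An object of class `paired_series`.
#' @export
paired_series <- function(predicted, reference, subject_ids = NULL) {
  predicted <- as.numeric(predicted)
  reference <- as.numeric(reference)
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (length(predicted) < 3L)
    stop("paired agreement needs at least 3 subjects (got ",
         length(predicted), ")")
  if (anyNA(predicted) || anyNA(reference))
    stop("paired series must not contain missing values; ",
         "exclude incomplete subjects upstream")
  if (any(!is.finite(c(predicted, reference))) ||
      any(c(predicted, reference) <= 0))
    stop("masses must be positive and finite")
  if (is.null(subject_ids)) subject_ids <- seq_along(predicted)
  structure(list(subject_ids = as.character(subject_ids),
                 predicted = predicted, reference = reference),
            class = "paired_series")
}

as_paired <- function(s) {
  if (!inherits(s, "paired_series")) stop("expected a paired_series")
  s
}

#' Bias and 95% limits of agreement
#'
#' Differences are `predicted - reference`, so a positive bias means the
#' method overestimates the reference. The limits of agreement are
#' `bias +/- multiplier * SD(differences)` with the sample (n-1) SD.
#'
#' @param s A [paired_series].
#' @param multiplier LOA multiplier (default 1.96 for 95% limits).
#' @return List with `bias`, `sd_diff` and `loa_half_width` (g).
#' @export
bias_loa <- function(s, multiplier = 1.96) {
  s <- as_paired(s)
  d <- s$predicted - s$reference
  sd_d <- stats::sd(d)
  list(bias = mean(d), sd_diff = sd_d, loa_half_width = multiplier * sd_d)
}

#' Coefficient of variation against the reference
#'
#' `100 * SD(differences) / mean(reference)` in percent: the difference SD
#' adjusted to the reference (anatomical) mass, treating the reference as
#' truth rather than as a second method.
#'
#' @param s A [paired_series].
#' @return CV in percent.
#' @export
cv_percent <- function(s) {
  s <- as_paired(s)
  m <- mean(s$reference)
  if (m == 0) stop("reference mean is zero; CV undefined")
  100 * stats::sd(s$predicted - s$reference) / m
}

#' Standard error of the estimate
#'
#' Residual SD of the ordinary least-squares regression of the method on the
#' reference (reference as independent variable):
#' `SEE = sqrt(sum(residual^2) / (n - 2))`.
#'
#' @param s A [paired_series].
#' @return SEE in g.
#' @export
see <- function(s) {
  s <- as_paired(s)
  if (stats::sd(s$reference) == 0)
    stop("degenerate regression: reference values are constant")
  fit <- stats::lm(predicted ~ reference,
                   data = list(predicted = s$predicted, reference = s$reference))
  sqrt(sum(stats::residuals(fit)^2) / (length(s$predicted) - 2))
}

#' Pearson correlation with two-sided p-value
#'
#' @param s A [paired_series].
#' @return List with `r` and `p` (two-sided, from the t distribution with
#'   n-2 degrees of freedom).
#' @export
pearson <- function(s) {
  s <- as_paired(s)
  if (stats::sd(s$predicted) == 0 || stats::sd(s$reference) == 0)
    stop("correlation undefined: a series is constant")
  ct <- stats::cor.test(s$predicted, s$reference, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test p-value
#'
#' Two-sided paired t-test of the differences against zero. Zero-variance
#' differences are handled by convention: p = 1 when the common difference
#' is zero (no disagreement at all), p = 0 in the limit of a constant
#' non-zero offset.
#'
#' @param s A [paired_series].
#' @return Two-sided p-value.
#' @export
paired_t <- function(s) {
  s <- as_paired(s)
  d <- s$predicted - s$reference
  if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  stats::t.test(s$predicted, s$reference, paired = TRUE)$p.value
}

#' Proportional bias
#'
#' OLS regression of the per-subject difference on the reference value
#' (reference as independent variable). A slope with p >= alpha is read as
#' "no proportional bias".
#'
#' @param s A [paired_series].
#' @param alpha Significance threshold for the verdict (default 0.05).
#' @return List with `slope` (g per g), `p` (two-sided) and `significant`.
#' @export
proportional_bias <- function(s, alpha = 0.05) {
  s <- as_paired(s)
  if (stats::sd(s$reference) == 0)
    stop("degenerate regression: reference values are constant")
  d <- s$predicted - s$reference
  fit <- stats::lm(d ~ reference, data = list(d = d, reference = s$reference))
  slope <- unname(stats::coef(fit)[2L])
  # degenerate case: differences are (numerically) constant, so the fit is
  # perfect with zero slope and there is no proportional bias by definition
  if (abs(slope) * stats::sd(s$reference) < 1e-10 * (1 + mean(abs(d))) &&
      sum(stats::residuals(fit)^2) < 1e-18 * (1 + sum(d^2)))
    return(list(slope = slope, p = 1, significant = FALSE))
  # an exactly linear dependence still triggers summary.lm's perfect-fit
  # warning; the limit p -> 0 it reports is the right answer here
  co <- stats::coef(suppressWarnings(summary(fit)))
  list(slope = slope,
       p = co["reference", "Pr(>|t|)"],
       significant = co["reference", "Pr(>|t|)"] < alpha)
}

#' Per-subject percentage differences
#'
#' `100 * (predicted - reference) / reference` per subject; positive values
#' are overestimation by the method.
#'
#' @param s A [paired_series].
#' @return Named numeric vector (by subject id) of percentages.
#' @export
percent_differences <- function(s) {
  s <- as_paired(s)
  if (any(s$reference == 0)) stop("zero reference value; percentage undefined")
  stats::setNames(100 * (s$predicted - s$reference) / s$reference,
                  s$subject_ids)
}

#' Per-subject most/least accurate method counts
#'
#' For each subject, the method with the smallest absolute percentage
#' difference is credited as most accurate and the largest as least
#' accurate. Ties split the credit equally (1/k for a k-way tie), so counts
#' always sum to the number of subjects.
#'
#' @param methods Named list of [paired_series], one per method, sharing
#'   subject ids.
#' @param complete_cases_only If `TRUE` (default) restrict to subjects
#'   present in every method's series.
#' @return Data frame with per-method `most_n`, `most_pct`, `least_n`,
#'   `least_pct` and the subject count as attribute `n_subjects`.
#' @export
rank_accuracy <- function(methods, complete_cases_only = TRUE) {
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("`methods` must be a named list of paired_series")
  pct <- lapply(methods, function(s) {
    s <- as_paired(s)
    stats::setNames(abs(percent_differences(s)), s$subject_ids)
  })
  ids <- Reduce(intersect, lapply(pct, names))
  if (!complete_cases_only)
    ids <- Reduce(union, lapply(pct, names))
  if (length(ids) < 1L) stop("no shared subjects across methods")
  most <- least <- stats::setNames(numeric(length(methods)), names(methods))
  tol <- 1e-12
  for (id in ids) {
    v <- vapply(pct, function(p) if (id %in% names(p)) p[[id]] else NA_real_,
                numeric(1L))
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    lo <- names(v)[v <= min(v) * (1 + tol) + tol]
    hi <- names(v)[v >= max(v) * (1 - tol) - tol]
    most[lo] <- most[lo] + 1 / length(lo)
    least[hi] <- least[hi] + 1 / length(hi)
  }
  out <- data.frame(method = names(methods), most_n = unname(most),
                    most_pct = unname(100 * most / length(ids)),
                    least_n = unname(least),
                    least_pct = unname(100 * least / length(ids)),
                    stringsAsFactors = FALSE)
  attr(out, "n_subjects") <- length(ids)
  out
}

#' Intra-/inter-reader variability
#'
#' Agreement of a repeat reading against the baseline reading of the same
#' recordings: differences are `repeat - baseline` (positive bias means the
#' repeat reading overestimates), CV uses the mean of the baseline reading
#' as denominator, and the SEE comes from regressing the repeat on the
#' baseline.
#'
#' @param baseline,repeated Numeric vectors of per-subject masses (g) from
#'   the two readings, aligned by `subject_ids`.
#' @param subject_ids Optional identifiers for both readings.
#' @param multiplier LOA multiplier.
#' @return List with `n`, `bias`, `sd_diff`, `loa_half_width`, `cv_pct`,
#'   `see`.
#' @export
reader_variability <- function(baseline, repeated, subject_ids = NULL,
                               multiplier = 1.96) {
  baseline <- as.numeric(baseline); repeated <- as.numeric(repeated)
  if (length(baseline) != length(repeated))
    stop("alignment error: readings cover different subjects")
  if (length(baseline) < 3L) stop("reader variability needs >= 3 subjects")
  if (anyNA(baseline) || anyNA(repeated))
    stop("alignment error: missing values in a reading")
  d <- repeated - baseline
  sd_d <- stats::sd(d)
  fit <- stats::lm(repeated ~ baseline,
                   data = list(repeated = repeated, baseline = baseline))
  list(n = length(baseline), bias = mean(d), sd_diff = sd_d,
       loa_half_width = multiplier * sd_d,
       cv_pct = 100 * sd_d / mean(baseline),
       see = sqrt(sum(stats::residuals(fit)^2) / (length(baseline) - 2)))
}

#' Full agreement summary of one method against the reference
#'
#' Bundles the whole agreement protocol — bias and limits of agreement,
#' CV, SEE, Pearson correlation, paired t-test and proportional-bias
#' regression — into one classed object with print, summary and a
#' Bland-Altman-style plot method.
#'
#' @param predicted,reference Per-subject masses in g (or a single
#'   [paired_series] as `predicted`).
#' @param subject_ids Optional identifiers.
#' @param loa_multiplier LOA multiplier (default 1.96).
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `lvm_agreement`.
#' @export
lvm_agreement <- function(predicted, reference = NULL, subject_ids = NULL,
                          loa_multiplier = 1.96, alpha = 0.05) {
  s <- if (inherits(predicted, "paired_series")) predicted
       else paired_series(predicted, reference, subject_ids)
  bl <- bias_loa(s, loa_multiplier)
  pe <- pearson(s)
  pb <- proportional_bias(s, alpha)
  structure(list(n = length(s$predicted),
                 mean_predicted = mean(s$predicted),
                 sd_predicted = stats::sd(s$predicted),
                 mean_reference = mean(s$reference),
                 bias = bl$bias, sd_diff = bl$sd_diff,
                 loa_half_width = bl$loa_half_width,
                 loa_multiplier = loa_multiplier,
                 cv_pct = cv_percent(s), see = see(s),
                 pearson_r = pe$r, pearson_p = pe$p,
                 paired_t_p = paired_t(s),
                 prop_bias_slope = pb$slope, prop_bias_p = pb$p,
                 alpha = alpha, series = s),
            class = "lvm_agreement")
}

#' @export
print.lvm_agreement <- function(x, ...) {
  cat(sprintf(
    "<lvm_agreement> n = %d | %.0f +/- %.0f g | bias %+.1f +/- %.1f g (95%% LOA) | CV %.1f%% | SEE %.1f g | r = %.2f\n",
    x$n, x$mean_predicted, x$sd_predicted, x$bias, x$loa_half_width,
    x$cv_pct, x$see, x$pearson_r))
  invisible(x)
}

#' @export
summary.lvm_agreement <- function(object, ...) {
  x <- object
  cat("Method-vs-reference agreement (n =", x$n, ")\n")
  cat(sprintf("  Method mean +/- SD : %.1f +/- %.1f g\n",
              x$mean_predicted, x$sd_predicted))
  cat(sprintf("  Bias (method - ref): %+.2f g  [positive = overestimation]\n",
              x$bias))
  cat(sprintf("  95%% LOA           : %+.2f to %+.2f g (%.2f x SD of diffs)\n",
              x$bias - x$loa_half_width, x$bias + x$loa_half_width,
              x$loa_multiplier))
  cat(sprintf("  CV                 : %.2f %% of reference mean (%.1f g)\n",
              x$cv_pct, x$mean_reference))
  cat(sprintf("  SEE                : %.2f g\n", x$see))
  cat(sprintf("  Pearson r          : %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p))
  cat(sprintf("  Paired t-test      : p = %.3g\n", x$paired_t_p))
  cat(sprintf("  Proportional bias  : slope %.4f g/g (p = %.3g) -> %s\n",
              x$prop_bias_slope, x$prop_bias_p,
              if (x$prop_bias_p < x$alpha) "significant" else
                "no proportional bias"))
  invisible(x)
}

#' Bland-Altman-style agreement plot
#'
#' Difference (method - reference) against the reference value, with the
#' bias (solid), the limits of agreement (dashed red), zero (dotted) and the
#' proportional-bias regression line (thin).
#'
#' @param x An `lvm_agreement`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lvm_agreement <- function(x, main = "Agreement vs reference", ...) {
  s <- x$series
  d <- s$predicted - s$reference
  ylim <- range(d, x$bias + x$loa_half_width, x$bias - x$loa_half_width, 0)
  graphics::plot(s$reference, d, xlab = "Reference LVM (g)",
                 ylab = "Method - reference (g)", main = main,
                 ylim = ylim + c(-1, 1) * 0.05 * diff(ylim), pch = 19, ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = x$bias + c(-1, 1) * x$loa_half_width,
                   col = "red", lty = 2)
  fit <- stats::lm(d ~ ref, data = list(d = d, ref = s$reference))
  graphics::abline(fit, lwd = 0.8)
  invisible(x)
}

#' Per-subject percentage-difference profile plot
#'
#' Percentage difference against the reference for each subject across
#' methods; one polyline per subject, methods on the x axis.
#'
#' @param methods Named list of [paired_series] sharing subject ids.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_percent_differences <- function(methods, ...) {
  pct <- lapply(methods, function(s) percent_differences(as_paired(s)))
  ids <- Reduce(intersect, lapply(pct, names))
  m <- vapply(pct, function(p) p[ids], numeric(length(ids)))
  graphics::matplot(t(m), type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "Method", ylab = "Difference vs reference (%)", ...)
  graphics::axis(1, at = seq_along(methods), labels = names(methods))
  graphics::abline(h = 0, lty = 3)
  invisible(m)
}
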