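#' Paired area series
#'
#' Pairs manual (`x`) and automated (`y`) defect-area measurements by
#' (eye, visit) key for method-comparison statistics. Pairs with a missing
#' value on either side are dropped listwise; the number dropped is
#' recorded.
#'
#' @param x Manual areas (mm^2).
#' @param y Automated areas (mm^2), same length.
#' @param keys Optional character vector of pair identifiers.
#' @return A list with class `"PairedAreas"`.
#' @export
paired_areas <- function(x, y, keys = NULL) {
  if (length(x) != length(y))
    stopf("x and y differ in length (%d vs %d)", length(x), length(y))
  if (is.null(keys)) keys <- as.character(seq_along(x))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stopf("need at least 2 complete pairs, have %d", sum(ok))
  if (any(x[ok] < 0) || any(y[ok] < 0)) stopf("areas must be non-negative")
  structure(
    list(x = as.numeric(x[ok]), y = as.numeric(y[ok]), keys = keys[ok],
         n_dropped = sum(!ok)),
    class = "PairedAreas"
  )
}

#' Intraclass correlation coefficient, ICC(A,1)
#'
#' Two-way model, absolute agreement, single measurement — the form that
#' asks whether two fixed methods give interchangeable single readings.
#' Computed from the mean-squares decomposition of the subject x method
#' layout: with `MSR` the between-subject, `MSC` the between-method and
#' `MSE` the residual mean square over `n` subjects and `k = 2` methods,
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param pairs A [paired_areas()] object.
#' @return List with `icc`, `icc_form = "ICC(A,1)"`, and the mean squares.
#' @export
icc <- function(pairs) {
  stopifnot(inherits(pairs, "PairedAreas"))
  n <- length(pairs$x)
  if (n < 3) stopf("ICC needs at least 3 pairs, have %d", n)
  m <- cbind(pairs$x, pairs$y)
  k <- 2
  grand <- mean(m)
  if (all(m == m[1])) stopf("ICC undefined: measurements have zero variance")
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) stopf("ICC undefined: measurements have zero variance")
  list(icc = (msr - mse) / denom, icc_form = "ICC(A,1)",
       msr = msr, msc = msc, mse = mse, n = n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are oriented automated minus manual (`y - x`), so a positive
#' bias reads as automated over-call. Limits of agreement are
#' `bias +/- 1.96 * SD` of the differences with the sample (n-1) SD.
#'
#' @param pairs A [paired_areas()] object.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "PairedAreas"))
  d <- pairs$y - pairs$x
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Wilcoxon signed-rank test for paired areas
#'
#' Compares the two measurement series without a normality assumption.
#' Zero differences are dropped; tied absolute differences are mid-ranked.
#' The exact null distribution is used when the number of non-zero
#' differences is at most 25 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' If every difference is zero the result is flagged degenerate with
#' `p = 1`.
#'
#' @param pairs A [paired_areas()] object.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`
#'   (two-tailed), `n_used`, `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(pairs) {
  stopifnot(inherits(pairs, "PairedAreas"))
  d <- pairs$y - pairs$x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_used = 0, exact = TRUE,
                degenerate = TRUE))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    # exact two-tailed p from the signed-rank null distribution
    p <- 2 * min(stats::psignrank(w_pos, n),
                 stats::psignrank(w_pos - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(p, 1)
    exact <- FALSE
  }
  list(statistic = w_pos, p_value = p, n_used = n, exact = exact,
       degenerate = FALSE)
}

#' All agreement statistics for a paired series
#'
#' @param pairs A [paired_areas()] object.
#' @return An `AgreementStats` list bundling [icc()], [bland_altman()] and
#'   [wilcoxon_signed_rank()] results.
#' @export
agreement_stats <- function(pairs) {
  i <- icc(pairs)
  ba <- bland_altman(pairs)
  w <- wilcoxon_signed_rank(pairs)
  structure(
    list(icc = i$icc, icc_form = i$icc_form,
         bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
         wilcoxon_stat = w$statistic, wilcoxon_p = w$p_value,
         n = length(pairs$x), n_dropped = pairs$n_dropped),
    class = "AgreementStats"
  )
}

#' @export
print.AgreementStats <- function(x, ...) {
  cat(sprintf("AgreementStats (n = %d pairs, %d dropped):\n", x$n,
              x$n_dropped))
  cat(sprintf("  %s = %.3f\n", x$icc_form, x$icc))
  cat(sprintf("  bias (automated - manual) = %.3f mm^2, LOA %.3f to %.3f\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  Wilcoxon signed-rank W+ = %g, p = %.3f\n",
              x$wilcoxon_stat, x$wilcoxon_p))
  invisible(x)
}

#' Per-visit summary of defect measurements
#'
#' @param measurements List of `DefectMeasurement` objects.
#' @return Data frame with one row per (visit, method): `n`, `min`, `max`,
#'   `mean`, `sd` (0 with `sd_flagged = TRUE` for n = 1), and the fraction
#'   of maps with a nonzero defect.
#' @export
summarize_measurements <- function(measurements) {
  df <- measurements_to_df(measurements)
  if (nrow(df) == 0) stopf("no measurements to summarize")
  groups <- split(df, list(df$visit_id, df$method), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    a <- g$total_area_mm2
    data.frame(visit_id = g$visit_id[1], method = g$method[1],
               n = length(a), min = min(a), max = max(a), mean = mean(a),
               sd = if (length(a) > 1) stats::sd(a) else 0,
               sd_flagged = length(a) == 1,
               frac_nonzero = mean(a > 0))
  }))
  rownames(out) <- NULL
  out[order(out$visit_id, out$method), ]
}

#' Bland-Altman and agreement scatter plots
#'
#' Writes two PNG figures: a Bland-Altman plot (differences against pair
#' means with bias and limits of agreement) and a manual-vs-automated
#' scatter with the identity line.
#'
#' @param pairs A [paired_areas()] object.
#' @param path_ba,path_scatter Output PNG paths.
#' @return Invisibly, the [agreement_stats()] of the pairs.
#' @export
plot_agreement <- function(pairs, path_ba, path_scatter) {
  st <- agreement_stats(pairs)
  ba <- bland_altman(pairs)
  grDevices::png(path_ba, width = 700, height = 600)
  means <- (pairs$x + pairs$y) / 2
  diffs <- pairs$y - pairs$x
  graphics::plot(means, diffs, pch = 19, col = "grey30",
                 xlab = "Mean of manual and automated area (mm^2)",
                 ylab = "Automated - manual (mm^2)",
                 main = "Bland-Altman")
  graphics::abline(h = ba$bias, col = "blue")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "red", lty = 2)
  grDevices::dev.off()
  grDevices::png(path_scatter, width = 600, height = 600)
  lim <- range(c(pairs$x, pairs$y))
  graphics::plot(pairs$x, pairs$y, pch = 19, col = "grey30", xlim = lim,
                 ylim = lim, xlab = "Manual area (mm^2)",
                 ylab = "Automated area (mm^2)",
                 main = sprintf("%s = %.2f", st$icc_form, st$icc))
  graphics::abline(0, 1, col = "blue")
  grDevices::dev.off()
  invisible(st)
}
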