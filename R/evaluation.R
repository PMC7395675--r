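# Test-set statistics: pointwise and sectoral MAE / Pearson r, cluster
# bootstrap CIs, model-comparison tests, error-by-threshold bins and
# exam-level error correlates.

#' Pointwise MAE and Pearson correlation
#'
#' Per visual-field point: mean absolute error and the Pearson correlation of
#' predicted with measured thresholds across exams, plus their averages over
#' points. A point with zero variance in either series has an undefined r,
#' reported `NA` with a warning and excluded from the average.
#'
#' @param pred,meas n x 52 matrices (dB).
#' @param grid Optional [build_grid_24_2()] grid to attach coordinates.
#' @return Object of class `pointwise_metrics`: data frame `point`, (`x`,
#'   `y`,) `mae`, `r`, with attributes `avg_mae` and `avg_r`.
#' @export
pointwise_metrics <- function(pred, meas, grid = NULL) {
  stop_if_not(is.matrix(pred) && is.matrix(meas) &&
                all(dim(pred) == dim(meas)), "pred and meas must match in shape")
  stop_if_not(nrow(pred) >= 2, "need at least 2 exams")
  mae <- colMeans(abs(pred - meas))
  r <- colwise_cor(pred, meas)
  if (anyNA(r)) warning(sprintf(
    "correlation undefined (zero variance) at %d point(s); excluded from average",
    sum(is.na(r))))
  out <- data.frame(point = seq_along(mae), mae = mae, r = r)
  if (!is.null(grid)) out <- cbind(out[1], grid$points, out[-1])
  attr(out, "avg_mae") <- mean(mae)
  attr(out, "avg_r") <- mean(r, na.rm = TRUE)
  class(out) <- c("pointwise_metrics", "data.frame")
  out
}

#' @export
print.pointwise_metrics <- function(x, ...) {
  cat(sprintf("pointwise metrics over %d points: average MAE %.2f dB, average r %.3f\n",
              nrow(x), attr(x, "avg_mae"), attr(x, "avg_r")))
  invisible(x)
}

#' Cluster bootstrap confidence intervals
#'
#' Resamples clusters (patients) with replacement, recomputes the statistic on
#' the exams of the drawn clusters, and returns empirical 2.5/97.5 percentile
#' intervals. Clustering at the patient level respects the dependence of
#' multiple tests from the same person.
#'
#' @param stat_fn `function(idx)` returning a named numeric vector of
#'   statistics for the exams indexed by `idx` (with repetition).
#' @param cluster Cluster id per exam (e.g. patient id).
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Data frame `stat`, `est`, `lo`, `hi`, with attribute `draws`
#'   (B x n_stats matrix of resampled statistics).
#' @export
bootstrap_cis <- function(stat_fn, cluster, B = 1000, seed = 1L, conf = 0.95) {
  stop_if_not(B >= 100, "B must be >= 100")
  cl <- split(seq_along(cluster), cluster)
  stop_if_not(length(cl) >= 2, "need at least 2 clusters")
  est <- stat_fn(seq_along(cluster))
  set.seed(seed)
  draws <- matrix(NA_real_, B, length(est),
                  dimnames = list(NULL, names(est)))
  for (b in seq_len(B)) {
    pick <- sample.int(length(cl), replace = TRUE)
    draws[b, ] <- stat_fn(unlist(cl[pick], use.names = FALSE))
  }
  a <- (1 - conf) / 2
  out <- data.frame(
    stat = names(est) %||% paste0("stat", seq_along(est)),
    est = unname(est),
    lo = apply(draws, 2, quantile, a, names = FALSE),
    hi = apply(draws, 2, quantile, 1 - a, names = FALSE))
  attr(out, "draws") <- draws
  out
}

#' Garway-Heath sector summaries
#'
#' Averages predictions and measurements within each sector per exam, then
#' computes MAE and Pearson r on the sector averages — one row per sector,
#' in the conventional order (central, temporal, inferior, inferior nasal,
#' superior, superior nasal). Optionally adds cluster-bootstrap CIs.
#'
#' @param pred,meas n x 52 matrices.
#' @param sectors A [assign_gh_sectors()] result.
#' @param cluster Optional cluster ids (enables bootstrap CIs).
#' @param B,seed Bootstrap settings.
#' @return Data frame `sector`, `mae`, `r` (plus `mae_lo`/`mae_hi`/`r_lo`/
#'   `r_hi` when `cluster` is given).
#' @export
sector_metrics <- function(pred, meas, sectors, cluster = NULL,
                           B = 1000, seed = 1L) {
  idx <- sector_indices(sectors)
  stop_if_not(all(lengths(idx) > 0), "every sector must contain points")
  avg <- function(m) vapply(idx, function(i) rowMeans(m[, i, drop = FALSE]),
                            numeric(nrow(m)))
  pa <- avg(pred); ma <- avg(meas)
  one <- function(rows) {
    p <- pa[rows, , drop = FALSE]; m <- ma[rows, , drop = FALSE]
    c(setNames(colMeans(abs(p - m)), paste0("mae_", colnames(pa))),
      setNames(colwise_cor(p, m), paste0("r_", colnames(pa))))
  }
  est <- one(seq_len(nrow(pa)))
  k <- ncol(pa)
  out <- data.frame(sector = colnames(pa),
                    mae = unname(est[seq_len(k)]),
                    r = unname(est[k + seq_len(k)]))
  if (!is.null(cluster)) {
    ci <- bootstrap_cis(one, cluster, B = B, seed = seed)
    out$mae_lo <- ci$lo[seq_len(k)]; out$mae_hi <- ci$hi[seq_len(k)]
    out$r_lo <- ci$lo[k + seq_len(k)]; out$r_hi <- ci$hi[k + seq_len(k)]
  }
  out
}

#' Compare two models' correlation with the measurements
#'
#' Primary method: cluster bootstrap of the difference in average pointwise r
#' (model A minus model B), giving a percentile CI and a two-sided p-value by
#' percentile inversion. A Fisher-z statistic on the average correlations is
#' reported for reference (it ignores the within-patient dependence the
#' bootstrap respects).
#'
#' @param pred_a,pred_b,meas n x 52 matrices on the same exams.
#' @param cluster Cluster (patient) id per exam.
#' @param B,seed Bootstrap settings.
#' @return List with `diff_r`, `ci`, `p_value`, `fisher_z`, `fisher_p`,
#'   `r_a`, `r_b`.
#' @export
compare_models_correlation <- function(pred_a, pred_b, meas, cluster,
                                       B = 1000, seed = 1L) {
  stop_if_not(all(dim(pred_a) == dim(meas)) && all(dim(pred_b) == dim(meas)),
              "predictions and measurements must cover the same exams")
  avg_r <- function(p, rows) {
    mean(colwise_cor(p[rows, , drop = FALSE], meas[rows, , drop = FALSE]),
         na.rm = TRUE)
  }
  stat <- function(rows) c(diff = avg_r(pred_a, rows) - avg_r(pred_b, rows))
  ci <- bootstrap_cis(stat, cluster, B = B, seed = seed)
  draws <- attr(ci, "draws")[, "diff"]
  p <- 2 * min(mean(c(draws, 0) <= 0), mean(c(draws, 0) >= 0))
  n <- nrow(meas)
  ra <- avg_r(pred_a, seq_len(n)); rb <- avg_r(pred_b, seq_len(n))
  z <- (atanh(ra) - atanh(rb)) / sqrt(2 / (n - 3))
  list(diff_r = ci$est, ci = c(ci$lo, ci$hi), p_value = min(p, 1),
       fisher_z = z, fisher_p = 2 * pnorm(-abs(z)), r_a = ra, r_b = rb)
}

#' Compare two models' absolute errors with a random-effects model
#'
#' Fits a random-intercept (participant) linear mixed model of absolute error
#' on the model indicator, accounting for multiple tests from the same
#' participant. The coefficient is the adjusted mean difference in absolute
#' error (model B minus model A), with Satterthwaite degrees of freedom for
#' the p-value.
#'
#' @param err_a,err_b Absolute errors per exam (same length and order), e.g.
#'   each exam's mean absolute error over the 52 points.
#' @param participant Participant id per exam.
#' @return List with `estimate`, `se`, `df`, `p_value`, `ci` and the fitted
#'   `model`.
#' @export
compare_models_abs_error <- function(err_a, err_b, participant) {
  stop_if_not(length(err_a) == length(err_b) &&
                length(err_a) == length(participant),
              "err_a, err_b and participant must have equal length")
  stop_if_not(length(unique(participant)) >= 2, "need at least 2 participants")
  d <- data.frame(
    abs_error = c(err_a, err_b),
    model = factor(rep(c("A", "B"), each = length(err_a))),
    participant = factor(rep(participant, 2)))
  fit <- lmerTest::lmer(abs_error ~ model + (1 | participant), data = d,
                        REML = TRUE)
  sm <- summary(fit)$coefficients["modelB", ]
  est <- unname(sm["Estimate"]); se <- unname(sm["Std. Error"])
  list(estimate = est, se = se, df = unname(sm["df"]),
       p_value = unname(sm["Pr(>|t|)"]),
       ci = est + c(-1, 1) * qt(0.975, unname(sm["df"])) * se,
       model = fit)
}

#' MAE grouped by bins of measured threshold
#'
#' Bins every (exam, point) observation by its measured threshold and reports
#' the count and the MAE of the predictions per bin; empty bins get `NA` MAE.
#'
#' @param pred,meas n x 52 matrices.
#' @param bin_width Bin width in dB.
#' @param range Threshold range covered by the bins.
#' @return Data frame `bin_lo`, `bin_hi`, `n`, `mae`.
#' @export
mae_by_threshold_bins <- function(pred, meas, bin_width = 2, range = c(0, 40)) {
  edges <- seq(range[1], range[2], by = bin_width)
  err <- abs(as.vector(pred) - as.vector(meas))
  m <- as.vector(meas)
  bin <- cut(m, breaks = edges, include.lowest = TRUE, right = FALSE)
  n <- as.vector(table(bin))
  mae <- as.vector(tapply(err, bin, mean))
  data.frame(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
             n = n, mae = mae)
}

#' Correlates of the per-exam prediction error
#'
#' Pearson correlation (with two-sided t-approximation p-values) of each
#' exam-level covariate — e.g. mean deviation, pattern standard deviation,
#' global RNFL thickness, age, quality score — with the exam's mean absolute
#' prediction error.
#'
#' @param abs_error Per-exam mean absolute error.
#' @param covariates Data frame of per-exam covariates.
#' @return Data frame `covariate`, `r`, `p_value`.
#' @export
error_correlates <- function(abs_error, covariates) {
  stop_if_not(length(abs_error) >= 3, "need at least 3 exams")
  stop_if_not(nrow(covariates) == length(abs_error),
              "covariates must have one row per exam")
  res <- lapply(names(covariates), function(nm) {
    ct <- cor.test(abs_error, covariates[[nm]])
    data.frame(covariate = nm, r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, res)
}


#' Plot pointwise metrics on the field grid
#'
#' Grayscale map of per-point MAE (or r) at the 24-2 locations, the value
#' printed inside each square — the conventional way to show pointwise
#' model performance across the field.
#'
#' @param x A [pointwise_metrics()] result built with a `grid`.
#' @param which `"mae"` or `"r"`.
#' @param ... Unused.
#' @export
plot.pointwise_metrics <- function(x, which = c("mae", "r"), ...) {
  which <- match.arg(which)
  stop_if_not(all(c("x", "y") %in% names(x)),
              "build the metrics with a grid to plot them")
  v <- x[[which]]
  rng <- range(v, na.rm = TRUE)
  rel <- (v - rng[1]) / max(rng[2] - rng[1], 1e-12)
  if (which == "r") rel <- 1 - rel  # darker = better, as in printouts
  op <- par(mar = c(4, 4, 3, 1)); on.exit(par(op))
  plot(x$x, x$y, pch = 22, cex = 3.4, bg = gray(rel),
       xlab = "temporal field [deg]", ylab = "superior field [deg]",
       main = sprintf("pointwise %s (mean %.2f)", toupper(which),
                      mean(v, na.rm = TRUE)), asp = 1)
  text(x$x, x$y, sprintf("%.1f", v), cex = 0.45,
       col = ifelse(rel > 0.5, "white", "black"))
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Plot the threshold histogram with binned MAE
#'
#' Frequency of measured thresholds with the per-bin MAE overlaid, showing
#' where in the dynamic range the model is accurate.
#'
#' @param bins A [mae_by_threshold_bins()] result.
#' @export
plot_mae_by_threshold <- function(bins) {
  op <- par(mar = c(4, 4, 3, 4)); on.exit(par(op))
  mid <- (bins$bin_lo + bins$bin_hi) / 2
  plot(mid, bins$n, type = "h", lwd = 8, lend = 1, col = "gray70",
       xlab = "measured sensitivity [dB]", ylab = "count",
       main = "threshold frequency and binned MAE")
  ok <- !is.na(bins$mae)
  sc <- max(bins$n) / max(bins$mae[ok], 1)
  lines(mid[ok], bins$mae[ok] * sc, lty = 2, lwd = 2)
  axis(4, at = pretty(bins$mae[ok]) * sc, labels = pretty(bins$mae[ok]))
  mtext("MAE [dB]", side = 4, line = 2.5)
  invisible(bins)
}
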