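# SAP-style report derivation: total deviation against age-corrected normals,
# pattern deviation against the "general height" (the 7th-best total
# deviation), probability categories from empirical normative percentiles,
# and the global indices MD / PSD. Rendering produces a deterministic
# fixed-layout text grid similar to a perimetry printout.

#' Total deviation
#'
#' `TD_i = threshold_i − (intercept_i + slope_i · age)`: the deviation of each
#' point from its age-corrected normal value. Ages outside the range the
#' normative model was fitted on are extrapolated with a warning.
#'
#' @param thresholds 52 measured or predicted thresholds (dB).
#' @param age Age in years.
#' @param normative A [derive_normative_tables()] object.
#' @param age_range Ages considered covered by the normative fit.
#' @return 52 total-deviation values (dB).
#' @export
total_deviation <- function(thresholds, age, normative,
                            age_range = c(18, 100)) {
  am <- normative$age_model
  stop_if_not(length(thresholds) == nrow(am),
              "normative table covers %d points, got %d thresholds",
              nrow(am), length(thresholds))
  if (age < age_range[1] || age > age_range[2])
    warning("age outside normative range; extrapolating")
  thresholds - (am$intercept + am$slope * age)
}

#' Pattern deviation
#'
#' Subtracts the general height — the 7th-largest total deviation (descending
#' sort, duplicates counted, 1-based) — from every point, exposing localized
#' loss on top of any diffuse depression. Invariant under a uniform TD shift.
#'
#' @param td 52 total-deviation values.
#' @return 52 pattern-deviation values.
#' @export
pattern_deviation <- function(td) {
  stop_if_not(length(td) >= 7, "need at least 7 total-deviation values")
  gh <- sort(td, decreasing = TRUE)[7]
  td - gh
}

#' Probability categories from a percentile table
#'
#' Assigns each deviation the most extreme percentile it falls at or below
#' (boundary inclusive toward abnormal): `<0.5%`, `<1%`, `<2%`, `<5%`, else
#' `ns`.
#'
#' @param deviations 52 TD or PD values.
#' @param percentile_table 52 x 4 matrix with columns `p5`, `p2`, `p1`,
#'   `p0.5` (as in `normative_tables$td_percentiles`).
#' @return Ordered factor of categories, levels `ns < <5% < <2% < <1% < <0.5%`.
#' @export
probability_categories <- function(deviations, percentile_table) {
  stop_if_not(nrow(percentile_table) == length(deviations),
              "percentile table must cover every point")
  stop_if_not(all(c("p5", "p2", "p1", "p0.5") %in% colnames(percentile_table)),
              "percentile table needs columns p5, p2, p1, p0.5")
  lv <- c("ns", "<5%", "<2%", "<1%", "<0.5%")
  cat <- rep("ns", length(deviations))
  cat[deviations <= percentile_table[, "p5"]] <- "<5%"
  cat[deviations <= percentile_table[, "p2"]] <- "<2%"
  cat[deviations <= percentile_table[, "p1"]] <- "<1%"
  cat[deviations <= percentile_table[, "p0.5"]] <- "<0.5%"
  factor(cat, levels = lv, ordered = TRUE)
}

#' Global indices MD and PSD
#'
#' MD is the unweighted mean of the total deviations and PSD the sample
#' standard deviation of the total deviations about MD. (Proprietary
#' eccentricity weights of commercial perimeters are not reproduced; this is
#' the package's documented simplification.)
#'
#' @param td Total-deviation values.
#' @return Named list `md`, `psd` (dB).
#' @export
global_indices <- function(td) {
  stop_if_not(length(td) >= 2, "need at least 2 values")
  list(md = mean(td), psd = sd(td))
}

#' Build a full SAP-style report
#'
#' Computes total deviation, pattern deviation, TD and PD probability
#' categories (both are derived, as on commercial printouts) and the global
#' indices for one field.
#'
#' @param thresholds 52 thresholds (dB), measured or predicted.
#' @param age Age in years.
#' @param normative A [derive_normative_tables()] object.
#' @return Object of class `vf_report`.
#' @export
vf_report <- function(thresholds, age, normative) {
  td <- total_deviation(thresholds, age, normative)
  pd <- pattern_deviation(td)
  gi <- global_indices(td)
  structure(
    list(thresholds = thresholds, age_years = age,
         total_deviation = td, pattern_deviation = pd,
         td_prob = probability_categories(td, normative$td_percentiles),
         pd_prob = probability_categories(pd, normative$pd_percentiles),
         md = gi$md, psd = gi$psd),
    class = "vf_report"
  )
}

#' @export
print.vf_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

prob_symbols <- c("ns" = " .", "<5%" = " :", "<2%" = " +", "<1%" = " x",
                  "<0.5%" = " #")

# layout helpers: column index of each x position on the text grid
grid_layout <- function(grid = build_grid_24_2("right")) {
  xs <- sort(unique(c(grid$points$x, grid$blind_spot$x)))
  ys <- sort(unique(grid$points$y), decreasing = TRUE)
  list(xs = xs, ys = ys, grid = grid)
}

render_block <- function(values, lay, fmt, blank = "   ---") {
  g <- lay$grid
  lines <- character(length(lay$ys))
  for (r in seq_along(lay$ys)) {
    cells <- rep(strrep(" ", 6), length(lay$xs))
    on_row <- which(g$points$y == lay$ys[r])
    for (i in on_row) {
      cells[match(g$points$x[i], lay$xs)] <- sprintf("%6s", fmt(values[i]))
    }
    bs <- which(g$blind_spot$y == lay$ys[r])
    for (i in bs) cells[match(g$blind_spot$x[i], lay$xs)] <- blank
    lines[r] <- paste(cells, collapse = "")
  }
  lines
}

#' Render a report as a fixed-layout text printout
#'
#' Thresholds (one decimal, clamped to `[0, 50]` dB for display only), total
#' and pattern deviations, and symbol-coded probability maps
#' (`. : + x #` for `ns <5% <2% <1% <0.5%`), laid out on the 24-2 grid with
#' the blind-spot positions shown as `---`. Rendering is deterministic:
#' identical reports produce byte-identical text.
#'
#' @param report A [vf_report()].
#' @param grid A [build_grid_24_2()] grid.
#' @return Character vector of lines.
#' @export
render_report <- function(report, grid = build_grid_24_2("right")) {
  lay <- grid_layout(grid)
  num <- function(v) sprintf("%.1f", v)
  sym <- function(v) prob_symbols[[as.character(v)]]
  c(sprintf("24-2 visual field report (age %.1f y)", report$age_years),
    sprintf("MD %.2f dB   PSD %.2f dB", report$md, report$psd),
    "", "Sensitivity thresholds [dB]:",
    render_block(clamp(report$thresholds, 0, 50), lay, num),
    "", "Total deviation [dB]:",
    render_block(report$total_deviation, lay, num),
    "", "Pattern deviation [dB]:",
    render_block(report$pattern_deviation, lay, num),
    "", "TD probability:",
    render_block(report$td_prob, lay, sym, blank = " -"),
    "", "PD probability:",
    render_block(report$pd_prob, lay, sym, blank = " -"))
}

#' Parse the threshold block of a rendered report
#'
#' Inverse of the threshold section of [render_report()]: recovers the 52
#' displayed threshold values (to the rendered 0.1 dB precision) in grid
#' order.
#'
#' @param lines Character vector as returned by [render_report()].
#' @param grid The grid used for rendering.
#' @return Numeric vector of 52 thresholds.
#' @export
parse_report_text <- function(lines, grid = build_grid_24_2("right")) {
  lay <- grid_layout(grid)
  start <- which(lines == "Sensitivity thresholds [dB]:") + 1
  stop_if_not(length(start) == 1, "threshold block not found")
  block <- lines[start:(start + length(lay$ys) - 1)]
  out <- numeric(grid$n_points)
  for (r in seq_along(lay$ys)) {
    on_row <- which(grid$points$y == lay$ys[r])
    for (i in on_row) {
      col <- match(grid$points$x[i], lay$xs)
      out[i] <- as.numeric(substr(block[r], (col - 1) * 6 + 1, col * 6))
    }
  }
  out
}

#' Plot a visual-field report
#'
#' Grayscale threshold map with PD probability symbols; a minimal graphical
#' rendering of the printout.
#'
#' @param x A `vf_report`.
#' @param grid A [build_grid_24_2()] grid.
#' @param main Title.
#' @param ... Unused.
#' @export
plot.vf_report <- function(x, grid = build_grid_24_2("right"),
                           main = "Visual field report", ...) {
  pts <- grid$points
  op <- par(mar = c(4, 4, 3, 1)); on.exit(par(op))
  shade <- gray(clamp(x$thresholds, 0, 40) / 40)
  plot(pts$x, pts$y, pch = 22, cex = 3, bg = shade,
       xlab = "temporal field [deg]", ylab = "superior field [deg]",
       main = main, asp = 1)
  bad <- x$pd_prob != "ns"
  if (any(bad)) points(pts$x[bad], pts$y[bad], pch = 4, cex = 1.2, col = "red")
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report A `vf_report`.
#' @param path File path.
#' @export
write_vf_report <- function(report, path) {
  jsonlite::write_json(
    list(thresholds = report$thresholds, age_years = report$age_years,
         total_deviation = report$total_deviation,
         pattern_deviation = report$pattern_deviation,
         td_prob = as.character(report$td_prob),
         pd_prob = as.character(report$pd_prob),
         md = report$md, psd = report$psd),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
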