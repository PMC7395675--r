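# Structure-function map assembly: push every simulated defect profile
# through a trained predictor, derive the SAP-style report for each, and
# collect the results into one map object, ordered by sector start angle
# (temporal -> superior -> nasal -> inferior) and shallow-to-deep within a
# sector.

#' Build a structure-function map from simulated defects
#'
#' Enumerates the 12 x |depths| defect simulations on the base profile,
#' predicts each simulated profile's visual field with the given model, and
#' derives a full report (TD, PD, probability categories, MD/PSD) for every
#' entry. Deterministic given model and tables.
#'
#' @param model Any predictor with a `predict(model, profiles)` method
#'   returning 52 thresholds per profile (a trained [build_cnn()] network, a
#'   [fit_linear_baseline()] model, or [forward_model_predictor()]).
#' @param base 768-point base profile (healthy mean).
#' @param normative A [derive_normative_tables()] object (supplies the
#'   glaucoma percentile profiles and the deviation percentiles).
#' @param depths Percentile depths (default `c(10, 5, 1)`).
#' @param age Age at which reports are derived (years).
#' @param sector_width Defect sector width (degrees).
#' @return Object of class `sf_map`: list of entries, each with `spec`,
#'   `profile`, `thresholds` and `report`; attributes `base`, `age`.
#' @export
build_sf_map <- function(model, base, normative, depths = c(10, 5, 1),
                         age = 63, sector_width = 30) {
  stop_if_not(length(base) == 768, "base profile must have 768 samples")
  sims <- enumerate_simulations(base, normative$glaucoma_percentiles,
                                sector_width = sector_width, depths = depths)
  profiles <- do.call(rbind, lapply(sims, `[[`, "profile"))
  preds <- predict(model, profiles)
  stop_if_not(ncol(preds) == nrow(normative$td_percentiles),
              "model output does not match the grid")
  entries <- lapply(seq_along(sims), function(i) {
    list(spec = sims[[i]]$spec, profile = sims[[i]]$profile,
         thresholds = preds[i, ],
         report = vf_report(preds[i, ], age, normative))
  })
  structure(entries, class = "sf_map", base = base, age = age)
}

#' @export
print.sf_map <- function(x, ...) {
  ab <- abnormal_counts(x)
  cat(sprintf("structure-function map: %d entries (%d sectors x %d depths); abnormal PD points per entry: %d-%d\n",
              length(x), length(unique(ab$sector_start)),
              length(unique(ab$depth)), min(ab$n_abnormal), max(ab$n_abnormal)))
  invisible(x)
}

#' Abnormal-point counts of an SF map
#'
#' An "abnormal" point is one whose pattern-deviation probability category is
#' worse than `ns` (i.e. below the 5% normative percentile).
#'
#' @param map An `sf_map`.
#' @return Data frame `sector_start`, `sector_end`, `depth`, `n_abnormal`.
#' @export
abnormal_counts <- function(map) {
  do.call(rbind, lapply(map, function(e) {
    data.frame(sector_start = e$spec$sector_start_deg,
               sector_end = e$spec$sector_end_deg,
               depth = e$spec$depth_percentile,
               n_abnormal = sum(e$report$pd_prob != "ns"))
  }))
}

abnormal_set <- function(entry) which(entry$report$pd_prob != "ns")

#' Compare two structure-function maps
#'
#' For each (sector, depth) entry, counts the abnormal PD points of each map
#' and their set relations: points abnormal in A only, in B only, and in
#' both. The two maps must enumerate the same defect specifications.
#'
#' @param map_a,map_b `sf_map` objects over the same enumeration.
#' @return Data frame with one row per entry: `sector_start`, `depth`,
#'   `n_a`, `n_b`, `both`, `a_only`, `b_only`.
#' @export
compare_maps <- function(map_a, map_b) {
  stop_if_not(length(map_a) == length(map_b), "maps enumerate different sets")
  do.call(rbind, lapply(seq_along(map_a), function(i) {
    sa <- map_a[[i]]$spec; sb <- map_b[[i]]$spec
    stop_if_not(sa$sector_start_deg == sb$sector_start_deg &&
                  sa$depth_percentile == sb$depth_percentile,
                "maps enumerate different defect specs")
    a <- abnormal_set(map_a[[i]]); b <- abnormal_set(map_b[[i]])
    data.frame(sector_start = sa$sector_start_deg,
               depth = sa$depth_percentile,
               n_a = length(a), n_b = length(b),
               both = length(intersect(a, b)),
               a_only = length(setdiff(a, b)),
               b_only = length(setdiff(b, a)))
  }))
}

#' Serialize an SF map to JSON
#'
#' @param map An `sf_map`.
#' @param path File path.
#' @export
write_sf_map <- function(map, path) {
  jsonlite::write_json(
    lapply(map, function(e) list(
      spec = unclass(e$spec),
      profile = e$profile,
      thresholds = e$thresholds,
      pattern_deviation = e$report$pattern_deviation,
      pd_prob = as.character(e$report$pd_prob),
      md = e$report$md, psd = e$report$psd)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Plot a structure-function map
#'
#' Rows are defect sectors, columns depths; the left column shows the
#' simulated profile with dashed sector boundaries, the right columns the
#' pattern-deviation probability plots — the conventional layout for this
#' kind of map.
#'
#' @param x An `sf_map`.
#' @param sectors_per_page Rows per page.
#' @param ... Unused.
#' @export
plot.sf_map <- function(x, sectors_per_page = 6, ...) {
  ab <- abnormal_counts(x)
  starts <- unique(ab$sector_start)
  depths <- unique(ab$depth)
  grid <- build_grid_24_2("right")
  theta <- rnfl_angles()
  base <- attr(x, "base")
  for (page in split(starts, ceiling(seq_along(starts) / sectors_per_page))) {
    op <- par(mfrow = c(length(page), length(depths) + 1),
              mar = c(2, 2, 2, 0.5))
    for (s in page) {
      entries <- x[vapply(x, function(e) e$spec$sector_start_deg == s, TRUE)]
      plot(theta, entries[[length(entries)]]$profile, type = "l",
           ylim = c(0, max(base) * 1.05), xlab = "", ylab = "",
           main = sprintf("%g-%g deg", s, s + (entries[[1]]$spec$sector_end_deg -
                                                 entries[[1]]$spec$sector_start_deg)))
      lines(theta, base, lty = 3)
      abline(v = c(s, entries[[1]]$spec$sector_end_deg), lty = 2)
      for (e in entries) {
        bad <- e$report$pd_prob != "ns"
        plot(grid$points$x, grid$points$y, pch = 22, cex = 1.2,
             bg = ifelse(bad, "black", "white"),
             main = sprintf("p%g", e$spec$depth_percentile),
             xlab = "", ylab = "", asp = 1)
        abline(h = 0, lty = 3)
      }
    }
    par(op)
  }
  invisible(x)
}
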