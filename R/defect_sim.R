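# Localized defect simulation: carve 30-degree wedge defects of population
# percentile depth into the normal average profile. Edges are abrupt (a step
# at the sector boundary); sector membership is half-open [start, end) so the
# 12 default sectors partition the 768 indices exactly.

#' Specification of a simulated localized defect
#'
#' @param sector_start_deg,sector_end_deg Half-open angular interval
#'   `[start, end)` in degrees (defaults are multiples of 30).
#' @param depth_percentile Depth as a glaucoma-population percentile:
#'   one of 10, 5, 1.
#' @return Object of class `defect_spec`.
#' @export
defect_spec <- function(sector_start_deg, sector_end_deg,
                        depth_percentile = c(10, 5, 1)) {
  q <- depth_percentile[1]
  stop_if_not(q %in% c(10, 5, 1), "depth percentile must be one of 10, 5, 1")
  stop_if_not(sector_start_deg >= 0 && sector_start_deg <= sector_end_deg &&
                sector_end_deg <= 360,
              "need 0 <= start <= end <= 360")
  structure(list(sector_start_deg = sector_start_deg,
                 sector_end_deg = sector_end_deg,
                 depth_percentile = q),
            class = "defect_spec")
}

#' @export
print.defect_spec <- function(x, ...) {
  cat(sprintf("defect [%g, %g) deg at p%g depth\n", x$sector_start_deg,
              x$sector_end_deg, x$depth_percentile))
  invisible(x)
}

#' Pointwise mean profile of healthy exams
#'
#' @param x A `paired_cohort` of healthy exams or an n x 768 matrix.
#' @return 768-vector, the pointwise mean.
#' @export
healthy_mean_profile <- function(x) {
  m <- if (inherits(x, "paired_cohort")) x$rnfl else x
  stop_if_not(is.matrix(m) && nrow(m) >= 1, "need at least one exam")
  colMeans(m)
}

#' Carve a localized defect into a profile
#'
#' Samples whose angle falls in `[start, end)` are replaced by
#' `min(base, P_q)` where `P_q` is the glaucoma percentile profile of the
#' requested depth; all other samples are untouched and the edges are abrupt.
#' The `min` guard means a percentile lying above the base can never thicken
#' the profile. Never increases any value.
#'
#' @param base 768-point base profile (µm), e.g. [healthy_mean_profile()].
#' @param spec A [defect_spec()].
#' @param percentile_profiles 768 x k matrix with columns named `p10`, `p5`,
#'   `p1` (as in `normative_tables$glaucoma_percentiles`).
#' @return The modified 768-point profile.
#' @export
simulate_defect <- function(base, spec, percentile_profiles) {
  stop_if_not(inherits(spec, "defect_spec"), "spec must be a defect_spec")
  col <- paste0("p", spec$depth_percentile)
  stop_if_not(col %in% colnames(percentile_profiles),
              "percentile profile %s not available", col)
  theta <- rnfl_angles(length(base))
  k <- theta >= spec$sector_start_deg & theta < spec$sector_end_deg
  out <- base
  out[k] <- pmin(base[k], percentile_profiles[k, col])
  out
}

#' Enumerate the full set of simulated defect profiles
#'
#' One profile per (sector, depth): sectors of the given width starting at 0°
#' and proceeding temporal -> superior -> nasal -> inferior, each at every
#' requested percentile depth (shallow to deep within a sector).
#'
#' @param base 768-point base profile.
#' @param percentile_profiles As in [simulate_defect()].
#' @param sector_width Sector width in degrees; must divide 360.
#' @param depths Percentile depths (default `c(10, 5, 1)`).
#' @return List of class `defect_simulations`; each element has `spec` and
#'   `profile`.
#' @export
enumerate_simulations <- function(base, percentile_profiles,
                                  sector_width = 30, depths = c(10, 5, 1)) {
  stop_if_not(360 %% sector_width == 0, "sector width must divide 360")
  starts <- seq(0, 360 - sector_width, by = sector_width)
  sims <- list()
  for (s in starts) {
    for (q in depths) {
      spec <- defect_spec(s, s + sector_width, q)
      sims[[length(sims) + 1]] <- list(
        spec = spec,
        profile = simulate_defect(base, spec, percentile_profiles))
    }
  }
  structure(sims, class = "defect_simulations", base = base)
}

#' @export
print.defect_simulations <- function(x, ...) {
  cat(sprintf("%d simulated defect profiles\n", length(x)))
  invisible(x)
}

#' Match a real profile to its closest simulated defect
#'
#' Returns the simulation minimizing the chosen distance to the given profile;
#' ties break toward the first simulation in enumeration order.
#'
#' @param profile A 768-point profile.
#' @param sims A [enumerate_simulations()] list.
#' @param metric `"rmse"` (default) or `"mae"`.
#' @return List with `spec`, `profile`, `distance` and `index`.
#' @export
match_real_to_simulated <- function(profile, sims, metric = c("rmse", "mae")) {
  metric <- match.arg(metric)
  stop_if_not(length(sims) > 0, "no simulations supplied")
  dist <- vapply(sims, function(s) {
    d <- profile - s$profile
    if (metric == "rmse") sqrt(mean(d^2)) else mean(abs(d))
  }, numeric(1))
  i <- which.min(dist)  # which.min takes the first minimum: enumeration order
  list(spec = sims[[i]]$spec, profile = sims[[i]]$profile,
       distance = dist[i], index = i)
}
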