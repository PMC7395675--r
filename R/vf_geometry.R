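# 24-2 test-point geometry, blind-spot exclusion, laterality handling and
# Garway-Heath sector assignment. Everything downstream indexes visual-field
# points by the fixed order defined here: rows from superior (y = +21) to
# inferior (y = -21), and within each row from nasal (most negative x) to
# temporal, in right-eye convention (positive x = temporal field, positive
# y = superior field).

#' Build the 24-2 visual-field test grid
#'
#' Constructs the 54 candidate locations of the 24-2 pattern (6° spacing with a
#' 3° offset from the meridians; rows at y = ±21, ±15, ±9, ±3 with 4, 6, 8 and
#' 9 points respectively, the ±3 rows extending nasally to 27°) and removes the
#' two locations adjacent to the blind spot, at (15, ±3) in right-eye
#' convention, leaving the 52 analysed points. A left-eye grid is the mirror
#' image (x negated) with the same point order, so indices align anatomically
#' across eyes.
#'
#' @param eye `"right"` or `"left"`.
#' @param exclude_blind_spot Drop the two blind-spot points (default `TRUE`;
#'   set `FALSE` to inspect the full 54-point pattern).
#' @return An object of class `vf_grid`: list with `points` (data frame of
#'   `x`, `y` in degrees, in the fixed order), `blind_spot` (the excluded
#'   locations), `n_points` and `eye`.
#' @export
#' @examples
#' g <- build_grid_24_2("right")
#' g$n_points  # 52
build_grid_24_2 <- function(eye = c("right", "left"), exclude_blind_spot = TRUE) {
  eye <- match.arg(eye)
  rows <- list(
    `21`  = seq(-9, 9, by = 6),
    `15`  = seq(-15, 15, by = 6),
    `9`   = seq(-21, 21, by = 6),
    `3`   = seq(-27, 21, by = 6),
    `-3`  = seq(-27, 21, by = 6),
    `-9`  = seq(-21, 21, by = 6),
    `-15` = seq(-15, 15, by = 6),
    `-21` = seq(-9, 9, by = 6)
  )
  pts <- do.call(rbind, lapply(names(rows), function(yy) {
    data.frame(x = rows[[yy]], y = as.numeric(yy))
  }))
  bs <- pts$x == 15 & abs(pts$y) == 3
  blind <- pts[bs, , drop = FALSE]
  if (exclude_blind_spot) pts <- pts[!bs, , drop = FALSE]
  if (eye == "left") {
    pts$x <- -pts$x
    blind$x <- -blind$x
  }
  rownames(pts) <- NULL
  structure(
    list(points = pts, blind_spot = blind, n_points = nrow(pts), eye = eye),
    class = "vf_grid"
  )
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf("24-2 visual-field grid (%s eye): %d points%s\n",
              x$eye, x$n_points,
              if (nrow(x$blind_spot) > 0 && x$n_points == 52)
                ", blind-spot points excluded" else ""))
  invisible(x)
}

#' Garway-Heath sector configuration
#'
#' Reads the per-point sector table mapping each of the 52 grid points to one
#' of the six Garway-Heath field regions (`central`, `temporal`, `superior`,
#' `superior_nasal`, `inferior`, `inferior_nasal`) and to an optic-disc entry
#' angle (degrees, TSNIT convention) used by the synthetic forward model. The
#' shipped default encodes a reconstruction of the published map; the exact
#' per-point assignment used clinically is not printed anywhere, so the table
#' is deliberately an editable YAML config rather than code.
#'
#' @param path YAML file; defaults to the configuration shipped with the
#'   package.
#' @return Data frame with columns `x`, `y`, `sector`, `disc_angle`.
#' @seealso [assign_gh_sectors()]
#' @export
read_sector_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gh_sectors.yaml", package = "oct2vf")
  }
  stop_if_not(nzchar(path) && file.exists(path),
              "sector config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(cfg$points, function(p) {
    data.frame(x = p$x, y = p$y, sector = p$sector, disc_angle = p$disc_angle)
  }))
  validate_sector_table(tab)
  tab
}

#' @rdname read_sector_config
#' @param table Sector table as returned by [read_sector_config()].
#' @export
write_sector_config <- function(table, path) {
  validate_sector_table(table)
  pts <- lapply(seq_len(nrow(table)), function(i) {
    list(x = table$x[i], y = table$y[i],
         sector = table$sector[i], disc_angle = table$disc_angle[i])
  })
  yaml::write_yaml(list(points = pts), path)
  invisible(path)
}

gh_sector_levels <- c("central", "temporal", "inferior", "inferior_nasal",
                      "superior", "superior_nasal")

validate_sector_table <- function(tab) {
  stop_if_not(all(c("x", "y", "sector", "disc_angle") %in% names(tab)),
              "sector table must have columns x, y, sector, disc_angle")
  stop_if_not(all(tab$sector %in% gh_sector_levels),
              "unknown sector label(s): %s",
              paste(setdiff(tab$sector, gh_sector_levels), collapse = ", "))
  stop_if_not(all(tab$disc_angle >= 0 & tab$disc_angle < 360),
              "disc angles must lie in [0, 360)")
  invisible(tab)
}

#' Assign Garway-Heath sectors to the grid
#'
#' Matches every grid point to exactly one row of the sector table (a
#' partition: uncovered or doubly covered points are an error) and returns the
#' per-point labels together with the disc entry angles. Left-eye grids are
#' first reflected into right-eye convention, on which the table is defined.
#'
#' @param grid A [build_grid_24_2()] grid.
#' @param table Sector table; defaults to the shipped configuration.
#' @return Object of class `gh_sectors`: data frame `point`, `x`, `y`,
#'   `sector` (factor over the six labels), `disc_angle`.
#' @export
assign_gh_sectors <- function(grid, table = read_sector_config()) {
  stop_if_not(inherits(grid, "vf_grid"), "grid must be a vf_grid")
  validate_sector_table(table)
  pts <- grid$points
  if (grid$eye == "left") pts$x <- -pts$x
  key_g <- paste(pts$x, pts$y)
  key_t <- paste(table$x, table$y)
  stop_if_not(!anyDuplicated(key_t),
              "sector table covers some point more than once")
  idx <- match(key_g, key_t)
  stop_if_not(!anyNA(idx), "sector table does not cover grid point(s): %s",
              paste(key_g[is.na(idx)], collapse = "; "))
  out <- data.frame(
    point = seq_len(nrow(pts)),
    x = grid$points$x, y = grid$points$y,
    sector = factor(table$sector[idx], levels = gh_sector_levels),
    disc_angle = table$disc_angle[idx]
  )
  class(out) <- c("gh_sectors", "data.frame")
  out
}

#' Indices of grid points in each Garway-Heath sector
#'
#' @param sectors A [assign_gh_sectors()] result.
#' @return Named list of integer vectors, one per sector label.
#' @export
sector_indices <- function(sectors) {
  stop_if_not(inherits(sectors, "gh_sectors"), "need a gh_sectors object")
  split(sectors$point, sectors$sector)
}

# ---- Laterality -------------------------------------------------------------

#' Reflect measurements into right-eye convention
#'
#' All analysis in the package is done in right-eye convention; left-eye exams
#' are mirrored on ingest. For a visual field, the left-eye point at (x, y)
#' maps to the right-eye point at (-x, y) (values are permuted accordingly; the
#' blind-spot exclusion is mirror-symmetric so the mapping is a bijection).
#' For an RNFL profile, the angular order is reflected about the 0°/180° axis:
#' sample index k (0-based) maps to (n - k) mod n, so a left-eye peak at 80°
#' appears at 280° after mirroring. Mirroring is an involution; right-eye
#' input is returned unchanged.
#'
#' @param values For `mirror_vf_to_right`, a vector of 52 thresholds or a
#'   matrix with 52 columns in grid order; for `mirror_rnfl_to_right`, a
#'   768-vector or matrix with 768 columns.
#' @param eye `"right"` or `"left"`; the laterality the values are tagged with.
#' @return Values in right-eye convention, same shape as the input.
#' @export
mirror_vf_to_right <- function(values, eye) {
  stop_if_not(!missing(eye) && eye %in% c("right", "left"),
              "laterality must be \"right\" or \"left\"")
  if (eye == "right") return(values)
  right <- build_grid_24_2("right")$points
  left <- build_grid_24_2("left")$points
  # left point i lands on the right-eye position (-x, y)
  perm <- match(paste(-left$x, left$y), paste(right$x, right$y))
  stop_if_not(!anyNA(perm), "internal: blind-spot mirror mismatch")
  if (is.matrix(values)) {
    stop_if_not(ncol(values) == nrow(right), "expected 52 columns")
    out <- values
    out[, perm] <- values
    out
  } else {
    stop_if_not(length(values) == nrow(right), "expected 52 values")
    out <- values
    out[perm] <- values
    out
  }
}

#' @rdname mirror_vf_to_right
#' @export
mirror_rnfl_to_right <- function(values, eye) {
  stop_if_not(!missing(eye) && eye %in% c("right", "left"),
              "laterality must be \"right\" or \"left\"")
  if (eye == "right") return(values)
  n <- if (is.matrix(values)) ncol(values) else length(values)
  k <- seq_len(n) - 1
  perm <- ((n - k) %% n) + 1
  if (is.matrix(values)) values[, perm, drop = FALSE] else values[perm]
}
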