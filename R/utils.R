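# Internal helpers shared across modules.

# Smallest absolute angular difference on the circle, in degrees.
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Angles (degrees) of the n peripapillary samples, TSNIT convention:
# index k (0-based) sits at k * 360 / n; 0 = temporal, 90 = superior,
# 180 = nasal, 270 = inferior (right-eye).

#' Sample angles of the peripapillary circle scan
#'
#' Angle (degrees) of each of the `n` evenly spaced RNFL thickness samples on
#' the peripapillary circle, in TSNIT convention: 0° temporal, 90° superior,
#' 180° nasal, 270° inferior (right-eye).
#'
#' @param n Number of samples on the circle (default 768).
#' @return Numeric vector of length `n` with angles in `[0, 360)`.
#' @export
#' @examples
#' rnfl_angles()[c(1, 193, 385, 577)]  # temporal, superior, nasal, inferior
rnfl_angles <- function(n = 768L) {
  (seq_len(n) - 1) * 360 / n
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Column-wise Pearson correlation between two matrices of equal shape;
# columns with zero variance in either matrix come back NA.
colwise_cor <- function(a, b) {
  vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
}
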