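# Angular conventions used throughout: degrees, counter-clockwise positive,
# 0 deg = rightward screen direction. Differences are wrapped into (-180, 180].

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(350, -190, 180, 540))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Signed angular difference a - b wrapped into (-180, 180]
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return wrapped signed difference in degrees.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

#' Reach angle from raw screen coordinates
#'
#' Signed angle between the start-to-target line and the start-to-hand line at
#' the moment the hand crosses the target's radial distance. Counter-clockwise
#' positive, wrapped into (-180, 180].
#'
#' @param start,target,crossing numeric length-2 vectors (x, y) or two-column
#'   matrices with one row per trial.
#' @return reach angle(s) in degrees.
#' @examples
#' reach_angle(c(0, 0), c(1, 0), c(1, 1))  # +45
#' @export
reach_angle <- function(start, target, crossing) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2)
  s <- as_mat(start); tg <- as_mat(target); cr <- as_mat(crossing)
  vt <- cbind(tg[, 1] - s[, 1], tg[, 2] - s[, 2])
  vh <- cbind(cr[, 1] - s[, 1], cr[, 2] - s[, 2])
  if (any(rowSums(vt^2) == 0) || any(rowSums(vh^2) == 0))
    stop("degenerate (zero-length) vector: start coincides with target or crossing point")
  a_t <- atan2(vt[, 2], vt[, 1]) * 180 / pi
  a_h <- atan2(vh[, 2], vh[, 1]) * 180 / pi
  wrap_angle(a_h - a_t)
}

# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. seed = NULL runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
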