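#' Angle and coordinate conventions
#'
#' All user-facing angles in cilquant are in degrees. Signed angles (collision
#' angles, redirect angles) live in the half-open interval (-180, 180] with
#' counterclockwise positive in the standard Cartesian frame (x right, y up).
#' Perimeter angles index the cell boundary as 0..359 degrees, 0 along +x,
#' increasing counterclockwise.
#'
#' Image arrays are `matrix[row, col]` with row 1 at the top, as returned by
#' [tiff::readTIFF()]. The package converts to the Cartesian frame by flipping
#' the row axis: a pixel at `(row, col)` has `x = col`, `y = -row` up to a
#' constant, so the point at angle `theta` and radius `r` from a center
#' `(cx, cy)` (in col/row units) is `col = cx + r*cos(theta)`,
#' `row = cy - r*sin(theta)`. Every function in the package goes through the
#' helpers documented here, so the convention is defined exactly once.
#'
#' @name angle-conventions
#' @keywords internal
NULL

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped into the signed convention (-180, 180].
#' @examples
#' wrap_angle_deg(c(0, 190, -180, 540))
#' @export
wrap_angle_deg <- function(deg) {
  w <- deg %% 360
  ifelse(w > 180, w - 360, w)
}

# unit direction for a perimeter/heading angle, in (dx_col, dy_row) image steps
angle_to_image_step <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  cbind(dx = cos(t), dy = -sin(t))
}

# angle (deg in [0, 360)) of image offsets measured y-up
image_offset_to_angle <- function(dx_col, dy_row) {
  (rad2deg(atan2(-dy_row, dx_col))) %% 360
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate expr with a temporary RNG state seeded by `seed`; restores the
# caller's .Random.seed so generators behave as pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
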