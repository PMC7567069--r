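#' Cell track objects
#'
#' A track is one cell's time-stamped 2D trajectory: a data frame with columns
#' `frame` (strictly increasing integers), `x` and `y` (micrometres), plus
#' attributes `track_id` and `dt` (seconds per frame, default 15, the frame
#' interval of the live recordings this package targets).
#'
#' @param frame integer vector of frame indices, strictly increasing.
#' @param x,y numeric coordinates in micrometres.
#' @param track_id identifier for the cell.
#' @param dt frame interval in seconds (> 0).
#' @return an object of class `cil_track` (a data frame).
#' @examples
#' trk <- cil_track(1:3, x = c(0, 1, 2), y = c(0, 0, 0))
#' directionality_ratio(trk)
#' @export
cil_track <- function(frame, x, y, track_id = "cell", dt = 15) {
  if (length(frame) < 2L) stopf("a track needs at least 2 points")
  if (length(x) != length(frame) || length(y) != length(frame)) {
    stopf("frame, x, y must have equal length")
  }
  if (!all(is.finite(frame)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stopf("track '%s': non-finite frame or coordinate values", track_id)
  }
  if (any(diff(frame) <= 0)) {
    stopf("track '%s': frames must be strictly increasing", track_id)
  }
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be > 0")
  out <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                    y = as.numeric(y))
  attr(out, "track_id") <- as.character(track_id)
  attr(out, "dt") <- dt
  class(out) <- c("cil_track", "data.frame")
  out
}

#' @export
print.cil_track <- function(x, ...) {
  cat(sprintf("<cil_track '%s': %d points, dt = %g s, span %.1f x %.1f um>\n",
              attr(x, "track_id"), nrow(x), attr(x, "dt"),
              diff(range(x$x)), diff(range(x$y))))
  invisible(x)
}

track_dt <- function(track) {
  dt <- attr(track, "dt")
  if (is.null(dt)) 15 else dt
}

track_id <- function(track) {
  id <- attr(track, "track_id")
  if (is.null(id)) "cell" else id
}

# position (x, y) at a given frame; exact match required
track_pos <- function(track, frame) {
  i <- match(frame, track$frame)
  if (is.na(i)) return(NULL)
  c(track$x[i], track$y[i])
}

#' Combine tracks into one long table
#'
#' @param tracks a list of [cil_track()] objects.
#' @return a data frame with columns `track_id, frame, x_um, y_um`.
#' @export
tracks_to_table <- function(tracks) {
  if (inherits(tracks, "cil_track")) tracks <- list(tracks)
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = track_id(tr), frame = tr$frame,
               x_um = tr$x, y_um = tr$y)
  }))
}
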