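#' Directionality ratio d/D of a trajectory
#'
#' The standard persistence measure of single-cell migration: `d`, the linear
#' start-to-end distance, divided by `D`, the total path length along
#' consecutive recorded points. 1 means perfectly straight migration. Tracks
#' with zero path length are flagged degenerate and given ratio 0.
#'
#' @param track a [cil_track()].
#' @param max_duration_s optional assay-duration filter: only points within
#'   this many seconds of the first point are used (e.g. 3600 for the
#'   one-hour single-cell assay).
#' @return a list with `d` (um), `D` (um), `ratio`, `duration` (s) and
#'   `degenerate` (TRUE when D = 0).
#' @examples
#' directionality_ratio(cil_track(1:3, c(0, 1, 1), c(0, 0, 1)))$ratio
#' @export
directionality_ratio <- function(track, max_duration_s = NULL) {
  stopifnot(inherits(track, "cil_track"))
  dt <- track_dt(track)
  if (!is.null(max_duration_s)) {
    keep <- (track$frame - track$frame[1]) * dt <= max_duration_s
    if (sum(keep) < 2L) stopf("duration filter leaves < 2 points")
    track <- track[keep, ]
  }
  n <- nrow(track)
  d <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  D <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  degenerate <- D == 0
  list(d = d, D = D, ratio = if (degenerate) 0 else d / D,
       duration = (track$frame[n] - track$frame[1]) * dt,
       degenerate = degenerate)
}

#' Closure progress of a migrating tissue edge
#'
#' Distance of a tracked leading-edge point from its starting position at
#' each frame. If the opposing edge's track is supplied, the closure frame is
#' the first frame at which the two edges approach within `contact_tol_um`.
#'
#' @param edge_track a [cil_track()] of the leading-edge point.
#' @param opposing_track optional [cil_track()] of the opposing edge, on the
#'   same frames.
#' @param contact_tol_um edge-contact tolerance in um.
#' @return a `closure_series`: data frame `frame`, `progress` (um) with
#'   attributes `closure_frame` (integer or NA) and `dt`.
#' @export
closure_progress <- function(edge_track, opposing_track = NULL,
                             contact_tol_um = 2) {
  stopifnot(inherits(edge_track, "cil_track"))
  prog <- sqrt((edge_track$x - edge_track$x[1])^2 +
               (edge_track$y - edge_track$y[1])^2)
  closure <- NA_integer_
  if (!is.null(opposing_track)) {
    common <- intersect(edge_track$frame, opposing_track$frame)
    i <- match(common, edge_track$frame)
    j <- match(common, opposing_track$frame)
    gap <- sqrt((edge_track$x[i] - opposing_track$x[j])^2 +
                (edge_track$y[i] - opposing_track$y[j])^2)
    hit <- which(gap <= contact_tol_um)
    if (length(hit)) closure <- as.integer(common[hit[1]])
  }
  out <- data.frame(frame = edge_track$frame, progress = prog)
  attr(out, "closure_frame") <- closure
  attr(out, "dt") <- track_dt(edge_track)
  attr(out, "series_id") <- track_id(edge_track)
  class(out) <- c("closure_series", "data.frame")
  out
}

#' Align closure series to a common closure time
#'
#' Shifts each series' time axis so that closure occurs at aligned time 0,
#' the way time-to-close plots from different recordings are superimposed.
#' Frames where a series has no observation are padded with NA.
#'
#' @param series a list of `closure_series`, each with its `closure_frame`
#'   attribute set (see [closure_progress()] / [simulate_closure()]).
#' @return a data frame whose first column `t_aligned` is frames relative to
#'   closure (0 = closure) and one progress column per series.
#' @export
align_to_closure <- function(series) {
  if (inherits(series, "closure_series")) series <- list(series)
  ids <- vapply(seq_along(series), function(i) {
    id <- attr(series[[i]], "series_id")
    if (is.null(id)) sprintf("series%02d", i) else id
  }, character(1))
  for (i in seq_along(series)) {
    cf <- attr(series[[i]], "closure_frame")
    if (is.null(cf) || is.na(cf)) {
      stopf("series '%s' has no closure_frame; cannot align", ids[i])
    }
  }
  shifted <- lapply(series, function(s) {
    data.frame(t_aligned = s$frame - attr(s, "closure_frame"),
               progress = s$progress)
  })
  t_all <- sort(unique(unlist(lapply(shifted, `[[`, "t_aligned"))))
  out <- data.frame(t_aligned = t_all)
  for (i in seq_along(shifted)) {
    out[[ids[i]]] <- shifted[[i]]$progress[match(t_all, shifted[[i]]$t_aligned)]
  }
  out
}
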