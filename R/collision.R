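#' Annotated collision event
#'
#' Pairs a track with an annotated cell-cell contact: the contact frame and
#' (optionally) the contact point. Displacements over a window (default
#' 300 s = 5 min, i.e. 20 frames at the 15-s frame interval) before and after
#' contact quantify the cell's response.
#'
#' @param track a [cil_track()].
#' @param contact_frame frame index of first contact.
#' @param contact_point optional `(x, y)` contact location, um.
#' @param window analysis window in seconds on each side of contact.
#' @return a `collision_event` list.
#' @export
collision_event <- function(track, contact_frame, contact_point = NULL,
                            window = 300) {
  stopifnot(inherits(track, "cil_track"))
  if (window <= 0) stopf("window must be > 0")
  ev <- structure(list(track = track, contact_frame = as.integer(contact_frame),
                       contact_point = contact_point, window = window),
                  class = "collision_event")
  pre_post_vectors(ev)  # validate frame availability up front
  ev
}

# locate the row matching `frame`, or the closest frame within one frame's
# tolerance on the stated side ("earlier" for pre, "later" for post)
nearest_frame_idx <- function(track, frame, side) {
  i <- match(frame, track$frame)
  if (!is.na(i)) return(list(idx = i, substituted = FALSE))
  cand <- if (side == "earlier") {
    which(track$frame < frame & track$frame >= frame - 1L)
  } else {
    which(track$frame > frame & track$frame <= frame + 1L)
  }
  if (length(cand)) {
    return(list(idx = if (side == "earlier") max(cand) else min(cand),
                substituted = TRUE))
  }
  NULL
}

#' Pre- and post-contact displacement vectors
#'
#' Net displacements over the window on each side of contact:
#' `pre = p(contact) - p(contact - w)`, `post = p(contact + w) - p(contact)`
#' with `w = window / dt` frames. When the exact outer frame was not
#' recorded, the closest frame within one frame's tolerance is used and
#' flagged.
#'
#' @param event a [collision_event()].
#' @return list with `pre`, `post` (length-2 um vectors), `window_frames`,
#'   `substituted` (logical: a tolerance frame was used) and `degenerate`
#'   (TRUE when either displacement is zero).
#' @export
pre_post_vectors <- function(event) {
  stopifnot(inherits(event, "collision_event"))
  tr <- event$track
  w <- round(event$window / track_dt(tr))
  cf <- event$contact_frame
  ic <- match(cf, tr$frame)
  if (is.na(ic)) stopf("contact_frame %d not present in track '%s'",
                       cf, track_id(tr))
  ipre <- nearest_frame_idx(tr, cf - w, "earlier")
  if (is.null(ipre)) {
    stopf("track '%s': no frame near %d on the pre side (need %d frames before contact)",
          track_id(tr), cf - w, w)
  }
  ipost <- nearest_frame_idx(tr, cf + w, "later")
  if (is.null(ipost)) {
    stopf("track '%s': no frame near %d on the post side (need %d frames after contact)",
          track_id(tr), cf + w, w)
  }
  pc <- c(tr$x[ic], tr$y[ic])
  pre <- pc - c(tr$x[ipre$idx], tr$y[ipre$idx])
  post <- c(tr$x[ipost$idx], tr$y[ipost$idx]) - pc
  list(pre = pre, post = post, window_frames = w,
       substituted = ipre$substituted || ipost$substituted,
       degenerate = all(pre == 0) || all(post == 0))
}

#' Signed collision angle
#'
#' The angle from the incident (pre-contact) direction to the departing
#' (post-contact) direction, degrees in (-180, 180], counterclockwise
#' positive. 0 means the cell kept going; +/-180 means it reversed.
#'
#' @param pre,post length-2 displacement vectors (um).
#' @return signed angle in degrees.
#' @examples
#' collision_angle(c(1, 0), c(0, 1))  # +90
#' @export
collision_angle <- function(pre, post) {
  if (all(pre == 0) || all(post == 0)) {
    stopf("collision_angle: zero displacement vector")
  }
  wrap_angle_deg(rad2deg(atan2(post[2], post[1]) - atan2(pre[2], pre[1])))
}

#' Post/pre velocity ratio
#'
#' Ratio of net displacement magnitudes over the post- and pre-contact
#' windows (both windows have equal duration, so this is the speed ratio).
#' A vanishing pre-contact displacement makes the ratio undefined; the
#' result is NA with `degenerate = TRUE` rather than a silent NaN.
#'
#' @param pre,post length-2 displacement vectors (um).
#' @return list with `ratio` and `degenerate`.
#' @export
velocity_ratio <- function(pre, post) {
  vp <- sqrt(sum(pre^2)); vq <- sqrt(sum(post^2))
  if (vp == 0) return(list(ratio = NA_real_, degenerate = TRUE))
  list(ratio = vq / vp, degenerate = FALSE)
}

#' Summarize one collision event
#'
#' @param event a [collision_event()].
#' @return list with `angle` (deg), `velocity_ratio`, `pre`, `post`,
#'   `degenerate`.
#' @export
collision_summary <- function(event) {
  v <- pre_post_vectors(event)
  if (v$degenerate) {
    return(list(angle = NA_real_, velocity_ratio = NA_real_,
                pre = v$pre, post = v$post, degenerate = TRUE))
  }
  vr <- velocity_ratio(v$pre, v$post)
  list(angle = collision_angle(v$pre, v$post), velocity_ratio = vr$ratio,
       pre = v$pre, post = v$post, degenerate = FALSE)
}

#' Circular mean and resultant length
#'
#' First trigonometric moment of a set of angles: `R e^{i theta_bar} =
#' mean(e^{i theta_k})`. `R` in `[0, 1]` measures concentration; the mean
#' angle is undefined (NA, flagged) when `R` vanishes (balanced angles).
#'
#' @param angles_deg numeric vector of angles, degrees.
#' @return list with `mean_deg` (in (-180, 180] or NA), `R`, `n`,
#'   `undefined`.
#' @examples
#' circular_mean(c(10, -10))   # mean 0, R = cos(10 deg)
#' circular_mean(c(0, 180))    # R = 0, mean undefined
#' @export
circular_mean <- function(angles_deg) {
  if (!length(angles_deg)) stopf("circular_mean: empty angle list")
  if (any(!is.finite(angles_deg))) stopf("circular_mean: non-finite angles")
  th <- deg2rad(angles_deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  undefined <- R < 1e-12
  list(mean_deg = if (undefined) NA_real_ else wrap_angle_deg(rad2deg(atan2(S, C))),
       R = R, n = length(angles_deg), undefined = undefined)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniform on the circle using the
#' resultant length. For the small samples typical of collision experiments
#' (`n <= 50`, the `"auto"` default) the p-value is computed from the exact
#' null distribution of the Pearson random-walk resultant via Kluyver's
#' Bessel-integral formula, `P(R* <= r) = r Int_0^inf J1(r t) J0(t)^n dt`
#' with resultant sum `R* = n R`; the widely used finite-n approximation
#' (Zar), `p = exp(sqrt(1 + 4n + 4(n^2 - R*^2)) - (1 + 2n))`, is applied for
#' larger n, where it is accurate and the integral grows costly. Results are
#' clipped to (0, 1].
#'
#' @param angles_deg numeric vector of angles, degrees (n >= 2).
#' @param method `"auto"` (exact for n <= 50, else Zar), `"exact"`, or
#'   `"zar"`.
#' @return list with `p`, `R`, `Z` (= n R^2), `n`, `method` used.
#' @examples
#' rayleigh_test(c(0, 90, 180, 270))$p  # 1: perfectly balanced
#' @export
rayleigh_test <- function(angles_deg, method = c("auto", "exact", "zar")) {
  method <- match.arg(method)
  n <- length(angles_deg)
  if (n < 2L) stopf("rayleigh_test: need at least 2 angles")
  cm <- circular_mean(angles_deg)
  Rsum <- n * cm$R
  if (method == "auto") method <- if (n <= 50) "exact" else "zar"
  p_zar <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rsum^2)) - (1 + 2 * n))
  p <- if (method == "exact") {
    pe <- rayleigh_p_exact(n, Rsum)
    # below the integral's numerical resolution the approximation's smooth
    # tail is the better estimate
    if (pe < 1e-8) { method <- "zar"; p_zar } else pe
  } else {
    p_zar
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p = p, R = cm$R, Z = n * cm$R^2, n = n, method = method)
}

# exact null tail P(resultant sum >= r) for n unit steps (Kluyver's formula),
# integrated piecewise between scaled Bessel oscillations
rayleigh_p_exact <- function(n, r) {
  if (r <= 0) return(1)
  f <- function(t) besselJ(r * t, 1) * besselJ(t, 0)^n
  brk <- seq(0, 400, by = pi / max(r, 1))
  cdf <- r * sum(vapply(seq_len(length(brk) - 1L), function(i) {
    stats::integrate(f, brk[i], brk[i + 1L], rel.tol = 1e-9,
                     stop.on.error = FALSE)$value
  }, numeric(1)))
  1 - cdf
}

#' Classify contact inhibition of locomotion
#'
#' Rule-based call on a circular summary of collision angles: normal CIL when
#' the mean angle magnitude exceeds `angle_hi` (default 120 degrees) with
#' `p < p_threshold`; defective CIL when the magnitude is below `angle_lo`
#' (default 60) with `p < p_threshold`; otherwise indeterminate. Magnitude is
#' used because reversals of either sign (e.g. a mean near -180) are
#' equally CIL-positive.
#'
#' @param mean_deg circular mean collision angle, degrees (NA allowed).
#' @param p Rayleigh-test p-value.
#' @param angle_hi,angle_lo classification thresholds, degrees.
#' @param p_threshold significance threshold.
#' @return one of `"normal_cil"`, `"defective_cil"`, `"indeterminate"`.
#' @examples
#' classify_cil(150, 0.01)   # normal_cil
#' classify_cil(30, 0.001)   # defective_cil
#' classify_cil(170, 0.43)   # indeterminate: not significant
#' @export
classify_cil <- function(mean_deg, p, angle_hi = 120, angle_lo = 60,
                         p_threshold = 0.05) {
  if (is.na(mean_deg) || is.na(p)) return("indeterminate")
  if (abs(mean_deg) > angle_hi && p < p_threshold) return("normal_cil")
  if (abs(mean_deg) < angle_lo && p < p_threshold) return("defective_cil")
  "indeterminate"
}

#' Circular summary of a set of collision events
#'
#' Computes per-event collision angles, then the circular mean, resultant
#' length, Rayleigh p and the CIL class. Degenerate events (zero pre or post
#' displacement) are excluded with a warning.
#'
#' @param events list of [collision_event()]s (or a single one).
#' @param angle_hi,angle_lo,p_threshold classification thresholds, see
#'   [classify_cil()].
#' @return a `circular_summary` list: `n`, `mean_deg`, `R`, `p`, `cil_class`,
#'   `angles_deg`, `velocity_ratios`, `n_degenerate`.
#' @export
summarize_collisions <- function(events, angle_hi = 120, angle_lo = 60,
                                 p_threshold = 0.05) {
  if (inherits(events, "collision_event")) events <- list(events)
  per <- lapply(events, collision_summary)
  deg <- vapply(per, `[[`, logical(1), "degenerate")
  if (any(deg)) {
    warning(sprintf("%d degenerate collision event(s) excluded", sum(deg)))
  }
  per <- per[!deg]
  if (!length(per)) stopf("no non-degenerate collision events")
  angles <- vapply(per, `[[`, numeric(1), "angle")
  ratios <- vapply(per, `[[`, numeric(1), "velocity_ratio")
  cm <- circular_mean(angles)
  p <- if (cm$n >= 2) rayleigh_test(angles)$p else NA_real_
  structure(list(n = cm$n, mean_deg = cm$mean_deg, R = cm$R, p = p,
                 cil_class = classify_cil(cm$mean_deg, p, angle_hi, angle_lo,
                                          p_threshold),
                 angles_deg = angles, velocity_ratios = ratios,
                 n_degenerate = sum(deg)),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary: n = %d, mean = %.1f deg, R = %.3f, p = %.3g, class = %s>\n",
              x$n, x$mean_deg, x$R, x$p, x$cil_class))
  invisible(x)
}

#' Polar plotting table for a collision set
#'
#' One row per event with the signed angle, the velocity ratio (the polar
#' radius, so the unit circle marks "same speed before and after"), and the
#' Cartesian coordinates of each point; the circular mean direction is
#' attached as attribute `mean_ray`.
#'
#' @param events list of [collision_event()]s.
#' @return a data frame `angle_deg, velocity_ratio, x, y`; empty input gives
#'   an empty table.
#' @export
vector_plot_data <- function(events) {
  if (inherits(events, "collision_event")) events <- list(events)
  if (!length(events)) {
    return(data.frame(angle_deg = numeric(0), velocity_ratio = numeric(0),
                      x = numeric(0), y = numeric(0)))
  }
  s <- summarize_collisions(events)
  th <- deg2rad(s$angles_deg)
  out <- data.frame(angle_deg = s$angles_deg,
                    velocity_ratio = s$velocity_ratios,
                    x = s$velocity_ratios * cos(th),
                    y = s$velocity_ratios * sin(th))
  attr(out, "mean_ray") <- c(angle_deg = s$mean_deg, R = s$R)
  out
}

#' Did the cell significantly change direction after contact?
#'
#' Event counter for contact-response frequency: TRUE when the magnitude of
#' the collision angle over the 5-min windows exceeds `angle_threshold`
#' (default 90 degrees).
#'
#' @param track a [cil_track()].
#' @param contact_frame frame of contact.
#' @param window window in seconds (default 300).
#' @param angle_threshold direction-change threshold, degrees.
#' @return logical.
#' @export
direction_change_event <- function(track, contact_frame, window = 300,
                                   angle_threshold = 90) {
  ev <- collision_event(track, contact_frame, window = window)
  s <- collision_summary(ev)
  if (s$degenerate) stopf("degenerate displacement window; direction undefined")
  abs(s$angle) > angle_threshold
}
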