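#' Channel image stack
#'
#' A fluorescence channel as a `height x width x frames` array of
#' non-negative intensities with acquisition metadata.
#'
#' @param data numeric array `H x W x F` (a single matrix is promoted to one
#'   frame).
#' @param channel channel label, e.g. `"YFP"` or `"CFP"`.
#' @param pixel_size_um pixel size in um/px.
#' @param dt frame interval, seconds.
#' @return a `channel_stack` object.
#' @export
channel_stack <- function(data, channel = "YFP", pixel_size_um = 0.25,
                          dt = 15) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) stopf("channel data must be H x W x frames")
  if (any(data < 0)) stopf("channel intensities must be non-negative")
  structure(list(data = data, channel = channel,
                 pixel_size_um = pixel_size_um, dt = dt),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<channel_stack %s: %d x %d px, %d frame(s), %g um/px, dt = %g s>\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_um, x$dt))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[3]

resolve_background <- function(frame, background) {
  if (is.numeric(background) && length(background) == 1L) return(background)
  if (is.list(background) && !is.null(background$region)) {
    r <- background$region  # c(x, y, w, h) in px
    rows <- seq(r[2], min(r[2] + r[4] - 1, nrow(frame)))
    cols <- seq(r[1], min(r[1] + r[3] - 1, ncol(frame)))
    return(stats::median(frame[rows, cols]))
  }
  stopf("background must be a fixed value or list(region = c(x, y, w, h))")
}

#' Smooth and background-correct both channels
#'
#' Each frame of each channel is Gaussian-smoothed (sigma
#' `smooth_sigma_px`; 0 skips smoothing) and background-corrected by
#' subtracting either a fixed value or the per-frame median of a stated
#' empty region, clipping at zero.
#'
#' @param yfp,cfp [channel_stack()]s with matching geometry.
#' @param smooth_sigma_px Gaussian sigma in pixels.
#' @param background a single number, or `list(region = c(x, y, w, h))`
#'   naming a cell-free rectangle (default: the 10x10 px top-left corner).
#' @return list with corrected `yfp` and `cfp` stacks; each carries a
#'   `preprocessing` attribute recording sigma and the per-frame background
#'   values.
#' @export
preprocess_channels <- function(yfp, cfp, smooth_sigma_px = 1,
                                background = list(region = c(1, 1, 10, 10))) {
  stopifnot(inherits(yfp, "channel_stack"), inherits(cfp, "channel_stack"))
  if (!identical(dim(yfp$data), dim(cfp$data))) {
    stopf("YFP and CFP stacks have mismatched dimensions")
  }
  fix1 <- function(stack) {
    bgs <- numeric(n_frames(stack))
    out <- stack$data
    for (f in seq_len(n_frames(stack))) {
      fr <- out[, , f]
      if (smooth_sigma_px > 0) fr <- EBImage::gblur(fr, sigma = smooth_sigma_px)
      bgs[f] <- resolve_background(fr, background)
      out[, , f] <- pmax(fr - bgs[f], 0)
    }
    stack$data <- out
    attr(stack, "preprocessing") <- list(smooth_sigma_px = smooth_sigma_px,
                                         background = bgs)
    stack
  }
  list(yfp = fix1(yfp), cfp = fix1(cfp))
}

#' Pixelwise YFP/CFP ratio stack
#'
#' Ratiometric biosensor readout: YFP divided by CFP wherever CFP exceeds a
#' positive floor; other pixels are masked (NA) because the ratio there is
#' dominated by noise.
#'
#' @param yfp,cfp preprocessed [channel_stack()]s.
#' @param cfp_floor strictly positive CFP intensity floor.
#' @return a `ratio_stack`: list with `ratio` (H x W x F, NA off-mask),
#'   `mask` (logical array), `pixel_size_um`, `dt`.
#' @export
ratio_image <- function(yfp, cfp, cfp_floor = 1e-3) {
  stopifnot(inherits(yfp, "channel_stack"), inherits(cfp, "channel_stack"))
  if (!identical(dim(yfp$data), dim(cfp$data))) {
    stopf("YFP and CFP stacks have mismatched dimensions")
  }
  if (!is.numeric(cfp_floor) || cfp_floor <= 0) {
    stopf("cfp_floor must be > 0")
  }
  mask <- cfp$data > cfp_floor
  ratio <- ifelse(mask, yfp$data / cfp$data, NA_real_)
  dim(ratio) <- dim(yfp$data)
  if (!any(mask)) warning("CFP below floor everywhere; ratio fully masked")
  structure(list(ratio = ratio, mask = mask,
                 pixel_size_um = yfp$pixel_size_um, dt = yfp$dt),
            class = "ratio_stack")
}

#' Intensity-weighted cell center
#'
#' Center of the (single) cell in a YFP frame: the intensity-weighted
#' centroid of pixels above the Otsu threshold of the frame.
#'
#' @param frame numeric matrix (one YFP frame).
#' @return `c(x, y)` in pixel (col, row) coordinates.
#' @export
find_center <- function(frame) {
  mx <- max(frame)
  if (mx <= 0) stopf("find_center: empty (all-zero) frame")
  thr <- EBImage::otsu(EBImage::Image(frame / mx)) * mx
  sel <- frame > thr
  if (!any(sel)) stopf("find_center: no pixels above threshold")
  w <- frame[sel]
  rows <- row(frame)[sel]
  cols <- col(frame)[sel]
  c(x = sum(cols * w) / sum(w), y = sum(rows * w) / sum(w))
}

# bilinear interpolation of img[row, col] at (x = col, y = row) positions;
# out-of-bounds -> NA. NA pixels propagate.
bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= W & y0 + 1 <= H
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * H + y0[ok]
    v00 <- img[i00]; v10 <- img[i00 + H]
    v01 <- img[i00 + 1]; v11 <- img[i00 + H + 1]
    out[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) + v10 * fx[ok] * (1 - fy[ok]) +
      v01 * (1 - fx[ok]) * fy[ok] + v11 * fx[ok] * fy[ok]
  }
  out
}

# outermost local maximum with prominence >= frac * dynamic range of v;
# returns index or NA
outermost_peak <- function(v, frac = 0.2) {
  m <- length(v)
  if (m < 3L) return(NA_integer_)
  rng <- max(v) - min(v)
  if (rng <= 0) return(NA_integer_)
  mid <- v[2:(m - 1)]
  is_pk <- which(mid > v[1:(m - 2)] & mid >= v[3:m]) + 1L
  if (!length(is_pk)) return(NA_integer_)
  for (p in rev(is_pk)) {  # outermost first
    higher_l <- which(v[seq_len(p - 1)] > v[p])
    lmin <- min(v[(if (length(higher_l)) max(higher_l) else 1):p])
    higher_r <- which(v[seq(p + 1, m)] > v[p]) + p
    rmin <- min(v[p:(if (length(higher_r)) min(higher_r) else m)])
    prom <- v[p] - max(lmin, rmin)
    if (prom >= frac * rng) return(p)
  }
  NA_integer_
}

#' Radial membrane-boundary detection
#'
#' Samples the YFP frame along 360 rays (one per degree, counterclockwise
#' from +x, y up) from the cell center in 0.5-px steps with bilinear
#' interpolation, and places the cell boundary at the outermost local
#' intensity maximum with prominence at least `prominence_frac` of the ray's
#' dynamic range -- the bright membrane ring, in preference to brighter
#' interior structures. Rays with no acceptable peak are filled by circular
#' linear interpolation from detected neighbors and counted; more than
#' `max_failed_frac` failed rays aborts (unreliable segmentation).
#'
#' @param frame numeric matrix, one (preprocessed) YFP frame.
#' @param center `c(x, y)` center in px; found with [find_center()] if NULL.
#' @param step_px radial sampling step.
#' @param prominence_frac peak prominence threshold as a fraction of each
#'   ray's dynamic range.
#' @param max_failed_frac maximum tolerated fraction of undetected rays.
#' @return a `boundary_sample` data frame: `angle_deg` (0..359), `radius_px`,
#'   `x`, `y` (boundary point, px), `detected`; attributes `center`,
#'   `n_interpolated`.
#' @export
radial_boundary <- function(frame, center = NULL, step_px = 0.5,
                            prominence_frac = 0.2, max_failed_frac = 0.25) {
  if (is.null(center)) center <- find_center(frame)
  cx <- center[1]; cy <- center[2]
  H <- nrow(frame); W <- ncol(frame)
  if (cx < 1 || cx > W || cy < 1 || cy > H) stopf("center outside image")
  rmax <- min(cx - 1, W - cx, cy - 1, H - cy)
  if (rmax < 3 * step_px) stopf("center too close to image border")
  t <- seq(step_px, rmax, by = step_px)
  dirs <- angle_to_image_step(0:359)
  radius <- rep(NA_real_, 360L)
  for (a in seq_len(360L)) {
    xs <- cx + t * dirs[a, "dx"]
    ys <- cy + t * dirs[a, "dy"]
    v <- bilinear(frame, xs, ys)
    v[is.na(v)] <- 0
    p <- outermost_peak(v, prominence_frac)
    if (!is.na(p)) radius[a] <- t[p]
  }
  failed <- is.na(radius)
  if (mean(failed) > max_failed_frac) {
    stopf("radial_boundary: %.0f%% of rays failed (max %.0f%%); segmentation unreliable",
          100 * mean(failed), 100 * max_failed_frac)
  }
  if (any(failed)) radius <- interp_circular(radius)
  out <- data.frame(angle_deg = 0:359, radius_px = radius,
                    x = cx + radius * dirs[, "dx"],
                    y = cy + radius * dirs[, "dy"],
                    detected = !failed)
  attr(out, "center") <- c(x = cx, y = cy)
  attr(out, "n_interpolated") <- sum(failed)
  class(out) <- c("boundary_sample", "data.frame")
  out
}

# circular linear interpolation of NA runs from flanking non-NA values
interp_circular <- function(v) {
  n <- length(v)
  ok <- which(!is.na(v))
  if (!length(ok)) return(v)
  # triplicate to handle wrap-around, interpolate, take middle
  x3 <- c(ok - n, ok, ok + n)
  y3 <- rep(v[ok], 3)
  filled <- stats::approx(x3, y3, xout = seq_len(n))$y
  ifelse(is.na(v), filled, v)
}

# circular moving average, window w: offsets -ceiling(w/2 - 1/2)..  for even
# w uses w/2 points before and w/2 - 1 after the center (plus the center)
circular_ma <- function(v, w = 10, na_rm = TRUE) {
  n <- length(v)
  before <- ceiling((w - 1) / 2)
  offs <- seq(-before, w - 1 - before)
  m <- vapply(offs, function(k) v[((seq_len(n) - 1 + k) %% n) + 1],
              numeric(n))
  rowMeans(m, na.rm = na_rm)
}

#' Perimeter ratio profile
#'
#' Samples the ratio image at each of the 360 boundary points (bilinear) and
#' applies a circular 10-point centered moving average (5 points before, 4
#' after, for the even window). Boundary points falling on masked ratio
#' pixels fall back to the nearest valid pixel within 2 px, else are
#' flagged and excluded from downstream statistics.
#'
#' @param ratio_frame numeric matrix of ratios (NA = masked), one frame of a
#'   `ratio_stack`.
#' @param boundary a `boundary_sample` from [radial_boundary()].
#' @param ma_window moving-average window (points of 360).
#' @return a `perimeter_profile` data frame: `angle_deg`, `x`, `y`, `ratio`,
#'   `smoothed`, `flagged`; attribute `n_flagged`.
#' @export
perimeter_profile <- function(ratio_frame, boundary, ma_window = 10) {
  stopifnot(inherits(boundary, "boundary_sample"))
  raw <- bilinear(ratio_frame, boundary$x, boundary$y)
  bad <- which(is.na(raw))
  for (i in bad) {  # nearest valid pixel within 2 px
    r0 <- round(boundary$y[i]); c0 <- round(boundary$x[i])
    rows <- max(1, r0 - 2):min(nrow(ratio_frame), r0 + 2)
    cols <- max(1, c0 - 2):min(ncol(ratio_frame), c0 + 2)
    patch <- ratio_frame[rows, cols, drop = FALSE]
    if (any(!is.na(patch))) {
      dr <- outer(rows - boundary$y[i], cols - boundary$x[i],
                  function(a, b) sqrt(a^2 + b^2))
      dr[is.na(patch)] <- Inf
      j <- which.min(dr)
      if (is.finite(dr[j]) && dr[j] <= 2) raw[i] <- patch[j]
    }
  }
  flagged <- is.na(raw)
  sm <- circular_ma(raw, ma_window, na_rm = TRUE)
  sm[flagged] <- NA_real_
  out <- data.frame(angle_deg = boundary$angle_deg, x = boundary$x,
                    y = boundary$y, ratio = raw, smoothed = sm,
                    flagged = flagged)
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "ma_window") <- ma_window
  class(out) <- c("perimeter_profile", "data.frame")
  out
}

#' Fraction of the boundary above a ratio threshold
#'
#' Percentage of (unflagged) perimeter points whose smoothed ratio strictly
#' exceeds `threshold` -- the "percent of the cell boundary with high
#' biosensor activity" statistic (default threshold 1.2).
#'
#' @param profile a [perimeter_profile()].
#' @param threshold ratio threshold (strict `>`).
#' @param use `"smoothed"` (default) or `"raw"` profile values.
#' @return percentage in `[0, 100]`.
#' @export
high_fraction <- function(profile, threshold = 1.2,
                          use = c("smoothed", "raw")) {
  use <- match.arg(use)
  v <- if (use == "smoothed") profile$smoothed else profile$ratio
  keep <- !profile$flagged & !is.na(v)
  if (!any(keep)) stopf("high_fraction: no valid boundary points")
  100 * sum(v[keep] > threshold) / sum(keep)
}

#' Perimeter kymograph registered to the migration front
#'
#' Stacks per-frame smoothed perimeter profiles into a `frames x 360` matrix
#' with each row circularly shifted so that the cell's pre-collision front
#' angle maps to the center column (column 181 of 360, zero-based 180).
#' Frames with missing front angle are left unshifted and flagged.
#'
#' @param profiles list of [perimeter_profile()]s, one per frame.
#' @param front_angle_deg numeric vector (recycled if length 1): front angle
#'   per frame, degrees; typically the direction of the 5-min pre-contact
#'   displacement (see [front_angle()]). NA = unknown.
#' @return a `kymograph` matrix with attributes `offsets` (columns shifted
#'   per frame) and `unregistered` (logical per frame).
#' @export
build_kymograph <- function(profiles, front_angle_deg = NA) {
  if (inherits(profiles, "perimeter_profile")) profiles <- list(profiles)
  nf <- length(profiles)
  if (!nf) stopf("build_kymograph: no profiles")
  front <- rep_len(front_angle_deg, nf)
  km <- matrix(NA_real_, nf, 360L)
  offsets <- integer(nf)
  for (f in seq_len(nf)) {
    v <- profiles[[f]]$smoothed
    if (is.na(front[f])) {
      km[f, ] <- v
      offsets[f] <- 0L
    } else {
      # column j holds angle (front + j - 181) mod 360
      src <- ((round(front[f]) + seq_len(360L) - 181L) %% 360L) + 1L
      km[f, ] <- v[src]
      offsets[f] <- as.integer(round(front[f]) - 180L) %% 360L
    }
  }
  structure(km, offsets = offsets, unregistered = is.na(front),
            class = c("kymograph", "matrix"))
}

#' Direction of migration before contact
#'
#' Angle (degrees, 0..360) of the displacement over the window preceding
#' `contact_frame` -- the "front" used to register kymographs.
#'
#' @param track a [cil_track()].
#' @param contact_frame frame of contact.
#' @param window window in seconds.
#' @return angle in degrees in `[0, 360)`.
#' @export
front_angle <- function(track, contact_frame, window = 300) {
  v <- pre_post_vectors(collision_event(track, contact_frame, window = window))
  if (all(v$pre == 0)) stopf("front_angle: zero pre-contact displacement")
  rad2deg(atan2(v$pre[2], v$pre[1])) %% 360
}

#' Biosensor activity at the contact site
#'
#' Classifies the contact zone as `"high"` when the smoothed ratio at the
#' boundary point nearest `contact_angle_deg` strictly exceeds `threshold`,
#' `"low"` otherwise (exact equality is low); flagged points give
#' `"indeterminate"`.
#'
#' @param profile a [perimeter_profile()].
#' @param contact_angle_deg angular position of the contact on the boundary.
#' @param threshold ratio threshold.
#' @return `"high"`, `"low"` or `"indeterminate"` (with a `reason`
#'   attribute).
#' @export
classify_contact_zone <- function(profile, contact_angle_deg,
                                  threshold = 1.2) {
  idx <- (as.integer(round(contact_angle_deg)) %% 360L) + 1L
  if (profile$flagged[idx] || is.na(profile$smoothed[idx])) {
    return(structure("indeterminate",
                     reason = "boundary ratio unavailable at contact angle"))
  }
  if (profile$smoothed[idx] > threshold) "high" else "low"
}
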