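#' Rendered-cell specification
#'
#' Describes a synthetic single cell for two-channel ratiometric rendering:
#' a bright membrane ring (Gaussian radial cross-section) around a dimmer
#' cytoplasm on a dark background in the YFP channel, and a CFP channel
#' constructed by pixelwise division so that the YFP/CFP ratio equals
#' `ratio_baseline` everywhere except on `active_arcs`, angular sectors of
#' elevated ratio emulating zones of high biosensor activity. The ground
#' truth (boundary radii, per-degree ratio) is therefore exact by
#' construction.
#'
#' `radii` may be a single number (circle radius, px), a length-2 vector
#' `c(a, b)` (ellipse semi-axes along x and y), or a length-360 vector of
#' per-degree radii.
#'
#' @param image_size image side length in pixels (square frames).
#' @param center cell center `(x, y)` in pixels (col, row-from-top units;
#'   see [angle-conventions]).
#' @param radii boundary radius specification, pixels (see Details).
#' @param ring_width Gaussian sigma of the membrane ring cross-section, px.
#' @param ring_intensity,cytoplasm_intensity,background_intensity intensities
#'   in arbitrary units.
#' @param ratio_baseline YFP/CFP ratio off the active arcs (> 0).
#' @param active_arcs list of `c(start_deg, end_deg, ratio_level)` sectors,
#'   `0 <= start < end <= 360`, `ratio_level > 0`. Overlapping arcs must
#'   agree on the level.
#' @param noise_sd SD of additive Gaussian noise per channel (same units as
#'   intensities).
#' @param seed integer seed for the noise.
#' @return a `cell_render_spec` list.
#' @export
cell_render_spec <- function(image_size = 200, center = NULL, radii = 50,
                             ring_width = 3, ring_intensity = 1,
                             cytoplasm_intensity = 0.3,
                             background_intensity = 0.05,
                             ratio_baseline = 1, active_arcs = list(),
                             noise_sd = 0, seed = NULL) {
  if (is.null(center)) center <- c(image_size, image_size) / 2
  r360 <- radii_per_degree(radii)
  if (any(r360 < ring_width)) stopf("radii must be >= ring_width everywhere")
  if (ratio_baseline <= 0) stopf("ratio_baseline must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(active_arcs) && !is.list(active_arcs)) {
    active_arcs <- list(active_arcs)
  }
  for (a in active_arcs) {
    if (length(a) != 3L) stopf("each arc must be c(start_deg, end_deg, level)")
    if (a[1] < 0 || a[2] > 360 || a[1] >= a[2]) {
      stopf("arc [%g, %g) must satisfy 0 <= start < end <= 360", a[1], a[2])
    }
    if (a[3] <= 0) stopf("arc ratio_level must be > 0")
  }
  # reject overlapping arcs whose levels conflict
  lev <- arc_levels_per_degree(active_arcs, ratio_baseline, check = TRUE)
  structure(list(image_size = as.integer(image_size), center = center,
                 radii = r360, ring_width = ring_width,
                 ring_intensity = ring_intensity,
                 cytoplasm_intensity = cytoplasm_intensity,
                 background_intensity = background_intensity,
                 ratio_baseline = ratio_baseline, active_arcs = active_arcs,
                 ratio_per_degree = lev, noise_sd = noise_sd, seed = seed),
            class = "cell_render_spec")
}

# expand a radius spec to 360 per-degree values
radii_per_degree <- function(radii) {
  th <- deg2rad(0:359)
  if (length(radii) == 1L) {
    rep(as.numeric(radii), 360L)
  } else if (length(radii) == 2L) {
    a <- radii[1]; b <- radii[2]
    a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  } else if (length(radii) == 360L) {
    as.numeric(radii)
  } else {
    stopf("radii must have length 1 (circle), 2 (ellipse) or 360")
  }
}

# per-degree ratio level implied by baseline + arcs; errors on conflicts
arc_levels_per_degree <- function(arcs, baseline, check = FALSE,
                                  rotate_deg = 0) {
  lev <- rep(baseline, 360L)
  set_by <- rep(NA_real_, 360L)
  dd <- 0:359
  for (a in arcs) {
    deg <- (dd[dd >= a[1] & dd < a[2]] + rotate_deg) %% 360
    idx <- unique(as.integer(deg)) + 1L
    if (check && any(!is.na(set_by[idx]) & set_by[idx] != a[3])) {
      stopf("overlapping active arcs with conflicting ratio levels")
    }
    set_by[idx] <- a[3]
    lev[idx] <- a[3]
  }
  lev
}

#' Render a two-channel FRET image stack
#'
#' Renders `n_frames` YFP/CFP frame pairs from a [cell_render_spec()]. The
#' YFP channel is `background + cytoplasm * inside(r) + ring *
#' exp(-(r - R(theta))^2 / (2 ring_width^2))`; the CFP channel is YFP divided
#' by the per-degree target ratio, so the noiseless pixelwise YFP/CFP ratio
#' equals the ground truth exactly. Independent Gaussian noise is then added
#' to each channel. `arc_rotation_deg_per_frame` rotates the active arcs
#' frame by frame (useful to script a travelling activity zone).
#'
#' @param spec a [cell_render_spec()].
#' @param n_frames number of frames.
#' @param arc_rotation_deg_per_frame degrees the arcs advance per frame
#'   (counterclockwise).
#' @return a list with `yfp` and `cfp` ([channel_stack()]s) and
#'   `ground_truth`: center, per-degree boundary radii and polygon, the
#'   per-frame 360-long target ratio, and the per-frame exact percentage of
#'   the boundary above ratio 1.2.
#' @examples
#' st <- render_fret_stack(cell_render_spec(radii = 50,
#'   active_arcs = list(c(0, 90, 1.5))))
#' st$ground_truth$high_fraction_pct  # 25: a 90-degree arc
#' @export
render_fret_stack <- function(spec, n_frames = 1,
                              arc_rotation_deg_per_frame = 0) {
  stopifnot(inherits(spec, "cell_render_spec"))
  sz <- spec$image_size
  cx <- spec$center[1]; cy <- spec$center[2]
  col <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # x
  row <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # y (top-down)
  dx <- col - cx
  dy <- row - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- image_offset_to_angle(dx, dy)
  deg_idx <- (as.integer(theta) %% 360L) + 1L
  Rb <- spec$radii[deg_idx]
  # cytoplasm edge rolls off smoothly at the ring (optical-blur-like sigmoid),
  # so the ring peak stays at R(theta) instead of being dragged inward by a
  # hard intensity step
  yfp1 <- spec$background_intensity +
    spec$cytoplasm_intensity * stats::pnorm((Rb - r) / spec$ring_width) +
    spec$ring_intensity * exp(-(r - Rb)^2 / (2 * spec$ring_width^2))
  dim(yfp1) <- c(sz, sz)

  yfp <- array(0, c(sz, sz, n_frames))
  cfp <- array(0, c(sz, sz, n_frames))
  ratio_truth <- matrix(0, n_frames, 360L)
  high_pct <- numeric(n_frames)
  with_seed(spec$seed, {
    for (f in seq_len(n_frames)) {
      rot <- (f - 1) * arc_rotation_deg_per_frame
      lev <- arc_levels_per_degree(spec$active_arcs, spec$ratio_baseline,
                                   rotate_deg = rot)
      ratio_truth[f, ] <- lev
      high_pct[f] <- 100 * mean(lev > 1.2)
      ratio_px <- matrix(lev[deg_idx], sz, sz)
      yf <- yfp1
      cf <- yfp1 / ratio_px
      if (spec$noise_sd > 0) {
        yf <- yf + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
        cf <- cf + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
      }
      yfp[, , f] <- pmax(yf, 0)
      cfp[, , f] <- pmax(cf, 0)
    }
  })
  poly_step <- angle_to_image_step(0:359)
  boundary <- data.frame(
    angle_deg = 0:359,
    x = cx + spec$radii * poly_step[, "dx"],
    y = cy + spec$radii * poly_step[, "dy"])
  list(
    yfp = channel_stack(yfp, channel = "YFP"),
    cfp = channel_stack(cfp, channel = "CFP"),
    ground_truth = list(center = c(x = cx, y = cy),
                        radii_px = spec$radii,
                        boundary = boundary,
                        ratio_per_degree = ratio_truth,
                        high_fraction_pct = high_pct))
}
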