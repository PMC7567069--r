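#' Persistent-random-walk parameters
#'
#' Parameters of the heading-diffusion persistent random walk (PRW) used to
#' emulate mesendoderm-like single-cell migration. The cell moves a fixed
#' step `speed * dt` each frame while its heading accumulates wrapped-normal
#' increments with variance `2 * rot_diffusion * dt`, the standard rotational
#' diffusion model of persistent migration.
#'
#' Defaults describe a cell migrating at 2 um/min with a directional
#' persistence time of roughly 1/rot_diffusion ~ 7 min, recorded at 15-s
#' intervals.
#'
#' @param speed migration speed in um/min (> 0).
#' @param rot_diffusion rotational diffusion coefficient in rad^2/min (>= 0).
#'   0 gives ballistic (perfectly straight) motion.
#' @param dt frame interval in seconds (> 0).
#' @param n_steps number of recorded positions (>= 2).
#' @param seed integer seed; identical seed and parameters give identical
#'   trajectories.
#' @return a `walk_params` list.
#' @export
walk_params <- function(speed = 2, rot_diffusion = 0.15, dt = 15,
                        n_steps = 240, seed = NULL) {
  for (nm in c("speed", "rot_diffusion", "dt", "n_steps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stopf("walk_params: %s must be a single finite number", nm)
    }
  }
  if (speed <= 0) stopf("walk_params: speed must be > 0")
  if (rot_diffusion < 0) stopf("walk_params: rot_diffusion must be >= 0")
  if (dt <= 0) stopf("walk_params: dt must be > 0")
  if (n_steps < 2) stopf("walk_params: n_steps must be >= 2")
  structure(list(speed = speed, rot_diffusion = rot_diffusion, dt = dt,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "walk_params")
}

#' Simulate a persistent random walk
#'
#' @param params a [walk_params()] object.
#' @param start numeric length-2 start position (um).
#' @param heading initial heading in degrees (Cartesian, CCW positive).
#' @param track_id identifier for the output track.
#' @return a [cil_track()] with `n_steps` positions at constant step length
#'   `speed * dt`.
#' @examples
#' trk <- simulate_prw(walk_params(rot_diffusion = 0, n_steps = 10, seed = 1))
#' directionality_ratio(trk)$ratio  # 1: ballistic limit
#' @export
simulate_prw <- function(params, start = c(0, 0), heading = 0,
                         track_id = "prw") {
  stopifnot(inherits(params, "walk_params"))
  if (!all(is.finite(start)) || length(start) != 2L) {
    stopf("start must be a finite (x, y)")
  }
  n <- params$n_steps
  dt_min <- params$dt / 60
  step <- params$speed * dt_min
  sd_inc <- sqrt(2 * params$rot_diffusion * dt_min)
  with_seed(params$seed, {
    inc <- if (sd_inc > 0) stats::rnorm(n - 1L, 0, sd_inc) else numeric(n - 1L)
    h <- deg2rad(heading) + cumsum(c(0, inc))[seq_len(n - 1L)]
    x <- start[1] + c(0, cumsum(step * cos(h)))
    y <- start[2] + c(0, cumsum(step * sin(h)))
    cil_track(seq_len(n), x, y, track_id = track_id, dt = params$dt)
  })
}

#' Scripted collision parameters
#'
#' Describes how a moving cell redirects after touching a stationary cell:
#' `cil` draws a post-contact redirect around `redirect_mean_deg` (typically
#' near 180, a reversal), `pass_through` forces a 0-degree redirect (no
#' contact inhibition), `partial` is any intermediate scripted mean.
#'
#' @param mode one of `"cil"`, `"pass_through"`, `"partial"`.
#' @param redirect_mean_deg mean redirect angle in degrees, CCW positive.
#' @param redirect_sd_deg SD of the redirect draw in degrees (>= 0).
#' @param speed_ratio post/pre speed ratio (> 0).
#' @param contact_frame frame at which the cells touch; at the 15-s default
#'   frame interval at least 20 frames (5 min) must remain on each side.
#' @return a `collision_script` list.
#' @export
collision_script <- function(mode = c("cil", "pass_through", "partial"),
                             redirect_mean_deg = 180, redirect_sd_deg = 0,
                             speed_ratio = 1, contact_frame = 40) {
  mode <- match.arg(mode)
  if (mode == "pass_through") redirect_mean_deg <- 0
  if (!is.finite(redirect_mean_deg)) stopf("redirect_mean_deg must be finite")
  if (!is.finite(redirect_sd_deg) || redirect_sd_deg < 0) {
    stopf("redirect_sd_deg must be >= 0")
  }
  if (!is.finite(speed_ratio) || speed_ratio <= 0) {
    stopf("speed_ratio must be > 0")
  }
  structure(list(mode = mode, redirect_mean_deg = redirect_mean_deg,
                 redirect_sd_deg = redirect_sd_deg, speed_ratio = speed_ratio,
                 contact_frame = as.integer(contact_frame)),
            class = "collision_script")
}

#' Simulate a scripted single-cell collision
#'
#' A moving cell approaches a stationary cell head-on and touches it at
#' `contact_frame` (contact defined as center-to-center distance equal to the
#' sum of the nominal cell radii). From the next frame on, its heading is the
#' incident heading plus one redirect angle drawn from
#' `Normal(redirect_mean_deg, redirect_sd_deg)`, and its speed is scaled by
#' `speed_ratio`. The drawn redirect is recorded as ground truth.
#'
#' @param script a [collision_script()].
#' @param walk a [walk_params()]; `rot_diffusion` adds heading noise on top
#'   of the scripted redirect (use 0 for exact recovery tests).
#' @param heading initial heading of the mover, degrees.
#' @param cell_radius_um nominal cell radius (um) used for the contact
#'   geometry; both cells share it.
#' @param seed integer seed for the redirect draw and heading noise.
#' @return a list with elements `mover` and `target` ([cil_track()]s), and
#'   `event` (a [collision_event()] whose `ground_truth` attribute stores the
#'   sampled redirect angle, the speed ratio and the contact point).
#' @examples
#' sim <- simulate_collision_pair(collision_script("cil", 180, 0),
#'                                walk_params(rot_diffusion = 0, n_steps = 80))
#' collision_summary(sim$event)$angle  # 180: scripted reversal
#' @export
simulate_collision_pair <- function(script, walk, heading = 0,
                                    cell_radius_um = 15, seed = walk$seed) {
  stopifnot(inherits(script, "collision_script"), inherits(walk, "walk_params"))
  k <- ceiling(300 / walk$dt)  # frames per 5-min window
  cf <- script$contact_frame
  if (cf - 1L < k) stopf("contact_frame leaves only %d pre-contact frames; %d needed",
                         cf - 1L, k)
  if (walk$n_steps - cf < k) {
    stopf("contact_frame leaves only %d post-contact frames; %d needed",
          walk$n_steps - cf, k)
  }
  n <- walk$n_steps
  dt_min <- walk$dt / 60
  step <- walk$speed * dt_min
  sd_inc <- sqrt(2 * walk$rot_diffusion * dt_min)
  with_seed(seed, {
    redirect <- stats::rnorm(1, script$redirect_mean_deg, script$redirect_sd_deg)
    noise <- if (sd_inc > 0) stats::rnorm(n - 1L, 0, sd_inc) else numeric(n - 1L)
    h <- deg2rad(heading) + cumsum(c(0, noise))[seq_len(n - 1L)]
    incident <- h[cf - 1L]  # heading of the step arriving at contact_frame
    post <- seq(cf, n - 1L)
    h[post] <- h[post] - h[cf] + incident + deg2rad(redirect)
    steps <- rep(step, n - 1L)
    steps[post] <- step * script$speed_ratio
    x <- c(0, cumsum(steps * cos(h)))
    y <- c(0, cumsum(steps * sin(h)))
    mover <- cil_track(seq_len(n), x, y, track_id = "mover", dt = walk$dt)
    u <- c(cos(incident), sin(incident))
    contact_pos <- c(x[cf], y[cf])
    target_center <- contact_pos + 2 * cell_radius_um * u
    target <- cil_track(seq_len(n), rep(target_center[1], n),
                        rep(target_center[2], n),
                        track_id = "target", dt = walk$dt)
    contact_point <- contact_pos + cell_radius_um * u
    ev <- collision_event(mover, contact_frame = cf,
                          contact_point = contact_point)
    attr(ev, "ground_truth") <- list(
      redirect_deg = wrap_angle_deg(redirect),
      speed_ratio = script$speed_ratio,
      contact_frame = cf, contact_point = contact_point)
    list(mover = mover, target = target, event = ev)
  })
}

#' Simulate tissue-closure progress curves
#'
#' Emulates leading-edge progress of closing mesendoderm mantles: the edge
#' advances at `pre_rate` (plus optional per-frame Gaussian jitter) until the
#' opposing edges collide at `collide_frame`, after which progress plateaus
#' (migration arrests on contact).
#'
#' @param n_embryos number of independent series.
#' @param n_frames series length in frames.
#' @param collide_frame frame of edge-edge collision (< `n_frames`).
#' @param pre_rate pre-collision closure rate in um/min.
#' @param dt frame interval, seconds.
#' @param noise_sd SD of per-frame progress jitter (um); 0 gives exact
#'   piecewise-linear curves.
#' @param seed integer seed; embryo `i` uses sub-seed `seed + i`.
#' @return a list of `closure_series` objects: data frames with columns
#'   `frame`, `progress` (um) and attributes `closure_frame`, `dt`.
#' @export
simulate_closure <- function(n_embryos = 5, n_frames = 120, collide_frame = 80,
                             pre_rate = 1, dt = 15, noise_sd = 0, seed = NULL) {
  if (collide_frame >= n_frames) stopf("collide_frame must be < n_frames")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  inc <- pre_rate * dt / 60
  lapply(seq_len(n_embryos), function(i) {
    with_seed(if (is.null(seed)) NULL else seed + i, {
      d <- c(rep(inc, collide_frame - 1L), rep(0, n_frames - collide_frame))
      if (noise_sd > 0) {
        d[seq_len(collide_frame - 1L)] <- pmax(
          0, d[seq_len(collide_frame - 1L)] +
            stats::rnorm(collide_frame - 1L, 0, noise_sd))
      }
      ser <- data.frame(frame = seq_len(n_frames), progress = c(0, cumsum(d)))
      attr(ser, "closure_frame") <- as.integer(collide_frame)
      attr(ser, "dt") <- dt
      attr(ser, "series_id") <- sprintf("embryo%02d", i)
      class(ser) <- c("closure_series", "data.frame")
      ser
    })
  })
}
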