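test_that("preprocessing with no smoothing and zero background is the identity", {
  st <- render_fret_stack(cell_render_spec(radii = 30, image_size = 120))
  out <- preprocess_channels(st$yfp, st$cfp, smooth_sigma_px = 0,
                             background = 0)
  expect_equal(out$yfp$data, st$yfp$data)
  expect_equal(out$cfp$data, st$cfp$data)
})

test_that("subtracting a uniform image's own background zeroes it", {
  u <- channel_stack(matrix(0.4, 50, 50))
  out <- preprocess_channels(u, u, smooth_sigma_px = 0, background = 0.4)
  expect_true(all(out$yfp$data == 0))
})

test_that("region-median background recovers the rendered offset", {
  st <- render_fret_stack(cell_render_spec(radii = 30, image_size = 160,
                                           background_intensity = 0.12))
  out <- preprocess_channels(st$yfp, st$cfp, smooth_sigma_px = 0,
                             background = list(region = c(1, 1, 10, 10)))
  expect_equal(attr(out$yfp, "preprocessing")$background, 0.12,
               tolerance = 1e-6)
  # corrected ring peak within 2% of ring + cytoplasm-tail spec
  expect_equal(max(out$yfp$data),
               max(st$yfp$data) - 0.12, tolerance = 0.02)
})

test_that("mismatched channel geometry is rejected", {
  a <- channel_stack(matrix(1, 20, 20))
  b <- channel_stack(matrix(1, 30, 30))
  expect_error(preprocess_channels(a, b), "mismatch")
  expect_error(ratio_image(a, b), "mismatch")
})

test_that("ratio image is YFP/CFP on the CFP-above-floor mask", {
  m <- matrix(0.5, 30, 30)
  rs <- ratio_image(channel_stack(m), channel_stack(m), cfp_floor = 1e-3)
  expect_true(all(rs$ratio[rs$mask] == 1))

  low <- channel_stack(matrix(1e-6, 30, 30))
  expect_warning(rs2 <- ratio_image(channel_stack(m), low, cfp_floor = 1e-3),
                 "masked")
  expect_true(all(is.na(rs2$ratio)))
  expect_error(ratio_image(channel_stack(m), channel_stack(m), cfp_floor = 0),
               "cfp_floor")
})

test_that("rendered arc ratio is recovered on the ring", {
  st <- render_fret_stack(cell_render_spec(
    radii = 50, active_arcs = list(c(0, 90, 1.5))))
  rs <- ratio_image(st$yfp, st$cfp)
  b <- radial_boundary(st$yfp$data[, , 1], c(100, 100))
  p <- perimeter_profile(rs$ratio[, , 1], b)
  on_arc <- p$angle_deg >= 15 & p$angle_deg <= 75  # away from the edges
  expect_equal(mean(p$ratio[on_arc]), 1.5, tolerance = 0.02)
})

test_that("find_center locates the rendered cell and rejects empty frames", {
  st <- render_fret_stack(cell_render_spec(image_size = 200,
                                           center = c(120, 90), radii = 40))
  ctr <- find_center(st$yfp$data[, , 1])
  expect_equal(unname(ctr), c(120, 90), tolerance = 1)
  expect_error(find_center(matrix(0, 50, 50)), "all-zero")
})

test_that("radial boundary matches circle and ellipse ground truth", {
  circ <- render_fret_stack(cell_render_spec(radii = 50))
  b <- radial_boundary(circ$yfp$data[, , 1], c(100, 100))
  expect_true(all(abs(b$radius_px - 50) < 1.5))

  ell <- render_fret_stack(cell_render_spec(radii = c(60, 40)))
  be <- radial_boundary(ell$yfp$data[, , 1], c(100, 100))
  expect_true(all(abs(be$radius_px - ellipse_radius(0:359, 60, 40)) < 1.5))
})

test_that("boundary points stay on the ring when the center is displaced", {
  circ <- render_fret_stack(cell_render_spec(radii = 50))
  b <- radial_boundary(circ$yfp$data[, , 1], c(105, 100))
  dist_from_ring <- abs(sqrt((b$x - 100)^2 + (b$y - 100)^2) - 50)
  expect_true(all(dist_from_ring < 1.5))
})

test_that("boundary detection survives ring SNR 5 noise", {
  st <- render_fret_stack(cell_render_spec(radii = 50, noise_sd = 0.2,
                                           seed = 31))
  pre <- preprocess_channels(st$yfp, st$cfp)  # default 1-px smoothing
  b <- radial_boundary(pre$yfp$data[, , 1])
  expect_lt(median(abs(b$radius_px - 50)), 3)
  expect_lt(attr(b, "n_interpolated") / 360, 0.05)
})

test_that("an unsegmentable frame errors rather than returning garbage", {
  set.seed(4)
  noise_only <- matrix(runif(200 * 200), 200, 200)
  expect_error(radial_boundary(noise_only, c(100, 100), prominence_frac = 0.95),
               "unreliable")
})

test_that("boundary output is rotation-equivariant", {
  st <- render_fret_stack(cell_render_spec(radii = c(60, 40),
                                           active_arcs = list(c(0, 90, 1.5))))
  fr <- st$yfp$data[, , 1]
  b0 <- radial_boundary(fr, c(100, 100))
  # the rotation permutes pixels about the matrix center, moving the cell
  # center from (100, 100) to (101, 100)
  br <- radial_boundary(rotate_ccw90(fr), c(101, 100))
  # radii shift by 90 degrees
  shifted <- b0$radius_px[((0:359 - 90) %% 360) + 1]
  expect_true(all(abs(br$radius_px - shifted) < 1))

  rs <- ratio_image(st$yfp, st$cfp)
  hf0 <- high_fraction(perimeter_profile(rs$ratio[, , 1], b0))
  rot_ratio <- rotate_ccw90(rs$ratio[, , 1])
  hfr <- high_fraction(perimeter_profile(rot_ratio, br))
  expect_lt(abs(hfr - hf0), 100 / 360)  # within 1 point of 360
})

test_that("ratio statistics are invariant to a common intensity scale", {
  st <- render_fret_stack(cell_render_spec(radii = 50,
                                           active_arcs = list(c(40, 160, 1.5))))
  k <- 7.3
  ys <- channel_stack(st$yfp$data * k)
  cs <- channel_stack(st$cfp$data * k)
  rs0 <- ratio_image(st$yfp, st$cfp)
  rsk <- ratio_image(ys, cs)
  expect_equal(rsk$ratio, rs0$ratio, tolerance = 1e-12)
  b <- radial_boundary(st$yfp$data[, , 1], c(100, 100))
  expect_equal(high_fraction(perimeter_profile(rsk$ratio[, , 1], b)),
               high_fraction(perimeter_profile(rs0$ratio[, , 1], b)))
})

test_that("perimeter profile is constant on a uniform ratio and keeps shape", {
  st <- render_fret_stack(cell_render_spec(radii = 50))
  rs <- ratio_image(st$yfp, st$cfp)
  b <- radial_boundary(st$yfp$data[, , 1], c(100, 100))
  p <- perimeter_profile(rs$ratio[, , 1], b)
  expect_equal(nrow(p), 360)
  expect_equal(p$smoothed, rep(1, 360), tolerance = 1e-6)
  expect_equal(high_fraction(p), 0)
})

test_that("the 10-point circular average turns a step into short ramps", {
  # analytic oracle on a synthetic profile, independent of the image path
  prof <- ifelse(0:359 >= 90 & 0:359 < 180, 1.5, 1.0)
  sm <- cilquant:::circular_ma(prof, 10)
  # plateau levels are exactly preserved away from the edges
  expect_true(all(sm[100:170] == 1.5))
  expect_true(all(sm[1:80] == 1.0))
  # transitions occupy at most 10 points each
  expect_lte(sum(sm > 1.0 + 1e-9 & sm < 1.5 - 1e-9), 20)
  # circular averaging conserves the mean
  expect_equal(mean(sm), mean(prof), tolerance = 1e-9)
})

test_that("high fraction recovers rendered arc sizes within 3 points", {
  for (deg in c(36, 90, 144, 180)) {
    st <- render_fret_stack(cell_render_spec(
      radii = 50, active_arcs = list(c(100, 100 + deg, 1.5))))
    rs <- ratio_image(st$yfp, st$cfp)
    b <- radial_boundary(st$yfp$data[, , 1], c(100, 100))
    hf <- high_fraction(perimeter_profile(rs$ratio[, , 1], b))
    expect_equal(hf, 100 * deg / 360, tolerance = 3,
                 label = sprintf("arc %d deg: %.2f", deg, hf))
  }
  expect_equal(high_fraction(data.frame(angle_deg = 0:359,
                                        ratio = rep(1.5, 360),
                                        smoothed = rep(1.5, 360),
                                        flagged = rep(FALSE, 360))), 100)
})

test_that("kymograph registration centers the migration front", {
  st <- render_fret_stack(cell_render_spec(radii = 50,
                                           active_arcs = list(c(0, 20, 1.5))))
  rs <- ratio_image(st$yfp, st$cfp)
  b <- radial_boundary(st$yfp$data[, , 1], c(100, 100))
  p <- perimeter_profile(rs$ratio[, , 1], b)

  km0 <- build_kymograph(list(p), front_angle_deg = 0)
  # front at 0 deg: shift of 180 columns; angle 0 lands at column 181
  expect_equal(km0[1, 181], p$smoothed[1])
  expect_equal(km0[1, ], p$smoothed[((0:359 + 180) %% 360) + 1],
               ignore_attr = TRUE)

  kmna <- build_kymograph(list(p), front_angle_deg = NA)
  expect_equal(kmna[1, ], p$smoothed, ignore_attr = TRUE)
  expect_true(attr(kmna, "unregistered")[1])

  const <- data.frame(angle_deg = 0:359, ratio = 1, smoothed = 1,
                      flagged = FALSE)
  class(const) <- c("perimeter_profile", "data.frame")
  kmc <- build_kymograph(list(const, const), front_angle_deg = c(10, 250))
  expect_true(all(kmc == 1))
})

test_that("a rotating arc traces a moving stripe across the kymograph", {
  st <- render_fret_stack(cell_render_spec(radii = 50,
                                           active_arcs = list(c(0, 30, 1.5))),
                          n_frames = 5, arc_rotation_deg_per_frame = 40)
  rs <- ratio_image(st$yfp, st$cfp)
  profs <- lapply(1:5, function(f) {
    b <- radial_boundary(st$yfp$data[, , f], c(100, 100))
    perimeter_profile(rs$ratio[, , f], b)
  })
  km <- build_kymograph(profs, front_angle_deg = NA)
  peaks <- apply(km, 1, which.max) - 1L  # angle of max ratio per frame
  drift <- diff(peaks) %% 360
  expect_true(all(abs(drift - 40) <= 3))
})

test_that("contact-zone classification is strict at the 1.2 threshold", {
  prof <- data.frame(angle_deg = 0:359, ratio = 1,
                     smoothed = rep(1.0, 360), flagged = rep(FALSE, 360))
  prof$smoothed[46] <- 1.5   # 45 degrees
  prof$smoothed[91] <- 1.2   # exactly the threshold at 90 degrees
  prof$flagged[181] <- TRUE
  class(prof) <- c("perimeter_profile", "data.frame")
  expect_equal(classify_contact_zone(prof, 45), "high")
  expect_equal(classify_contact_zone(prof, 0), "low")
  expect_equal(classify_contact_zone(prof, 90), "low")  # strict >
  expect_equal(c(classify_contact_zone(prof, 180)), "indeterminate")
})

test_that("front_angle reports the pre-contact migration direction", {
  ev <- scripted_events(1, mean_deg = 180, sd_deg = 0, seed0 = 3)[[1]]
  expect_equal(front_angle(ev$track, ev$contact_frame), 0, tolerance = 1)
})
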