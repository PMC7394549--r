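test_that("pole detection finds synthetic Gaussians to sub-pixel precision", {
  truth_px <- rbind(c(40.3, 60.7), c(85.6, 70.2))
  img <- chiralflow:::render_spots(128, 128, truth_px, sigma = 2,
                                   amplitude = 150)
  det <- detect_poles(img, expected_separation = 40)
  expect_true(det$ok)
  found <- det$positions[order(det$positions[, 1]), ]
  expect_lt(max(abs(found - truth_px)), 0.5)
  # single blob -> flagged
  one <- chiralflow:::render_spots(128, 128, rbind(c(60, 60)), sigma = 2,
                                   amplitude = 150)
  expect_false(detect_poles(one, expected_separation = 40)$ok)
})

test_that("detection stays within 1 px under noise (seeded Monte-Carlo)", {
  truth_px <- rbind(c(40, 64), c(88, 64))
  errs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      img <- chiralflow:::render_spots(128, 128, truth_px, sigma = 2,
                                       amplitude = 50)
      img <- matrix(rpois(length(img), pmax(img, 0)), 128, 128) +
        matrix(rnorm(length(img), sd = 10), 128, 128)  # SNR ~ 5
    })
    det <- detect_poles(img, expected_separation = 48)
    if (!det$ok) return(Inf)
    found <- det$positions[order(det$positions[, 1]), ]
    max(sqrt(rowSums((found - truth_px)^2)))
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("tracking preserves identity, interpolates gaps and flags failures", {
  mov <- sim_spindle_movie(spindle_truth(seed = 4), n_frames = 30)
  track <- track_poles(mov)
  expect_equal(nrow(track), 30)
  # identities preserved: pole 1 stays the left pole throughout
  expect_true(all(track$x1 < track$x2))
  err <- max(abs(cbind(track$x1, track$y1, track$x2, track$y2) -
                   cbind(mov$track_truth$x1, mov$track_truth$y1,
                         mov$track_truth$x2, mov$track_truth$y2)))
  expect_lt(err, 0.2)  # um
  # static poles -> constant track
  static <- sim_spindle_movie(
    spindle_truth(skew_rate_profile = function(t) rep(0, length(t)),
                  elongation_profile = function(t) rep(0, length(t)),
                  noise_sigma = 0, seed = 1),
    n_frames = 5
  )
  st <- track_poles(static)
  expect_lt(max(abs(st$x1 - st$x1[1])), 0.05)
  # a blank frame in the middle is gap-interpolated and flagged
  mov2 <- mov
  mov2$stack$frames[[10]] <- matrix(0, 128, 128)
  tr2 <- track_poles(mov2)
  expect_true(tr2$interpolated[tr2$frame == 10])
  expect_true(any(grepl("gap interpolated", attr(tr2, "flags"))))
})

test_that("plane projection is coordinate selection for identity axes", {
  axes <- list(ap = c(1, 0, 0), dv = c(0, 0, 1), lr = c(0, 1, 0))
  tr3 <- tibble::tibble(
    frame = 1:3, time_s = c(0, 3, 6),
    x1 = c(0, 1, 2), y1 = c(5, 5, 5), z1 = c(1, 2, 3),
    x2 = c(10, 11, 12), y2 = c(7, 7, 7), z2 = c(4, 5, 6)
  )
  ap_dv <- project_track(tr3, "AP-DV", axes)
  expect_equal(ap_dv$x1, tr3$x1)
  expect_equal(ap_dv$y1, tr3$z1)
  lr_dv <- project_track(tr3, "LR-DV", axes)
  expect_equal(lr_dv$x1, tr3$y1)
  expect_equal(attr(lr_dv, "viewing"), "from the anterior")
  # a track lying in the AP-DV plane collapses its AP spread in LR-DV
  expect_equal(diff(range(lr_dv$x1)), 0)
  # a prescribed 3-D skew splits into the constructed per-plane angles
  ang_ap <- 20 * pi / 180
  tr_skew <- tibble::tibble(
    frame = 1:2, time_s = c(0, 60),
    x1 = c(-4, -4 * cos(ang_ap)), y1 = c(0, 0), z1 = c(0, -4 * sin(ang_ap)),
    x2 = c(4, 4 * cos(ang_ap)), y2 = c(0, 0), z2 = c(0, 4 * sin(ang_ap))
  )
  pr <- project_track(tr_skew, "AP-DV", axes)
  expect_equal(skew_angle(pr), 20, tolerance = 1e-9)
  bad <- list(ap = c(1, 0, 0), dv = c(1, 0, 0), lr = c(0, 0, 1))
  expect_error(project_track(tr3, "AP-DV", bad), "orthonormal")
})

test_that("skew angles are rotation- and identity-invariant line angles", {
  t0 <- spindle_track(1:2, c(0, 60),
                      x1 = c(0, 0), y1 = c(0, 0),
                      x2 = c(8, 8 * cos(37.51 * pi / 180)),
                      y2 = c(0, 8 * sin(37.51 * pi / 180)))
  expect_equal(skew_angle(t0), 37.51, tolerance = 1e-9)
  # identical orientations -> 0
  tid <- spindle_track(1:2, c(0, 60), c(0, 0), c(0, 0), c(8, 8), c(0, 0))
  expect_equal(skew_angle(tid), 0)
  # global rotation of all positions leaves the angle unchanged
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  a <- 0.7
  p11 <- rot(c(0, 0), a); p12 <- rot(c(8, 0), a)
  p21 <- rot(c(0, 0), a)
  p22 <- rot(8 * c(cos(37.51 * pi / 180), sin(37.51 * pi / 180)), a)
  tr_rot <- spindle_track(1:2, c(0, 60), c(p11[1], p21[1]), c(p11[2], p21[2]),
                          c(p12[1], p22[1]), c(p12[2], p22[2]))
  expect_equal(skew_angle(tr_rot), 37.51, tolerance = 1e-9)
  # swapping pole identities leaves the line angle unchanged
  tr_sw <- spindle_track(1:2, c(0, 60), t0$x2, t0$y2, t0$x1, t0$y1)
  expect_equal(skew_angle(tr_sw), skew_angle(t0), tolerance = 1e-12)
  # zero-length axis errors
  tz <- spindle_track(1:2, c(0, 60), c(0, 1), c(0, 1), c(8, 1), c(0, 1))
  expect_error(skew_angle(tz), "Zero-length")
})

test_that("rate analysis recovers constructed slopes and respects the window", {
  # linear ramp a*t -> peak rate = a regardless of smoothing
  ra <- rate_analysis(rotating_track(function(t) rep(1.2, length(t))))
  expect_equal(ra$peak_skew_rate, 1.2, tolerance = 1e-6)
  # piecewise ramp: 3 deg/min before 30 s, 1.5 deg/min inside 60-120 s;
  # the steeper out-of-window slope must be ignored
  rate_fun <- function(t) ifelse(t < 0.5, 3, ifelse(t >= 1 & t <= 2, 1.5, 0.2))
  ra2 <- rate_analysis(rotating_track(rate_fun))
  expect_equal(ra2$peak_skew_rate, 1.5, tolerance = 0.1)
  expect_lt(ra2$peak_skew_rate, 2)
  # constant elongation at 1 um/min -> peak elongation rate 1
  tt <- seq(0, 180, by = 3)
  sep <- 8 + tt / 60
  tr_el <- spindle_track(seq_along(tt), tt, x1 = -sep / 2, y1 = 0 * tt,
                         x2 = sep / 2, y2 = 0 * tt)
  expect_equal(rate_analysis(tr_el)$peak_elongation_rate, 1, tolerance = 1e-6)
  # short track flagged
  short <- rotating_track(function(t) rep(1, length(t)), t_end_s = 40)
  ra3 <- rate_analysis(short)
  expect_true(any(grepl("shorter", ra3$flags)))
})

test_that("rate analysis of an integrated rate profile recovers its in-window max", {
  # peaked profile with max 1.3 deg/min at t = 90 s (inside 60-120 s)
  prof <- function(t) 0.4 + 0.9 * exp(-(t - 1.5)^2 / (2 * 0.4^2))
  ra <- rate_analysis(rotating_track(prof))
  expect_equal(ra$peak_skew_rate, 1.3, tolerance = 0.05)
})

test_that("synthetic movies round-trip skew angle and peak rate", {
  # 37.5 deg prescribed final skew at 30 s sampling
  tr <- spindle_truth(pole1 = c(8.8, 12.8), pole2 = c(16.8, 12.8),
                      skew_rate_profile = function(t) rep(0.5, length(t)),
                      elongation_profile = function(t) rep(0.08, length(t)),
                      frame_interval = 30, seed = 2)
  mov <- sim_spindle_movie(tr, n_frames = 151)
  track <- track_poles(mov)
  expect_lt(abs(skew_angle(track) - 37.5), 2)
  # peak rate from noisy movies (mean over seeds, peaked profile)
  prof <- function(t) 0.4 + 0.9 * exp(-(t - 1.5)^2 / (2 * 0.4^2))
  peaks <- vapply(1:4, function(s) {
    m <- sim_spindle_movie(spindle_truth(seed = s, skew_rate_profile = prof),
                           n_frames = 61)
    rate_analysis(track_poles(m))$peak_skew_rate
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 1.3) / 1.3, 0.1)
})
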