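test_that("PIV recovers exact translations to sub-pixel precision", {
  cases <- list(c(1.2, -0.8), c(0.5, 0.25), c(2.5, 0))
  for (sh in cases) {
    vf <- compute_piv(speckle_pair(sh))
    expect_lt(abs(median(vf$u_px) - sh[1]), 0.1)
    expect_lt(abs(median(vf$v_px) - sh[2]), 0.1)
  }
})

test_that("PIV degenerate inputs behave as documented", {
  # identical consecutive frames -> zero field
  st <- speckle_pair(c(0, 0))
  vf <- compute_piv(st)
  expect_lt(max(abs(c(vf$u_px, vf$v_px))), 0.05)
  # window larger than image -> error
  small <- image_stack(list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8)),
                       0.2, 3)
  expect_error(compute_piv(small), "larger than the image")
  # all-dark frames -> empty mask with a warning
  dark <- image_stack(list(matrix(0, 64, 64), matrix(0, 64, 64)), 0.2, 3)
  expect_warning(vfd <- compute_piv(dark, windows = c(32, 16)), "All-dark")
  expect_false(any(vfd$valid))
})

test_that("chiral statistics match hand-evaluated cross products", {
  fr <- unit_frame()
  # e_z . (e_x x v2 - e_x x v1) evaluated by hand:
  expect_equal(chiral_velocity(c(0, 2), c(0, -2), fr), -4)
  expect_equal(chiral_velocity(c(1, -3), c(-1, 3), fr), 6)
  expect_equal(chiral_velocity(c(0, 3), c(0, 3), fr), 0)   # pure net rotation
  expect_equal(net_rotation_velocity(c(0, 2), c(0, 2), fr), 4)
  expect_equal(net_rotation_velocity(c(0, 2), c(0, -2), fr), 0)
  expect_equal(net_rotation_velocity(c(0, 0), c(0, 0), fr), 0)
  expect_equal(contractile_velocity(c(2, 0), c(-2, 0), fr), -4)
  expect_equal(contractile_velocity(c(1.3, 2), c(1.3, -5), fr), 0)
  expect_equal(flow_speed(c(3, 4), c(0, 0)), 5)
  expect_equal(flow_speed(c(0, 2), c(0, -2)), 4)
  expect_equal(flow_speed(c(0, 0), c(0, 0)), 0)
  # handedness encoding
  expect_equal(handedness(-4), "right-handed")
  expect_equal(handedness(3), "left-handed")
  expect_equal(handedness(0.1, ci95 = 0.5), "none")
})

test_that("planar reduction, mirror and swap identities hold on random vectors", {
  fr <- unit_frame()
  withr::with_seed(11, {
    for (i in 1:200) {
      v1 <- rnorm(2, sd = 3); v2 <- rnorm(2, sd = 3)
      vc <- chiral_velocity(v1, v2, fr)
      vr <- net_rotation_velocity(v1, v2, fr)
      vcon <- contractile_velocity(v1, v2, fr)
      # Eq. 2 equals the e_y-component difference in the plane
      expect_equal(vc, v2[2] - v1[2], tolerance = 1e-12)
      # mirror flip (y -> -y) negates vc and vr, preserves vcontr
      m1 <- c(v1[1], -v1[2]); m2 <- c(v2[1], -v2[2])
      expect_equal(chiral_velocity(m1, m2, fr), -vc, tolerance = 1e-12)
      expect_equal(net_rotation_velocity(m1, m2, fr), -vr, tolerance = 1e-12)
      expect_equal(contractile_velocity(m1, m2, fr), vcon, tolerance = 1e-12)
      # ROI swap negates vc and vcontr, preserves vr
      expect_equal(chiral_velocity(v2, v1, fr), -vc, tolerance = 1e-12)
      expect_equal(contractile_velocity(v2, v1, fr), -vcon, tolerance = 1e-12)
      expect_equal(net_rotation_velocity(v2, v1, fr), vr, tolerance = 1e-12)
    }
  })
})

test_that("division frames reject degenerate input and non-orthonormal axes", {
  expect_error(division_frame(c(1, 1), c(1, 1), c(1, 0)), "zero length")
  expect_error(division_frame(c(0, 0), c(0, 10), c(0, 1)), "parallel")
  fr <- unit_frame()
  broken <- fr
  broken$ex <- c(2, 0)
  expect_error(chiral_velocity(c(0, 1), c(0, 1), broken), "orthonormal")
})

test_that("ROI placement follows the published cell-size scaling", {
  fr <- unit_frame()
  expect_equal(place_rois(fr, "AB")$outer[["2"]], 8.5)
  expect_equal(place_rois(fr, "P0")$outer[["1"]], 10)
  expect_equal(place_rois(fr, "P2")$outer[["2"]], 4)
  r <- place_rois(fr, outer_extent = 5.5)
  expect_equal(unname(r$outer), c(5.5, 5.5))
  expect_error(place_rois(fr, "XYZ"), "Unknown")
  expect_error(place_rois(fr, "AB", inner_offset = 0.5), "inner_offset")
  expect_warning(
    place_rois(fr, "P0", pixel_size = 1, image_shape = c(99, 55)),
    "clipped"
  )
})

test_that("ROI averaging reduces constant and antisymmetric fields correctly", {
  fr <- unit_frame()
  # synthetic field on a grid straddling the ring at x = 50
  grid <- expand.grid(x = seq(8, 92, by = 4), y = seq(8, 92, by = 4))
  base <- tibble::tibble(pair = 1L, x = grid$x, y = grid$y, valid = TRUE)
  mk <- function(u, v) {
    velocity_field(dplyr::mutate(base, u_px = 0, v_px = 0, u = u, v = v),
                   pixel_size = 1, frame_interval = 1, window = 16, step = 4)
  }
  rois <- place_rois(fr, outer_extent = 20, width = 60, pixel_size = 1)
  # constant field (a, b)
  av <- average_roi_velocity(mk(1.5, -2.5), rois, fr, time_window = 1)
  expect_equal(av$v1, c(1.5, -2.5), tolerance = 1e-12)
  expect_equal(av$v2, c(1.5, -2.5), tolerance = 1e-12)
  # antisymmetric y-field +/- u about the ring
  anti <- mk(0, ifelse(grid$x > 50, 3, -3))
  av2 <- average_roi_velocity(anti, rois, fr, time_window = 1)
  expect_equal(av2$v1, c(0, -3), tolerance = 1e-12)
  expect_equal(av2$v2, c(0, 3), tolerance = 1e-12)
  # low-coverage flag when most vectors are invalid
  sparse <- mk(1, 1)
  sparse$valid <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), length.out = nrow(sparse))
  av3 <- average_roi_velocity(sparse, rois, fr, time_window = 1)
  expect_true(all(av3$low_coverage))
})

test_that("vc sample summaries behave on constant, symmetric and Gaussian data", {
  s <- summarize_vc_samples(rep(2.5, 10))
  expect_equal(s$mean, 2.5)
  expect_equal(s$ci95, 0)
  expect_equal(s$sigma, 0)
  expect_equal(summarize_vc_samples(c(-3, 3))$mean, 0)
  expect_true(is.na(summarize_vc_samples(c(-3, 3))$ci95))  # < 3 samples
  withr::with_seed(5, x <- rnorm(200, mean = -7, sd = 1))
  s2 <- summarize_vc_samples(x)
  expect_lt(abs(s2$mu + 7), s2$ci95)
  expect_equal(s2$sigma, sd(x) * sqrt(199 / 200), tolerance = 1e-12)
})

test_that("long-axis binning matches a quadrature oracle", {
  fr <- unit_frame()
  f <- function(xi) 2 * sin(xi / 10)  # e_y velocity as a function of xi (um)
  # bin edges aligned halfway between sample columns so the discrete bin
  # mean is a midpoint rule for the integral oracle
  grid <- expand.grid(x = seq(2.5, 97.5, by = 1), y = seq(10, 90, by = 4))
  field <- velocity_field(
    tibble::tibble(pair = 1L, x = grid$x, y = grid$y, u_px = 0, v_px = 0,
                   u = 0, v = f(grid$x - 50), valid = TRUE),
    pixel_size = 1, frame_interval = 1, window = 16, step = 4
  )
  prof <- bin_longaxis_profile(field, fr, n_bins = 8,
                               axis_range = c(-48, 48))
  edges <- seq(-48, 48, length.out = 9)
  oracle <- vapply(seq_len(8), function(b) {
    stats::integrate(f, edges[b], edges[b + 1])$value / diff(edges)[b]
  }, numeric(1))
  expect_equal(prof$vy, oracle, tolerance = 1e-3)
  # constant field -> all bins equal
  const <- velocity_field(
    tibble::tibble(pair = 1L, x = grid$x, y = grid$y, u_px = 0, v_px = 0,
                   u = 0, v = 1.7, valid = TRUE),
    pixel_size = 1, frame_interval = 1, window = 16, step = 4
  )
  expect_equal(bin_longaxis_profile(const, fr, n_bins = 5)$vy, rep(1.7, 5))
})

test_that("full movie round trip recovers all three flow components", {
  mov <- sim_flow_movie(flow_truth(vc = -5, vr = 1.5, vcontr = -3,
                                   noise_sigma = 0.3, seed = 9))
  cs <- analyze_movie(mov)
  s <- glance(cs)
  expect_lt(abs(s$vc - (-5)) / 5, 0.1)
  expect_lt(abs(s$vcontr - (-3)) / 3, 0.1)
  expect_lt(abs(s$vr - 1.5), 0.5)
  expect_equal(s$handedness, "right-handed")
  expect_equal(nrow(tidy(cs)), 7)  # 21 s window at 3 s intervals
  # mirrored movie: vc and vr negate, vcontr invariant
  mirrored <- mov
  mirrored$stack <- mirror_stack(mov$stack)
  sm <- glance(analyze_movie(mirrored))
  expect_equal(sm$vc, -s$vc, tolerance = 1e-9)
  expect_equal(sm$vr, -s$vr, tolerance = 1e-9)
  expect_equal(sm$vcontr, s$vcontr, tolerance = 1e-9)
})
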