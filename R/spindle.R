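#' Ground truth for a synthetic spindle-pole movie
#'
#' Two diffraction-limited poles (Gaussian spots of width `psf_sigma`)
#' whose separation grows according to `elongation_profile` while the
#' pole-to-pole axis rotates in the projection plane at
#' `skew_rate_profile`. Defaults emulate an AB-like anaphase: initial
#' separation 8 um, steady elongation of 1.5 um/min and a skew rate of
#' 0.5 deg/min, imaged every 3 s.
#'
#' @param pole1,pole2 initial pole positions (um, 2-vectors in the
#'   projection plane); must be distinct.
#' @param skew_rate_profile function of time (min) returning deg/min.
#' @param elongation_profile function of time (min) returning um/min.
#' @param frame_interval seconds between frames (> 0).
#' @param psf_sigma spot width (um).
#' @param amplitude photon amplitude of each spot (counts).
#' @param noise_sigma additive Gaussian camera noise (counts).
#' @param seed integer seed.
#' @return A `spindle_truth` list.
#' @export
spindle_truth <- function(pole1 = c(8, 12.8), pole2 = c(16, 12.8),
                          skew_rate_profile = function(t) rep(0.5, length(t)),
                          elongation_profile = function(t) rep(1.5, length(t)),
                          frame_interval = 3, psf_sigma = 0.4,
                          amplitude = 150, noise_sigma = 2, seed = 1L) {
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  if (all(pole1 == pole2)) abort("Poles must be distinct at t0.")
  structure(
    list(pole1 = pole1, pole2 = pole2,
         skew_rate_profile = skew_rate_profile,
         elongation_profile = elongation_profile,
         frame_interval = frame_interval, psf_sigma = psf_sigma,
         amplitude = amplitude, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "spindle_truth"
  )
}

# integrate the prescribed profiles to per-frame pole positions (um)
spindle_trajectory <- function(truth, n_frames) {
  dt_min <- truth$frame_interval / 60
  t_min <- (seq_len(n_frames) - 1) * dt_min
  center <- (truth$pole1 + truth$pole2) / 2
  sep0 <- truth$pole2 - truth$pole1
  s0 <- sqrt(sum(sep0^2))
  theta0 <- atan2(sep0[2], sep0[1])
  # trapezoidal integration of the rate profiles
  cum <- function(rate) {
    r <- rate(t_min)
    c(0, cumsum((head(r, -1) + tail(r, -1)) / 2 * dt_min))
  }
  theta <- theta0 + cum(truth$skew_rate_profile) * pi / 180
  s <- s0 + cum(truth$elongation_profile)
  tibble(
    frame = seq_len(n_frames),
    time_s = t_min * 60,
    x1 = center[1] - s / 2 * cos(theta), y1 = center[2] - s / 2 * sin(theta),
    x2 = center[1] + s / 2 * cos(theta), y2 = center[2] + s / 2 * sin(theta)
  )
}

#' Simulate a spindle-pole movie
#'
#' Renders the two poles as Gaussian spots along their integrated
#' skew/elongation trajectories and adds Poisson photon noise plus
#' Gaussian camera noise. Movies whose poles would leave the field of view
#' or approach each other within `2 * psf_sigma` (the ambiguous-detection
#' regime) are rejected.
#'
#' @param truth a [spindle_truth()].
#' @param image_shape `c(ny, nx)` in pixels.
#' @param n_frames number of frames.
#' @param pixel_size um per pixel.
#' @return A `spindle_movie` list with `stack`, `truth`, and
#'   `track_truth` (tibble of exact per-frame pole positions, um).
#' @export
sim_spindle_movie <- function(truth, image_shape = c(128, 128), n_frames = 60,
                              pixel_size = 0.2) {
  stopifnot(inherits(truth, "spindle_truth"))
  ny <- image_shape[1]; nx <- image_shape[2]
  traj <- spindle_trajectory(truth, n_frames)
  px <- cbind(traj$x1, traj$y1, traj$x2, traj$y2) / pixel_size
  if (any(px[, c(1, 3)] < 2 | px[, c(1, 3)] > nx - 1) ||
      any(px[, c(2, 4)] < 2 | px[, c(2, 4)] > ny - 1)) {
    abort("Poles leave the field of view; shrink the trajectory or enlarge the image.")
  }
  sep <- sqrt((traj$x2 - traj$x1)^2 + (traj$y2 - traj$y1)^2)
  if (any(sep < 2 * truth$psf_sigma)) {
    abort("Poles overlap within 2 * psf_sigma: ambiguous detection regime.")
  }
  sigma_px <- truth$psf_sigma / pixel_size
  frames <- withr::with_seed(truth$seed, {
    lapply(seq_len(n_frames), function(i) {
      img <- render_spots(
        nx, ny,
        positions = rbind(px[i, 1:2], px[i, 3:4]),
        sigma = sigma_px, amplitude = truth$amplitude
      )
      img <- matrix(rpois(length(img), pmax(img, 0)), ny, nx)
      img + matrix(rnorm(length(img), sd = truth$noise_sigma), ny, nx)
    })
  })
  stack <- image_stack(frames, pixel_size, truth$frame_interval,
                       channel = "tubulin")
  structure(list(stack = stack, truth = truth, track_truth = traj),
            class = "spindle_movie")
}

# lightweight separable Gaussian blur (replicated edges)
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Detect the two spindle poles in a single frame
#'
#' Gaussian-smoothed local-maxima detection: the brightest maximum and the
#' next brightest maximum at least half the expected separation away,
#' refined to sub-pixel precision by an intensity-weighted centroid.
#'
#' @param img intensity matrix.
#' @param expected_separation expected pole separation (px).
#' @param smooth_sigma smoothing width (px).
#' @return A list with `positions` (2 x 2 matrix, rows = poles, columns =
#'   x, y in px) and `ok`; frames without two separated maxima return
#'   `ok = FALSE` and are meant to be excluded.
#' @export
detect_poles <- function(img, expected_separation, smooth_sigma = 2) {
  sm <- gaussian_blur(img, smooth_sigma)
  ny <- nrow(sm); nx <- ncol(sm)
  inner <- sm[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner >= sm[1:(ny - 2), 2:(nx - 1)] &
    inner >= sm[3:ny, 2:(nx - 1)] &
    inner >= sm[2:(ny - 1), 1:(nx - 2)] &
    inner >= sm[2:(ny - 1), 3:nx] &
    inner >= sm[1:(ny - 2), 1:(nx - 2)] &
    inner >= sm[3:ny, 3:nx] &
    inner >= sm[1:(ny - 2), 3:nx] &
    inner >= sm[3:ny, 1:(nx - 2)]
  thresh <- median(sm) + 2 * mad(sm)
  idx <- which(is_max & inner > thresh, arr.ind = TRUE)
  if (nrow(idx) < 2) return(list(positions = NULL, ok = FALSE))
  cand <- tibble(x = idx[, 2] + 1, y = idx[, 1] + 1,
                 i = inner[idx])
  cand <- cand[order(-cand$i), ]
  p1 <- c(cand$x[1], cand$y[1])
  rest <- cand[-1, ]
  dist2 <- (rest$x - p1[1])^2 + (rest$y - p1[2])^2
  far <- which(dist2 >= (expected_separation / 2)^2)
  if (!length(far)) return(list(positions = NULL, ok = FALSE))
  p2 <- c(rest$x[far[1]], rest$y[far[1]])
  # 3-point Gaussian sub-pixel fit on the smoothed peak (the smoothed
  # spot is itself Gaussian, so this is unbiased and precise)
  refine <- function(p) {
    x0 <- clamp(p[1], 2L, nx - 1L); y0 <- clamp(p[2], 2L, ny - 1L)
    dx <- subpixel_1d(sm[y0, x0 - 1], sm[y0, x0], sm[y0, x0 + 1])
    dy <- subpixel_1d(sm[y0 - 1, x0], sm[y0, x0], sm[y0 + 1, x0])
    c(x0 + dx, y0 + dy)
  }
  list(positions = rbind(refine(p1), refine(p2)), ok = TRUE)
}

#' Track the spindle poles through a movie
#'
#' Runs [detect_poles()] on every frame and links detections by nearest
#' neighbour while preserving pole identity; gaps of up to `max_gap`
#' frames (failed detections) are interpolated linearly and flagged.
#' Frames where the identity assignment is ambiguous (the two pairings
#' have nearly equal cost) are flagged as crossings.
#'
#' @param movie a `spindle_movie`, or an [image_stack()].
#' @param expected_separation expected pole separation (px); defaults to
#'   the truth separation for a `spindle_movie`.
#' @param max_gap maximum run of missing frames to interpolate.
#' @return A `spindle_track`: tibble with `frame`, `time_s`, `x1`, `y1`,
#'   `x2`, `y2` (um) and `interpolated`; attributes `flags` (character)
#'   and `pixel_size`.
#' @export
track_poles <- function(movie, expected_separation = NULL, max_gap = 2) {
  if (inherits(movie, "spindle_movie")) {
    stack <- movie$stack
    if (is.null(expected_separation)) {
      t0 <- movie$track_truth[1, ]
      expected_separation <- sqrt((t0$x2 - t0$x1)^2 + (t0$y2 - t0$y1)^2) /
        stack$pixel_size
    }
  } else {
    stack <- movie
    if (is.null(expected_separation)) {
      abort("`expected_separation` (px) is required for a raw stack.")
    }
  }
  n <- length(stack$frames)
  det <- lapply(stack$frames, detect_poles,
                expected_separation = expected_separation)
  flags <- character(0)
  pos <- array(NA_real_, dim = c(n, 2, 2))  # frame x pole x (x, y)
  prev <- NULL
  for (i in seq_len(n)) {
    if (!det[[i]]$ok) {
      flags <- c(flags, sprintf("frame %d: <2 maxima, excluded", i))
      next
    }
    p <- det[[i]]$positions
    if (is.null(prev)) {
      pos[i, , ] <- p
    } else {
      cost_id <- sum((p[1, ] - prev[1, ])^2) + sum((p[2, ] - prev[2, ])^2)
      cost_sw <- sum((p[2, ] - prev[1, ])^2) + sum((p[1, ] - prev[2, ])^2)
      if (cost_sw < cost_id) p <- p[2:1, ]
      if (abs(cost_id - cost_sw) < 1) {
        flags <- c(flags, sprintf("frame %d: identity ambiguous (crossing)", i))
      }
      pos[i, , ] <- p
    }
    prev <- pos[i, , ]
  }
  valid <- which(!is.na(pos[, 1, 1]))
  if (length(valid) < 2) abort("Fewer than 2 frames with valid detections.")
  interpolated <- rep(FALSE, n)
  for (i in setdiff(seq_len(n), valid)) {
    lo <- max(valid[valid < i], -Inf); hi <- min(valid[valid > i], Inf)
    if (is.finite(lo) && is.finite(hi) && (hi - lo - 1) <= max_gap) {
      f <- (i - lo) / (hi - lo)
      pos[i, , ] <- (1 - f) * pos[lo, , ] + f * pos[hi, , ]
      interpolated[i] <- TRUE
      flags <- c(flags, sprintf("frame %d: gap interpolated", i))
    }
  }
  keep <- which(!is.na(pos[, 1, 1]))
  ps <- stack$pixel_size
  out <- tibble(
    frame = keep,
    time_s = (keep - 1) * stack$frame_interval,
    x1 = pos[keep, 1, 1] * ps, y1 = pos[keep, 1, 2] * ps,
    x2 = pos[keep, 2, 1] * ps, y2 = pos[keep, 2, 2] * ps,
    interpolated = interpolated[keep]
  )
  attr(out, "flags") <- flags
  attr(out, "pixel_size") <- ps
  class(out) <- c("spindle_track", class(out))
  out
}

#' Build a spindle track directly from known pole positions
#'
#' @param frame,time_s,x1,y1,x2,y2 per-frame pole coordinates (um).
#' @return A `spindle_track` tibble.
#' @export
spindle_track <- function(frame, time_s, x1, y1, x2, y2) {
  out <- tibble(frame = frame, time_s = time_s, x1 = x1, y1 = y1,
                x2 = x2, y2 = y2, interpolated = FALSE)
  class(out) <- c("spindle_track", class(out))
  out
}

#' Project a 3-D spindle track onto a named embryo plane
#'
#' Orthogonal projection of 3-D pole positions onto the
#' anteroposterior-dorsoventral (AP-DV) or left-right-dorsoventral (LR-DV)
#' plane; the LR-DV view is taken from the anterior.
#'
#' @param track a data frame with per-frame 3-D pole positions `x1, y1,
#'   z1, x2, y2, z2` (um) plus `frame`, `time_s`.
#' @param plane `"AP-DV"` or `"LR-DV"`.
#' @param axes list of orthonormal embryo axis 3-vectors `ap`, `dv`, `lr`.
#' @return A `spindle_track` with 2-D coordinates in the projection plane
#'   (first axis = AP or LR, second = DV); the viewing direction is
#'   recorded in attribute `"viewing"`.
#' @export
project_track <- function(track, plane = c("AP-DV", "LR-DV"), axes) {
  plane <- match.arg(plane)
  A <- rbind(axes$ap, axes$dv, axes$lr)
  if (max(abs(A %*% t(A) - diag(3))) > 1e-8) {
    abort("Embryo axes must be orthonormal.")
  }
  basis <- if (plane == "AP-DV") list(axes$ap, axes$dv) else list(axes$lr, axes$dv)
  pr <- function(px, py, pz, b) px * b[1] + py * b[2] + pz * b[3]
  out <- spindle_track(
    frame = track$frame, time_s = track$time_s,
    x1 = pr(track$x1, track$y1, track$z1, basis[[1]]),
    y1 = pr(track$x1, track$y1, track$z1, basis[[2]]),
    x2 = pr(track$x2, track$y2, track$z2, basis[[1]]),
    y2 = pr(track$x2, track$y2, track$z2, basis[[2]])
  )
  attr(out, "viewing") <- if (plane == "LR-DV") "from the anterior" else "from the left"
  out
}

track_axis <- function(track, i) {
  c(track$x2[i] - track$x1[i], track$y2[i] - track$y1[i])
}

#' Spindle skew angle between two timepoints
#'
#' The angle between the pole-to-pole line at the onset of spindle
#' elongation (anaphase-B) and at completion of cytokinesis. By default
#' the unsigned line-to-line angle (<= 90 deg) is returned, matching how
#' skew magnitudes are summarised; `signed = TRUE` returns the signed
#' in-plane rotation (positive = counter-clockwise in the viewing
#' convention recorded on the track).
#'
#' @param track a `spindle_track`.
#' @param t0_frame,t1_frame frame indices of the initial and final
#'   orientation (defaults: first and last tracked frame).
#' @param signed return the signed rotation instead of the line angle.
#' @return Angle in degrees.
#' @export
skew_angle <- function(track, t0_frame = NULL, t1_frame = NULL,
                       signed = FALSE) {
  i0 <- if (is.null(t0_frame)) 1L else which(track$frame == t0_frame)
  i1 <- if (is.null(t1_frame)) nrow(track) else which(track$frame == t1_frame)
  if (!length(i0) || !length(i1)) abort("Requested frames are not in the track.")
  a0 <- track_axis(track, i0); a1 <- track_axis(track, i1)
  n0 <- sqrt(sum(a0^2)); n1 <- sqrt(sum(a1^2))
  if (n0 == 0 || n1 == 0) abort("Zero-length spindle axis.")
  ang <- atan2(a0[1] * a1[2] - a0[2] * a1[1], sum(a0 * a1)) * 180 / pi
  if (signed) ang else {
    u <- abs(ang)
    if (u > 90) 180 - u else u
  }
}

moving_average <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(n, i + w %/% 2)
    mean(v[lo:hi])
  }, numeric(1))
}

# sliding-window least-squares slope (centred local linear regression,
# truncated at the series ends); reduces to a centred difference for
# window <= 3
moving_slope <- function(t, v, w) {
  n <- length(v)
  hw <- max(1L, w %/% 2)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - hw):min(n, i + hw)
    tt <- t[idx] - mean(t[idx])
    sum(tt * (v[idx] - mean(v[idx]))) / sum(tt^2)
  }, numeric(1))
}

#' Skew and elongation kinematics of a spindle track
#'
#' Synchronises the track at the onset of anaphase-B, computes the
#' cumulative skew angle (difference between the spindle angle at each
#' timepoint and at onset) and the pole separation, smooths both with a
#' centred moving average, estimates rates with a sliding-window
#' least-squares ("moving slope") estimator on the smoothed series, and
#' reports the peak rates within the 60-120 s window after onset. Tracks
#' shorter than the window use the available overlap and are flagged.
#'
#' @param track a `spindle_track`.
#' @param onset_frame frame index of anaphase-B onset (default: first
#'   tracked frame). Alternatively `detect_onset = TRUE` uses the first
#'   frame where the smoothed elongation rate exceeds 0.5 um/min for 3
#'   consecutive frames.
#' @param smoothing_window moving-average width in frames (default 5,
#'   i.e. 15 s at 3 s intervals).
#' @param slope_window width (frames) of the local regression used for
#'   the rate estimate (default 9); a slope estimated over too few frames
#'   is dominated by centroid noise.
#' @param rate_window `c(min, max)` seconds after onset in which peak
#'   rates are sought (default `c(60, 120)`).
#' @param detect_onset auto-detect anaphase-B onset from the elongation
#'   rate.
#' @return A `skew_summary` list with `series` (tibble of time, skew
#'   angle, elongation and their smoothed rates), `skew_angle` (final
#'   minus initial, deg), `peak_skew_rate` (deg/min),
#'   `peak_elongation_rate` (um/min), `flags`.
#' @export
rate_analysis <- function(track, onset_frame = NULL, smoothing_window = 5,
                          slope_window = 9, rate_window = c(60, 120),
                          detect_onset = FALSE) {
  stopifnot(nrow(track) >= 3)
  t_s <- track$time_s
  elong <- sqrt((track$x2 - track$x1)^2 + (track$y2 - track$y1)^2)
  flags <- character(0)
  if (detect_onset) {
    sm_e <- moving_average(elong, smoothing_window)
    er <- moving_slope(t_s / 60, sm_e, smoothing_window)
    run <- rle(er > 0.5)
    pos <- cumsum(c(1, run$lengths))
    hit <- which(run$values & run$lengths >= 3)
    onset_idx <- if (length(hit)) pos[hit[1]] else 1L
  } else {
    onset_idx <- if (is.null(onset_frame)) 1L else which(track$frame == onset_frame)
    if (!length(onset_idx)) abort("`onset_frame` is not in the track.")
  }
  sub <- track[onset_idx:nrow(track), ]
  t_rel <- sub$time_s - sub$time_s[1]
  a_on <- track_axis(sub, 1)
  angle <- vapply(seq_len(nrow(sub)), function(i) {
    a <- track_axis(sub, i)
    abs(atan2(a_on[1] * a[2] - a_on[2] * a[1], sum(a_on * a))) * 180 / pi
  }, numeric(1))
  elong_sub <- sqrt((sub$x2 - sub$x1)^2 + (sub$y2 - sub$y1)^2)
  sm_a <- moving_average(angle, smoothing_window)
  sm_e <- moving_average(elong_sub, smoothing_window)
  t_min <- t_rel / 60
  skew_rate <- moving_slope(t_min, sm_a, slope_window)
  elong_rate <- moving_slope(t_min, sm_e, slope_window)
  in_win <- t_rel >= rate_window[1] & t_rel <= rate_window[2]
  if (!any(in_win)) {
    flags <- c(flags, "track shorter than the rate window; using full overlap")
    in_win <- rep(TRUE, length(t_rel))
  } else if (max(t_rel) < rate_window[2]) {
    flags <- c(flags, "track ends inside the rate window; peak over available overlap")
  }
  structure(
    list(
      series = tibble(
        time_s = t_rel, skew_angle = angle, skew_angle_smooth = sm_a,
        elongation = elong_sub, elongation_smooth = sm_e,
        skew_rate = skew_rate, elongation_rate = elong_rate
      ),
      skew_angle = angle[length(angle)],
      peak_skew_rate = max(skew_rate[in_win]),
      peak_elongation_rate = max(elong_rate[in_win]),
      onset_frame = sub$frame[1],
      smoothing_window = smoothing_window,
      rate_window = rate_window,
      flags = flags
    ),
    class = "skew_summary"
  )
}

#' @export
print.skew_summary <- function(x, ...) {
  cat(sprintf(
    "<skew_summary> skew %.2f deg; peak skew rate %.3g deg/min; peak elongation rate %.3g um/min\n",
    x$skew_angle, x$peak_skew_rate, x$peak_elongation_rate
  ))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @method tidy skew_summary
#' @export
tidy.skew_summary <- function(x, ...) x$series

#' @method glance skew_summary
#' @export
glance.skew_summary <- function(x, ...) {
  tibble(skew_angle = x$skew_angle, peak_skew_rate = x$peak_skew_rate,
         peak_elongation_rate = x$peak_elongation_rate,
         onset_frame = x$onset_frame, n_flags = length(x$flags))
}
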