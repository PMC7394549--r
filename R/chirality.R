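#' Chiral flow statistics from ROI-averaged velocities
#'
#' Given the time-averaged cortical velocities `v1` and `v2` in the two cell
#' halves (ROI 1 on the side opposite the `e_x` pole, ROI 2 on the `e_x`
#' side), these reductions quantify the flow's chirality:
#'
#' * `chiral_velocity()` computes the chiral counter-rotating flow velocity
#'   \deqn{v_c = \bar e_z \cdot (\bar e_x \times \bar v_2 - \bar e_x \times \bar v_1),}
#'   which for in-plane vectors reduces to the difference of the
#'   `e_y`-components. `v_c > 0` means left-handed counter-rotation (flows
#'   appear clockwise viewed from the cytokinetic plane toward each pole),
#'   `v_c < 0` right-handed.
#' * `net_rotation_velocity()` computes
#'   \eqn{v_r = \bar e_z \cdot (\bar e_x \times \bar v_1 + \bar e_x \times \bar v_2)},
#'   the common-mode (whole-cell) rotation.
#' * `contractile_velocity()` computes
#'   \eqn{v_{contr} = \bar e_x \cdot (\bar v_2 - \bar v_1)}; flows
#'   converging on the ring give \eqn{v_{contr} < 0}.
#' * `flow_speed()` is \eqn{|\bar v_1| + |\bar v_2|}.
#'
#' @param v1,v2 ROI-averaged velocity 2-vectors `c(vx, vy)` in um/min,
#'   image coordinates (y up).
#' @param frame a [division_frame()].
#' @return A scalar velocity in um/min.
#' @export
chiral_velocity <- function(v1, v2, frame) {
  check_frame(frame)
  ex3 <- c(frame$ex, 0)
  cr <- cross3(ex3, c(v2, 0)) - cross3(ex3, c(v1, 0))
  sum(frame$ez * cr)
}

#' @rdname chiral_velocity
#' @export
net_rotation_velocity <- function(v1, v2, frame) {
  check_frame(frame)
  ex3 <- c(frame$ex, 0)
  cr <- cross3(ex3, c(v1, 0)) + cross3(ex3, c(v2, 0))
  sum(frame$ez * cr)
}

#' @rdname chiral_velocity
#' @export
contractile_velocity <- function(v1, v2, frame) {
  check_frame(frame)
  sum(frame$ex * (v2 - v1))
}

#' @rdname chiral_velocity
#' @export
flow_speed <- function(v1, v2) {
  sqrt(sum(v1^2)) + sqrt(sum(v2^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Handedness label from a counter-rotating flow velocity
#'
#' Left-handed for `vc > 0`, right-handed for `vc < 0`. When a 95%
#' confidence half-width is supplied and the interval covers zero the label
#' is `"none"`.
#'
#' @param vc mean chiral counter-rotating flow velocity (um/min).
#' @param ci95 optional half-width of the 95% confidence interval.
#' @return `"left-handed"`, `"right-handed"` or `"none"`.
#' @export
handedness <- function(vc, ci95 = NULL) {
  if (!is.null(ci95) && is.finite(ci95) && abs(vc) <= ci95) return("none")
  if (vc > 0) "left-handed" else if (vc < 0) "right-handed" else "none"
}

#' Average a velocity field inside the two ROIs
#'
#' Vector mean of the valid PIV vectors inside each ROI, over the frame
#' pairs falling in the analysis window (by default 21 s starting at the
#' annotated onset of furrow ingression, i.e. when the ring has ingressed
#' about 10%).
#'
#' @param field a [velocity_field()] tibble.
#' @param rois a [roi_pair()] from [place_rois()].
#' @param frame a [division_frame()].
#' @param onset_frame index of the first frame of the analysis window.
#' @param time_window window length in seconds (default 21).
#' @return A list with `v1`, `v2` (velocity 2-vectors, um/min), per-ROI
#'   vector counts and `low_coverage` flags (fewer than 25% valid vectors).
#' @export
average_roi_velocity <- function(field, rois, frame, onset_frame = 1,
                                 time_window = 21) {
  check_frame(frame)
  meta <- field_meta(field)
  dt <- meta$frame_interval
  pairs <- unique(field$pair)
  keep <- pairs[(pairs - onset_frame) * dt >= -1e-9 &
                  (pairs - onset_frame) * dt < time_window - 1e-9]
  if (!length(keep)) abort("No frame pairs fall inside the analysis window.")
  sub <- dplyr::filter(field, .data$pair %in% keep)
  fc <- frame_coords(frame, sub$x, sub$y, meta$pixel_size)
  half_w <- rois$width / 2
  in_width <- abs(fc$psi) <= half_w
  in1 <- in_width & fc$xi <= -rois$inner_offset & fc$xi >= -rois$outer[["1"]]
  in2 <- in_width & fc$xi >= rois$inner_offset & fc$xi <= rois$outer[["2"]]
  roi_mean <- function(sel) {
    tot <- sum(sel)
    val <- sel & sub$valid
    if (tot == 0L) {
      return(list(v = c(NA_real_, NA_real_), n = 0L, frac = 0))
    }
    list(v = c(mean(sub$u[val]), mean(sub$v[val])),
         n = sum(val), frac = sum(val) / tot)
  }
  m1 <- roi_mean(in1); m2 <- roi_mean(in2)
  list(
    v1 = m1$v, v2 = m2$v, n1 = m1$n, n2 = m2$n,
    low_coverage = c(`1` = m1$frac < 0.25, `2` = m2$frac < 0.25),
    pairs = keep
  )
}

#' Per-frame and time-averaged chiral statistics of a movie's flow field
#'
#' Applies the ROI averaging frame pair by frame pair and reduces each pair
#' to instantaneous chiral statistics, then summarises them over the
#' analysis window (mean, 95% error of the mean using the Student-t
#' quantile) and assigns the handedness label.
#'
#' @inheritParams average_roi_velocity
#' @return A `chiral_stats` object: a list with `per_frame` (tibble of
#'   instantaneous `vc`, `vr`, `vcontr`, `flow_speed` per frame pair) and
#'   `summary` (one-row tibble of time-averaged values with confidence
#'   half-widths and handedness).
#' @export
chiral_stats <- function(field, rois, frame, onset_frame = 1,
                         time_window = 21) {
  check_frame(frame)
  meta <- field_meta(field)
  avg <- average_roi_velocity(field, rois, frame, onset_frame, time_window)
  per_frame <- purrr::map_dfr(avg$pairs, function(p) {
    a <- average_roi_velocity(
      field, rois, frame,
      onset_frame = p, time_window = meta$frame_interval
    )
    tibble(
      pair = p,
      time_s = (p - onset_frame) * meta$frame_interval,
      vc = chiral_velocity(a$v1, a$v2, frame),
      vr = net_rotation_velocity(a$v1, a$v2, frame),
      vcontr = contractile_velocity(a$v1, a$v2, frame),
      flow_speed = flow_speed(a$v1, a$v2)
    )
  })
  s <- summarize_vc_samples(per_frame$vc)
  summary <- tibble(
    vc = chiral_velocity(avg$v1, avg$v2, frame),
    vr = net_rotation_velocity(avg$v1, avg$v2, frame),
    vcontr = contractile_velocity(avg$v1, avg$v2, frame),
    flow_speed = flow_speed(avg$v1, avg$v2),
    vc_ci95 = s$ci95,
    n_pairs = length(avg$pairs)
  )
  summary$handedness <- handedness(summary$vc, summary$vc_ci95)
  structure(
    list(per_frame = per_frame, summary = summary,
         v1 = avg$v1, v2 = avg$v2,
         low_coverage = avg$low_coverage),
    class = "chiral_stats"
  )
}

#' @export
print.chiral_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<chiral_stats> vc = %.2f +/- %.2f um/min (%s), vr = %.2f, vcontr = %.2f, speed = %.2f\n",
    s$vc, s$vc_ci95, s$handedness, s$vr, s$vcontr, s$flow_speed
  ))
  invisible(x)
}

#' @method tidy chiral_stats
#' @export
tidy.chiral_stats <- function(x, ...) x$per_frame

#' @method glance chiral_stats
#' @export
glance.chiral_stats <- function(x, ...) x$summary

#' Summarise instantaneous counter-rotating flow velocities
#'
#' Sample mean, 95% error of the mean (Student-t) and a maximum-likelihood
#' Gaussian fit for display against the histogram of instantaneous values.
#' With fewer than 3 samples only the mean is reported.
#'
#' @param samples numeric vector of instantaneous `vc` values (um/min).
#' @return A one-row tibble with `mean`, `ci95`, `mu`, `sigma`, `n`.
#' @export
summarize_vc_samples <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  m <- if (n) mean(samples) else NA_real_
  if (n >= 3) {
    se <- sd(samples) / sqrt(n)
    ci <- qt(0.975, df = n - 1) * se
    sigma <- sqrt(mean((samples - m)^2))  # Gaussian MLE
  } else {
    ci <- NA_real_
    sigma <- NA_real_
  }
  tibble(mean = m, ci95 = ci, mu = m, sigma = sigma, n = n)
}

#' Long-axis profile of the transverse flow
#'
#' Tiles the flow field into `n_bins` sections along the cell's long axis
#' and reports the time-averaged `e_y`-velocity per section over the whole
#' flow duration, in normalised long-axis coordinates. This is the profile
#' the thin-film active chiral fluid model is fitted to.
#'
#' @param field a [velocity_field()] tibble.
#' @param frame a [division_frame()].
#' @param n_bins number of sections (>= 3; 9 matches the published
#'   analysis).
#' @param axis_range optional `c(min, max)` of the long-axis coordinate
#'   (um, relative to the ring centre) delimiting the cell; defaults to the
#'   span of the velocity grid.
#' @return A tibble with `bin`, `x_mid` (normalised 0..1), `xi_mid` (um
#'   from the ring), `vy` (um/min), `n`; empty bins carry `NA`.
#' @export
bin_longaxis_profile <- function(field, frame, n_bins = 9, axis_range = NULL) {
  check_frame(frame)
  if (n_bins < 3) abort("`n_bins` must be >= 3.")
  meta <- field_meta(field)
  fc <- frame_coords(frame, field$x, field$y, meta$pixel_size)
  vy_ey <- field$u * frame$ey[1] + field$v * frame$ey[2]
  rng <- axis_range %||% range(fc$xi)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(fc$xi, edges, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin) & field$valid
  agg <- tibble(bin = bin[ok], vy = vy_ey[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(vy = mean(.data$vy), n = dplyr::n(), .groups = "drop")
  out <- tibble(
    bin = seq_len(n_bins),
    xi_mid = (head(edges, -1) + tail(edges, -1)) / 2,
    x_mid = (seq_len(n_bins) - 0.5) / n_bins
  ) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  out[, c("bin", "x_mid", "xi_mid", "vy", "n")]
}
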