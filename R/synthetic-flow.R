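#' Ground truth for a synthetic cortical flow movie
#'
#' Describes the composite cortical flow of a dividing cell as the sum of a
#' counter-rotating component (y-velocity of opposite sign in the two cell
#' halves, amplitude set so the chiral counter-rotating flow velocity equals
#' `vc`), a net-rotating component (common-mode y-velocity giving `vr`), a
#' contractile component (x-velocity converging on the cytokinetic ring
#' giving `vcontr`, negative for ring-directed flow) and spatially
#' correlated Gaussian velocity noise.
#'
#' Defaults emulate the AB cell of the two-cell embryo: right-handed
#' counter-rotation at -6 um/min, no net rotation, ring-directed contractile
#' flow, a centred ring, and a 24 um long axis.
#'
#' @param vc chiral counter-rotating flow velocity (um/min; negative =
#'   right-handed).
#' @param vr net-rotating flow velocity (um/min).
#' @param vcontr contractile flow velocity (um/min; negative = into ring).
#' @param cell_length cell long-axis length (um, > 0).
#' @param ring_x position of the cytokinetic ring along the long axis (um,
#'   strictly inside `(0, cell_length)`).
#' @param noise_sigma standard deviation of the velocity noise field
#'   (um/min, >= 0).
#' @param seed integer seed; all randomness in the generated movie flows
#'   from it.
#' @return A `flow_truth` list.
#' @export
flow_truth <- function(vc = -6, vr = 0, vcontr = -4,
                       cell_length = 24, ring_x = cell_length / 2,
                       noise_sigma = 0.5, seed = 1L) {
  if (cell_length <= 0) abort("`cell_length` must be > 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (ring_x <= 0 || ring_x >= cell_length) {
    abort("`ring_x` must lie strictly inside (0, cell_length).")
  }
  structure(
    list(vc = vc, vr = vr, vcontr = vcontr, cell_length = cell_length,
         ring_x = ring_x, noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "flow_truth"
  )
}

# Analytic composite velocity field (um/min) at long-axis position x_um.
# The two halves are blended with a tanh of width `transition` (um) so the
# advected texture stays smooth across the ring.
truth_velocity <- function(truth, x_um, transition = 0.5) {
  s <- tanh((x_um - truth$ring_x) / transition)
  list(vx = (truth$vcontr / 2) * s,
       vy = truth$vr / 2 + (truth$vc / 2) * s)
}

#' Evaluate the prescribed analytic flow field of a synthetic movie
#'
#' Returns the noise-free composite velocity (um/min) at the given long-axis
#' positions. Used to check the chiral statistics against the generator by
#' construction, independently of any image analysis.
#'
#' @param truth a [flow_truth()].
#' @param x_um positions along the long axis (um).
#' @param transition blend width across the ring (um).
#' @return A tibble with columns `x`, `vx`, `vy`.
#' @export
flow_field_truth <- function(truth, x_um, transition = 0.5) {
  v <- truth_velocity(truth, x_um, transition)
  tibble(x = x_um, vx = v$vx, vy = v$vy)
}

# Smooth random velocity field: i.i.d. normals on a coarse grid, bilinearly
# upsampled. Returns a function(x_px, y_px) -> list(vx, vy) in um/min.
random_velocity_field <- function(nx, ny, sigma, spacing = 16) {
  gx <- seq(1, nx + spacing, by = spacing)
  gy <- seq(1, ny + spacing, by = spacing)
  fx <- matrix(rnorm(length(gy) * length(gx), sd = sigma), length(gy), length(gx))
  fy <- matrix(rnorm(length(gy) * length(gx), sd = sigma), length(gy), length(gx))
  function(x, y) {
    xi <- (x - 1) / spacing + 1
    yi <- (y - 1) / spacing + 1
    list(vx = interp_bilinear(fx, xi, yi), vy = interp_bilinear(fy, xi, yi))
  }
}

#' Simulate a speckled cortical flow movie with known chiral statistics
#'
#' Generates a random speckle texture (Gaussian spots emulating cortical
#' myosin foci) and advects it frame by frame with the composite flow
#' prescribed by `truth`. Velocity noise is applied to the displacement
#' field itself, not only to the image intensities, so downstream PIV is
#' exercised against genuine flow variability. Particles leaving the field
#' of view re-enter on the opposite side, keeping the texture statistics
#' stationary.
#'
#' @param truth a [flow_truth()].
#' @param image_shape `c(ny, nx)` frame size in pixels. The cell long axis
#'   spans the image width, so `nx * pixel_size` should be >=
#'   `truth$cell_length`.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames (>= 2).
#' @param speckle_density speckles per square pixel. Must give at least 5
#'   speckles per final PIV interrogation window.
#' @param speckle_sigma Gaussian spot width (px).
#' @param intensity_noise additive Gaussian image noise (a.u.).
#' @param transition blend width of the two halves across the ring (um).
#' @param final_window final PIV interrogation window (px) used to validate
#'   that the prescribed displacement is resolvable.
#' @return A `flow_movie` list with elements `stack` ([image_stack()]),
#'   `truth`, and `frame` (the [division_frame()] fixed by the generator's
#'   geometry: `e_x` along +x, ring vertical at `truth$ring_x`).
#' @export
sim_flow_movie <- function(truth,
                           image_shape = c(96, 144),
                           pixel_size = 0.2,
                           frame_interval = 3,
                           n_frames = 8,
                           speckle_density = 0.06,
                           speckle_sigma = 1,
                           intensity_noise = 0.05,
                           transition = 0.5,
                           final_window = 16) {
  stopifnot(inherits(truth, "flow_truth"))
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  ny <- image_shape[1]; nx <- image_shape[2]
  if (speckle_density * final_window^2 < 5) {
    abort("Speckle density too low: need >= 5 speckles per final PIV window.")
  }
  # displacement per frame (px) must stay resolvable by PIV
  vmax <- sqrt((abs(truth$vcontr) / 2 + truth$noise_sigma)^2 +
                 (abs(truth$vr) / 2 + abs(truth$vc) / 2 + truth$noise_sigma)^2)
  disp_px <- vmax / 60 * frame_interval / pixel_size
  if (disp_px > final_window / 2) {
    abort(sprintf(
      "Prescribed displacement (%.2f px/frame) exceeds half the final PIV window (%d px).",
      disp_px, final_window
    ))
  }

  dt_min <- frame_interval / 60
  withr::with_seed(truth$seed, {
    n_speckles <- round(speckle_density * nx * ny)
    pos <- cbind(x = runif(n_speckles, 0.5, nx + 0.5),
                 y = runif(n_speckles, 0.5, ny + 0.5))
    amp <- runif(n_speckles, 0.5, 1.5)
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      img <- render_spots(nx, ny, pos, sigma = speckle_sigma, amplitude = amp)
      if (intensity_noise > 0) {
        img <- img + matrix(rnorm(nx * ny, sd = intensity_noise), ny, nx)
      }
      frames[[t]] <- img
      if (t < n_frames) {
        v <- truth_velocity(truth, pos[, 1] * pixel_size, transition)
        if (truth$noise_sigma > 0) {
          nf <- random_velocity_field(nx, ny, truth$noise_sigma)
          dv <- nf(pos[, 1], pos[, 2])
          v$vx <- v$vx + dv$vx
          v$vy <- v$vy + dv$vy
        }
        pos[, 1] <- (pos[, 1] - 0.5 + v$vx * dt_min / pixel_size) %% nx + 0.5
        pos[, 2] <- (pos[, 2] - 0.5 + v$vy * dt_min / pixel_size) %% ny + 0.5
      }
    }
  })

  stack <- image_stack(frames, pixel_size, frame_interval, channel = "myosin")
  ring_px <- truth$ring_x / pixel_size
  frame <- division_frame(
    ring_start = c(ring_px, 1),
    ring_end = c(ring_px, ny),
    ex_toward = c(1, 0),
    viewing_side = "right"
  )
  structure(list(stack = stack, truth = truth, frame = frame),
            class = "flow_movie")
}

#' @export
print.flow_movie <- function(x, ...) {
  cat(sprintf(
    "<flow_movie> vc=%.2f vr=%.2f vcontr=%.2f um/min, ring at %.1f/%.1f um, seed %d\n",
    x$truth$vc, x$truth$vr, x$truth$vcontr, x$truth$ring_x,
    x$truth$cell_length, x$truth$seed
  ))
  print(x$stack)
  invisible(x)
}
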