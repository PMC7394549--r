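#' Time-lapse image stacks
#'
#' An `image_stack` is the in-memory carrier for a calibrated fluorescence
#' time-lapse: a list of 2-D intensity matrices ordered in time plus the
#' physical calibration needed to convert pixel displacements to velocities.
#'
#' Coordinate convention: a frame is a matrix with `dim = c(ny, nx)`;
#' column index is the x coordinate (the long axis of the cell in all
#' synthetic movies) and row index is the y coordinate, with y increasing
#' upward so that the analysis frame `(e_x, e_y, e_z)` is right-handed with
#' `e_z` pointing out of the image toward the viewer. Pixel centers sit at
#' integer coordinates.
#'
#' @param frames list of numeric matrices, all with the same dimensions.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param frame_interval time between consecutive frames in seconds (> 0).
#' @param channel optional channel label (e.g. `"myosin"`, `"tubulin"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, channel = NULL) {
  if (!is.list(frames) || length(frames) < 1L) {
    abort("`frames` must be a non-empty list of matrices.")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All frames must share the same dimensions.")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a positive number (um/px).")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be a positive number (s).")
  }
  structure(
    list(
      frames = frames,
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      channel = channel
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> %d frame(s), %d x %d px, %.3g um/px, %.3g s/frame%s\n",
    length(x$frames), d[2], d[1], x$pixel_size, x$frame_interval,
    if (is.null(x$channel)) "" else paste0(", channel ", x$channel)
  ))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Mirror a stack across the long axis
#'
#' Reflects every frame about the horizontal mid-line (y -> -y). Under this
#' reflection the recovered counter-rotating and net-rotating flow
#' velocities change sign while the contractile flow velocity is unchanged,
#' which is the mirror property used to validate handedness assignment.
#'
#' @param stack an [image_stack()].
#' @return The mirrored `image_stack`.
#' @export
mirror_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack$frames <- lapply(stack$frames, function(f) f[rev(seq_len(nrow(f))), , drop = FALSE])
  stack
}

# Bilinear interpolation of matrix `m` at points (x = column, y = row).
# Points outside the grid are clamped to the border.
interp_bilinear <- function(m, x, y) {
  nx <- ncol(m); ny <- nrow(m)
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# Render Gaussian spots onto an image. positions: matrix with columns x, y
# (pixel coordinates, y up = row index); amplitudes recycled.
render_spots <- function(nx, ny, positions, sigma, amplitude = 1) {
  img <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(positions) == 0L) return(img)
  amplitude <- rep_len(amplitude, nrow(positions))
  r <- ceiling(3 * sigma)
  for (k in seq_len(nrow(positions))) {
    px <- positions[k, 1]; py <- positions[k, 2]
    cx <- round(px); cy <- round(py)
    xs <- max(1, cx - r):min(nx, cx + r)
    ys <- max(1, cy - r):min(ny, cy + r)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - px)^2 / (2 * sigma^2))
    gy <- exp(-(ys - py)^2 / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + amplitude[k] * outer(gy, gx)
  }
  img
}

#' Write / read an image stack as plain text
#'
#' Frames are stored as one long CSV (`frame,row,col,value`) together with a
#' JSON sidecar holding the calibration, so stacks survive text-only
#' round-trips without any image-format dependency.
#'
#' @param stack an [image_stack()].
#' @param dir directory to write into (created if needed).
#' @param truth optional list of ground-truth metadata stored in the sidecar.
#' @return `write_image_stack()` returns `dir` invisibly;
#'   `read_image_stack()` returns the `image_stack` (with any stored truth
#'   attached as attribute `"truth"`).
#' @export
write_image_stack <- function(stack, dir, truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- purrr::imap_dfr(stack$frames, function(f, i) {
    tibble(
      frame = i,
      row = rep(seq_len(nrow(f)), times = ncol(f)),
      col = rep(seq_len(ncol(f)), each = nrow(f)),
      value = as.vector(f)
    )
  })
  utils::write.csv(long, file.path(dir, "frames.csv"), row.names = FALSE)
  meta <- list(
    pixel_size = stack$pixel_size,
    frame_interval = stack$frame_interval,
    channel = stack$channel,
    n_frames = length(stack$frames),
    dim = dim(stack$frames[[1]]),
    truth = truth
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "frames.csv"))
  ny <- meta$dim[1]; nx <- meta$dim[2]
  frames <- lapply(seq_len(meta$n_frames), function(i) {
    sub <- long[long$frame == i, ]
    m <- matrix(0, nrow = ny, ncol = nx)
    m[cbind(sub$row, sub$col)] <- sub$value
    m
  })
  out <- image_stack(frames, meta$pixel_size, meta$frame_interval,
                     channel = meta$channel %||% NULL)
  attr(out, "truth") <- meta$truth
  out
}
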