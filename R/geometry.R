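#' Per-division coordinate frame
#'
#' Fixes the coordinate system in which chiral flow statistics are defined.
#' `e_x` is the in-plane unit vector orthogonal to the cytokinetic ring that
#' points toward the cell pole lying in the direction of the
#' anteroposterior axis; `e_y` is parallel to the ring and chosen so that
#' `(e_x, e_y, e_z)` is right-handed with `e_z = e_x x e_y` pointing out of
#' the image toward the viewer. The recorded `viewing_side` documents from
#' which side of the embryo the cortex was imaged, since mirror-image
#' viewing flips the sign of the counter-rotating and net-rotating flow
#' velocities.
#'
#' @param ring_start,ring_end endpoints of the visible cytokinetic ring
#'   segment (pixel coordinates `c(x, y)`, y up).
#' @param ex_toward a direction (any nonzero 2-vector) indicating which side
#'   of the ring `e_x` points to; its component orthogonal to the ring is
#'   normalised.
#' @param viewing_side `"left"` or `"right"`.
#' @return A `division_frame` object.
#' @export
division_frame <- function(ring_start, ring_end, ex_toward,
                           viewing_side = c("right", "left")) {
  viewing_side <- match.arg(viewing_side)
  ring_vec <- ring_end - ring_start
  len <- sqrt(sum(ring_vec^2))
  if (len == 0) abort("Ring segment has zero length.")
  t_hat <- ring_vec / len
  ex <- ex_toward - sum(ex_toward * t_hat) * t_hat
  nex <- sqrt(sum(ex^2))
  if (nex < 1e-12) abort("`ex_toward` is parallel to the ring segment.")
  ex <- ex / nex
  ey <- c(-ex[2], ex[1])  # +90 deg CCW so (e_x, e_y, +z) is right-handed
  structure(
    list(
      ring_start = ring_start, ring_end = ring_end,
      ring_center = (ring_start + ring_end) / 2,
      ring_length = len,
      ex = ex, ey = ey, ez = c(0, 0, 1),
      viewing_side = viewing_side
    ),
    class = "division_frame"
  )
}

#' @export
print.division_frame <- function(x, ...) {
  cat(sprintf(
    "<division_frame> ring %.1f px at (%.1f, %.1f); e_x = (%.3f, %.3f); viewed from %s\n",
    x$ring_length, x$ring_center[1], x$ring_center[2], x$ex[1], x$ex[2],
    x$viewing_side
  ))
  invisible(x)
}

check_frame <- function(frame) {
  if (!inherits(frame, "division_frame")) abort("Need a `division_frame`.")
  ok <- abs(sum(frame$ex^2) - 1) < 1e-8 &&
    abs(sum(frame$ey^2) - 1) < 1e-8 &&
    abs(sum(frame$ex * frame$ey)) < 1e-8
  if (!ok) abort("Division frame axes must be orthonormal unit vectors.")
  invisible(frame)
}

# ROI outer extents (um from the ring, along the long axis), scaled with
# cell size for the first divisions; ~4 um for the small late cells.
roi_outer_extent_um <- c(
  P0 = 10, AB = 8.5, P1 = 6, ABa = 6.5, ABp = 6.5, EMS = 6.5,
  P2 = 4, ABal = 4, ABpr = 4
)

#' Place the two flow-averaging ROIs beside the cytokinetic ring
#'
#' Builds the pair of rectangular regions of interest used to average the
#' cortical flow field in each cell half. The inner boundary of each ROI
#' sits `inner_offset` (default 1 um) from the ring so that the saturating
#' ring signal does not bias the velocity estimates; the outer boundary is
#' scaled with cell size (10, 8.5, 6, 6.5, 6.5, 6.5 um for P0, AB, P1, ABa,
#' ABp, EMS; about 4 um for P2, ABal, ABpr), and the ROI width equals the
#' visible ring length. ROI 2 is the half toward which `e_x` points; ROI 1
#' is the opposite half.
#'
#' @param frame a [division_frame()].
#' @param cell_id one of `"P0", "AB", "P1", "ABa", "ABp", "EMS", "P2",
#'   "ABal", "ABpr"`, or `NULL` when `outer_extent` is given explicitly.
#' @param outer_extent explicit outer boundary distance from the ring (um);
#'   overrides the `cell_id` default on both sides.
#' @param inner_offset inner boundary distance from the ring (um, >= 1).
#' @param width ROI width along the ring (um); defaults to the visible ring
#'   length.
#' @param pixel_size um per pixel (used to convert the ring length).
#' @param image_shape optional `c(ny, nx)`; ROIs poking outside the image
#'   are clipped along the long axis with a warning.
#' @return A `roi_pair` object: extents are expressed in the division frame
#'   (xi along `e_x` from the ring, psi along `e_y` from the ring centre),
#'   in micrometres.
#' @export
place_rois <- function(frame, cell_id = NULL, outer_extent = NULL,
                       inner_offset = 1, width = NULL, pixel_size = 1,
                       image_shape = NULL) {
  check_frame(frame)
  if (inner_offset < 1) abort("`inner_offset` must be >= 1 um.")
  if (is.null(outer_extent)) {
    if (is.null(cell_id) || !cell_id %in% names(roi_outer_extent_um)) {
      abort("Unknown `cell_id` and no explicit `outer_extent` given.")
    }
    outer_extent <- unname(roi_outer_extent_um[cell_id])
  }
  if (outer_extent <= inner_offset) {
    abort("`outer_extent` must exceed `inner_offset`.")
  }
  width <- width %||% (frame$ring_length * pixel_size)
  outer <- c(`1` = outer_extent, `2` = outer_extent)
  if (!is.null(image_shape)) {
    # available room along +/- e_x from the ring centre, in um
    for (sgn in c(1, -1)) {
      dir <- sgn * frame$ex
      room <- Inf
      for (axis in 1:2) {
        lim <- if (axis == 1) c(1, image_shape[2]) else c(1, image_shape[1])
        if (abs(dir[axis]) > 1e-12) {
          reach <- (lim - frame$ring_center[axis]) / dir[axis]
          room <- min(room, max(reach))
        }
      }
      room_um <- room * pixel_size
      key <- if (sgn > 0) "2" else "1"
      if (room_um < outer[key]) {
        warn(sprintf("ROI %s clipped from %.1f to %.1f um by the image bounds.",
                     key, outer[key], room_um))
        outer[key] <- room_um
      }
    }
  }
  structure(
    list(inner_offset = inner_offset, outer = outer, width = width,
         cell_id = cell_id),
    class = "roi_pair"
  )
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf(
    "<roi_pair>%s inner %.1f um, outer %.1f / %.1f um, width %.1f um\n",
    if (is.null(x$cell_id)) "" else paste0(" ", x$cell_id),
    x$inner_offset, x$outer[["1"]], x$outer[["2"]], x$width
  ))
  invisible(x)
}

# Project pixel coordinates into the division frame: xi along e_x from the
# ring centre, psi along e_y; returned in um.
frame_coords <- function(frame, x_px, y_px, pixel_size) {
  dx <- (x_px - frame$ring_center[1]) * pixel_size
  dy <- (y_px - frame$ring_center[2]) * pixel_size
  list(xi = dx * frame$ex[1] + dy * frame$ex[2],
       psi = dx * frame$ey[1] + dy * frame$ey[2])
}
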