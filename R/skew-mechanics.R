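#' Geometric ("bulldozer") relation between lab-frame flows and skew rate
#'
#' Decomposes the lab-frame cortical y-velocities measured on the left and
#' right side of the dividing cell into a rigid rotation plus a perfect
#' counter-rotation: in the co-rotating body frame one always observes two
#' perfectly counter-rotating cell halves, and any common-mode velocity is
#' the rotation of the whole cell. The angular skew velocity is
#' \deqn{\omega = \frac{v_{y,L} + v_{y,R}}{2R},}
#' and the body-frame counter-rotation speed is
#' \eqn{v' = (v_{y,L} - v_{y,R}) / 2}.
#'
#' @param v_y_left,v_y_right lab-frame y-velocities on the left and right
#'   side (um/min), measured at distance `R` from the rotation axis with a
#'   common sign convention.
#' @param R distance from the cytokinetic ring to the ROI centres (um, > 0).
#' @return A list with `omega_rad` (rad/min), `omega_deg` (deg/min) and
#'   `v_counter` (um/min, the body-frame counter-rotation speed).
#' @export
omega_geometric <- function(v_y_left, v_y_right, R) {
  if (R <= 0) abort("`R` must be > 0.")
  omega <- (v_y_left + v_y_right) / (2 * R)
  list(
    omega_rad = omega,
    omega_deg = omega * 180 / pi,
    v_counter = (v_y_left - v_y_right) / 2
  )
}

#' Torque-balance prediction of the angular skew velocity
#'
#' For a cell whose two halves counter-rotate at surface speed `v` while
#' experiencing friction `gamma_L`, `gamma_R` over contact areas `A_L`,
#' `A_R` against the eggshell on the left and right side, torque balance
#' (neglecting the neighbouring-cell contact and extra-embryonic fluid)
#' gives
#' \deqn{\omega = \frac{\gamma_L A_L - \gamma_R A_R}
#'   {\gamma_L A_L + \gamma_R A_R}\,\frac{v}{R}.}
#' `omega < 0` corresponds to a clockwise skew when the embryo is viewed
#' from the left side; any left-right asymmetry in total friction with
#' `v != 0` yields a nonzero skew.
#'
#' @param gamma_L,gamma_R local friction coefficients (a.u., > 0; only
#'   their ratio matters).
#' @param A_L,A_R contact surface areas (um^2, > 0).
#' @param v counter-rotation surface speed (um/min, >= 0 by convention).
#'   When both sides were measured take `v = |v'|` from
#'   [omega_geometric()]; with a single side use `v = |vc| / 2`.
#' @param R distance from the ring to the ROI centres (um, > 0).
#' @return A `skew_prediction` list with `omega_rad`, `omega_deg`, the
#'   implied lab-frame velocities `v_y_left`, `v_y_right` (for closed-loop
#'   checks against [omega_geometric()]), the friction asymmetry factor and
#'   a handedness interpretation string.
#' @export
omega_torque_balance <- function(gamma_L, gamma_R, A_L, A_R, v, R) {
  if (any(c(gamma_L, gamma_R, A_L, A_R, R) <= 0)) {
    abort("Friction coefficients, areas and R must be > 0.")
  }
  if (v < 0) abort("`v` must be >= 0 (its sign convention is positive).")
  fL <- gamma_L * A_L; fR <- gamma_R * A_R
  asym <- (fL - fR) / (fL + fR)
  omega <- asym * v / R
  structure(
    list(
      omega_rad = omega,
      omega_deg = omega * 180 / pi,
      asymmetry = asym,
      v = v, R = R,
      v_y_left = omega * R + v,
      v_y_right = omega * R - v,
      interpretation = if (omega < 0) {
        "clockwise skew viewed from the left side"
      } else if (omega > 0) {
        "counter-clockwise skew viewed from the left side"
      } else {
        "no skew (left-right symmetric friction)"
      }
    ),
    class = "skew_prediction"
  )
}

#' @export
print.skew_prediction <- function(x, ...) {
  cat(sprintf("<skew_prediction> omega = %.4g rad/min (%.3g deg/min): %s\n",
              x$omega_rad, x$omega_deg, x$interpretation))
  invisible(x)
}

#' @method tidy skew_prediction
#' @export
tidy.skew_prediction <- function(x, ...) {
  tibble(omega_rad = x$omega_rad, omega_deg = x$omega_deg,
         asymmetry = x$asymmetry, v = x$v, R = x$R)
}

#' Contact-area ratio from in-focus cortex masks
#'
#' Estimates the ratio of the contact surface areas on the right and left
#' side from binary masks of the cortex area that is in focus, with a
#' Poisson counting uncertainty on the pixel counts.
#'
#' @param mask_L,mask_R binary (logical or 0/1) matrices with the same
#'   pixel calibration.
#' @param pixel_size um per pixel (common to both masks).
#' @return A list with `ratio` (`A_R / A_L`), `se` (counting standard
#'   error), and the two areas in um^2.
#' @export
area_ratio_from_masks <- function(mask_L, mask_R, pixel_size = 1) {
  nL <- sum(mask_L != 0); nR <- sum(mask_R != 0)
  if (nL == 0 || nR == 0) abort("Empty mask: cannot form an area ratio.")
  ratio <- nR / nL
  list(
    ratio = ratio,
    se = ratio * sqrt(1 / nL + 1 / nR),
    A_L = nL * pixel_size^2,
    A_R = nR * pixel_size^2
  )
}

#' Counter-rotation speed for the torque balance
#'
#' Maps measured flows to the positive surface speed `v` entering
#' [omega_torque_balance()]. With both sides measured it is the body-frame
#' counter-rotation speed `|v'|` from the geometric decomposition; with a
#' single-side measurement it falls back to `|vc| / 2`. The method used is
#' recorded so the two conventions are never mixed silently.
#'
#' @param v_y_left,v_y_right lab-frame y-velocities (um/min), optional.
#' @param vc single-side chiral counter-rotating flow velocity (um/min),
#'   optional fallback.
#' @return A list with `v` (um/min) and `method`.
#' @export
counter_rotation_speed <- function(v_y_left = NULL, v_y_right = NULL,
                                   vc = NULL) {
  if (!is.null(v_y_left) && !is.null(v_y_right)) {
    list(v = abs(v_y_left - v_y_right) / 2, method = "two-sided |v'|")
  } else if (!is.null(vc)) {
    list(v = abs(vc) / 2, method = "single-side |vc|/2")
  } else {
    abort("Provide either both side velocities or `vc`.")
  }
}
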