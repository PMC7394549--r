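#' Velocity fields
#'
#' A `velocity_field` is a tibble with one row per frame pair and grid
#' point: columns `pair` (index of the first frame of the pair), `x`, `y`
#' (grid positions, px, y up), `u_px`, `v_px` (displacement, px/frame),
#' `u`, `v` (velocity, um/min) and `valid` (FALSE where the local-median
#' outlier filter replaced the raw vector). Calibration and PIV settings
#' travel in the `"piv"` attribute.
#'
#' @param df a data frame with the columns above.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param window final interrogation window (px).
#' @param step final grid step (px).
#' @return The tibble with class `velocity_field`.
#' @export
velocity_field <- function(df, pixel_size, frame_interval, window, step) {
  out <- as_tibble(df)
  attr(out, "piv") <- list(
    pixel_size = pixel_size, frame_interval = frame_interval,
    window = window, step = step
  )
  class(out) <- c("velocity_field", class(out))
  out
}

field_meta <- function(field) {
  meta <- attr(field, "piv")
  if (is.null(meta)) abort("Not a velocity_field: missing PIV metadata.")
  meta
}

#' Multi-pass particle image velocimetry
#'
#' Estimates per-frame-pair displacement fields by windowed FFT
#' cross-correlation with three-point Gaussian sub-pixel peak
#' interpolation. The default is a three-step multi-pass (interrogation
#' windows 64, 32, 16 px) with a final step size of 8 px; between passes
#' the coarse displacement field is used to shift the interrogation
#' windows (integer shift, a robust approximation of linear window
#' deformation). After each pass, vectors deviating from the local 3x3
#' median by more than twice the local median absolute deviation are
#' replaced by that median; replacements on the final pass are flagged in
#' the validity mask.
#'
#' @param stack an [image_stack()].
#' @param windows decreasing interrogation window sizes (px).
#' @param final_step grid step of the final pass (px); earlier passes use
#'   half their window size.
#' @param mad_tol outlier threshold in multiples of the local MAD.
#' @param mad_floor additive floor (px) protecting against a degenerate
#'   zero MAD in uniform flow.
#' @return A [velocity_field()] tibble.
#' @export
compute_piv <- function(stack, windows = c(64, 32, 16), final_step = 8,
                        mad_tol = 2, mad_floor = 0.2) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames[[1]])
  ny <- d[1]; nx <- d[2]
  windows <- sort(unique(as.integer(windows)), decreasing = TRUE)
  if (any(windows > min(nx, ny))) {
    abort("Interrogation window larger than the image.")
  }
  n_pairs <- length(stack$frames) - 1L
  px_per_min <- stack$pixel_size / stack$frame_interval * 60
  res <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    res[[p]] <- piv_pair(
      stack$frames[[p]], stack$frames[[p + 1L]],
      windows = windows, final_step = final_step,
      mad_tol = mad_tol, mad_floor = mad_floor
    )
    res[[p]]$pair <- p
  }
  df <- dplyr::bind_rows(res)
  df$u <- df$u_px * px_per_min
  df$v <- df$v_px * px_per_min
  velocity_field(
    df[, c("pair", "x", "y", "u_px", "v_px", "u", "v", "valid")],
    pixel_size = stack$pixel_size, frame_interval = stack$frame_interval,
    window = min(windows), step = final_step
  )
}

piv_pair <- function(A, B, windows, final_step, mad_tol, mad_floor) {
  ny <- nrow(A); nx <- ncol(A)
  if (sd(A) == 0 || sd(B) == 0) {
    warn("All-dark frame: returning zero field with empty validity mask.")
    w <- min(windows); s <- final_step
    g <- piv_grid(nx, ny, w, s)
    return(tibble(x = g$cx[g$ix], y = g$cy[g$iy],
                  u_px = 0, v_px = 0, valid = FALSE))
  }
  pred_u <- pred_v <- NULL
  prev_grid <- NULL
  n_pass <- length(windows)
  for (k in seq_len(n_pass)) {
    w <- windows[k]
    s <- if (k == n_pass) final_step else w %/% 2L
    g <- piv_grid(nx, ny, w, s)
    nxg <- length(g$cx); nyg <- length(g$cy)
    # predictor interpolated from the previous pass grid
    if (is.null(pred_u)) {
      Pu <- matrix(0, nyg, nxg); Pv <- matrix(0, nyg, nxg)
    } else {
      xi <- (rep(g$cx, each = nyg) - prev_grid$cx[1]) / prev_grid$s + 1
      yi <- (rep(g$cy, times = nxg) - prev_grid$cy[1]) / prev_grid$s + 1
      Pu <- matrix(interp_bilinear(pred_u, xi, yi), nyg, nxg)
      Pv <- matrix(interp_bilinear(pred_v, xi, yi), nyg, nxg)
    }
    U <- matrix(NA_real_, nyg, nxg); V <- matrix(NA_real_, nyg, nxg)
    for (j in seq_len(nxg)) {
      for (i in seq_len(nyg)) {
        x0 <- g$x0[j]; y0 <- g$y0[i]
        sx <- round(Pu[i, j]); sy <- round(Pv[i, j])
        sx <- clamp(sx, 1L - x0, nx - w + 1L - x0)
        sy <- clamp(sy, 1L - y0, ny - w + 1L - y0)
        a <- A[y0:(y0 + w - 1L), x0:(x0 + w - 1L)]
        b <- B[(y0 + sy):(y0 + sy + w - 1L), (x0 + sx):(x0 + sx + w - 1L)]
        dxy <- corr_peak(a, b)
        if (is.null(dxy)) next
        U[i, j] <- sx + dxy[1]
        V[i, j] <- sy + dxy[2]
      }
    }
    filt <- median_filter_field(U, V, mad_tol, mad_floor)
    U <- filt$U; V <- filt$V
    pred_u <- U; pred_v <- V
    prev_grid <- list(cx = g$cx, cy = g$cy, s = s)
    if (k == n_pass) {
      return(tibble(
        x = rep(g$cx, each = nyg),
        y = rep(g$cy, times = nxg),
        u_px = as.vector(U),
        v_px = as.vector(V),
        valid = as.vector(filt$valid)
      ))
    }
  }
}

piv_grid <- function(nx, ny, w, s) {
  x0 <- seq(1L, nx - w + 1L, by = s)
  y0 <- seq(1L, ny - w + 1L, by = s)
  list(x0 = x0, y0 = y0,
       cx = x0 + w / 2 - 0.5, cy = y0 + w / 2 - 0.5,
       ix = rep(seq_along(x0), each = length(y0)),
       iy = rep(seq_along(y0), times = length(x0)))
}

clamp <- function(x, lo, hi) max(lo, min(hi, x))

# FFT cross-correlation peak with 3-point Gaussian sub-pixel fit.
# Returns c(dx, dy): displacement of the pattern from `a` to `b`,
# or NULL when a window has no texture.
corr_peak <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) return(NULL)
  w <- nrow(a)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  iy <- pk[1]; ix <- pk[2]
  # index -> signed displacement (circular)
  sx <- ix - 1; if (sx > w / 2) sx <- sx - w
  sy <- iy - 1; if (sy > w / 2) sy <- sy - w
  # circular neighbours for the sub-pixel fit; the raw circular
  # correlation carries a triangular overlap factor (w - |lag|) per
  # dimension that pulls the 3-point fit toward integer lags, so each
  # value is rescaled by its own overlap before fitting
  ym <- ((iy - 2) %% w) + 1; yp <- (iy %% w) + 1
  xm <- ((ix - 2) %% w) + 1; xp <- (ix %% w) + 1
  ov <- function(lag) pmax(w - abs(lag), 1)
  dy <- subpixel_1d(cc[ym, ix] / ov(sy - 1), cc[iy, ix] / ov(sy),
                    cc[yp, ix] / ov(sy + 1))
  dx <- subpixel_1d(cc[iy, xm] / ov(sx - 1), cc[iy, ix] / ov(sx),
                    cc[iy, xp] / ov(sx + 1))
  c(sx + dx, sy + dy)
}

subpixel_1d <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    lm <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- 2 * (lm + lp - 2 * l0)
    if (den < 0) return((lm - lp) / den)
  }
  den <- 2 * (cm + cp - 2 * c0)
  if (den < 0) (cm - cp) / den else 0
}

# Local 3x3 median validation; outliers replaced by the neighbourhood
# median. NA vectors (textureless windows) are filled the same way.
median_filter_field <- function(U, V, mad_tol, mad_floor) {
  nyg <- nrow(U); nxg <- ncol(U)
  valid <- matrix(TRUE, nyg, nxg)
  U2 <- U; V2 <- V
  for (j in seq_len(nxg)) {
    for (i in seq_len(nyg)) {
      ii <- max(1, i - 1):min(nyg, i + 1)
      jj <- max(1, j - 1):min(nxg, j + 1)
      nu <- U[ii, jj]; nv <- V[ii, jj]
      nu <- nu[!is.na(nu)]; nv <- nv[!is.na(nv)]
      if (!length(nu)) { valid[i, j] <- FALSE; U2[i, j] <- 0; V2[i, j] <- 0; next }
      mu <- median(nu); mv <- median(nv)
      if (is.na(U[i, j])) {
        U2[i, j] <- mu; V2[i, j] <- mv; valid[i, j] <- FALSE
        next
      }
      tu <- mad_tol * median(abs(nu - mu)) + mad_floor
      tv <- mad_tol * median(abs(nv - mv)) + mad_floor
      if (abs(U[i, j] - mu) > tu || abs(V[i, j] - mv) > tv) {
        U2[i, j] <- mu; V2[i, j] <- mv; valid[i, j] <- FALSE
      }
    }
  }
  list(U = U2, V = V2, valid = valid)
}
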