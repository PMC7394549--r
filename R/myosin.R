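#' Step-plus-Gaussian myosin intensity model
#'
#' Model for the cortical myosin distribution along the normalised cell
#' division axis: an error-function step between the anterior plateau `IA`
#' (x -> 0) and the posterior plateau `IP` (x -> 1), plus a Gaussian ring
#' contribution of weight `IR` centred at the ring position `xr`:
#' \deqn{I(x) = \tfrac12 (I_P - I_A)(\mathrm{erf}[(x - x_r)/w] - 1) + I_P
#'   + \frac{I_R}{\sqrt{2\pi w^2}} \exp[-(x - x_r)^2 / (2 w^2)].}
#' The erf argument and the Gaussian share the single width parameter `w`
#' (no extra factor of sqrt(2) in the erf argument).
#'
#' @param x positions on the normalised division axis.
#' @param IA,IP anterior / posterior plateau intensities (a.u.).
#' @param IR ring intensity weight (a.u. x normalised length).
#' @param w shared width (normalised length, > 0).
#' @param xr ring position (normalised, in (0, 1)).
#' @return Intensities at `x`.
#' @export
myosin_model <- function(x, IA, IP, IR, w, xr) {
  0.5 * (IP - IA) * (erf((x - xr) / w) - 1) + IP +
    IR / sqrt(2 * pi * w^2) * exp(-(x - xr)^2 / (2 * w^2))
}

erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1

#' Ground truth for a synthetic myosin profile
#'
#' Defaults correspond to an asymmetrically dividing cell: anterior
#' enrichment ratio 2 (P-lineage-like), a ring at 0.58 of the axis, and
#' measurement noise of 0.02 a.u.
#'
#' @inheritParams myosin_model
#' @param noise_sigma i.i.d. Gaussian intensity noise (a.u., >= 0).
#' @param n_points number of sample positions (>= 20).
#' @param seed integer seed.
#' @return A `profile_truth` list.
#' @export
profile_truth <- function(IA = 2, IP = 1, IR = 0.3, w = 0.05, xr = 0.58,
                          noise_sigma = 0.02, n_points = 100, seed = 1L) {
  if (w <= 0) abort("`w` must be > 0.")
  if (xr <= 0 || xr >= 1) abort("`xr` must lie in (0, 1).")
  if (n_points < 20) abort("`n_points` must be >= 20.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  structure(
    list(IA = IA, IP = IP, IR = IR, w = w, xr = xr,
         noise_sigma = noise_sigma, n_points = as.integer(n_points),
         seed = as.integer(seed)),
    class = "profile_truth"
  )
}

#' Myosin intensity profile container
#'
#' @param positions strictly increasing positions on the normalised axis.
#' @param intensities non-negative intensities (clipped at zero).
#' @param stripe_width stripe width (px) used during extraction, if any.
#' @return A `myosin_profile` tibble with columns `position`, `intensity`.
#' @export
myosin_profile <- function(positions, intensities, stripe_width = NA_real_) {
  if (any(diff(positions) <= 0)) {
    abort("`positions` must be strictly increasing.")
  }
  out <- tibble(position = positions, intensity = pmax(intensities, 0))
  attr(out, "stripe_width") <- stripe_width
  class(out) <- c("myosin_profile", class(out))
  out
}

#' Sample a noisy myosin profile from its ground truth
#'
#' Evaluates the step-plus-Gaussian model at `n_points` uniformly spaced
#' positions in `[0, 1]` and adds i.i.d. Gaussian noise.
#'
#' @param truth a [profile_truth()].
#' @return A list with `profile` (a [myosin_profile()]) and `truth`.
#' @export
sim_myosin_profile <- function(truth) {
  stopifnot(inherits(truth, "profile_truth"))
  x <- seq(0, 1, length.out = truth$n_points)
  ideal <- myosin_model(x, truth$IA, truth$IP, truth$IR, truth$w, truth$xr)
  noisy <- withr::with_seed(truth$seed,
                            ideal + rnorm(length(x), sd = truth$noise_sigma))
  list(profile = myosin_profile(x, noisy), truth = truth)
}

#' Extract a myosin profile along the division axis of a movie
#'
#' Computes the mean intensity in a `stripe_width`-pixel-wide stripe along
#' the given axis, resampled onto the normalised axis coordinate, averaged
#' over the requested frames.
#'
#' @param stack an [image_stack()].
#' @param axis_start,axis_end axis endpoints (pixel coordinates `c(x, y)`).
#' @param stripe_width stripe width in pixels (default 20).
#' @param frames frame indices to average over (default: all).
#' @param n_samples number of samples along the axis (default: axis length
#'   in px).
#' @param background constant background intensity subtracted before
#'   clipping at zero (e.g. the median of an off-embryo region); default 0.
#' @return A [myosin_profile()].
#' @export
extract_axis_profile <- function(stack, axis_start, axis_end,
                                 stripe_width = 20, frames = NULL,
                                 n_samples = NULL, background = 0) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- frames %||% seq_along(stack$frames)
  d <- dim(stack$frames[[1]])
  ny <- d[1]; nx <- d[2]
  axis_vec <- axis_end - axis_start
  len <- sqrt(sum(axis_vec^2))
  if (len == 0) abort("Zero-length axis.")
  u <- axis_vec / len
  nvec <- c(-u[2], u[1])
  n_samples <- n_samples %||% max(20L, ceiling(len))
  t_pos <- seq(0, 1, length.out = n_samples)
  offs <- seq(-(stripe_width - 1) / 2, (stripe_width - 1) / 2, by = 1)
  px <- outer(axis_start[1] + t_pos * axis_vec[1], offs * nvec[1], `+`)
  py <- outer(axis_start[2] + t_pos * axis_vec[2], offs * nvec[2], `+`)
  if (any(px < 1 | px > nx | py < 1 | py > ny)) {
    abort("Sampling stripe extends outside the image.")
  }
  acc <- 0
  for (f in frames) {
    vals <- matrix(interp_bilinear(stack$frames[[f]], as.vector(px), as.vector(py)),
                   nrow = n_samples)
    acc <- acc + rowMeans(vals)
  }
  myosin_profile(t_pos, acc / length(frames) - background,
                 stripe_width = stripe_width)
}

#' Anterior/posterior myosin ratio
#'
#' Mean intensity over the anterior 20% of the normalised division axis
#' divided by the mean over the posterior 20%. The middle of the axis is
#' excluded so the strong ring signal cannot bias the ratio.
#'
#' @param profile a [myosin_profile()] covering `[0, 0.2]` and `[0.8, 1]`.
#' @return The dimensionless ratio.
#' @export
myosin_ratio <- function(profile) {
  x <- profile$position
  if (min(x) > 0.2 || max(x) < 0.8) {
    abort("Profile must cover the outer 20% segments of the axis.")
  }
  ant <- mean(profile$intensity[x <= 0.2])
  post <- mean(profile$intensity[x >= 0.8])
  if (!is.finite(post) || post == 0) abort("Zero posterior mean intensity.")
  ant / post
}

#' Fit the step-plus-Gaussian model to a myosin profile
#'
#' Nonlinear least squares (`nls`, port algorithm) with deterministic,
#' data-driven starting values: the plateau intensities from the outer-20%
#' segment means, the ring position from the profile argmax, `w = 0.05`,
#' and the ring weight from the excess mass above the step. Bounds keep
#' the ring term identifiable (`w` in \[0.005, 0.3\], `xr` in \[0.1, 0.9\],
#' intensities >= 0). Non-convergence is flagged, never silent: the
#' returned fit then carries the starting values.
#'
#' @param profile a [myosin_profile()] with at least 20 points.
#' @return A `myosin_fit` object with elements `params` (named list `IA`,
#'   `IP`, `IR`, `w`, `xr`), `converged`, `rss`, `start`, `n`.
#' @export
fit_myosin_profile <- function(profile) {
  x <- profile$position
  yv <- profile$intensity
  if (length(x) < 20) abort("Need at least 20 profile points.")
  ia0 <- mean(yv[x <= 0.2])
  ip0 <- mean(yv[x >= 0.8])
  xr0 <- clamp(x[which.max(yv)], 0.1, 0.9)
  w0 <- 0.05
  step0 <- 0.5 * (ip0 - ia0) * (erf((x - xr0) / w0) - 1) + ip0
  excess <- sum((yv - step0) * c(diff(x)[1], diff(x)))
  ir0 <- clamp(excess, 1e-3, Inf)
  start <- list(IA = max(ia0, 0), IP = max(ip0, 1e-6), IR = ir0, w = w0, xr = xr0)
  dat <- data.frame(x = x, y = yv)
  fit <- tryCatch(
    nls(
      y ~ myosin_model(x, IA, IP, IR, w, xr),
      data = dat, start = start, algorithm = "port",
      lower = c(IA = 0, IP = 0, IR = 0, w = 0.005, xr = 0.1),
      upper = c(IA = Inf, IP = Inf, IR = Inf, w = 0.3, xr = 0.9),
      control = nls.control(maxiter = 200, warnOnly = FALSE)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warn(paste0("Myosin profile fit did not converge: ", conditionMessage(fit),
                " Returning starting values."))
    params <- start
    rss <- sum((yv - do.call(myosin_model, c(list(x = x), start)))^2)
    converged <- FALSE
    fit <- NULL
  } else {
    params <- as.list(coef(fit))
    rss <- sum(stats::residuals(fit)^2)
    converged <- TRUE
  }
  structure(
    list(params = params, converged = converged, rss = rss,
         start = start, n = length(x), fit = fit, profile = profile),
    class = "myosin_fit"
  )
}

#' @export
print.myosin_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<myosin_fit>%s IA=%.3g IP=%.3g IR=%.3g w=%.3g xr=%.3g (rss %.3g)\n",
    if (x$converged) "" else " [NOT CONVERGED]",
    p$IA, p$IP, p$IR, p$w, p$xr, x$rss
  ))
  invisible(x)
}

#' @method tidy myosin_fit
#' @export
tidy.myosin_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @method glance myosin_fit
#' @export
glance.myosin_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n = x$n,
         sigma = sqrt(x$rss / max(x$n - 5, 1)))
}

#' Relative cytokinetic ring position along the division axis
#'
#' The division axis is the line through the two spindle poles, normalised
#' between the annotated cell boundaries; the ring position is the
#' normalised coordinate where the ingressing ring intersects it
#' (0.5 = centred division).
#'
#' @param boundary_start,boundary_end cell boundary points delimiting the
#'   normalised axis (2- or 3-vectors).
#' @param ring_point the intersection point of the ring with the axis.
#' @return A scalar in `[0, 1]`.
#' @export
ring_position <- function(boundary_start, boundary_end, ring_point) {
  axis_vec <- boundary_end - boundary_start
  l2 <- sum(axis_vec^2)
  if (l2 == 0) abort("Degenerate zero-length division axis.")
  t_par <- sum((ring_point - boundary_start) * axis_vec) / l2
  if (t_par < -1e-9 || t_par > 1 + 1e-9) {
    abort("Ring intersection lies outside the boundary span.")
  }
  clamp(t_par, 0, 1)
}
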