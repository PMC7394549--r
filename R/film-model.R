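#' Thin-film active chiral fluid model of azimuthal cortical flow
#'
#' Describes the cortex of a dividing cell as a two-dimensional active
#' fluid film in which gradients of a myosin-proportional active torque
#' density drive azimuthal (chiral) flow `v(x)` along the long axis `x`.
#' The steady force balance solved by [solve_chiral_flow()] is, on a
#' surface of revolution with meridian radius `r(x)`,
#' \deqn{\eta \frac{1}{r^2}\frac{d}{dx}\Big[r^3 \frac{d}{dx}\frac{v}{r}\Big]
#'   - \gamma(x)\, v = \chi \frac{dc}{dx},}
#' with zero tangential shear stress (`d(v/r)/dx = 0`) at both poles. On
#' the flat strip (`r` constant) this reduces to
#' \eqn{\eta\, v'' - \gamma v = \chi\, c'}. `eta` is the 2-D cortical
#' viscosity, `gamma` the substrate friction coefficient, `chi` the
#' active torque coefficient (its sign sets the flow handedness) and
#' `c(x)` the myosin concentration profile. The hydrodynamic length
#' `ell = sqrt(eta / gamma)` sets the decay length of the flows; since only
#' ratios and shapes are compared to data, `chi` is a free amplitude.
#'
#' Geometry is a flat strip by default; the axisymmetric ellipsoid option
#' uses the meridian radius of a prolate spheroid with semi-axes `L/2`
#' and `radius`, truncated 2% of `L` from each pole to avoid the polar
#' coordinate singularity (stress-free conditions at the truncation).
#' The curvature term in the viscous operator makes the azimuthal flow
#' vanish toward the poles (`v ~ r`), which is what lets an off-centre
#' ring produce weaker counter-rotation.
#'
#' @param length domain length `L` along the long axis (um).
#' @param ell hydrodynamic length `sqrt(eta/gamma)` (um, default `L/4`);
#'   together with `eta` it sets the (uniform) friction
#'   `gamma = eta / ell^2`.
#' @param eta 2-D viscosity (Pa s um).
#' @param chi active torque coefficient; negative values give
#'   right-handed (vc < 0) counter-rotation for a ring-peaked `c(x)`.
#' @param myosin myosin profile `c(x)` as a function of the normalised
#'   coordinate `x/L` in `[0, 1]`.
#' @param geometry `"flat"` (default) or `"ellipsoid"`.
#' @param radius equatorial radius of the ellipsoid (um); ignored for the
#'   flat strip.
#' @param gamma_fun optional spatially varying friction `gamma(x_um)`
#'   overriding the uniform `eta / ell^2`.
#' @return A `film_model` object.
#' @export
film_model <- function(length = 24, ell = length / 4, eta = 1, chi = -1,
                       myosin = function(x) myosin_model(x, 1, 1, 0.3, 0.05, 0.5),
                       geometry = c("flat", "ellipsoid"),
                       radius = length / 3, gamma_fun = NULL) {
  geometry <- match.arg(geometry)
  if (length <= 0 || ell <= 0 || eta <= 0) {
    abort("`length`, `ell` and `eta` must be positive.")
  }
  structure(
    list(L = length, ell = ell, eta = eta, gamma = eta / ell^2, chi = chi,
         myosin = myosin, geometry = geometry, radius = radius,
         gamma_fun = gamma_fun, truncation = 0.02),
    class = "film_model"
  )
}

#' @export
print.film_model <- function(x, ...) {
  cat(sprintf(
    "<film_model> %s, L = %.3g um, ell = %.3g um (gamma = %.3g), chi = %.3g\n",
    x$geometry, x$L, x$ell, x$gamma, x$chi
  ))
  invisible(x)
}

film_radius <- function(model, x_um) {
  if (model$geometry == "flat") {
    rep(1, length(x_um))
  } else {
    a <- model$L / 2
    arg <- 1 - ((x_um - a) / a)^2
    model$radius * sqrt(pmax(arg, 0))
  }
}

#' Solve the thin-film chiral force balance
#'
#' Cell-centred finite-volume discretisation (second order in the grid
#' spacing) of the force balance, with exact zero-flux (stress-free)
#' boundary conditions; the resulting tridiagonal system is solved
#' directly. With `gamma > 0` everywhere the operator is strictly
#' invertible.
#'
#' @param model a [film_model()].
#' @param n_grid number of grid cells (>= 101).
#' @return A `film_solution`: list with `grid` (tibble `x`, `x_norm`, `v`,
#'   `c`), the `model`, and the discrete `residual` (max norm).
#' @export
solve_chiral_flow <- function(model, n_grid = 401) {
  stopifnot(inherits(model, "film_model"))
  if (n_grid < 101) abort("`n_grid` must be >= 101.")
  L <- model$L
  lo <- if (model$geometry == "flat") 0 else model$truncation * L
  hi <- L - lo
  h <- (hi - lo) / n_grid
  x <- lo + (seq_len(n_grid) - 0.5) * h      # cell centres
  xf <- lo + (0:n_grid) * h                  # faces
  r_c <- film_radius(model, x)
  r_f <- film_radius(model, xf)
  gam <- if (is.null(model$gamma_fun)) rep(model$gamma, n_grid) else model$gamma_fun(x)
  if (any(gam <= 0)) abort("Friction gamma(x) must be positive.")
  cval <- model$myosin(x / L)
  dc <- c_gradient(model$myosin, x / L) / L
  rhs <- model$chi * dc
  # solved in the angular variable u = v / r so the stress-free
  # condition d(v/r)/dx = 0 is the natural zero-flux boundary:
  # eta (1/r^2) d/dx [r^3 du/dx] - gamma r u = chi c'
  wl <- c(0, model$eta * r_f[2:n_grid]^3 / (r_c[2:n_grid]^2 * h^2))
  wu <- c(model$eta * r_f[2:n_grid]^3 / (r_c[1:(n_grid - 1)]^2 * h^2), 0)
  diag_main <- -(wl + wu) - gam * r_c
  M <- Matrix::bandSparse(
    n_grid, n_grid, k = c(-1, 0, 1),
    diagonals = list(wl[-1], diag_main, wu[-n_grid])
  )
  u <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                error = function(e) abort(paste0(
                  "Singular or ill-conditioned discretisation: ",
                  conditionMessage(e))))
  v <- r_c * u
  if (any(!is.finite(v))) abort("Non-finite solution; check model inputs.")
  residual <- max(abs(as.numeric(M %*% u) - rhs))
  structure(
    list(grid = tibble(x = x, x_norm = x / L, v = v, c = cval),
         model = model, residual = residual, h = h),
    class = "film_solution"
  )
}

# centred finite-difference gradient of the myosin profile (normalised x)
c_gradient <- function(cfun, x_norm, eps = 1e-5) {
  (cfun(x_norm + eps) - cfun(x_norm - eps)) / (2 * eps)
}

#' @export
print.film_solution <- function(x, ...) {
  cat(sprintf(
    "<film_solution> %d cells on [%.3g, %.3g] um, max |v| = %.3g um/min, residual %.2g\n",
    nrow(x$grid), min(x$grid$x), max(x$grid$x), max(abs(x$grid$v)), x$residual
  ))
  invisible(x)
}

#' @method tidy film_solution
#' @export
tidy.film_solution <- function(x, ...) x$grid

#' Predicted counter-rotating flow velocity from a film solution
#'
#' Evaluates the azimuthal flow at the model's ROI centres, `xr - d` (ROI 1)
#' and `xr + d` (ROI 2, the `e_x` side), and combines them with the same
#' convention as the measurement pipeline: `vc_pred = v(xr + d) - v(xr - d)`.
#'
#' @param solution a `film_solution`.
#' @param xr ring position (um along the domain).
#' @param d distance from the ring to each ROI centre (um).
#' @return Predicted `vc` (um/min).
#' @export
predict_vc <- function(solution, xr, d) {
  stopifnot(inherits(solution, "film_solution"))
  g <- solution$grid
  pts <- c(xr - d, xr + d)
  if (any(pts < min(g$x) | pts > max(g$x))) {
    abort("ROI offset falls outside the solved domain.")
  }
  vv <- approx(g$x, g$v, xout = pts)$y
  vv[2] - vv[1]
}

# Eq.5-parameterised torque profile at fixed total myosin: the asymmetry
# `ratio` = IA/IP is applied at constant geometric mean (IA = sqrt(ratio),
# IP = 1/sqrt(ratio)) and the whole profile is normalised so that the mean
# concentration along the axis is 1. This compares distribution shapes at
# fixed overall myosin amount.
asymmetry_profile <- function(ratio, ring_pos, w = 0.05, ir = 0.3) {
  ia <- sqrt(ratio); ip <- 1 / sqrt(ratio)
  raw <- function(x) myosin_model(x, ia, ip, ir, w, ring_pos)
  xs <- seq(0, 1, length.out = 2001)
  total <- mean(raw(xs))
  function(x) raw(x) / total
}

#' Sweep myosin asymmetry and ring position in the film model
#'
#' Computes the predicted counter-rotating flow velocity over a grid of
#' myosin ratios and relative ring positions, using the step-plus-Gaussian
#' torque profile at fixed total myosin (see Details of [film_model()]),
#' and reports where `|vc|` is maximal together with normalised
#' sensitivities of `|vc|` to each control parameter over its
#' experimentally observed range (ratio 1 to 2, ring position 0.5 to 0.6).
#'
#' @param model a [film_model()]; its `myosin` entry is replaced by the
#'   swept profiles.
#' @param ratios myosin ratios IA/IP to sweep.
#' @param ring_positions relative ring positions `xr/L` to sweep.
#' @param d ROI-centre distance from the ring (um).
#' @param w,ir ring width and weight of the swept profiles (normalised).
#' @param n_grid solver resolution.
#' @return A tibble (`ratio`, `ring_pos`, `vc_pred`, `abs_vc`) with
#'   attributes `argmax` (row with maximal `|vc|`) and `sensitivity`
#'   (named vector with the relative drop of `|vc|` over each parameter's
#'   observed range).
#' @export
sweep_asymmetry <- function(model,
                            ratios = c(0.5, 2 / 3, 0.8, 1, 1.25, 1.5, 2),
                            ring_positions = c(0.4, 0.45, 0.5, 0.55, 0.6),
                            d = 4.5, w = 0.05, ir = 0.3, n_grid = 401) {
  stopifnot(inherits(model, "film_model"))
  eval_vc <- function(ratio, ring_pos) {
    m <- model
    m$myosin <- asymmetry_profile(ratio, ring_pos, w = w, ir = ir)
    sol <- solve_chiral_flow(m, n_grid = n_grid)
    predict_vc(sol, xr = ring_pos * model$L, d = d)
  }
  grid <- tidyr::expand_grid(ratio = ratios, ring_pos = ring_positions)
  grid$vc_pred <- purrr::map2_dbl(grid$ratio, grid$ring_pos, eval_vc)
  grid$abs_vc <- abs(grid$vc_pred)
  sym <- abs(eval_vc(1, 0.5))
  sens <- c(
    ratio = (sym - abs(eval_vc(2, 0.5))) / sym,
    ring_pos = (sym - abs(eval_vc(1, 0.6))) / sym
  )
  attr(grid, "argmax") <- grid[which.max(grid$abs_vc), ]
  attr(grid, "sensitivity") <- sens
  grid
}

#' Fit the film model to a binned transverse-flow profile
#'
#' Least-squares fit of the solver output to a binned `e_y`-velocity
#' profile (such as [bin_longaxis_profile()] returns) over the
#' hydrodynamic length and a free amplitude, assuming uniform viscosity
#' across the surface. The amplitude enters linearly and is profiled out;
#' the hydrodynamic length is found by golden-section search on a log
#' scale. A flat residual landscape (relative variation below `1e-4`
#' across +/-50% of the fitted length) is flagged as non-identifiable.
#'
#' @param profile a data frame with `x_mid` (normalised bin centres) and
#'   `vy` (um/min); `NA` bins are dropped.
#' @param model a [film_model()] supplying geometry and the myosin profile
#'   `c(x)` (measured or fitted).
#' @param ell_range search range for the hydrodynamic length (um).
#' @param n_grid solver resolution.
#' @return A `film_fit` object with `ell`, `amplitude` (the fitted
#'   multiplier of the unit-`chi` solution), `rss`, `identifiable`,
#'   `fitted` (tibble of bin predictions), `model`.
#' @export
fit_flow_profile <- function(profile, model,
                             ell_range = c(0.02, 2) * model$L,
                             n_grid = 401) {
  stopifnot(inherits(model, "film_model"))
  keep <- is.finite(profile$vy)
  xb <- profile$x_mid[keep]; yb <- profile$vy[keep]
  if (length(xb) < 5) abort("Need at least 5 bins to fit the film model.")
  edges <- bin_edges_from_centers(xb)
  shape_for <- function(ell) {
    m <- model
    m$ell <- ell
    m$gamma <- m$eta / ell^2
    m$gamma_fun <- NULL
    m$chi <- 1
    sol <- solve_chiral_flow(m, n_grid = n_grid)
    bin_average(sol$grid$x_norm, sol$grid$v, edges)
  }
  obj <- function(log_ell) {
    vb <- shape_for(exp(log_ell))
    a <- sum(vb * yb) / sum(vb^2)
    sum((yb - a * vb)^2)
  }
  opt <- optimize(obj, interval = log(ell_range), tol = 1e-6)
  ell <- exp(opt$minimum)
  vb <- shape_for(ell)
  amplitude <- sum(vb * yb) / sum(vb^2)
  rss <- sum((yb - amplitude * vb)^2)
  near <- vapply(c(0.5, 1.5), function(f) obj(log(clamp(ell * f,
                                                        ell_range[1],
                                                        ell_range[2]))),
                 numeric(1))
  denom <- max(rss, 1e-12)
  identifiable <- max(abs(near - rss)) / denom > 1e-4
  if (!identifiable) {
    warn("Flat residual landscape: hydrodynamic length is not identifiable.")
  }
  structure(
    list(ell = ell, amplitude = amplitude, rss = rss,
         identifiable = identifiable,
         fitted = tibble(x_mid = xb, vy = yb, vy_fit = amplitude * vb),
         model = model),
    class = "film_fit"
  )
}

bin_edges_from_centers <- function(centers) {
  d <- diff(centers)
  c(centers[1] - d[1] / 2, centers[-length(centers)] + d / 2,
    centers[length(centers)] + d[length(d)] / 2)
}

bin_average <- function(x, y, edges) {
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  out <- rep(NA_real_, length(edges) - 1)
  agg <- tapply(y, bin, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' @export
print.film_fit <- function(x, ...) {
  cat(sprintf(
    "<film_fit> ell = %.3g um, amplitude = %.3g, rss = %.3g%s\n",
    x$ell, x$amplitude, x$rss,
    if (x$identifiable) "" else " [NOT IDENTIFIABLE]"
  ))
  invisible(x)
}

#' @method tidy film_fit
#' @export
tidy.film_fit <- function(x, ...) {
  tibble(term = c("ell", "amplitude"),
         estimate = c(x$ell, x$amplitude))
}

#' @method glance film_fit
#' @export
glance.film_fit <- function(x, ...) {
  tibble(rss = x$rss, identifiable = x$identifiable,
         n = nrow(x$fitted))
}

#' Friction ratio from two hydrodynamic lengths
#'
#' With uniform viscosity, `ell = sqrt(eta / gamma)` implies that the
#' friction ratio between the two sides is the inverse squared ratio of
#' their hydrodynamic lengths: `gamma_R / gamma_L = (ell_L / ell_R)^2`.
#'
#' @param ell_left,ell_right hydrodynamic lengths fitted on the left and
#'   right side (um, > 0).
#' @return `gamma_R / gamma_L`.
#' @export
friction_ratio_from_lengths <- function(ell_left, ell_right) {
  if (ell_left <= 0 || ell_right <= 0) abort("Hydrodynamic lengths must be > 0.")
  (ell_left / ell_right)^2
}

#' Simulate a binned flow profile from the film model
#'
#' Solves the model, averages the azimuthal flow into `n_bins` equal
#' sections of the normalised long axis (the nine-section tiling of the
#' published analysis), and adds i.i.d. Gaussian noise. The generating
#' model is retained as ground truth.
#'
#' @param model a [film_model()].
#' @param noise_sigma additive noise on the bin means (um/min).
#' @param n_bins number of sections (>= 5).
#' @param seed integer seed.
#' @param n_grid solver resolution.
#' @return A list with `profile` (tibble `x_mid`, `vy`), `truth` (the
#'   model), `clean` (noise-free bin means).
#' @export
sim_model_flow_profile <- function(model, noise_sigma = 0, n_bins = 9,
                                   seed = 1L, n_grid = 401) {
  stopifnot(inherits(model, "film_model"))
  if (n_bins < 5) abort("`n_bins` must be >= 5.")
  sol <- solve_chiral_flow(model, n_grid = n_grid)
  edges <- seq(0, 1, length.out = n_bins + 1)
  clean <- bin_average(sol$grid$x_norm, sol$grid$v, edges)
  vy <- withr::with_seed(seed, clean + rnorm(n_bins, sd = noise_sigma))
  list(
    profile = tibble(x_mid = (head(edges, -1) + tail(edges, -1)) / 2, vy = vy),
    truth = model,
    clean = clean
  )
}
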