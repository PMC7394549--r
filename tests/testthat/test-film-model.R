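ring_profile <- function(w = 0.05, xr = 0.5, ir = 0.3, ia = 1, ip = 1) {
  function(x) myosin_model(x, ia, ip, ir, w, xr)
}

test_that("constant myosin produces no flow; chi = 0 predicts vc = 0", {
  m <- film_model(length = 24, myosin = function(x) rep(1, length(x)))
  expect_equal(max(abs(solve_chiral_flow(m)$grid$v)), 0)
  m0 <- film_model(length = 24, chi = 0, myosin = ring_profile())
  expect_equal(predict_vc(solve_chiral_flow(m0), 12, 4.5), 0)
})

test_that("friction-dominated limit matches the closed form within 2%", {
  cfun <- ring_profile(w = 0.15)
  m <- film_model(length = 24, ell = 24 / 100, chi = -1, myosin = cfun)
  sol <- solve_chiral_flow(m, n_grid = 4001)
  g <- sol$grid
  closed <- -m$chi / m$gamma * chiralflow:::c_gradient(cfun, g$x_norm) / m$L
  expect_lt(max(abs(g$v - closed)) / max(abs(closed)), 0.02)
})

test_that("discretisation converges at second order and is grid-stable", {
  m <- film_model(length = 24, ell = 4, myosin = ring_profile(w = 0.15))
  ref <- solve_chiral_flow(m, n_grid = 6400)$grid
  err <- vapply(c(200, 400, 800), function(n) {
    g <- solve_chiral_flow(m, n_grid = n)$grid
    max(abs(g$v - approx(ref$x, ref$v, xout = g$x)$y))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5)
  # n = 201 vs n = 2001 agree within 0.5%
  g1 <- solve_chiral_flow(m, n_grid = 201)$grid
  g2 <- solve_chiral_flow(m, n_grid = 2001)$grid
  v2 <- approx(g2$x, g2$v, xout = g1$x)$y
  expect_lt(max(abs(g1$v - v2)) / max(abs(v2)), 0.005)
})

test_that("solution is linear in chi and superposes in c", {
  c1 <- ring_profile(xr = 0.4)
  c2 <- ring_profile(xr = 0.65, w = 0.08)
  base <- film_model(length = 24, ell = 5, chi = -1, myosin = c1)
  v1 <- solve_chiral_flow(base)$grid$v
  m2 <- base; m2$chi <- -2.5
  expect_equal(solve_chiral_flow(m2)$grid$v, 2.5 * v1, tolerance = 1e-9)
  mb <- base; mb$myosin <- c2
  vb <- solve_chiral_flow(mb)$grid$v
  ms <- base; ms$myosin <- function(x) c1(x) + c2(x)
  expect_equal(solve_chiral_flow(ms)$grid$v, v1 + vb, tolerance = 1e-8)
})

test_that("reflection equivariance and predict_vc antisymmetry hold", {
  for (geom in c("flat", "ellipsoid")) {
    m <- film_model(length = 24, ell = 6, geometry = geom,
                    myosin = ring_profile(xr = 0.4, ia = 1.3, ip = 0.8))
    g <- solve_chiral_flow(m)$grid
    mr <- m; mr$myosin <- function(x) m$myosin(1 - x)
    gr <- solve_chiral_flow(mr)$grid
    expect_equal(gr$v, -rev(g$v), tolerance = 1e-8)
    # symmetric c about a centred ring: v antisymmetric, |vc| = 2|v(xr+d)|
    msym <- film_model(length = 24, ell = 6, geometry = geom,
                       myosin = ring_profile(xr = 0.5))
    sol <- solve_chiral_flow(msym)
    vc <- predict_vc(sol, 12, 4.5)
    v_at <- approx(sol$grid$x, sol$grid$v, xout = 16.5)$y
    expect_equal(vc, 2 * v_at, tolerance = 1e-9)
    expect_equal(abs(vc), 2 * abs(v_at), tolerance = 1e-9)
  }
  expect_error(predict_vc(solve_chiral_flow(film_model(length = 24)), 12, 13),
               "outside")
})

test_that("asymmetry sweep peaks at the symmetric division", {
  m <- film_model(length = 24, ell = 6, geometry = "ellipsoid", radius = 8)
  sw <- sweep_asymmetry(m, ratios = c(0.5, 1, 1.5, 2),
                        ring_positions = c(0.4, 0.45, 0.5, 0.55, 0.6),
                        n_grid = 201)
  am <- attr(sw, "argmax")
  expect_equal(am$ratio, 1)
  expect_equal(am$ring_pos, 0.5)
  # monotone decrease as the ratio departs from 1 at a centred ring
  at_centre <- sw$abs_vc[sw$ring_pos == 0.5]
  ratios <- sw$ratio[sw$ring_pos == 0.5]
  ord <- order(abs(log(ratios)))
  expect_true(all(diff(at_centre[ord]) <= 1e-10))
  # monotone decrease as the ring moves off-centre at ratio 1
  at_one <- sw$abs_vc[sw$ratio == 1]
  rings <- sw$ring_pos[sw$ratio == 1]
  ord2 <- order(abs(rings - 0.5))
  expect_true(all(diff(at_one[ord2]) <= 1e-10))
  # sensitivity to the ratio exceeds sensitivity to the ring position
  sens <- attr(sw, "sensitivity")
  expect_gt(sens[["ratio"]], sens[["ring_pos"]])
  expect_gt(sens[["ratio"]], 0)
  expect_gt(sens[["ring_pos"]], 0)
})

test_that("hydrodynamic length fitting is exact without noise and robust with it", {
  m <- film_model(length = 24, ell = 6, chi = -1, myosin = ring_profile())
  clean <- sim_model_flow_profile(m, noise_sigma = 0, n_bins = 9)
  fit <- fit_flow_profile(clean$profile, m)
  expect_equal(fit$ell, 6, tolerance = 1e-3)
  expect_equal(fit$amplitude, -1, tolerance = 1e-3)
  expect_true(fit$identifiable)
  # amplitude and ell recovered independently when both perturbed +/-50%
  for (tr in list(c(3, -0.5), c(9, -1.5))) {
    mt <- film_model(length = 24, ell = tr[1], chi = tr[2],
                     myosin = ring_profile())
    simt <- sim_model_flow_profile(mt, noise_sigma = 0, n_bins = 9)
    ft <- fit_flow_profile(simt$profile, m)
    expect_equal(ft$ell, tr[1], tolerance = 0.02)
    expect_equal(ft$amplitude, tr[2], tolerance = 0.02)
  }
  # 20% noise: ell recovered within 15% in the Monte-Carlo aggregate
  nmax <- max(abs(clean$clean))
  ells <- vapply(1:20, function(s) {
    sim <- sim_model_flow_profile(m, noise_sigma = 0.2 * nmax, n_bins = 9,
                                  seed = s)
    fit_flow_profile(sim$profile, m)$ell
  }, numeric(1))
  expect_lt(abs(median(ells) - 6) / 6, 0.15)
  expect_lt(median(abs(ells - 6) / 6), 0.15)
})

test_that("friction ratios follow from hydrodynamic lengths", {
  expect_equal(friction_ratio_from_lengths(5, 5), 1)
  expect_equal(friction_ratio_from_lengths(8, 4), 4)
  expect_equal(friction_ratio_from_lengths(sqrt(1.7) * 3, 3), 1.7,
               tolerance = 1e-12)
  expect_error(friction_ratio_from_lengths(-1, 2), "> 0")
})
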