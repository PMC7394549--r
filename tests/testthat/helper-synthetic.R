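# Shared fixture builders. Everything is generated in code, seeded.

# Render a speckle texture and an exactly translated copy of it.
speckle_pair <- function(shift, nx = 128, ny = 128, n = 1000, seed = 42,
                         sigma = 1) {
  withr::with_seed(seed, {
    pos <- cbind(runif(n, 0.5, nx + 0.5), runif(n, 0.5, ny + 0.5))
  })
  f1 <- chiralflow:::render_spots(nx, ny, pos, sigma = sigma)
  p2 <- cbind((pos[, 1] - 0.5 + shift[1]) %% nx + 0.5,
              (pos[, 2] - 0.5 + shift[2]) %% ny + 0.5)
  f2 <- chiralflow:::render_spots(nx, ny, p2, sigma = sigma)
  image_stack(list(f1, f2), pixel_size = 0.2, frame_interval = 3)
}

# Full generator -> PIV -> chirality round trip on one synthetic movie.
analyze_movie <- function(mov, cell_id = "AB") {
  vf <- compute_piv(mov$stack)
  rois <- place_rois(mov$frame, cell_id = cell_id,
                     pixel_size = mov$stack$pixel_size,
                     image_shape = dim(mov$stack$frames[[1]]))
  chiral_stats(vf, rois, mov$frame)
}

# Axis-aligned division frame used in vector-level tests: e_x along +x,
# ring vertical through the origin-ish centre.
unit_frame <- function() {
  division_frame(ring_start = c(50, 1), ring_end = c(50, 99),
                 ex_toward = c(1, 0))
}

# Noise-free spindle track rotating at `rate_fun(t_min)` deg/min with
# fixed separation, sampled every `dt_s` seconds.
rotating_track <- function(rate_fun, t_end_s = 180, dt_s = 3, sep = 8) {
  tt <- seq(0, t_end_s, by = dt_s)
  t_min <- tt / 60
  r <- rate_fun(t_min)
  ang_deg <- c(0, cumsum((head(r, -1) + tail(r, -1)) / 2 * diff(t_min)))
  a <- ang_deg * pi / 180
  spindle_track(seq_along(tt), tt,
                x1 = 10 - sep / 2 * cos(a), y1 = 10 - sep / 2 * sin(a),
                x2 = 10 + sep / 2 * cos(a), y2 = 10 + sep / 2 * sin(a))
}

# Exhaustive-enumeration Wilcoxon rank-sum oracle: distribution of the
# rank-sum of group x over all label assignments (no ties assumed).
wilcox_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U of x
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
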