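# Synthetic wall-motion generators, particle rendering, and analytic
# benchmark solutions.

test_that("peristaltic motion is periodic with the closed-form indentation", {
  spec <- peristaltic_spec(n_cycles = 2)
  fld <- generate_peristaltic_motion(spec)
  expect_equal(fld$node_count, 2 * spec$n_wall + 2 * spec$n_cap)
  expect_true(all(diff(fld$times) > 0))
  # occlusion 0: static straight tube
  fld0 <- generate_peristaltic_motion(peristaltic_spec(occlusion = 0,
                                                       n_cycles = 1))
  expect_lt(max(abs(sweep(fld0$positions, 1:2, fld0$positions[, , 1]))),
            1e-12)
  # periodicity: t and t + 1/f coincide
  p1 <- wall_position(fld, 0.2)
  p2 <- wall_position(fld, 0.2 + 1 / spec$frequency)
  expect_lt(max(abs(p1 - p2)), 1e-10)
  # gap at the wave crest = rest gap * (1 - occ), from the closed form
  h <- peristaltic_halfwidth(spec)
  t0 <- 0.31
  crest <- spec$wave_speed * t0 + spec$wavelength / 2   # sin^2 = 1 there
  expect_equal(h(crest, t0), spec$half_width * (1 - spec$occlusion),
               tolerance = 1e-12)
  # generated wall nodes sit on the +/- h profile at every sample
  k <- 25
  tk <- fld$times[k]
  wallnodes <- which(fld$tags == "wall")
  pos <- fld$positions[wallnodes, , k]
  expect_lt(max(abs(abs(pos[, 2]) - h(pos[, 1], tk))), 1e-9)
  expect_error(peristaltic_spec(occlusion = 1), "occlusion")
})

test_that("two-chamber motion modulates areas with the phase lag", {
  spec <- two_chamber_spec(phase_lag = 0.5, n_cycles = 1)
  h <- two_chamber_halfwidth(spec)
  # closed-form chamber areas: integrate h over each chamber's half-domain
  xs_a <- seq(0, spec$length / 2, length.out = 300)
  xs_v <- seq(spec$length / 2, spec$length, length.out = 300)
  area <- function(xs, t) sum(2 * h(xs, t) * (xs[2] - xs[1]))
  ts <- seq(0, 1 / spec$frequency, length.out = 60)
  Aa <- vapply(ts, function(t) area(xs_a, t), numeric(1))
  Av <- vapply(ts, function(t) area(xs_v, t), numeric(1))
  # antiphase on the fundamental: correlation of the centered signals = -1
  expect_lt(cor(Aa - mean(Aa), Av - mean(Av)), -0.99)
  # zero modulation -> static geometry
  fld0 <- generate_two_chamber_motion(two_chamber_spec(amplitude = 0,
                                                       n_cycles = 1))
  expect_lt(max(abs(sweep(fld0$positions, 1:2, fld0$positions[, , 1]))),
            1e-12)
  # constant node count across samples by construction
  fld <- generate_two_chamber_motion(spec)
  expect_equal(dim(fld$positions)[1], fld$node_count)
})

test_that("piston fixture matches its closed-form area derivative", {
  fld <- generate_piston_motion(length = 0.1, height = 0.02, stroke = 0.03,
                                period = 1, sample_rate = 100)
  A <- attr(fld, "area"); dA <- attr(fld, "dareadt")
  # shoelace area of the generated loop equals the closed form
  for (t in c(0, 0.13, 0.5)) {
    sh <- abs(polygon_area(wall_position(fld, t)))
    expect_equal(sh, A(t), tolerance = 1e-8)
  }
  # analytic dA/dt equals centered shoelace differentiation
  t0 <- 0.27; eps <- 1e-4
  num <- (abs(polygon_area(wall_position(fld, t0 + eps))) -
            abs(polygon_area(wall_position(fld, t0 - eps)))) / (2 * eps)
  expect_equal(num, dA(t0), tolerance = 1e-4)
})

test_that("particle rendering is deterministic and advects exactly", {
  zero <- function(x, y) cbind(rep(0, length(x)), rep(0, length(x)))
  r1 <- render_particle_images(c(64, 64), 2, zero, seed = 3)
  r2 <- render_particle_images(c(64, 64), 2, zero, seed = 3)
  expect_identical(r1$frames, r2$frames)
  # zero flow, no noise: frames bit-identical
  expect_identical(r1$frames[[1]], r1$frames[[2]])
  # uniform flow: ground truth grid is uniformly the prescribed shift
  u4 <- function(x, y) cbind(rep(4, length(x)), rep(0, length(x)))
  r3 <- render_particle_images(c(64, 64), 2, u4, seed = 4)
  g <- r3$truth(c(10, 30, 50), c(10, 30, 50))
  expect_true(all(g[, 1] == 4 & g[, 2] == 0))
  expect_error(render_particle_images(c(64, 64), 2, u4, diameter = 1),
               "diameter")
})

test_that("analytic channel solutions satisfy their identities", {
  pois <- poiseuille_solution(0.01, 0.1, 0.07)
  expect_equal(pois$centerline, 0.15)
  expect_equal(pois$wss, 4.2, tolerance = 1e-12)
  # mean of the profile is U_mean (trapezoid over a fine grid)
  y <- seq(0, 0.01, length.out = 2001)
  pv <- pois$profile(y)
  expect_equal(sum((pv[-1] + pv[-2001]) / 2 * diff(y)) / 0.01, 0.1,
               tolerance = 1e-6)
  # Womersley at alpha -> 0 reduces to quasi-steady Poiseuille
  w <- womersley_solution(0.01, 0.01, 0.1)
  for (ph in c(0.3, 1.2, 2.5, 4.4)) {
    quasi <- 1.5 * 0.1 * sin(ph) * (1 - ((y - 0.005) / 0.005)^2)
    expect_lt(max(abs(w$u(y, ph) - quasi)) / (1.5 * 0.1), 1e-3)
  }
  # at moderate alpha the profile departs from the parabola
  w2 <- womersley_solution(0.01, 5, 0.1)
  quasi <- 1.5 * 0.1 * sin(1) * (1 - ((y - 0.005) / 0.005)^2)
  expect_gt(max(abs(w2$u(y, 1) - quasi)) / (1.5 * 0.1), 0.05)
})

test_that("generated fields satisfy the wall-motion invariants", {
  for (fld in list(generate_peristaltic_motion(peristaltic_spec(n_cycles = 1)),
                   generate_two_chamber_motion(two_chamber_spec(n_cycles = 1)))) {
    expect_true(all(diff(fld$times) > 0))
    expect_equal(length(fld$tags), fld$node_count)
    expect_equal(dim(fld$positions), c(fld$node_count, 2L,
                                       length(fld$times)))
    # boundary loop stays a valid simple polygon at sampled times
    for (k in c(1L, length(fld$times) %/% 2L)) {
      loop <- fld$positions[, , k]
      expect_gt(abs(polygon_area(loop)), 0)
      expect_s3_class(boundary_trace(loop, fld$tags), "boundary_trace")
    }
  }
})
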