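# Post-processing: WSS, peak averaging, pressure gradient, stream
# function, and the scalar formulas.

couette_state <- function(m, gam) {
  n <- nrow(m$coords)
  flow_state(m, u = cbind(gam * m$coords[, 2], rep(0, n)))
}

test_that("WSS is exact for Couette and accurate for Poiseuille", {
  H <- 0.01; L <- 0.03
  m <- channel_mesh(L, H, 10, 8)
  mu <- 0.07
  # quiescent: zero everywhere
  w0 <- compute_wss(flow_state(m), m, mu)
  expect_equal(max(abs(w0$tau)), 0)
  # Couette u = (gam y, 0): tau = mu gam on both walls, exactly (P1-linear)
  gam <- 25
  wc <- compute_wss(couette_state(m, gam), m, mu)
  interior <- wc$x > 0 & wc$x < 0.03    # corner nodes have oblique tangents
  expect_lt(max(abs(wc$tau[interior] - mu * gam)), 1e-8)
  # Poiseuille: solved flow, wall tau = 6 mu U / H within 2% (fine wall mesh)
  U <- 0.1
  mf <- channel_mesh(0.03, H, 15, 80)
  props <- blood_properties(1.06, mu)
  pois <- poiseuille_solution(H, U, mu)
  bc <- flow_bc(inlet = function(xy, t) cbind(pois$profile(xy[, 2]), 0))
  st <- steady_solve(mf, props, bc, tol = 1e-11)
  ws <- compute_wss(st, mf, mu)
  interior_bottom <- ws$y == 0 & ws$x > 0.005 & ws$x < 0.025
  expect_lt(abs(mean(ws$tau[interior_bottom]) / pois$wss - 1), 0.02)
  expect_equal(pois$wss, 4.2, tolerance = 1e-12)   # mu=0.07, U=0.1, H=0.01
})

test_that("region peak average follows the highest-k rule", {
  expect_equal(region_peak_average(rep(3.5, 30), k = 10), 3.5)
  v <- numeric(40); v[11:30] <- 1:20
  expect_equal(region_peak_average(v, region = 11:30, k = 10), mean(11:20))
  expect_warning(out <- region_peak_average(1:5, k = 10), "5 < k")
  expect_equal(out, 3)
  expect_error(region_peak_average(numeric(0)), "empty region")
  # averaged peak never drops below the region mean
  set.seed(3)
  for (i in 1:20) {
    vv <- rexp(25)
    expect_gte(region_peak_average(vv, k = 10), mean(vv))
  }
})

test_that("pressure gradient is linear-exact, antisymmetric, zero for uniform", {
  m <- channel_mesh(1, 0.5, 20, 10)
  n <- nrow(m$coords)
  a <- 7.3
  st <- flow_state(m, p = a * m$coords[, 1])
  c1 <- c(0.2, 0.25); c2 <- c(0.8, 0.25)
  dp <- compute_pressure_gradient(st, m, c1, c2, k = 10)
  # oracle: a * (mean x of the k nodes nearest c2 - same for c1)
  nearest <- function(ctr) {
    d <- (m$coords[, 1] - ctr[1])^2 + (m$coords[, 2] - ctr[2])^2
    order(d)[1:10]
  }
  dx <- mean(m$coords[nearest(c2), 1]) - mean(m$coords[nearest(c1), 1])
  expect_equal(as.numeric(dp), a * dx, tolerance = 1e-12)
  expect_equal(as.numeric(dp), a * 0.6, tolerance = 1e-6)
  # antisymmetry and uniform field
  dp_sw <- compute_pressure_gradient(st, m, c2, c1, k = 10)
  expect_equal(as.numeric(dp_sw), -as.numeric(dp))
  stu <- flow_state(m, p = rep(4, n))
  expect_equal(as.numeric(compute_pressure_gradient(stu, m, c1, c2)), 0)
  expect_error(compute_pressure_gradient(st, m, c(-1, 0), c2), "outside")
})

test_that("stream function recovers uniform flow, rotation, and is gauge-free", {
  m <- square_mesh(16)
  n <- nrow(m$coords)
  U <- 0.7
  sf <- compute_streamfunction(flow_state(m, u = cbind(rep(U, n), 0)), m)
  psi_exp <- U * m$coords[, 2]
  psi_exp <- psi_exp - psi_exp[sf$ref_node]
  expect_lt(max(abs(sf$psi - psi_exp)), 1e-10)
  # solid-body rotation
  Om <- 2
  st <- flow_state(m, u = cbind(-Om * (m$coords[, 2] - 0.5),
                                Om * (m$coords[, 1] - 0.5)))
  sf2 <- compute_streamfunction(st, m)
  pex <- -Om * ((m$coords[, 1] - 0.5)^2 + (m$coords[, 2] - 0.5)^2) / 2
  pex <- pex - pex[sf2$ref_node]
  expect_lt(sqrt(mean((sf2$psi - pex)^2)) / sqrt(mean(pex^2)), 0.02)
  # gauge: changing the reference node shifts psi by a constant only
  sf3 <- compute_streamfunction(st, m, ref_node = 40L)
  expect_lt(diff(range(sf2$psi - sf3$psi)), 1e-10)
})

test_that("ellipsoid volume, ejection fraction, Re and alpha formulas", {
  expect_equal(ventricular_volume(1, 1, 1), pi / 6, tolerance = 1e-12)
  d <- 0.37
  expect_equal(ventricular_volume(d, d, d), pi * d^3 / 6, tolerance = 1e-12)
  expect_equal(ventricular_volume(2, 1), pi / 3, tolerance = 1e-12)
  expect_error(ventricular_volume(-1, 1, 1), "positive")

  expect_equal(ejection_fraction(1, 0)$fraction, 1)
  expect_equal(ejection_fraction(1, 1)$fraction, 0)
  vef <- ejection_fraction(1.0472, 0.3351)
  expect_equal(vef$fraction, 0.680, tolerance = 1e-3)
  expect_error(ejection_fraction(1, 1.2), "data error")

  expect_equal(reynolds_number(1.06, 0, 0.01, 0.07), 0)
  expect_equal(womersley_number(1.06, 0, 0.01, 0.07), 0)
  expect_equal(reynolds_number(1.06, 1, 0.01, 0.07), 1.06 * 0.01 / 0.07,
               tolerance = 1e-12)                      # ~0.151
  expect_equal(womersley_number(1.06, 4 * pi, 0.01, 0.07),
               sqrt(1.06 * 4 * pi * 1e-4 / 0.07), tolerance = 1e-12) # ~0.138
  # unit invariance: CGS vs SI give identical dimensionless numbers
  expect_equal(reynolds_number(1060, 0.01, 1e-4, 0.007),
               reynolds_number(1.06, 1, 0.01, 0.07), tolerance = 1e-12)
  expect_equal(womersley_number(1060, 4 * pi, 1e-4, 0.007),
               womersley_number(1.06, 4 * pi, 0.01, 0.07), tolerance = 1e-12)
})

test_that("the AV-canal locator finds the throat of a two-chamber domain", {
  spec <- two_chamber_spec(n_cycles = 1)
  motion <- generate_two_chamber_motion(spec)
  mesh <- triangulate(wall_position(motion, 0), 0.006, motion$tags)
  av <- av_canal_region(mesh, window = 0.02)
  # throat sits between the chambers, near mid-domain, at the narrow gap
  expect_gt(av$center[1], 0.35 * spec$length)
  expect_lt(av$center[1], 0.65 * spec$length)
  expect_lt(av$throat_width, 2.5 * 2 * spec$throat_half_width)
  expect_gt(length(av$region), 0)
})
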