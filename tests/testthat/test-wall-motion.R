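# Boundary traces, spline fitting, equidistant resampling, and the
# Lagrangian high-rate wall-motion field.

test_that("trace validation rejects bad inputs and self-intersections", {
  expect_error(boundary_trace(cbind(0:2, 0:2)), "at least 4")
  # figure-eight style crossing
  pts <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1), c(-1, 0.5))
  expect_error(boundary_trace(pts), "self-intersecting")
  # non-contiguous inlet span
  pts2 <- cbind(0:5, 0)
  expect_error(boundary_trace(pts2, c("inlet", "wall", "inlet", "wall",
                                      "wall", "wall")),
               "contiguous")
  tr <- boundary_trace(pts2, rep("wall", 6), frame = 3L, time = 0.15)
  expect_s3_class(tr, "boundary_trace")
  expect_equal(tr$time, 0.15)
})

test_that("interpolating spline reproduces knots, lines, and arc length", {
  # 8 points on the unit circle, smoothing 0: exact at knots
  tr <- circle_trace(8)
  cv <- fit_boundary_spline(tr, smoothing = 0)
  at_knots <- curve_eval(cv, cv$knots)
  expect_equal(at_knots, unname(tr$points), tolerance = 1e-12)
  # collinear points stay collinear
  trl <- boundary_trace(cbind(seq(0, 2, length.out = 7), 0))
  cvl <- fit_boundary_spline(trl, 0)
  s <- seq(0, cvl$tmax, length.out = 200)
  expect_lt(max(abs(curve_eval(cvl, s)[, 2])), 1e-12)
  # ellipse (a = 2, b = 1): arc length within 0.5% of dense quadrature
  a <- 2; b <- 1
  th <- seq(0, 2 * pi, length.out = 33)[1:32]
  tre <- boundary_trace(cbind(a * cos(th), b * sin(th)))
  cve <- fit_boundary_spline(tre, 0)
  # oracle: dense quadrature on the exact ellipse over the same arc span
  thf <- seq(0, th[32], length.out = 20001)
  speed <- sqrt(a^2 * sin(thf)^2 + b^2 * cos(thf)^2)
  perim <- sum((speed[-1] + speed[-length(speed)]) / 2 * diff(thf))
  expect_lt(abs(curve_arclength(cve) / perim - 1), 0.005)
})

test_that("smoothing splines preserve endpoints exactly", {
  set.seed(4)
  x <- seq(0, 1, length.out = 25)
  tr <- boundary_trace(cbind(x, sin(2 * pi * x) + rnorm(25, 0, 0.02)))
  cv <- fit_boundary_spline(tr, smoothing = 0.6)
  expect_equal(curve_eval(cv, 0)[1, ], unname(tr$points[1, ]),
               tolerance = 1e-12)
  expect_equal(curve_eval(cv, cv$tmax)[1, ], unname(tr$points[25, ]),
               tolerance = 1e-12)
})

test_that("equidistant resampling yields uniform arc-length gaps", {
  expect_error(resample_equidistant(
    fit_boundary_spline(circle_trace(8)), 3), ">= 4")
  # straight segment: exact uniform subdivision
  trs <- boundary_trace(cbind(seq(0, 1, length.out = 5), 0))
  nodes <- resample_equidistant(fit_boundary_spline(trs, 0), 5)
  expect_equal(nodes[, 1], c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-9)
  # regular polygon, polyline parameterization: 22 equal segments split
  # into 11 equal-arc gaps land on every other vertex -> equal chords
  cvc <- fit_boundary_spline(circle_trace(23), 0, method = "linear")
  nc <- resample_equidistant(cvc, 12)
  ch <- sqrt(rowSums(diff(nc)^2))
  expect_lt(diff(range(ch)) / mean(ch), 1e-6)
  # ellipse, N = 64: per-gap arc length = total/63 within 1e-4 relative
  a <- 2; b <- 1
  th <- seq(0, 2 * pi, length.out = 65)[1:64]
  cve <- fit_boundary_spline(
    boundary_trace(cbind(a * cos(th), b * sin(th))), 0)
  ne <- resample_equidistant(cve, 64)
  tpar <- attr(ne, "param")
  # oracle: dense Simpson arc length between consecutive node parameters
  gap <- vapply(seq_len(63), function(i) {
    tt <- seq(tpar[i], tpar[i + 1], length.out = 201)
    d <- curve_eval(cve, tt, deriv = 1)
    sp <- sqrt(d[, 1]^2 + d[, 2]^2)
    sum((sp[-1] + sp[-201]) / 2 * diff(tt))
  }, numeric(1))
  expect_lt(max(abs(gap / mean(gap) - 1)), 1e-4)
  # round trip: a polyline whose vertices already sit at equal chord
  # spacing (regular polygon) resamples to itself
  tr2 <- circle_trace(16)
  n2 <- resample_equidistant(fit_boundary_spline(tr2, 0, method = "linear"),
                             16)
  expect_lt(max(abs(n2 - tr2$points)), 1e-9)
})

test_that("temporal interpolation is exact at frames and C2 between", {
  N <- 6
  base <- cbind(seq_len(N), 0)
  # static: identical at all samples
  frames <- rep(list(base), 10)
  fld <- interpolate_motion(frames, target_rate = 100)
  expect_true(all(vapply(seq_along(fld$times), function(k)
    max(abs(fld$positions[, , k] - base)) == 0, logical(1))))
  # inconsistent node counts rejected
  bad <- frames; bad[[3]] <- base[1:5, ]
  expect_error(interpolate_motion(bad), "correspondence")
  # linear motion reproduced exactly by cubic splines
  tf <- (0:9) / 20
  frames_lin <- lapply(tf, function(t) cbind(base[, 1] + 2 * t, 3 * t))
  fl <- interpolate_motion(frames_lin, tf, target_rate = 100)
  mid <- wall_position(fl, 0.123)
  expect_equal(mid, cbind(base[, 1] + 2 * 0.123, rep(3 * 0.123, N)),
               tolerance = 1e-12)
  # sinusoid at 20 fps resampled to 100 Hz within 2e-3 of truth
  tfs <- (0:20) / 20
  frames_sin <- lapply(tfs, function(t) cbind(base[, 1], sin(2 * pi * t)))
  fs <- interpolate_motion(frames_sin, tfs, target_rate = 100)
  err <- vapply(seq_along(fs$times), function(k)
    max(abs(fs$positions[, 2, k] - sin(2 * pi * fs$times[k]))), numeric(1))
  expect_lt(max(err), 2e-3)
})

test_that("wall velocity is the spline derivative, consistent with position", {
  N <- 5
  tf <- (0:20) / 20
  frames <- lapply(tf, function(t)
    cbind(seq_len(N) + 0.5 * t, sin(2 * pi * t)))
  fld <- interpolate_motion(frames, tf, target_rate = 100)
  # static field -> zero velocity
  fld0 <- interpolate_motion(rep(list(cbind(seq_len(N), 0)), 5),
                             (0:4) / 20)
  expect_equal(wall_velocity(fld0, 0.1), matrix(0, N, 2))
  # linear component exact, sinusoid within 2% at mid-span
  v <- wall_velocity(fld, 0.5)
  expect_equal(v[, 1], rep(0.5, N), tolerance = 1e-9)
  expect_lt(max(abs(v[, 2] - 2 * pi * cos(pi))) / (2 * pi), 0.02)
  # extrapolation guarded
  expect_error(wall_velocity(fld, 1.2), "extrapolation")
  # trapezoid integral of velocity reproduces position change within 1e-3
  ts <- seq(0.1, 0.9, by = 0.005)
  vs <- vapply(ts, function(t) wall_velocity(fld, t)[2, 2], numeric(1))
  dy <- sum((vs[-1] + vs[-length(vs)]) / 2 * diff(ts))
  truth <- wall_position(fld, 0.9)[2, 2] - wall_position(fld, 0.1)[2, 2]
  expect_lt(abs(dy - truth) / max(abs(truth), 1e-12), 1e-3)
})

test_that("traces_to_motion preserves node count and tags", {
  th <- seq(0, pi, length.out = 20)
  traces <- lapply(0:4, function(k)
    boundary_trace(cbind(cos(th), sin(th) * (1 + 0.05 * k)),
                   tags = c(rep("inlet", 3), rep("wall", 14),
                            rep("outlet", 3)),
                   frame = k + 1L, time = k / 20))
  fld <- traces_to_motion(traces, N = 30)
  expect_equal(fld$node_count, 30L)
  expect_true(all(dim(fld$positions)[1] == 30))
  expect_setequal(unique(fld$tags), c("inlet", "wall", "outlet"))
})
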