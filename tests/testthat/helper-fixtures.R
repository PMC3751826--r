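# Shared fixtures: analytic manufactured solutions, small canonical
# meshes, and cached expensive runs.

# unit circle trace with n points (open polyline along the arc)
circle_trace <- function(n, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  boundary_trace(cbind(r * cos(th), r * sin(th)))
}

# square mesh with every boundary node velocity-prescribed ("inlet")
all_dirichlet_square <- function(n) {
  m <- square_mesh(n)
  m$loop_tags[] <- "inlet"
  m$edge_tags[] <- "inlet"
  m$boundary <- list(wall = integer(0), inlet = sort(m$loop),
                     outlet = integer(0))
  m
}

# steady manufactured solution on the unit square:
# u = (sin(pi x) cos(pi y), -cos(pi x) sin(pi y)), p = cos(pi x) cos(pi y)
mms_fields <- function(rho = 1, mu = 1) {
  uex <- function(x, y) cbind(sin(pi * x) * cos(pi * y),
                              -cos(pi * x) * sin(pi * y))
  pex <- function(x, y) cos(pi * x) * cos(pi * y)
  # f = rho (u.grad)u - mu lap u + grad p (hand-derived)
  bf <- function(x, y, t)
    cbind(rho * (pi / 2) * sin(2 * pi * x) +
            2 * mu * pi^2 * sin(pi * x) * cos(pi * y) -
            pi * sin(pi * x) * cos(pi * y),
          rho * (pi / 2) * sin(2 * pi * y) -
            2 * mu * pi^2 * cos(pi * x) * sin(pi * y) -
            pi * cos(pi * x) * sin(pi * y))
  list(u = uex, p = pex, f = bf)
}

mms_solve <- function(n, rho = 1, mu = 1) {
  mm <- mms_fields(rho, mu)
  m <- all_dirichlet_square(n)
  bc <- flow_bc(inlet = function(xy, t) mm$u(xy[, 1], xy[, 2]),
                body_force = mm$f,
                pin_pressure = list(node = 1L, value = mm$p(0, 0)))
  st <- steady_solve(m, blood_properties(rho, mu), bc, tol = 1e-11,
                     max_iter = 30)
  list(mesh = m, state = st, mm = mm)
}

# discrete L2 norm of a nodal scalar field (P1, edge-midpoint quadrature)
l2_norm <- function(mesh, v) {
  A <- triangle_areas(mesh)
  tri <- mesh$tri
  s <- 0
  for (q in list(c(1, 2), c(2, 3), c(1, 3)))
    s <- s + sum(A / 3 * ((v[tri[, q[1]]] + v[tri[, q[2]]]) / 2)^2)
  sqrt(s)
}

mms_errors <- function(sol) {
  ue <- sol$mm$u(sol$mesh$coords[, 1], sol$mesh$coords[, 2])
  pe <- sol$mm$p(sol$mesh$coords[, 1], sol$mesh$coords[, 2])
  du <- sqrt(rowSums((sol$state$u - ue)^2))
  dp <- sol$state$p - pe
  c(u = l2_norm(sol$mesh, du), p = l2_norm(sol$mesh, dp))
}

# cached peristaltic simulation at the study conditions (shared by the
# conservation, Newton-behavior and regime tests)
peristaltic_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- peristaltic_spec()
      motion <- generate_peristaltic_motion(spec)
      mesh <- triangulate(wall_position(motion, 0), 0.004, motion$tags)
      sim <- run_simulation(mesh, blood_properties(),
                            flow_bc(inlet_type = "traction", beta = 0.2),
                            time_config(dt = 0.002,
                                        t_end = 2 / spec$frequency),
                            motion = motion, keep_every = 5L)
      cache <<- list(spec = spec, motion = motion, mesh = mesh, sim = sim)
    }
    cache
  }
})
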