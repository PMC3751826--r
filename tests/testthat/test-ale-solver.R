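# Stabilized ALE Navier-Stokes solver: residual consistency, fixed
# points, moving-mesh exactness, energy and backflow behavior.

test_that("residual vanishes for quiescent and uniform states", {
  m <- channel_mesh(1, 0.5, 6, 4)
  props <- blood_properties(1, 0.01)
  st0 <- flow_state(m)
  r0 <- assemble_residual_jacobian(st0, m, props, flow_bc(),
                                   want_jacobian = FALSE)
  expect_equal(max(abs(r0$residual)), 0)
  # uniform flow annihilates every derivative term
  n <- nrow(m$coords)
  stU <- flow_state(m, u = cbind(rep(0.3, n), 0))
  rU <- assemble_residual_jacobian(stU, m, props, flow_bc(),
                                   want_jacobian = FALSE)
  expect_lt(max(abs(rU$residual)), 1e-14)
})

test_that("assembled residual of the manufactured interpolant refines to zero", {
  mm <- mms_fields()
  res_norm <- vapply(c(8, 16, 32), function(n) {
    m <- all_dirichlet_square(n)
    st <- flow_state(m, u = mm$u(m$coords[, 1], m$coords[, 2]),
                     p = mm$p(m$coords[, 1], m$coords[, 2]))
    bc <- flow_bc(body_force = mm$f)
    r <- assemble_residual_jacobian(st, m, blood_properties(1, 1), bc,
                                    want_jacobian = FALSE)
    free <- setdiff(seq_len(3 * nrow(m$coords)),
                    c(3 * (m$loop - 1) + 1, 3 * (m$loop - 1) + 2))
    sqrt(sum(r$residual[free]^2))
  }, numeric(1))
  # consistency: the defect shrinks under refinement at a definite rate
  expect_lt(res_norm[2], res_norm[1] / 1.8)
  expect_lt(res_norm[3], res_norm[2] / 1.8)
})

test_that("tangent matches a finite-difference probe of the residual", {
  m <- channel_mesh(1, 1, 3, 3)
  n <- nrow(m$coords)
  set.seed(7)
  st <- flow_state(m, u = matrix(rnorm(2 * n, 0, 0.1), n, 2),
                   p = rnorm(n, 0, 0.1))
  props <- blood_properties(1, 0.05)
  bc <- flow_bc(beta = 0.2)
  out <- assemble_residual_jacobian(st, m, props, bc)
  dv <- matrix(rnorm(2 * n, 0, 1), n, 2)
  dp <- rnorm(n)
  eps <- 1e-6
  st2 <- st
  st2$u <- st$u + eps * dv
  st2$p <- st$p + eps * dp
  r2 <- assemble_residual_jacobian(st2, m, props, bc,
                                   want_jacobian = FALSE)$residual
  pert <- numeric(3 * n)
  pert[seq(1, 3 * n, by = 3)] <- dv[, 1]
  pert[seq(2, 3 * n, by = 3)] <- dv[, 2]
  pert[seq(3, 3 * n, by = 3)] <- dp
  fd <- (r2 - out$residual) / eps
  jac <- as.vector(out$jacobian %*% pert)
  # tau and backflow-switch derivatives are deliberately dropped, so ask
  # for agreement, not machine precision
  expect_lt(max(abs(fd - jac)) / max(abs(jac)), 0.05)
})

test_that("a steady channel state is a fixed point of the time stepper", {
  H <- 0.01; L <- 0.04; U <- 0.1
  m <- channel_mesh(L, H, 12, 10)
  props <- blood_properties()
  pois <- poiseuille_solution(H, U, props$viscosity)
  bc <- flow_bc(inlet = function(xy, t) cbind(pois$profile(xy[, 2]), 0))
  st <- steady_solve(m, props, bc, tol = 1e-12)
  cfg <- time_config(dt = 0.002, t_end = 1)
  st1 <- advance_step(st, m, props, bc, cfg)
  expect_lt(max(abs(st1$u - st$u)) / max(abs(st$u)), 1e-3)
})

test_that("impulsively started channel flow approaches steady Poiseuille", {
  H <- 0.01; L <- 0.04; U <- 0.1
  m <- channel_mesh(L, H, 12, 30)
  props <- blood_properties()
  pois <- poiseuille_solution(H, U, props$viscosity)
  bc <- flow_bc(inlet = function(xy, t) cbind(pois$profile(xy[, 2]), 0))
  # t_end = 20 ms >> rho H^2 / mu = 1.5 ms
  sim <- run_simulation(m, props, bc, time_config(dt = 0.002, t_end = 0.02))
  stf <- sim$states[[length(sim$states)]]
  uc <- interp_state(stf, m, cbind(L / 2, H / 2))$ux
  expect_lt(abs(uc / pois$centerline - 1), 0.01)
  expect_true(all(sim$log$converged))
})

test_that("uniformly translating closed box preserves the free stream", {
  # rigid translation: wall data and mesh motion agree with u = V
  V <- c(0.4, -0.2)
  base <- rbind(cbind(seq(0, 1, length.out = 8), 0),
                cbind(1, seq(0.25, 0.75, length.out = 3)),
                cbind(seq(1, 0, length.out = 8), 1),
                cbind(0, seq(0.75, 0.25, length.out = 3)))
  keep <- !duplicated(round(base, 9))
  base <- base[keep, ]
  tf <- seq(0, 0.2, by = 0.02)
  frames <- lapply(tf, function(t) sweep(base, 2, V * t, "+"))
  motion <- interpolate_motion(frames, tf, target_rate = 100,
                               tags = rep("wall", nrow(base)))
  mesh <- triangulate(base, 0.25, rep("wall", nrow(base)))
  props <- blood_properties(1, 0.02)
  bc <- flow_bc(pin_pressure = list(node = 1L, value = 0))
  n <- nrow(mesh$coords)
  init <- flow_state(mesh, time = 0, u = matrix(V, n, 2, byrow = TRUE))
  sim <- run_simulation(mesh, props, bc,
                        time_config(dt = 0.01, t_end = 0.1, max_newton = 8),
                        motion = motion, init = init)
  stf <- sim$states[[length(sim$states)]]
  expect_lt(max(abs(sweep(stf$u, 2, V))) / max(abs(V)), 1e-6)
})

test_that("coupled stepping with static walls matches the rigid-mesh path", {
  H <- 0.01; L <- 0.03
  m <- channel_mesh(L, H, 8, 6)
  # static wall-motion field covering the loop
  base <- m$coords[m$loop, ]
  tf <- seq(0, 0.1, by = 0.01)
  motion <- interpolate_motion(rep(list(base), length(tf)), tf,
                               target_rate = 100,
                               tags = m$loop_tags)
  props <- blood_properties()
  bc <- flow_bc(inlet_type = "traction", beta = 0.2)
  cfg <- time_config(dt = 0.002, t_end = 0.01)
  n <- nrow(m$coords)
  set.seed(11)
  init <- flow_state(m, u = matrix(rnorm(2 * n, 0, 0.01), n, 2))
  s_rigid <- advance_step(init, m, props, bc, cfg)
  s_coupled <- solve_coupled_step(init, m, props, bc, cfg, motion = motion)
  expect_equal(s_coupled$u, s_rigid$u, tolerance = 1e-12)
  expect_equal(s_coupled$coords, m$coords)
})

test_that("kinetic energy decays in a closed cavity with no inflow", {
  m <- channel_mesh(1, 1, 10, 10)
  n <- nrow(m$coords)
  props <- blood_properties(1, 0.05)
  st0 <- flow_state(m, u = 2 * cbind(-(m$coords[, 2] - 0.5),
                                     m$coords[, 1] - 0.5))
  bc <- flow_bc(inlet = function(xy, t) matrix(0, nrow(xy), 2), beta = 0.2)
  sim <- run_simulation(m, props, bc,
                        time_config(dt = 0.01, t_end = 0.2, max_newton = 6),
                        init = st0)
  ke <- vapply(sim$states, kinetic_energy, numeric(1), mesh = m)
  expect_true(all(diff(ke) <= 1e-10 * ke[1]))
  expect_lt(ke[length(ke)], ke[1])
})

test_that("backflow stabilization keeps a reversed outlet bounded where beta = 0 blows up", {
  m <- channel_mesh(2, 1, 20, 10)
  props <- blood_properties(1, 0.002)     # inertial regime, Re ~ 500
  suck <- function(xy, t) cbind(-6 * xy[, 2] * (1 - xy[, 2]) *
                                  pmin(t / 0.1, 1), 0)
  run_beta <- function(b) {
    sim <- run_simulation(m, props, flow_bc(inlet = suck, beta = b),
                          time_config(dt = 0.02, t_end = 1.2),
                          on_fail = "warn")
    max(vapply(sim$states, kinetic_energy, numeric(1), mesh = m))
  }
  ke0 <- suppressWarnings(run_beta(0))
  ke2 <- suppressWarnings(run_beta(0.2))
  expect_lt(ke2, 3)          # bounded: driving velocity is O(1)
  expect_gt(ke0, 10 * ke2)   # unstabilized run diverges on the same fixture
})

test_that("run_simulation reports convergence per step and honors on_fail", {
  m <- channel_mesh(0.03, 0.01, 6, 4)
  props <- blood_properties()
  bc <- flow_bc(inlet = function(xy, t)
    cbind(6 * 0.1 * xy[, 2] * (0.01 - xy[, 2]) / 0.01^2, 0))
  sim <- run_simulation(m, props, bc, time_config(dt = 0.002, t_end = 0.01))
  expect_equal(nrow(sim$log), 5L)
  expect_true(all(sim$log$converged))
  expect_true(all(sim$log$newton_iters <= 5))
  g <- glance(sim)
  expect_s3_class(g, "tbl_df")
  expect_true(g$all_converged)
  td <- tidy(sim)
  expect_true(all(c("kinetic_energy", "area", "flux_open") %in% names(td)))
})
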