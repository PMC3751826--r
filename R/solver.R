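# Stabilized equal-order ALE Navier-Stokes time stepping.
#
# Space: P1/P1 triangles with SUPG/PSPG (+ grad-div) stabilization and the
# ALE convective velocity (u - umesh).  Time: second-order generalized-alpha
# for first-order systems with spectral radius rho_inf; the solver unknowns
# are the end-of-step accelerations and pressures.  Linearization: modified
# Newton-Raphson (tangent frozen after the first iteration of each step;
# full Newton available).  Outlets carry zero traction plus backflow
# stabilization beta.  Linear solves use a sparse LU factorization, which at
# the desk scales targeted here (<~10^4 dofs) is faster and more robust than
# an iterative Schur-complement pass.

#' Time-integration configuration
#'
#' Defaults mirror the printed simulation protocol: time step 2 ms,
#' 5 s of physical time, Newton stopped when the residual norm drops below
#' 0.001 (relative to the step's initial residual) or after 5 iterations.
#'
#' @param dt time step (s)
#' @param t_end end time (s)
#' @param rho_inf generalized-alpha spectral radius in `[0, 1]`
#' @param newton_tol Newton residual tolerance
#' @param newton_tol_type `"relative"` (to the step's first residual norm)
#'   or `"absolute"`
#' @param max_newton maximum Newton iterations per step
#' @param max_coupling maximum fluid/mesh coupling sweeps per step
#' @param newton `"modified"` (tangent frozen after iteration 1) or `"full"`
#' @param ci inverse-estimate constant in tau (viscous term), default 36
#' @param lsic include grad-div (LSIC) stabilization, default TRUE
#' @param tau_dt time scale used in the transient term of tau; default
#'   `NULL` (the step size).  Fixing it decouples the stabilization
#'   operator from `dt`, as required in temporal-refinement studies.
#' @return an object of class `time_config`
#' @export
time_config <- function(dt = 0.002, t_end = 5, rho_inf = 0.5,
                        newton_tol = 1e-3, newton_tol_type = "relative",
                        max_newton = 5L, max_coupling = 3L,
                        newton = c("modified", "full"),
                        ci = 36, lsic = TRUE, tau_dt = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (rho_inf < 0 || rho_inf > 1) stop("rho_inf must be in [0, 1]")
  newton <- match.arg(newton)
  newton_tol_type <- match.arg(newton_tol_type, c("relative", "absolute"))
  structure(list(dt = dt, t_end = t_end, rho_inf = rho_inf,
                 newton_tol = newton_tol, newton_tol_type = newton_tol_type,
                 max_newton = as.integer(max_newton),
                 max_coupling = as.integer(max_coupling),
                 newton = newton, ci = ci, lsic = lsic, tau_dt = tau_dt),
            class = "time_config")
}

#' Boundary conditions for the flow problem
#'
#' The boundary is partitioned by the mesh tags: wall and (by default)
#' inlet spans carry Dirichlet velocity, outlet spans carry the traction
#' condition `T.n = h` (default h = 0) plus backflow stabilization.
#'
#' @param inlet `NULL` (inlet velocity taken from the wall-motion field, or
#'   zero on a rigid mesh) or a function `(xy, t)` returning an n x 2
#'   velocity matrix for the n inlet-node coordinates `xy`
#' @param inlet_type `"dirichlet"` or `"traction"` (open inlet treated like
#'   an outlet)
#' @param traction `NULL` for h = 0 or a function `(xy, t)` returning n x 2
#'   tractions on outlet-edge quadrature points
#' @param beta backflow stabilization coefficient (default 0.2)
#' @param body_force `NULL` or a function `(x, y, t)` returning an n x 2
#'   matrix (dyn/cm^3); used by manufactured-solution verification
#' @param pin_pressure `NULL`, or a list `(node, value)` fixing one nodal
#'   pressure when no traction boundary sets the pressure level
#' @return an object of class `flow_bc`
#' @export
flow_bc <- function(inlet = NULL, inlet_type = c("dirichlet", "traction"),
                    traction = NULL, beta = 0.2, body_force = NULL,
                    pin_pressure = NULL) {
  inlet_type <- match.arg(inlet_type)
  structure(list(inlet = inlet, inlet_type = inlet_type,
                 traction = traction, beta = beta, body_force = body_force,
                 pin_pressure = pin_pressure),
            class = "flow_bc")
}

#' Construct a flow state
#' @param mesh a `mesh2d`
#' @param time state time (s)
#' @param u,udot N x 2 velocity and acceleration (zero default)
#' @param p length-N pressure (zero default)
#' @param coords current node coordinates (mesh reference default)
#' @param umesh N x 2 mesh velocity (zero default)
#' @return an object of class `flow_state`
#' @export
flow_state <- function(mesh, time = 0, u = NULL, udot = NULL, p = NULL,
                       coords = NULL, umesh = NULL) {
  n <- nrow(mesh$coords)
  z <- matrix(0, n, 2)
  structure(list(time = time,
                 u = if (is.null(u)) z else u,
                 udot = if (is.null(udot)) z else udot,
                 p = if (is.null(p)) numeric(n) else p,
                 coords = if (is.null(coords)) mesh$coords else coords,
                 umesh = if (is.null(umesh)) z else umesh),
            class = "flow_state")
}

# --- assembly ---------------------------------------------------------------

# body force at the kernel's element quadrature points (edge midpoints,
# in the order mid(1,2), mid(2,3), mid(1,3)), as an M x 6 matrix
body_force_quad <- function(bf, coords, tri, t) {
  m <- nrow(tri)
  if (is.null(bf)) return(matrix(0, m, 6))
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  out <- matrix(0, m, 6)
  qs <- list((p1 + p2) / 2, (p2 + p3) / 2, (p1 + p3) / 2)
  for (q in 1:3) {
    f <- bf(qs[[q]][, 1], qs[[q]][, 2], t)
    out[, 2 * q - 1] <- f[, 1]
    out[, 2 * q] <- f[, 2]
  }
  out
}

# edges of the mesh carrying traction/backflow terms
open_edges <- function(mesh, bc) {
  tags <- "outlet"
  if (!is.null(bc) && bc$inlet_type == "traction") tags <- c(tags, "inlet")
  keep <- mesh$edge_tags %in% tags
  mesh$edges[keep, , drop = FALSE]
}

# backflow + prescribed-traction residual (and optional tangent triplets)
# on the open-boundary edges; loop order is CCW so the outward normal of
# edge (p1 -> p2) is (dy, -dx)/L
edge_terms <- function(mesh, coords, u, bc, rho, t, fac_u, want_jac) {
  ed <- open_edges(mesh, bc)
  n <- nrow(coords)
  res <- numeric(3 * n)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  if (nrow(ed) == 0)
    return(list(res = res, i = ti, j = tj, x = tx))
  gp <- c(-1, 1) / sqrt(3)
  for (k in seq_len(nrow(ed))) {
    n1 <- ed[k, 1]; n2 <- ed[k, 2]
    p1 <- coords[n1, ]; p2 <- coords[n2, ]
    dx <- p2 - p1
    L <- sqrt(sum(dx^2))
    nrm <- c(dx[2], -dx[1]) / L
    for (g in gp) {
      N1 <- (1 - g) / 2; N2 <- (1 + g) / 2
      w <- L / 2
      uq <- N1 * u[n1, ] + N2 * u[n2, ]
      un <- sum(uq * nrm)
      unm <- min(un, 0)
      coef <- -bc$beta * rho / 2 * unm
      xq <- N1 * p1 + N2 * p2
      hq <- if (is.null(bc$traction)) c(0, 0) else
        as.numeric(bc$traction(matrix(xq, 1), t))
      for (d in 1:2) {
        res[3 * (n1 - 1) + d] <- res[3 * (n1 - 1) + d] +
          w * N1 * (coef * uq[d] - hq[d])
        res[3 * (n2 - 1) + d] <- res[3 * (n2 - 1) + d] +
          w * N2 * (coef * uq[d] - hq[d])
      }
      if (want_jac && coef != 0) {
        for (a in list(c(n1, N1), c(n2, N2))) for (b in list(c(n1, N1), c(n2, N2)))
          for (d in 1:2) {
            ti <- c(ti, 3L * (a[[1]] - 1L) + d)
            tj <- c(tj, 3L * (b[[1]] - 1L) + d)
            tx <- c(tx, w * a[[2]] * b[[2]] * coef * fac_u)
          }
      }
    }
  }
  list(res = res, i = ti, j = tj, x = tx)
}

#' Assemble the stabilized ALE residual (and tangent) at a state
#'
#' Weak-form residual of the incompressible ALE Navier-Stokes equations
#' with SUPG/PSPG (+ grad-div) stabilization, convective velocity
#' `u - umesh`, outlet backflow stabilization, and optional body force.
#' Dirichlet conditions are not applied; this is the raw assembled system,
#' used directly by manufactured-solution verification.
#'
#' @param state a [flow_state()] (its `coords`/`umesh` define the
#'   configuration)
#' @param mesh a `mesh2d`
#' @param props [blood_properties()]
#' @param bc [flow_bc()]
#' @param dt time-step used in the stabilization parameter; `0` for the
#'   steady form
#' @param want_jacobian also return the sparse tangent (w.r.t. `u` and `p`)
#' @param cfg a [time_config()] supplying stabilization constants
#' @return list with `residual` (length 3N, dofs ux, uy, p per node) and
#'   optionally `jacobian` (sparse 3N x 3N)
#' @export
assemble_residual_jacobian <- function(state, mesh, props, bc = flow_bc(),
                                       dt = 0, want_jacobian = TRUE,
                                       cfg = time_config()) {
  fq <- body_force_quad(bc$body_force, state$coords, mesh$tri, state$time)
  out <- .cpp_ns_assemble(state$coords, mesh$tri, state$u, state$udot,
                          state$p, state$umesh, fq,
                          props$density, props$viscosity, dt,
                          0, 1, cfg$ci, cfg$lsic, want_jacobian)
  et <- edge_terms(mesh, state$coords, state$u, bc, props$density,
                   state$time, 1, want_jacobian)
  res <- out$res + et$res
  if (!want_jacobian) return(list(residual = res))
  n3 <- 3L * nrow(state$coords)
  J <- Matrix::sparseMatrix(i = c(out$i, et$i), j = c(out$j, et$j),
                            x = c(out$x, et$x), dims = c(n3, n3))
  list(residual = res, jacobian = J)
}

# velocity-Dirichlet node set and values at time t_new
dirichlet_values <- function(mesh, bc, motion, t_new, coords_new) {
  n <- nrow(mesh$coords)
  g <- matrix(NA_real_, n, 2)
  if (!is.null(motion)) {
    if (motion$node_count != length(mesh$loop))
      stop("wall-motion field and mesh boundary loop sizes differ")
    g[mesh$loop, ] <- wall_velocity(motion, t_new)
  } else {
    g[mesh$boundary$wall, ] <- 0
    if (bc$inlet_type == "dirichlet") g[mesh$boundary$inlet, ] <- 0
  }
  if (bc$inlet_type == "traction") {
    g[mesh$boundary$inlet, ] <- NA_real_
  } else if (!is.null(bc$inlet)) {
    idx <- mesh$boundary$inlet
    g[idx, ] <- bc$inlet(coords_new[idx, , drop = FALSE], t_new)
  }
  g[mesh$boundary$outlet, ] <- NA_real_
  nodes <- which(!is.na(g[, 1]))
  list(nodes = nodes, values = g[nodes, , drop = FALSE])
}

new_step_log <- function() {
  tibble::tibble(time = numeric(0), newton_iters = integer(0),
                 residual = numeric(0), residual0 = numeric(0),
                 converged = logical(0), coupling_iters = integer(0))
}

#' Advance one generalized-alpha time step on a (possibly moving) mesh
#'
#' @param state state at time t_n (a [flow_state()])
#' @param mesh reference `mesh2d`
#' @param props [blood_properties()]
#' @param bc [flow_bc()]
#' @param cfg [time_config()]
#' @param motion optional `wall_motion_field` driving the boundary
#' @param coords_new,umesh_new node coordinates at t_{n+1} and in-step mesh
#'   velocity; default: rigid mesh
#' @return the state at t_{n+1}, with attribute `"log"` (one-row tibble:
#'   Newton iterations, final and initial residual norms, convergence flag)
#' @export
advance_step <- function(state, mesh, props, bc = flow_bc(),
                         cfg = time_config(), motion = NULL,
                         coords_new = NULL, umesh_new = NULL) {
  dt <- cfg$dt
  t_new <- state$time + dt
  n <- nrow(mesh$coords)
  if (is.null(coords_new)) coords_new <- state$coords
  if (is.null(umesh_new)) umesh_new <- (coords_new - state$coords) / dt

  rho_inf <- cfg$rho_inf
  am <- 0.5 * (3 - rho_inf) / (1 + rho_inf)
  af <- 1 / (1 + rho_inf)
  gamma <- 0.5 + am - af
  fac_a <- am
  fac_u <- af * gamma * dt

  coords_af <- state$coords + af * (coords_new - state$coords)
  t_af <- state$time + af * dt

  dt_tau <- if (is.null(cfg$tau_dt)) dt else cfg$tau_dt
  dir <- dirichlet_values(mesh, bc, motion, t_new, coords_new)
  # acceleration consistent with the prescribed end-of-step velocity
  a <- (gamma - 1) / gamma * state$udot          # same-velocity predictor
  if (length(dir$nodes) > 0)
    a[dir$nodes, ] <- ((dir$values - state$u[dir$nodes, , drop = FALSE]) / dt -
                         (1 - gamma) * state$udot[dir$nodes, , drop = FALSE]) /
      gamma
  p <- state$p

  fixed_dofs <- c(3L * (dir$nodes - 1L) + 1L, 3L * (dir$nodes - 1L) + 2L)
  if (!is.null(bc$pin_pressure))
    fixed_dofs <- c(fixed_dofs, 3L * (bc$pin_pressure$node - 1L) + 3L)
  free <- setdiff(seq_len(3L * n), fixed_dofs)
  if (!is.null(bc$pin_pressure)) p[bc$pin_pressure$node] <- bc$pin_pressure$value

  fact <- NULL
  norm0 <- NA_real_
  resn <- NA_real_
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_newton + 1L)) {
    u_new <- state$u + dt * ((1 - gamma) * state$udot + gamma * a)
    u_af <- state$u + af * (u_new - state$u)
    a_am <- state$udot + am * (a - state$udot)
    want_jac <- is.null(fact) || cfg$newton == "full"
    fq <- body_force_quad(bc$body_force, coords_af, mesh$tri, t_af)
    out <- .cpp_ns_assemble(coords_af, mesh$tri, u_af, a_am, p, umesh_new,
                            fq, props$density, props$viscosity, dt_tau,
                            fac_a, fac_u, cfg$ci, cfg$lsic, want_jac)
    et <- edge_terms(mesh, coords_af, u_af, bc, props$density, t_af,
                     fac_u, want_jac)
    res <- out$res + et$res
    resn <- sqrt(sum(res[free]^2))
    if (it == 1L) norm0 <- resn
    tol_ok <- if (cfg$newton_tol_type == "relative")
      resn < cfg$newton_tol * max(norm0, 1e-300) || resn < 1e-12
    else resn < cfg$newton_tol
    if (tol_ok) { converged <- TRUE; break }
    if (it > cfg$max_newton) break
    if (want_jac) {
      n3 <- 3L * n
      J <- Matrix::sparseMatrix(i = c(out$i, et$i), j = c(out$j, et$j),
                                x = c(out$x, et$x), dims = c(n3, n3))
      Jff <- J[free, free, drop = FALSE]
      fact <- Matrix::lu(Jff)
    }
    dv <- numeric(3L * n)
    dv[free] <- -as.vector(Matrix::solve(fact, res[free]))
    a[, 1] <- a[, 1] + dv[seq(1, 3 * n, by = 3)]
    a[, 2] <- a[, 2] + dv[seq(2, 3 * n, by = 3)]
    p <- p + dv[seq(3, 3 * n, by = 3)]
    iters <- it
  }
  u_new <- state$u + dt * ((1 - gamma) * state$udot + gamma * a)
  out <- flow_state(mesh, time = t_new, u = u_new, udot = a, p = p,
                    coords = coords_new, umesh = umesh_new)
  attr(out, "log") <- tibble::tibble(
    time = t_new, newton_iters = iters, residual = resn,
    residual0 = norm0, converged = converged, coupling_iters = 1L)
  out
}

#' Advance one step with quasi-direct fluid/mesh coupling
#'
#' Solves the mesh-motion elasticity problem for the configuration at
#' t_{n+1} from the prescribed wall positions, then the fluid step, in an
#' iterative sweep until both subproblems are converged.  With motion
#' prescribed (not fluid-driven) the mesh subproblem converges in the
#' first sweep; the loop structure reports coupling iterations regardless.
#'
#' @inheritParams advance_step
#' @param mesh_op cached [mesh_motion_operator()]
#' @return state at t_{n+1} (attribute `"log"` as in [advance_step()])
#' @export
solve_coupled_step <- function(state, mesh, props, bc = flow_bc(),
                               cfg = time_config(), motion = NULL,
                               mesh_op = NULL) {
  if (is.null(motion))
    return(advance_step(state, mesh, props, bc, cfg))
  if (is.null(mesh_op)) mesh_op <- mesh_motion_operator(mesh)
  t_new <- state$time + cfg$dt
  new_state <- NULL
  coupling <- 0L
  for (sweep in seq_len(cfg$max_coupling)) {
    coupling <- sweep
    bd <- wall_position(motion, t_new) - mesh$coords[mesh$loop, , drop = FALSE]
    disp <- solve_mesh_motion(mesh, bd, op = mesh_op)
    coords_new <- mesh$coords + disp
    umesh_new <- (coords_new - state$coords) / cfg$dt
    new_state <- advance_step(state, mesh, props, bc, cfg, motion = motion,
                              coords_new = coords_new, umesh_new = umesh_new)
    fluid_conv <- attr(new_state, "log")$converged
    # walls are prescribed, not fluid-driven, so the mesh Dirichlet data
    # cannot change between sweeps; re-evaluate it to confirm stationarity
    bd2 <- wall_position(motion, t_new) - mesh$coords[mesh$loop, , drop = FALSE]
    mesh_conv <- max(abs(bd2 - bd)) < 1e-12
    if (fluid_conv && mesh_conv) break
  }
  lg <- attr(new_state, "log")
  lg$coupling_iters <- coupling
  attr(new_state, "log") <- lg
  new_state
}

#' Run a full moving-domain simulation
#'
#' Marches the coupled mesh-motion + fluid problem from the initial time to
#' `cfg$t_end` in steps of `cfg$dt`, starting from fluid at rest unless an
#' initial state is given.
#'
#' @param mesh reference `mesh2d` (the most-contracted configuration when a
#'   motion field is supplied)
#' @param props [blood_properties()]
#' @param bc [flow_bc()]
#' @param cfg [time_config()]
#' @param motion optional `wall_motion_field`; `NULL` for a rigid domain
#' @param init optional initial [flow_state()]
#' @param t_start start time; defaults to the motion field's first sample
#'   (or 0 on a rigid mesh)
#' @param keep_every store every k-th state (all by default)
#' @param on_fail `"error"` (default) or `"warn"` on a non-converged step
#' @return an object of class `cardio_sim`: list of states, per-step
#'   convergence log (tibble), and the inputs
#' @export
run_simulation <- function(mesh, props, bc = flow_bc(), cfg = time_config(),
                           motion = NULL, init = NULL, t_start = NULL,
                           keep_every = 1L, on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  if (is.null(t_start))
    t_start <- if (is.null(motion)) 0 else motion$times[1]
  mesh_op <- if (is.null(motion)) NULL else mesh_motion_operator(mesh)
  state <- init
  if (is.null(state)) {
    coords0 <- mesh$coords
    if (!is.null(motion)) {
      bd0 <- wall_position(motion, t_start) -
        mesh$coords[mesh$loop, , drop = FALSE]
      coords0 <- mesh$coords + solve_mesh_motion(mesh, bd0, op = mesh_op)
    }
    state <- flow_state(mesh, time = t_start, coords = coords0)
  }
  nsteps <- max(1L, round((cfg$t_end - state$time) / cfg$dt))
  if (!is.null(motion)) {
    span_steps <- floor((motion$times[length(motion$times)] - state$time) /
                          cfg$dt + 1e-9)
    nsteps <- min(nsteps, span_steps)
  }
  states <- vector("list", nsteps %/% keep_every + 1L)
  states[[1]] <- state
  nkept <- 1L
  log <- new_step_log()
  for (k in seq_len(nsteps)) {
    state <- if (is.null(motion))
      advance_step(state, mesh, props, bc, cfg)
    else
      solve_coupled_step(state, mesh, props, bc, cfg, motion, mesh_op)
    lg <- attr(state, "log")
    log <- rbind(log, lg)
    if (!lg$converged && on_fail == "error")
      stop(sprintf(
        "step to t = %g failed to converge (residual %g after %d iterations)",
        lg$time, lg$residual, lg$newton_iters))
    if (k %% keep_every == 0L || k == nsteps) {
      nkept <- nkept + 1L
      states[[nkept]] <- state
    }
  }
  structure(list(states = states[seq_len(nkept)], mesh = mesh,
                 props = props, bc = bc, cfg = cfg, motion = motion,
                 log = log),
            class = "cardio_sim")
}

#' @export
print.cardio_sim <- function(x, ...) {
  cat(sprintf(
    "cardio_sim: %d stored states, t in [%g, %g] s, %d/%d steps converged\n",
    length(x$states), x$states[[1]]$time,
    x$states[[length(x$states)]]$time,
    sum(x$log$converged), nrow(x$log)))
  invisible(x)
}

# --- diagnostics ------------------------------------------------------------

#' Kinetic energy of a state
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @return kinetic energy per unit depth (erg/cm)
#' @export
kinetic_energy <- function(state, mesh) {
  A <- triangle_areas(mesh, state$coords)
  tri <- mesh$tri
  u <- state$u
  ke <- 0
  # 3-point edge-midpoint rule, exact for the quadratic |u|^2
  for (q in list(c(1, 2), c(2, 3), c(1, 3))) {
    uq1 <- (u[tri[, q[1]], 1] + u[tri[, q[2]], 1]) / 2
    uq2 <- (u[tri[, q[1]], 2] + u[tri[, q[2]], 2]) / 2
    ke <- ke + sum(A / 3 * (uq1^2 + uq2^2))
  }
  0.5 * ke
}

#' Volumetric flux through tagged boundary edges
#'
#' Trapezoidal line integral of `u . n` over the edges carrying the given
#' tags, on the state's current configuration; outward normal per the CCW
#' boundary loop.
#'
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param tags edge tags to include (default the open boundary)
#' @return flux per unit depth (cm^2/s); positive out of the domain
#' @export
boundary_flux <- function(state, mesh, tags = c("inlet", "outlet")) {
  keep <- mesh$edge_tags %in% tags
  ed <- mesh$edges[keep, , drop = FALSE]
  if (nrow(ed) == 0) return(0)
  p1 <- state$coords[ed[, 1], , drop = FALSE]
  p2 <- state$coords[ed[, 2], , drop = FALSE]
  dx <- p2 - p1
  L <- sqrt(rowSums(dx^2))
  nx <- dx[, 2] / L; ny <- -dx[, 1] / L
  un1 <- state$u[ed[, 1], 1] * nx + state$u[ed[, 1], 2] * ny
  un2 <- state$u[ed[, 2], 1] * nx + state$u[ed[, 2], 2] * ny
  sum(L * (un1 + un2) / 2)
}

#' Domain area of a state
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @return area (cm^2)
#' @export
domain_area <- function(state, mesh) {
  pts <- state$coords[mesh$loop, , drop = FALSE]
  abs(polygon_area(pts))
}

#' Per-step moving-domain mass balance of a simulation
#'
#' Compares the open-boundary outflux with the domain shrink rate
#' `-dA/dt` (centered finite differences of the shoelace area): for an
#' incompressible flow on a moving domain these must agree step by step.
#'
#' @param sim a `cardio_sim`
#' @return tibble with `time`, `flux_open` (cm^2/s), `dAdt`, and
#'   `imbalance = flux_open + dAdt` alongside the normalizing `max |dA/dt|`
#' @export
mass_balance <- function(sim) {
  times <- vapply(sim$states, function(s) s$time, numeric(1))
  areas <- vapply(sim$states, domain_area, numeric(1), mesh = sim$mesh)
  flux <- vapply(sim$states, boundary_flux, numeric(1), mesh = sim$mesh)
  ns <- length(times)
  dAdt <- rep(NA_real_, ns)
  if (ns >= 3) {
    dAdt[2:(ns - 1)] <- (areas[3:ns] - areas[1:(ns - 2)]) /
      (times[3:ns] - times[1:(ns - 2)])
  }
  tibble::tibble(time = times, area = areas, flux_open = flux, dAdt = dAdt,
                 imbalance = flux + dAdt)
}

# --- steady solves ----------------------------------------------------------

#' Solve the steady stabilized Navier-Stokes problem
#'
#' Full Newton on the steady form (no transient term; `dt = 0` in tau),
#' with the same boundary handling as the transient solver.  Used by the
#' manufactured-solution convergence studies and steady benchmarks.
#'
#' @param mesh a `mesh2d`
#' @param props [blood_properties()]
#' @param bc [flow_bc()]
#' @param u0,p0 optional initial guess
#' @param tol relative residual tolerance
#' @param max_iter Newton iteration cap
#' @param cfg [time_config()] supplying stabilization constants
#' @return a converged [flow_state()] (attribute `"log"`)
#' @export
steady_solve <- function(mesh, props, bc = flow_bc(), u0 = NULL, p0 = NULL,
                         tol = 1e-10, max_iter = 25L, cfg = time_config()) {
  n <- nrow(mesh$coords)
  u <- if (is.null(u0)) matrix(0, n, 2) else u0
  p <- if (is.null(p0)) numeric(n) else p0
  dir <- dirichlet_values(mesh, bc, NULL, 0, mesh$coords)
  if (length(dir$nodes) > 0) u[dir$nodes, ] <- dir$values
  fixed_dofs <- c(3L * (dir$nodes - 1L) + 1L, 3L * (dir$nodes - 1L) + 2L)
  if (!is.null(bc$pin_pressure)) {
    fixed_dofs <- c(fixed_dofs, 3L * (bc$pin_pressure$node - 1L) + 3L)
    p[bc$pin_pressure$node] <- bc$pin_pressure$value
  }
  free <- setdiff(seq_len(3L * n), fixed_dofs)
  zero <- matrix(0, n, 2)
  norm0 <- NA_real_
  converged <- FALSE
  iters <- 0L
  resn <- NA_real_
  for (it in seq_len(max_iter + 1L)) {
    fqm <- body_force_quad(bc$body_force, mesh$coords, mesh$tri, 0)
    out <- .cpp_ns_assemble(mesh$coords, mesh$tri, u, zero, p, zero, fqm,
                            props$density, props$viscosity, 0,
                            0, 1, cfg$ci, cfg$lsic, TRUE)
    et <- edge_terms(mesh, mesh$coords, u, bc, props$density, 0, 1, TRUE)
    res <- out$res + et$res
    resn <- sqrt(sum(res[free]^2))
    if (it == 1L) norm0 <- max(resn, 1e-300)
    if (resn < tol * norm0 || resn < 1e-13) { converged <- TRUE; break }
    if (it > max_iter) break
    n3 <- 3L * n
    J <- Matrix::sparseMatrix(i = c(out$i, et$i), j = c(out$j, et$j),
                              x = c(out$x, et$x), dims = c(n3, n3))
    dv <- numeric(n3)
    dv[free] <- -as.vector(Matrix::solve(J[free, free, drop = FALSE],
                                         res[free]))
    u[, 1] <- u[, 1] + dv[seq(1, n3, by = 3)]
    u[, 2] <- u[, 2] + dv[seq(2, n3, by = 3)]
    p <- p + dv[seq(3, n3, by = 3)]
    iters <- it
  }
  st <- flow_state(mesh, time = 0, u = u, p = p)
  attr(st, "log") <- tibble::tibble(time = 0, newton_iters = iters,
                                    residual = resn, residual0 = norm0,
                                    converged = converged,
                                    coupling_iters = 0L)
  st
}
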