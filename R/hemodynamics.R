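# Biomechanical read-outs from flow states: wall shear stress, chamber
# pressure gradients, stream functions, ellipsoid ventricular volume and
# ejection fraction, Reynolds and Womersley numbers.  CGS units: stresses
# in dyn/cm^2, pressures in dyn/cm^2 (barye).

node_patch_gradients <- function(state, mesh) {
  # element-constant velocity gradients, area-weighted onto nodes
  tri <- mesh$tri
  coords <- state$coords
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  A <- det / 2
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  c_ <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  u1 <- matrix(state$u[tri, 1], ncol = 3)
  u2 <- matrix(state$u[tri, 2], ncol = 3)
  g11 <- rowSums(b * u1); g12 <- rowSums(c_ * u1)   # du_x/dx, du_x/dy
  g21 <- rowSums(b * u2); g22 <- rowSums(c_ * u2)   # du_y/dx, du_y/dy
  n <- nrow(coords)
  acc <- function(v) {
    out <- numeric(n)
    for (k in 1:3) {
      w <- tapply(A * v, tri[, k], sum)
      idx <- as.integer(names(w))
      out[idx] <- out[idx] + w
    }
    out
  }
  wsum <- acc(rep(1, nrow(tri)))
  list(g11 = acc(g11) / wsum, g12 = acc(g12) / wsum,
       g21 = acc(g21) / wsum, g22 = acc(g22) / wsum,
       node_weight = wsum)
}

#' Wall shear stress at the wall nodes of a state
#'
#' The viscous traction's tangential component,
#' tau = t . mu (grad u + grad u^T) . n, with t the local wall tangent
#' (CCW boundary loop direction) and n the into-fluid normal, and the
#' velocity gradient recovered by area-weighted averaging of the
#' element-constant P1 gradients over each wall node's element patch.
#' For a straight wall this reduces to mu du/dy with y measured from the
#' wall into the fluid: positive tau means the fluid drags the wall along
#' the local tangent (a plane Couette flow gives +mu*gamma on both walls).
#'
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param mu dynamic viscosity (poise), or a [blood_properties()]
#' @return tibble: `node`, `x`, `y`, `tau` (dyn/cm^2) for every wall node
#' @export
compute_wss <- function(state, mesh, mu) {
  if (inherits(mu, "fluid_properties")) mu <- mu$viscosity
  g <- node_patch_gradients(state, mesh)
  loop <- mesh$loop
  nl <- length(loop)
  prev <- c(nl, seq_len(nl - 1L)); nxt <- c(seq_len(nl - 1L) + 1L, 1L)
  pts <- state$coords[loop, , drop = FALSE]
  tanv <- pts[nxt, , drop = FALSE] - pts[prev, , drop = FALSE]
  tl <- sqrt(rowSums(tanv^2))
  tanv <- tanv / tl
  nrm <- cbind(-tanv[, 2], tanv[, 1])          # into the fluid (CCW loop)
  iswall <- mesh$loop_tags == "wall"
  nodes <- loop[iswall]
  tau <- numeric(sum(iswall))
  bad <- g$node_weight[nodes] <= 0 | !is.finite(g$node_weight[nodes])
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    i <- which(loop == nd)
    S11 <- 2 * g$g11[nd]; S22 <- 2 * g$g22[nd]
    S12 <- g$g12[nd] + g$g21[nd]
    t_ <- tanv[i, ]; n_ <- nrm[i, ]
    tau[k] <- mu * (t_[1] * (S11 * n_[1] + S12 * n_[2]) +
                      t_[2] * (S12 * n_[1] + S22 * n_[2]))
  }
  if (any(bad)) {
    warning(sprintf("%d wall node(s) with degenerate element patch: tau = NaN",
                    sum(bad)))
    tau[bad] <- NaN
  }
  tibble::tibble(node = nodes, x = state$coords[nodes, 1],
                 y = state$coords[nodes, 2], tau = tau)
}

#' Mean of the k largest values in a region
#'
#' The averaging rule used for the near-canal read-outs: the region of
#' interest is cropped to a node mask and the highest `k` values (10 by
#' default) are averaged.  Regions smaller than `k` fall back to the mean
#' of all values with a warning.
#'
#' @param values numeric per-node values
#' @param region logical or integer mask selecting the region
#' @param k number of top values to average (default 10)
#' @return scalar mean of the k largest region values
#' @export
region_peak_average <- function(values, region = seq_along(values), k = 10) {
  v <- values[region]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty region")
  if (length(v) < k) {
    warning(sprintf("region has %d < k = %d nodes; averaging all", length(v), k))
    return(mean(v))
  }
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Locate the atrioventricular throat and its wall-node region
#'
#' Automates the manual near-canal crop: the throat is the wall node with
#' the smallest gap to the opposite wall (nearest wall node at least
#' `min_sep` loop positions away), and the region is every wall node within
#' `window` (cm) of the throat location.
#'
#' @param mesh a `mesh2d`
#' @param coords optional deformed coordinates (default reference)
#' @param window half-width of the region around the throat (cm)
#' @param min_sep minimum loop-index separation defining "opposite" wall
#' @param end_margin_frac wall nodes within this fraction of the domain
#'   extent from an inlet/outlet node are excluded from the throat search
#'   (the canal is interior by definition)
#' @return list: `throat_node`, `throat_width` (cm), `region` (wall node
#'   indices), `center` (throat midpoint)
#' @export
av_canal_region <- function(mesh, coords = NULL, window = 0.02,
                            min_sep = 5L, end_margin_frac = 0.12) {
  if (is.null(coords)) coords <- mesh$coords
  loop <- mesh$loop
  iswall <- mesh$loop_tags == "wall"
  wi <- which(iswall)
  open_idx <- which(!iswall)
  if (length(open_idx) > 0 && end_margin_frac > 0) {
    pts_all <- coords[loop, , drop = FALSE]
    extent <- max(apply(pts_all, 2, function(v) diff(range(v))))
    margin <- end_margin_frac * extent
    dmin <- vapply(wi, function(a)
      sqrt(min((pts_all[open_idx, 1] - pts_all[a, 1])^2 +
                 (pts_all[open_idx, 2] - pts_all[a, 2])^2)), numeric(1))
    if (any(dmin > margin)) wi <- wi[dmin > margin]
  }
  pts <- coords[loop, , drop = FALSE]
  best <- c(Inf, NA, NA)
  for (a in wi) {
    d2 <- (pts[wi, 1] - pts[a, 1])^2 + (pts[wi, 2] - pts[a, 2])^2
    sep <- pmin(abs(wi - a), length(loop) - abs(wi - a))
    d2[sep < min_sep] <- Inf
    j <- which.min(d2)
    if (d2[j] < best[1]) best <- c(d2[j], a, wi[j])
  }
  a <- best[2]; b <- best[3]
  center <- (pts[a, ] + pts[b, ]) / 2
  d <- sqrt((pts[wi, 1] - center[1])^2 + (pts[wi, 2] - center[2])^2)
  region <- loop[wi[d <= sqrt(best[1]) / 2 + window]]
  list(throat_node = loop[a], throat_width = sqrt(best[1]),
       region = region, center = center)
}

#' Inter-chamber pressure gradient
#'
#' Averages the pressure over the `k` nodes nearest each chamber center and
#' reports their difference, ventricle minus atrium.
#'
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param atrial_center,ventricular_center length-2 points inside the domain
#' @param k sample size per chamber (default 10)
#' @return scalar `dP = <p>_ventricle - <p>_atrium` (dyn/cm^2), with the
#'   node sets as attributes
#' @export
compute_pressure_gradient <- function(state, mesh, atrial_center,
                                      ventricular_center, k = 10) {
  poly <- state$coords[mesh$loop, , drop = FALSE]
  for (ctr in list(atrial_center, ventricular_center))
    if (!point_in_polygon(ctr[1], ctr[2], poly))
      stop(sprintf("geometry error: center (%g, %g) lies outside the domain",
                   ctr[1], ctr[2]))
  nearest <- function(ctr) {
    d <- (state$coords[, 1] - ctr[1])^2 + (state$coords[, 2] - ctr[2])^2
    order(d)[seq_len(min(k, length(d)))]
  }
  ia <- nearest(atrial_center)
  iv <- nearest(ventricular_center)
  if (length(intersect(ia, iv)) > 0)
    stop("chamber sample sets overlap; move the centers apart or reduce k")
  dp <- mean(state$p[iv]) - mean(state$p[ia])
  attr(dp, "atrial_nodes") <- ia
  attr(dp, "ventricular_nodes") <- iv
  dp
}

#' Stream function of a velocity snapshot
#'
#' Least-squares recovery of psi with grad psi = (-u_y, u_x) (so contours
#' of psi are the instantaneous streamlines), gauge-fixed by psi = 0 at a
#' reference node.  Solves the P1 Poisson normal equations; the recovered
#' field reproduces the divergence-free part of u.
#'
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param ref_node gauge node (default: the first wall node of the
#'   boundary loop)
#' @return list of class `stream_function`: `psi` (per node), `ref_node`
#' @export
compute_streamfunction <- function(state, mesh, ref_node = NULL) {
  if (is.null(ref_node)) {
    w <- which(mesh$loop_tags == "wall")
    ref_node <- if (length(w) > 0) mesh$loop[w[1]] else mesh$loop[1]
  }
  tri <- mesh$tri
  coords <- state$coords
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  A <- det / 2
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  c_ <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  # element-mean target field (-u_y, u_x)
  t1 <- -rowMeans(matrix(state$u[tri, 2], ncol = 3))
  t2 <- rowMeans(matrix(state$u[tri, 1], ncol = 3))
  m <- nrow(tri)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  f <- numeric(nrow(coords))
  for (a in 1:3) {
    fa <- A * (b[, a] * t1 + c_[, a] * t2)
    w <- tapply(fa, tri[, a], sum)
    idx <- as.integer(names(w))
    f[idx] <- f[idx] + w
    for (bb in 1:3) {
      ii <- c(ii, tri[, a]); jj <- c(jj, tri[, bb])
      xx <- c(xx, A * (b[, a] * b[, bb] + c_[, a] * c_[, bb]))
    }
  }
  n <- nrow(coords)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  free <- setdiff(seq_len(n), ref_node)
  psi <- numeric(n)
  psi[free] <- as.vector(Matrix::solve(K[free, free, drop = FALSE], f[free]))
  structure(list(psi = psi, ref_node = ref_node), class = "stream_function")
}

#' Ellipsoid ventricular volume
#'
#' `V = (pi/6) L D1 D2` for a ventricle idealized as an ellipsoid with
#' major length L and orthogonal minor diameters D1, D2 (often assumed
#' equal when only one minor axis is measurable in 2-D).
#'
#' @param L major length (cm)
#' @param D1,D2 minor diameters (cm); `D2` defaults to `D1`
#' @return volume (cm^3)
#' @export
ventricular_volume <- function(L, D1, D2 = D1) {
  if (any(c(L, D1, D2) <= 0)) stop("all dimensions must be positive")
  pi / 6 * L * D1 * D2
}

#' Ventricular ejection fraction
#'
#' Stroke volume over end-diastolic volume,
#' `VEF = (EDV - ESV) / EDV`.
#'
#' @param EDV end-diastolic volume (cm^3), > 0
#' @param ESV end-systolic volume (cm^3), in `[0, EDV]`
#' @return list: `fraction` and `percent`
#' @export
ejection_fraction <- function(EDV, ESV) {
  if (EDV <= 0) stop("EDV must be positive")
  if (ESV < 0 || ESV > EDV) stop("data error: need 0 <= ESV <= EDV")
  f <- (EDV - ESV) / EDV
  list(fraction = f, percent = 100 * f)
}

#' Reynolds number `Re = rho u D / mu`
#' @param rho density (g/cm^3); @param u characteristic velocity (cm/s)
#' @param D characteristic diameter (cm); @param mu viscosity (poise)
#' @return dimensionless Re
#' @export
reynolds_number <- function(rho, u, D, mu) {
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  if (u < 0 || D < 0) stop("u and D must be non-negative")
  rho * u * D / mu
}

#' Womersley number `alpha = sqrt(rho omega R^2 / mu)`
#' @param rho density (g/cm^3); @param omega angular frequency (rad/s)
#' @param R tract radius (cm); @param mu viscosity (poise)
#' @return dimensionless alpha
#' @export
womersley_number <- function(rho, omega, R, mu) {
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  if (omega < 0 || R < 0) stop("omega and R must be non-negative")
  sqrt(rho * omega * R^2 / mu)
}

# --- field interpolation and section fluxes ---------------------------------

#' Interpolate nodal fields at arbitrary points
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param pts n x 2 query points (current configuration)
#' @return tibble `x`, `y`, `ux`, `uy`, `p` (NA outside the mesh)
#' @export
interp_state <- function(state, mesh, pts) {
  pts <- matrix(pts, ncol = 2)
  tri <- mesh$tri
  coords <- state$coords
  n <- nrow(pts)
  ux <- uy <- p <- rep(NA_real_, n)
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  for (q in seq_len(n)) {
    l2 <- ((pts[q, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
             (pts[q, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])) / det
    l3 <- ((pts[q, 2] - p1[, 2]) * (p2[, 1] - p1[, 1]) -
             (pts[q, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / det
    l1 <- 1 - l2 - l3
    tol <- -1e-10
    e <- which(l1 >= tol & l2 >= tol & l3 >= tol)[1]
    if (is.na(e)) next
    lam <- c(l1[e], l2[e], l3[e])
    nd <- tri[e, ]
    ux[q] <- sum(lam * state$u[nd, 1])
    uy[q] <- sum(lam * state$u[nd, 2])
    p[q] <- sum(lam * state$p[nd])
  }
  tibble::tibble(x = pts[, 1], y = pts[, 2], ux = ux, uy = uy, p = p)
}

#' Flux and mean velocity across a vertical section
#'
#' Samples the velocity on the segment where the line `x = x0` crosses the
#' lumen and integrates the x-component: positive means flow toward +x.
#'
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param x0 section abscissa (cm)
#' @param nsample sample points across the gap
#' @return list: `flux` (cm^2/s), `mean_velocity` (cm/s), `width` (cm),
#'   `profile` (tibble y, ux)
#' @export
cross_section_flux <- function(state, mesh, x0, nsample = 25) {
  poly <- state$coords[mesh$loop, , drop = FALSE]
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  hit <- which((x1 - x0) * (x2 - x0) <= 0 & x1 != x2)
  ys <- y1[hit] + (x0 - x1[hit]) / (x2[hit] - x1[hit]) * (y2[hit] - y1[hit])
  if (length(ys) < 2) stop("section does not cross the lumen")
  ylo <- min(ys); yhi <- max(ys)
  eps <- 1e-6 * (yhi - ylo)
  yy <- seq(ylo + eps, yhi - eps, length.out = nsample)
  s <- interp_state(state, mesh, cbind(x0, yy))
  ok <- is.finite(s$ux)
  flux <- sum(diff(yy[ok]) * (head(s$ux[ok], -1) + tail(s$ux[ok], -1)) / 2)
  list(flux = flux, mean_velocity = flux / (yhi - ylo), width = yhi - ylo,
       profile = tibble::tibble(y = yy, ux = s$ux))
}

#' Hemodynamic time series of a simulation
#'
#' Per stored state: near-canal peak-average |WSS|, the inter-chamber
#' pressure difference (when centers are given), and the throat section
#' flux.  This is the tabular summary the metrics stage writes to CSV.
#'
#' @param sim a `cardio_sim`
#' @param props fluid properties (viscosity for WSS); default the
#'   simulation's own
#' @param k averaging size for the peak rules (default 10)
#' @param av_window region half-width around the throat (cm)
#' @param centers optional list(atrium = c(x, y), ventricle = c(x, y))
#' @param drop_transient_s initial washout interval to drop (s)
#' @return tibble of class `hemodynamic_series`
#' @export
hemodynamics_series <- function(sim, props = sim$props, k = 10,
                                av_window = 0.02, centers = NULL,
                                drop_transient_s = 0) {
  t0 <- sim$states[[1]]$time + drop_transient_s
  states <- Filter(function(s) s$time >= t0 - 1e-12, sim$states)
  av <- av_canal_region(sim$mesh, window = av_window)
  rows <- lapply(states, function(s) {
    wss <- compute_wss(s, sim$mesh, props$viscosity)
    reg <- wss$node %in% av$region
    wss_pk <- suppressWarnings(region_peak_average(abs(wss$tau), reg, k))
    dp <- if (is.null(centers)) NA_real_ else
      as.numeric(compute_pressure_gradient(s, sim$mesh, centers$atrium,
                                           centers$ventricle, k))
    fl <- tryCatch(cross_section_flux(s, sim$mesh, av$center[1]),
                   error = function(e) list(flux = NA_real_,
                                            mean_velocity = NA_real_))
    tibble::tibble(time = s$time, wss_peak_avg = wss_pk, dP = dp,
                   throat_flux = fl$flux,
                   throat_mean_velocity = fl$mean_velocity)
  })
  out <- do.call(rbind, rows)
  attr(out, "throat") <- av
  class(out) <- c("hemodynamic_series", class(out))
  out
}
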