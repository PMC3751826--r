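# Triangulated moving computational domains.
#
# Meshes are generated once from the most-contracted configuration
# (Delaunay triangulation of the boundary loop plus a jittered interior
# hex grid) and deformed every step by solving plane-strain linear
# elasticity with Jacobian stiffening: element Young's modulus
# E_e = E0 / det(J_e)^chi of the *reference* mesh, so small elements near
# the wall deform least and the stiffness factorization is reused across
# the whole run.

#' Construct a 2-D triangle mesh
#'
#' @param coords N x 2 node coordinates (cm)
#' @param tri M x 3 triangle connectivity (1-based); reoriented CCW
#' @param loop integer indices of the boundary nodes in loop order
#' @param loop_tags character tags (`wall`/`inlet`/`outlet`) per loop node
#' @param h target edge length used at generation time (cm), or NA
#' @return an object of class `mesh2d`
#' @export
mesh2d <- function(coords, tri, loop, loop_tags, h = NA_real_) {
  coords <- as.matrix(coords); storage.mode(coords) <- "double"
  tri <- as.matrix(tri); storage.mode(tri) <- "integer"
  a2 <- signed_areas2(coords, tri)
  flip <- a2 < 0
  if (any(flip)) tri[flip, ] <- tri[flip, c(1L, 3L, 2L)]
  if (any(abs(a2) < .Machine$double.eps))
    stop("degenerate (zero-area) triangle in connectivity")
  loop_tags <- as.character(loop_tags)
  stopifnot(length(loop) == length(loop_tags),
            all(loop_tags %in% VALID_TAGS))
  edges <- cbind(loop, c(loop[-1], loop[1]))
  etag <- ifelse(loop_tags == "outlet" |
                   c(loop_tags[-1], loop_tags[1]) == "outlet", "outlet",
                 ifelse(loop_tags == "inlet" |
                          c(loop_tags[-1], loop_tags[1]) == "inlet", "inlet",
                        "wall"))
  boundary <- lapply(setNames(VALID_TAGS, VALID_TAGS),
                     function(tg) sort(loop[loop_tags == tg]))
  structure(list(coords = coords, tri = tri, loop = as.integer(loop),
                 loop_tags = loop_tags, edges = edges, edge_tags = etag,
                 boundary = boundary, h = h,
                 ref_detJ = 2 * abs(a2)),
            class = "mesh2d")
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("mesh2d: %d nodes, %d triangles, %d boundary nodes (%s)\n",
              nrow(x$coords), nrow(x$tri), length(x$loop),
              paste(sprintf("%s %d", VALID_TAGS,
                            tabulate(factor(x$loop_tags, VALID_TAGS), 3L)),
                    collapse = ", ")))
  invisible(x)
}

signed_areas2 <- function(coords, tri) {
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
}

#' Triangle areas of a mesh
#' @param mesh a `mesh2d`
#' @param coords optional alternative node coordinates
#' @return vector of positive areas (cm^2)
#' @export
triangle_areas <- function(mesh, coords = NULL) {
  if (is.null(coords)) coords <- mesh$coords
  signed_areas2(coords, mesh$tri) / 2
}

#' Shoelace area of a closed polygon
#' @param pts n x 2 matrix of vertices in order (unclosed)
#' @return signed area (positive if counter-clockwise)
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    cr <- ((y1[i] > py) != (y2[i] > py)) &
      (px < (x2[i] - x1[i]) * (py - y1[i]) / (y2[i] - y1[i]) + x1[i])
    inside <- xor(inside, cr)
  }
  inside
}

dist_to_polygon <- function(px, py, poly) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  d2 <- rep(Inf, length(px))
  for (i in seq_along(x1)) {
    vx <- x2[i] - x1[i]; vy <- y2[i] - y1[i]
    L2 <- vx * vx + vy * vy
    t <- pmin(pmax(((px - x1[i]) * vx + (py - y1[i]) * vy) / L2, 0), 1)
    dx <- px - (x1[i] + t * vx); dy <- py - (y1[i] + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Triangulate the interior of a closed boundary loop
#'
#' Delaunay triangulation (Bowyer-Watson) of the boundary nodes plus an
#' interior hexagonal point grid at the target edge length; triangles
#' outside the polygon are discarded.  All input boundary nodes appear
#' unchanged in the mesh, as nodes `1..length(loop)` in loop order.
#'
#' @param loop_points n x 2 matrix: closed boundary polygon vertices in
#'   order (first point not repeated)
#' @param target_edge_length interior point spacing (cm)
#' @param loop_tags per-vertex tags (`wall`/`inlet`/`outlet`)
#' @return a [mesh2d()]
#' @export
triangulate <- function(loop_points, target_edge_length,
                        loop_tags = NULL) {
  loop_points <- as.matrix(loop_points)
  n <- nrow(loop_points)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  if (!is.numeric(target_edge_length) || target_edge_length <= 0)
    stop("target_edge_length must be positive")
  if (is.null(loop_tags)) loop_tags <- rep("wall", n)
  closed <- rbind(loop_points, loop_points[1, ])
  xi <- polyline_self_intersection(closed)
  if (!is.null(xi))
    stop(sprintf("geometry error: polygon self-intersects near (%.6g, %.6g)",
                 xi$point[1], xi$point[2]))
  if (polygon_area(loop_points) < 0) {     # enforce CCW
    loop_points <- loop_points[n:1, , drop = FALSE]
    loop_tags <- loop_tags[n:1]
  }
  h <- target_edge_length
  bb <- apply(loop_points, 2, range)
  ys <- seq(bb[1, 2] - h, bb[2, 2] + h, by = h * sqrt(3) / 2)
  pts <- NULL
  for (r in seq_along(ys)) {
    xs <- seq(bb[1, 1] - h, bb[2, 1] + h, by = h)
    if (r %% 2L == 0L) xs <- xs + h / 2
    pts <- rbind(pts, cbind(xs, ys[r]))
  }
  # deterministic jitter breaks the hex grid's cocircular quadruples
  jit <- 1e-3 * h
  pts[, 1] <- pts[, 1] + jit * sin(seq_len(nrow(pts)) * 12.9898)
  pts[, 2] <- pts[, 2] + jit * cos(seq_len(nrow(pts)) * 78.233)
  keep <- point_in_polygon(pts[, 1], pts[, 2], loop_points) &
    dist_to_polygon(pts[, 1], pts[, 2], loop_points) > 0.55 * h
  interior <- pts[keep, , drop = FALSE]
  allp <- rbind(loop_points, interior)
  tri <- .cpp_delaunay(allp)
  cx <- (allp[tri[, 1], 1] + allp[tri[, 2], 1] + allp[tri[, 3], 1]) / 3
  cy <- (allp[tri[, 1], 2] + allp[tri[, 2], 2] + allp[tri[, 3], 2]) / 3
  tri <- tri[point_in_polygon(cx, cy, loop_points), , drop = FALSE]
  # every boundary segment must be a mesh edge
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- unique(c(ek(tri[, 1], tri[, 2]), ek(tri[, 2], tri[, 3]),
                    ek(tri[, 3], tri[, 1])))
  bseg <- ek(seq_len(n), c(2:n, 1L))
  missing <- which(!(bseg %in% edges))
  if (length(missing) > 0)
    stop(sprintf(
      "boundary segment %d not recovered by the triangulation; reduce target_edge_length (current %g)",
      missing[1], h))
  used <- sort(unique(as.vector(tri)))
  if (!all(seq_len(n) %in% used))
    stop("triangulation dropped boundary nodes; reduce target_edge_length")
  # drop unused interior points (outside the polygon) and remap
  remap <- integer(nrow(allp)); remap[used] <- seq_along(used)
  mesh2d(allp[used, , drop = FALSE],
         matrix(remap[tri], ncol = 3), seq_len(n), loop_tags, h = h)
}

#' Structured triangulated channel mesh
#'
#' Rectangle `[0, L] x [0, H]` on an nx-by-ny quad grid split into
#' triangles; left edge tagged inlet, right edge outlet, top/bottom (and
#' corners) wall.  Used for the analytic channel benchmarks where nodes
#' exactly on the centerline are convenient.
#'
#' @param L,H channel length and height (cm)
#' @param nx,ny number of element intervals in x and y
#' @return a [mesh2d()]
#' @export
channel_mesh <- function(L, H, nx, ny) {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, H, length.out = ny + 1)
  coords <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i   # i in 1..nx+1, j in 1..ny+1
  tri <- matrix(0L, 2L * nx * ny, 3L)
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- id(i, j); b <- id(i + 1L, j); c <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
    tri[k + 1L, ] <- c(a, b, c); tri[k + 2L, ] <- c(a, c, d)
    k <- k + 2L
  }
  loop <- c(id(seq_len(nx), 1L),                    # bottom, left -> right
            id(nx + 1L, seq_len(ny)),               # right, bottom -> top
            id(rev(seq_len(nx) + 1L), ny + 1L),     # top, right -> left
            id(1L, rev(seq_len(ny) + 1L)))          # left, top -> bottom
  tags <- c(rep("wall", nx), rep("outlet", ny), rep("wall", nx),
            rep("inlet", ny))
  tags[c(nx, nx + ny, 2L * nx + ny, 2L * (nx + ny))] <- "wall"  # corners
  mesh2d(coords, tri, loop, tags, h = max(L / nx, H / ny))
}

#' Structured unit-square mesh with all-wall boundary
#' @param n element intervals per side
#' @param L side length
#' @return a [mesh2d()]
#' @export
square_mesh <- function(n, L = 1) {
  m <- channel_mesh(L, L, n, n)
  m$loop_tags[] <- "wall"
  m$edge_tags[] <- "wall"
  m$boundary <- list(wall = sort(m$loop), inlet = integer(0),
                     outlet = integer(0))
  m
}

#' Mesh quality metrics
#'
#' @param mesh a `mesh2d`
#' @param coords optional deformed coordinates
#' @return list with per-element tibble (`min_angle_deg`, `detJ`,
#'   `aspect`) and scalar summaries; non-positive det J counted as failures
#' @export
mesh_quality_report <- function(mesh, coords = NULL) {
  if (is.null(coords)) coords <- mesh$coords
  tri <- mesh$tri
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  e1 <- sqrt(rowSums((p2 - p3)^2))   # opposite node 1
  e2 <- sqrt(rowSums((p3 - p1)^2))
  e3 <- sqrt(rowSums((p1 - p2)^2))
  ang <- function(a, b, c) acos(pmin(pmax((b^2 + c^2 - a^2) / (2 * b * c), -1), 1))
  a1 <- ang(e1, e2, e3); a2 <- ang(e2, e3, e1); a3 <- ang(e3, e1, e2)
  detJ <- signed_areas2(coords, tri)
  area <- abs(detJ) / 2
  longest <- pmax(e1, e2, e3)
  aspect <- ifelse(area > 0, longest^2 / (2 * area), Inf)
  per <- tibble::tibble(
    element = seq_len(nrow(tri)),
    min_angle_deg = pmin(a1, a2, a3) * 180 / pi,
    detJ = detJ, area = area, aspect = aspect)
  list(elements = per,
       min_angle_deg = min(per$min_angle_deg),
       detJ_range = range(detJ),
       max_aspect = max(aspect),
       n_failed = sum(detJ <= 0))
}

#' Precompute the Jacobian-stiffened mesh-motion operator
#'
#' Assembles and factorizes the plane-strain elasticity stiffness on the
#' reference mesh with element Young's modulus `E0 / det(J_e)^exponent`,
#' Dirichlet on all boundary-loop nodes.  Reused across time steps.
#'
#' @param mesh a `mesh2d` (reference configuration)
#' @param E0 stiffness scale (arbitrary; cancels in the solve)
#' @param nu Poisson ratio (plane strain), default 0.3
#' @param exponent Jacobian-stiffening exponent; 0 gives uniform stiffness
#' @return an opaque operator object for [solve_mesh_motion()]
#' @export
mesh_motion_operator <- function(mesh, E0 = 1, nu = 0.3, exponent = 1) {
  Ee <- E0 / (mesh$ref_detJ / max(mesh$ref_detJ))^exponent
  trip <- .cpp_elasticity_assemble(mesh$coords, mesh$tri, Ee, nu)
  ndof <- 2L * nrow(mesh$coords)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(ndof, ndof))
  bnodes <- mesh$loop
  fixed <- sort(c(2L * bnodes - 1L, 2L * bnodes))
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free, drop = FALSE]
  list(fact = Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
       Kfb = K[free, fixed, drop = FALSE],
       free = free, fixed = fixed, bnodes = bnodes,
       n = nrow(mesh$coords))
}

#' Propagate boundary displacement into the mesh interior
#'
#' Solves the Jacobian-stiffened elasticity system with the prescribed
#' boundary displacement as Dirichlet data; boundary values are satisfied
#' exactly, and element inversion in the deformed mesh is reported as a
#' mesh-entanglement error naming the worst element.
#'
#' @param mesh a `mesh2d` (reference configuration)
#' @param boundary_displacement matrix `length(mesh$loop) x 2`, ordered as
#'   `mesh$loop` (cm)
#' @param op operator from [mesh_motion_operator()]; built on the fly if NULL
#' @param check_validity error on inverted deformed elements (default TRUE)
#' @return N x 2 full displacement field (cm)
#' @export
solve_mesh_motion <- function(mesh, boundary_displacement, op = NULL,
                              check_validity = TRUE) {
  if (is.null(op)) op <- mesh_motion_operator(mesh)
  bd <- as.matrix(boundary_displacement)
  if (nrow(bd) != length(op$bnodes) || ncol(bd) != 2L)
    stop("boundary_displacement must be length(mesh$loop) x 2")
  # fixed dofs are sorted; map loop-ordered values onto them
  ub <- numeric(length(op$fixed))
  dofs <- c(rbind(2L * op$bnodes - 1L, 2L * op$bnodes))
  vals <- as.vector(t(bd))
  ub[match(dofs, op$fixed)] <- vals
  disp <- numeric(2L * op$n)
  disp[op$fixed] <- ub
  if (length(op$free) > 0) {
    rhs <- -op$Kfb %*% ub
    disp[op$free] <- as.vector(Matrix::solve(op$fact, rhs))
  }
  out <- cbind(disp[seq(1, 2L * op$n, by = 2L)],
               disp[seq(2, 2L * op$n, by = 2L)])
  if (check_validity) {
    a2 <- signed_areas2(mesh$coords + out, mesh$tri)
    if (any(a2 <= 0)) {
      worst <- which.min(a2)
      stop(sprintf(
        "mesh-entanglement error: element %d inverted (det J = %g) under the prescribed boundary motion",
        worst, a2[worst]))
    }
  }
  out
}

#' Mesh velocity from two displacement snapshots
#'
#' Finite difference consistent with the time integrator's constant
#' in-step mesh velocity.
#'
#' @param disp_prev,disp_next N x 2 displacement fields (cm)
#' @param dt time increment (s), > 0
#' @return N x 2 mesh velocity (cm/s)
#' @export
mesh_velocity <- function(disp_prev, disp_next, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (!all(dim(disp_prev) == dim(disp_next)))
    stop("displacement fields must share dimensions")
  (disp_next - disp_prev) / dt
}
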