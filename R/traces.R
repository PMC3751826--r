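# Boundary traces and Lagrangian wall-motion fields.
#
# A trace is one video frame's ordered endocardial boundary polyline with
# per-point tags partitioning it into wall / inlet / outlet spans.  Traces
# are smoothed into parametric curves, resampled to a constant number of
# equidistant nodes (Lagrangian node identity by arc-length fraction), and
# interpolated in time with natural cubic splines to the solver rate
# (100 Hz by default); the per-node time-spline derivative supplies the
# moving-wall Dirichlet velocity.

VALID_TAGS <- c("wall", "inlet", "outlet")

#' Construct a single-frame boundary trace
#'
#' @param points numeric N x 2 matrix of ordered boundary coordinates (cm)
#' @param tags character vector of length N with values in
#'   `"wall"`, `"inlet"`, `"outlet"`; defaults to all-wall
#' @param frame integer frame index
#' @param time acquisition time of the frame (s)
#' @return an object of class `boundary_trace`
#' @export
boundary_trace <- function(points, tags = NULL, frame = 1L, time = 0) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must be an N x 2 matrix")
  n <- nrow(points)
  if (n < 4L) stop("a boundary trace needs at least 4 points")
  if (anyNA(points)) stop("points contain NA")
  if (is.null(tags)) tags <- rep("wall", n)
  tags <- as.character(tags)
  if (length(tags) != n) stop("tags must have one entry per point")
  if (!all(tags %in% VALID_TAGS))
    stop("tags must be one of: ", paste(VALID_TAGS, collapse = ", "))
  xi <- polyline_self_intersection(points)
  if (!is.null(xi))
    stop(sprintf(
      "trace is self-intersecting near (%.6g, %.6g) (segments %d and %d)",
      xi$point[1], xi$point[2], xi$seg1, xi$seg2))
  for (tg in c("inlet", "outlet")) {
    idx <- which(tags == tg)
    if (length(idx) > 1L && any(diff(idx) != 1L))
      stop(sprintf("%s span must be contiguous", tg))
  }
  structure(list(points = points, tags = tags,
                 frame = as.integer(frame), time = as.numeric(time)),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("Boundary trace: frame %d at t = %g s, %d points (%s)\n",
              x$frame, x$time, nrow(x$points),
              paste(sprintf("%s: %d", VALID_TAGS,
                            tabulate(factor(x$tags, VALID_TAGS), 3L)),
                    collapse = ", ")))
  invisible(x)
}

# First proper crossing of non-adjacent segments, or NULL.
polyline_self_intersection <- function(points) {
  n <- nrow(points) - 1L
  if (n < 3L) return(NULL)
  for (i in seq_len(n - 2L)) {
    p1 <- points[i, ]; p2 <- points[i + 1L, ]
    for (j in seq.int(i + 2L, n)) {
      q1 <- points[j, ]; q2 <- points[j + 1L, ]
      d1 <- p2 - p1; d2 <- q2 - q1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-300) next
      s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
      t <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
      eps <- 1e-12
      if (s > eps && s < 1 - eps && t > eps && t < 1 - eps)
        return(list(point = p1 + s * d1, seg1 = i, seg2 = j))
    }
  }
  NULL
}

#' Fit a parametric spline curve through a boundary trace
#'
#' Fits per-coordinate cubic splines over the cumulative-chord-length
#' parameter.  With `smoothing = 0` the curve interpolates every point
#' (natural cubic spline); with `smoothing` in (0, 1] a penalized smoothing
#' spline (`spar = smoothing`) is fitted and then corrected by a linear
#' ramp so that the two endpoints are always reproduced exactly.
#'
#' @param trace a [boundary_trace()]
#' @param smoothing 0 for interpolation, or `spar` in (0, 1] for smoothing
#' @param method `"cubic"` (natural cubic spline, default) or `"linear"`
#'   (chord-length polyline: the curve is the trace itself, so nodes that
#'   already sit at equal arc length are reproduced verbatim on resampling)
#' @return an object of class `boundary_curve` with fields `fx`, `fy`
#'   (parameter functions), `tmax` (parameter range) and `tags`
#' @export
fit_boundary_spline <- function(trace, smoothing = 0,
                                method = c("cubic", "linear")) {
  stopifnot(inherits(trace, "boundary_trace"))
  method <- match.arg(method)
  pts <- trace$points
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (any(diff(s) <= 0)) stop("trace contains coincident consecutive points")
  fit1 <- function(y) {
    if (method == "linear") return(linear_paramfun(s, y))
    if (smoothing <= 0) return(splinefun(s, y, method = "natural"))
    sm <- smooth.spline(s, y, spar = smoothing)
    yh <- predict(sm, s)$y
    # pin endpoints exactly with a linear correction
    a <- y[1] - yh[1]
    b <- (y[length(y)] - yh[length(y)] - a) / (s[length(s)] - s[1])
    yh <- yh + a + b * (s - s[1])
    splinefun(s, yh, method = "natural")
  }
  structure(list(fx = fit1(pts[, 1]), fy = fit1(pts[, 2]),
                 knots = s, tmax = s[length(s)], tags = trace$tags,
                 frame = trace$frame, time = trace$time),
            class = "boundary_curve")
}

# piecewise-linear parameter function with a derivative, mirroring the
# splinefun(t, deriv) interface
linear_paramfun <- function(s, y) {
  slopes <- diff(y) / diff(s)
  function(t, deriv = 0) {
    if (deriv == 0) return(approx(s, y, xout = t, rule = 2)$y)
    i <- pmin(pmax(findInterval(t, s), 1L), length(slopes))
    slopes[i]
  }
}

#' Evaluate a boundary curve at parameter values
#' @param curve a `boundary_curve`
#' @param t parameter values in `[0, curve$tmax]`
#' @param deriv derivative order (0 or 1)
#' @return length(t) x 2 matrix
#' @export
curve_eval <- function(curve, t, deriv = 0) {
  cbind(curve$fx(t, deriv = deriv), curve$fy(t, deriv = deriv))
}

curve_speed <- function(curve, t) {
  d <- curve_eval(curve, t, deriv = 1)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

# Cumulative arc length on a fine Simpson grid; returns a lookup usable for
# inversion and refinement.
curve_arclength_table <- function(curve, n = 4097L) {
  if (n %% 2L == 0L) n <- n + 1L
  t <- seq(0, curve$tmax, length.out = n)
  sp <- curve_speed(curve, t)
  h <- t[2] - t[1]
  # composite Simpson over consecutive pairs of intervals
  pair <- (sp[seq(1, n - 2L, by = 2L)] + 4 * sp[seq(2, n - 1L, by = 2L)] +
             sp[seq(3, n, by = 2L)]) * h / 3
  cum <- c(0, cumsum(pair))              # at odd grid points
  tt <- t[seq(1, n, by = 2L)]
  list(t = tt, s = cum, total = cum[length(cum)])
}

#' Total arc length of a boundary curve
#' @param curve a `boundary_curve`
#' @return arc length (cm)
#' @export
curve_arclength <- function(curve) curve_arclength_table(curve)$total

#' Resample a curve into N equidistant nodes
#'
#' Node k sits at arc-length fraction (k-1)/(N-1) from the first endpoint;
#' both endpoints are preserved exactly.  Arc length is computed by dense
#' composite Simpson quadrature and node parameters are polished with two
#' Newton steps, so successive gaps agree to ~1e-9 relative.
#'
#' @param curve a `boundary_curve` from [fit_boundary_spline()]
#' @param N number of nodes (>= 4)
#' @return N x 2 matrix of node coordinates with attribute `"param"`
#' @export
resample_equidistant <- function(curve, N) {
  if (!is.numeric(N) || N < 4) stop("N must be an integer >= 4")
  N <- as.integer(N)
  tab <- curve_arclength_table(curve)
  target <- tab$total * (seq_len(N) - 1) / (N - 1)
  t <- approx(tab$s, tab$t, xout = target, rule = 2)$y
  # Newton refinement: S(t) - target = 0, S' = speed
  for (it in 1:3) {
    st <- gauss_arclength(curve, tab, t)
    t <- t - (st - target) / pmax(curve_speed(curve, t), 1e-300)
    t <- pmin(pmax(t, 0), curve$tmax)
  }
  t[1] <- 0; t[N] <- curve$tmax
  out <- curve_eval(curve, t)
  attr(out, "param") <- t
  out
}

# Arc length at arbitrary parameters: table value at the nearest lower grid
# node plus 5-point Gauss-Legendre on the remainder.
gauss_arclength <- function(curve, tab, t) {
  gx <- c(-0.9061798459386640, -0.5384693101056831, 0,
          0.5384693101056831, 0.9061798459386640)
  gw <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
          0.4786286704993665, 0.2369268850561891)
  i <- findInterval(t, tab$t, rightmost.closed = TRUE)
  t0 <- tab$t[i]
  base <- tab$s[i]
  half <- (t - t0) / 2
  mid <- (t + t0) / 2
  add <- numeric(length(t))
  for (k in seq_along(gx))
    add <- add + gw[k] * curve_speed(curve, mid + half * gx[k])
  base + add * half
}

#' Interpolate per-frame node positions to a high-rate wall-motion field
#'
#' Every node's coordinates are interpolated over time with natural cubic
#' splines (C^2), reproducing the source frames exactly at their times, and
#' sampled at `target_rate`.  The spline derivative defines the prescribed
#' wall velocity g used as moving-wall Dirichlet data.
#'
#' @param per_frame_nodes list of N x 2 matrices (one per frame, equal N)
#' @param frame_times strictly increasing frame times (s); default 20 fps
#' @param target_rate output sample rate in Hz (default 100)
#' @param tags per-node boundary tags recycled across frames
#' @return an object of class `wall_motion_field`
#' @export
interpolate_motion <- function(per_frame_nodes, frame_times = NULL,
                               target_rate = 100, tags = NULL) {
  if (is.array(per_frame_nodes) && length(dim(per_frame_nodes)) == 3L)
    per_frame_nodes <- lapply(seq_len(dim(per_frame_nodes)[3]),
                              function(k) per_frame_nodes[, , k])
  nf <- length(per_frame_nodes)
  if (nf < 2L) stop("need at least 2 frames")
  N <- nrow(per_frame_nodes[[1]])
  for (k in seq_len(nf))
    if (nrow(per_frame_nodes[[k]]) != N)
      stop(sprintf(
        "node-correspondence error: frame %d has %d nodes, expected %d",
        k, nrow(per_frame_nodes[[k]]), N))
  if (is.null(frame_times)) frame_times <- (seq_len(nf) - 1) / 20  # 20 fps
  if (length(frame_times) != nf || any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing, one per frame")
  if (is.null(tags)) tags <- rep("wall", N)

  X <- vapply(per_frame_nodes, function(m) m[, 1], numeric(N))
  Y <- vapply(per_frame_nodes, function(m) m[, 2], numeric(N))
  fx <- lapply(seq_len(N), function(i)
    splinefun(frame_times, X[i, ], method = "natural"))
  fy <- lapply(seq_len(N), function(i)
    splinefun(frame_times, Y[i, ], method = "natural"))
  times <- seq(frame_times[1], frame_times[nf], by = 1 / target_rate)
  pos <- array(NA_real_, c(N, 2L, length(times)))
  for (i in seq_len(N)) {
    pos[i, 1, ] <- fx[[i]](times)
    pos[i, 2, ] <- fy[[i]](times)
  }
  structure(list(node_count = N, times = times, positions = pos,
                 tags = tags, sample_rate = target_rate,
                 frame_times = frame_times, fx = fx, fy = fy),
            class = "wall_motion_field")
}

#' @export
print.wall_motion_field <- function(x, ...) {
  cat(sprintf(
    "Wall-motion field: %d Lagrangian nodes, t in [%g, %g] s at %g Hz (%d samples)\n",
    x$node_count, min(x$times), max(x$times), x$sample_rate, length(x$times)))
  invisible(x)
}

#' Wall node positions at an arbitrary time
#' @param field a `wall_motion_field`
#' @param t time (s) within the field span
#' @return N x 2 matrix (cm)
#' @export
wall_position <- function(field, t) {
  check_time_in_span(field, t)
  cbind(vapply(field$fx, function(f) f(t), numeric(1)),
        vapply(field$fy, function(f) f(t), numeric(1)))
}

#' Prescribed wall velocity g at an arbitrary time
#'
#' The analytic time derivative of each node's position spline; this is the
#' no-slip Dirichlet velocity imposed on the moving wall.
#'
#' @param field a `wall_motion_field`
#' @param t time (s) within the field span
#' @return N x 2 matrix (cm/s)
#' @export
wall_velocity <- function(field, t) {
  check_time_in_span(field, t)
  cbind(vapply(field$fx, function(f) f(t, deriv = 1), numeric(1)),
        vapply(field$fy, function(f) f(t, deriv = 1), numeric(1)))
}

check_time_in_span <- function(field, t) {
  tol <- 1e-9 * max(1, abs(field$times[length(field$times)]))
  if (t < field$times[1] - tol || t > field$times[length(field$times)] + tol)
    stop(sprintf("extrapolation error: t = %g outside field span [%g, %g]",
                 t, field$times[1], field$times[length(field$times)]))
  invisible(TRUE)
}

#' Build a wall-motion field from a list of frame traces
#'
#' Convenience wrapper: smooth each frame's trace, resample to `N`
#' equidistant nodes (arc-length-fraction correspondence from the first
#' endpoint), and interpolate over time.
#'
#' @param traces list of [boundary_trace()] objects with matching tag layout
#' @param N node count per frame
#' @param target_rate output rate (Hz)
#' @param smoothing passed to [fit_boundary_spline()]
#' @return a `wall_motion_field`
#' @export
traces_to_motion <- function(traces, N, target_rate = 100, smoothing = 0) {
  frames <- lapply(traces, function(tr)
    resample_equidistant(fit_boundary_spline(tr, smoothing), N))
  times <- vapply(traces, function(tr) tr$time, numeric(1))
  # carry tags from the first frame, mapped to resampled nodes by nearest
  # original point along the polyline
  tr1 <- traces[[1]]
  s <- c(0, cumsum(sqrt(rowSums(diff(tr1$points)^2))))
  sf <- s / s[length(s)]
  node_frac <- (seq_len(N) - 1) / (N - 1)
  tags <- tr1$tags[vapply(node_frac, function(f) which.min(abs(sf - f)),
                          integer(1))]
  interpolate_motion(frames, times, target_rate, tags)
}
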