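# Synthetic study fixtures: peristaltic heart-tube and two-chamber wall
# motion in the embryonic regime, a closed-end piston domain for mass
# conservation, rendered particle videos with known advecting flow for PIV
# ground truth, and analytic channel benchmark solutions.
#
# Dimensions are sized to the early embryonic heart (lumen ~100-200 um,
# beat ~0.9 Hz, i.e. 54 bpm) so the computed flows land in the same
# creeping, quasi-steady regime (Re < 1, Womersley alpha ~ 0.1) as the
# organism.

#' Peristaltic heart-tube specification
#'
#' A straight valveless tube with a traveling sinusoidal indentation,
#' the 20-30 hpf analogue.  The local half-width is
#' `h(x, t) = w0 (1 - occ sin^2(pi (x - c t) / lambda))` with one
#' wavelength per tube (`lambda = length`, wave speed `c = f lambda`), so
#' the motion is periodic at the beat frequency and the lumen area is
#' constant in time (any frame serves as the most-contracted reference).
#'
#' @param length tube length (cm)
#' @param half_width rest half-width w0 (cm)
#' @param occlusion indentation depth as a fraction of w0, in `[0, 1)`
#' @param frequency beat frequency (Hz); default 0.9 Hz = 54 bpm
#' @param n_wall nodes per wall side
#' @param n_cap interior nodes per end cap
#' @param sample_rate output rate (Hz)
#' @param n_cycles cycles of motion to generate
#' @return list of class `peristaltic_spec`
#' @export
peristaltic_spec <- function(length = 0.15, half_width = 0.01,
                             occlusion = 0.6, frequency = 0.9,
                             n_wall = 41, n_cap = 7, sample_rate = 100,
                             n_cycles = 2) {
  if (occlusion < 0 || occlusion >= 1)
    stop("occlusion must be in [0, 1): full closure is not representable")
  if (frequency <= 0) stop("frequency must be positive")
  structure(list(length = length, half_width = half_width,
                 occlusion = occlusion, frequency = frequency,
                 wavelength = length, wave_speed = frequency * length,
                 n_wall = n_wall, n_cap = n_cap,
                 sample_rate = sample_rate, n_cycles = n_cycles),
            class = "peristaltic_spec")
}

#' Half-width profile of a peristaltic tube
#' @param spec a [peristaltic_spec()]
#' @return function `(x, t)` giving the half-width (cm)
#' @export
peristaltic_halfwidth <- function(spec) {
  function(x, t)
    spec$half_width * (1 - spec$occlusion *
                         sin(pi * (x - spec$wave_speed * t) /
                               spec$wavelength)^2)
}

# closed CCW loop of a symmetric tube with half-width function h(x):
# bottom wall left->right, outlet cap, top wall right->left, inlet cap
tube_loop <- function(xs, hfun, n_cap) {
  L <- xs[length(xs)]
  nb <- length(xs)
  cap_frac <- seq_len(n_cap) / (n_cap + 1)      # interior fractions, 0->1
  h0 <- hfun(0); hL <- hfun(L)
  pts <- rbind(cbind(xs, -hfun(xs)),                          # bottom
               cbind(L, -hL + cap_frac * 2 * hL),             # outlet cap
               cbind(rev(xs), hfun(rev(xs))),                 # top
               cbind(0, h0 - cap_frac * 2 * h0))              # inlet cap
  tags <- c(rep("wall", nb), rep("outlet", n_cap),
            rep("wall", nb), rep("inlet", n_cap))
  list(points = pts, tags = tags)
}

generate_tube_motion <- function(hfun2, L, n_wall, n_cap, sample_rate,
                                 duration) {
  xs <- seq(0, L, length.out = n_wall)
  times <- seq(0, duration, by = 1 / sample_rate)
  frames <- lapply(times, function(t)
    tube_loop(xs, function(x) hfun2(x, t), n_cap)$points)
  tags <- tube_loop(xs, function(x) hfun2(x, 0), n_cap)$tags
  interpolate_motion(frames, times, target_rate = sample_rate, tags = tags)
}

#' Generate peristaltic-tube wall motion
#'
#' Lagrangian boundary nodes of the traveling-wave tube: wall nodes keep
#' their x and move transversally with the indentation; cap nodes keep a
#' fixed fraction of the local gap.
#'
#' @param spec a [peristaltic_spec()]
#' @return a `wall_motion_field` covering `n_cycles` beats
#' @export
generate_peristaltic_motion <- function(spec) {
  h <- peristaltic_halfwidth(spec)
  fld <- generate_tube_motion(h, spec$length, spec$n_wall, spec$n_cap,
                              spec$sample_rate,
                              spec$n_cycles / spec$frequency)
  attr(fld, "spec") <- spec
  fld
}

#' Two-chamber heart specification
#'
#' Two bulbous chambers joined by a narrow throat (the AV canal), the
#' 110-120 hpf analogue: chamber half-widths are Gaussian bumps over a
#' baseline throat half-width, and the chamber sizes modulate sinusoidally
#' with a phase lag (atrium leads).  The throat half-width is constant.
#'
#' @param chamber_radius rest bump amplitude of each chamber (cm),
#'   length-2 vector (atrium, ventricle)
#' @param throat_half_width baseline (and throat) half-width (cm)
#' @param length domain length (cm)
#' @param amplitude fractional radius modulation
#' @param phase_lag ventricle delay as a fraction of the cycle, in `[0, 1)`
#' @param frequency beat frequency (Hz); default 2.5 Hz = 150 bpm
#' @param n_wall,n_cap,sample_rate,n_cycles as in [peristaltic_spec()]
#' @return list of class `two_chamber_spec`
#' @export
two_chamber_spec <- function(chamber_radius = c(0.022, 0.022),
                             throat_half_width = 0.005, length = 0.16,
                             amplitude = 0.25, phase_lag = 0.3,
                             frequency = 2.5, n_wall = 49, n_cap = 5,
                             sample_rate = 100, n_cycles = 2) {
  if (phase_lag < 0 || phase_lag >= 1) stop("phase_lag must be in [0, 1)")
  if (throat_half_width >= min(chamber_radius))
    stop("throat width must be smaller than the chamber diameters")
  structure(list(chamber_radius = chamber_radius,
                 throat_half_width = throat_half_width, length = length,
                 amplitude = amplitude, phase_lag = phase_lag,
                 frequency = frequency, n_wall = n_wall, n_cap = n_cap,
                 sample_rate = sample_rate, n_cycles = n_cycles),
            class = "two_chamber_spec")
}

#' Half-width profile of the two-chamber geometry
#' @param spec a [two_chamber_spec()]
#' @return function `(x, t)` giving the half-width (cm)
#' @export
two_chamber_halfwidth <- function(spec) {
  L <- spec$length
  xa <- 0.28 * L; xv <- 0.72 * L          # chamber centers
  s <- 0.11 * L                           # bump width
  function(x, t) {
    ph <- 2 * pi * spec$frequency * t
    ra <- spec$chamber_radius[1] * (1 + spec$amplitude * sin(ph))
    rv <- spec$chamber_radius[2] *
      (1 + spec$amplitude * sin(ph - 2 * pi * spec$phase_lag))
    spec$throat_half_width + ra * exp(-((x - xa) / s)^2) +
      rv * exp(-((x - xv) / s)^2)
  }
}

#' Generate two-chamber wall motion with an AV constriction
#' @param spec a [two_chamber_spec()]
#' @return a `wall_motion_field`
#' @export
generate_two_chamber_motion <- function(spec) {
  h <- two_chamber_halfwidth(spec)
  fld <- generate_tube_motion(h, spec$length, spec$n_wall, spec$n_cap,
                              spec$sample_rate,
                              spec$n_cycles / spec$frequency)
  attr(fld, "spec") <- spec
  fld
}

#' Closed-end piston wall motion
#'
#' A rectangular box whose left end wall (the piston) advances as
#' `s(t) = stroke sin^2(pi t / period)`; top, bottom and piston are walls,
#' the right end is the only outlet, and interior wall nodes stretch
#' affinely in x.  The displaced area is known in closed form, making this
#' the conservation fixture.
#'
#' @param length,height box dimensions (cm)
#' @param stroke piston travel (cm), `< length`
#' @param period piston period (s)
#' @param n_wall,n_cap,sample_rate,duration sampling controls
#' @return a `wall_motion_field` (attribute `"area"`: function of t)
#' @export
generate_piston_motion <- function(length = 0.1, height = 0.02,
                                   stroke = 0.03, period = 1,
                                   n_wall = 31, n_cap = 7,
                                   sample_rate = 100, duration = period) {
  if (stroke >= length) stop("stroke must be smaller than the box length")
  s <- function(t) stroke * sin(pi * t / period)^2
  xs0 <- seq(0, length, length.out = n_wall)
  cap_frac <- seq_len(n_cap) / (n_cap + 1)
  times <- seq(0, duration, by = 1 / sample_rate)
  h2 <- height / 2
  frames <- lapply(times, function(t) {
    xs <- s(t) + xs0 / length * (length - s(t))
    rbind(cbind(xs, -h2),                                  # bottom
          cbind(length, -h2 + cap_frac * height),          # outlet cap
          cbind(rev(xs), h2),                              # top
          cbind(s(t), h2 - cap_frac * height))             # piston face
  })
  tags <- c(rep("wall", n_wall), rep("outlet", n_cap),
            rep("wall", n_wall), rep("wall", n_cap))
  fld <- interpolate_motion(frames, times, target_rate = sample_rate,
                            tags = tags)
  attr(fld, "area") <- function(t) (length - s(t)) * height
  attr(fld, "dareadt") <- function(t)
    -height * stroke * pi / period * sin(2 * pi * t / period)
  fld
}

#' Render synthetic particle image frames with a known flow
#'
#' Gaussian-spot particles advected by a closed-form pixel displacement
#' field; the standard PIV ground truth.  Deterministic under `seed`.
#'
#' @param dims image size `c(rows, cols)` (px)
#' @param n_frames number of frames
#' @param flow_px function `(x, y)` (px coordinates) returning an n x 2
#'   matrix of per-frame displacements (px/frame)
#' @param density particles per px^2 (default 0.02)
#' @param diameter particle image diameter (px), >= 2
#' @param noise_sd additive Gaussian intensity noise (image max is ~1)
#' @param seed RNG seed
#' @return list: `frames` (list of matrices), `truth` (function `(x, y)`
#'   = `flow_px`), `dims`
#' @export
render_particle_images <- function(dims = c(128, 128), n_frames = 2,
                                   flow_px, density = 0.02, diameter = 3,
                                   noise_sd = 0, seed = 1) {
  if (diameter < 2) stop("particle image diameter must be >= 2 px")
  if (density <= 0) stop("density must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pad <- 16
  np <- round(density * (dims[1] + 2 * pad) * (dims[2] + 2 * pad))
  xp <- stats::runif(np, 1 - pad, dims[2] + pad)
  yp <- stats::runif(np, 1 - pad, dims[1] + pad)
  sigma <- diameter / 4
  render <- function(xp, yp) {
    img <- matrix(0, dims[1], dims[2])
    r <- ceiling(3 * sigma)
    for (k in seq_along(xp)) {
      c0 <- round(xp[k]); r0 <- round(yp[k])
      if (c0 + r < 1 || c0 - r > dims[2] || r0 + r < 1 || r0 - r > dims[1])
        next
      cs <- max(1, c0 - r):min(dims[2], c0 + r)
      rs <- max(1, r0 - r):min(dims[1], r0 + r)
      gx <- exp(-(cs - xp[k])^2 / (2 * sigma^2))
      gy <- exp(-(rs - yp[k])^2 / (2 * sigma^2))
      img[rs, cs] <- img[rs, cs] + outer(gy, gx)
    }
    if (noise_sd > 0) img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
    img
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frames[[f]] <- render(xp, yp)
    d <- flow_px(xp, yp)
    xp <- xp + d[, 1]
    yp <- yp + d[, 2]
  }
  list(frames = frames, truth = flow_px, dims = dims)
}

#' Analytic plane Poiseuille channel solution
#'
#' Steady pressure-driven flow between parallel plates a distance H apart:
#' `u(y) = 6 U y (H - y) / H^2`, centerline `1.5 U`, wall shear
#' `6 mu U / H`, pressure gradient `-12 mu U / H^2`.
#'
#' @param H channel height (cm)
#' @param U_mean cross-section mean velocity (cm/s)
#' @param mu dynamic viscosity (poise)
#' @return list: `profile(y)`, `centerline`, `wss`, `dpdx`
#' @export
poiseuille_solution <- function(H, U_mean, mu) {
  if (H <= 0 || mu <= 0) stop("H and mu must be positive")
  list(profile = function(y) 6 * U_mean * y * (H - y) / H^2,
       centerline = 1.5 * U_mean,
       wss = 6 * mu * U_mean / H,
       dpdx = -12 * mu * U_mean / H^2)
}

#' Analytic oscillatory (Womersley) channel solution
#'
#' Two-dimensional channel flow driven by an oscillating pressure
#' gradient, scaled so the cross-section mean velocity is
#' `amplitude * sin(phase)` in the quasi-steady limit.  As `alpha -> 0`
#' the profile reduces to the instantaneous Poiseuille parabola.
#'
#' @param H channel height (cm)
#' @param alpha Womersley number based on the half-height
#' @param amplitude mean-velocity amplitude (cm/s)
#' @return list: `u(y, phase)` (vectorized in `y`), `mean(phase)`, `alpha`
#' @export
womersley_solution <- function(H, alpha, amplitude) {
  if (H <= 0 || alpha < 0) stop("H must be positive and alpha non-negative")
  R <- H / 2
  ccosh <- function(z) (exp(z) + exp(-z)) / 2
  ctanh <- function(z) (exp(z) - exp(-z)) / (exp(z) + exp(-z))
  if (alpha < 1e-4) {
    u <- function(y, phase) {
      eta <- (y - R) / R
      amplitude * 1.5 * (1 - eta^2) * sin(phase)
    }
  } else {
    beta <- alpha * sqrt(1i)
    m <- 1 - ctanh(beta) / beta
    u <- function(y, phase) {
      eta <- (y - R) / R
      f <- 1 - ccosh(beta * eta) / ccosh(beta)
      amplitude * Im(f / m * exp(1i * phase))
    }
  }
  list(u = u, mean = function(phase) amplitude * sin(phase), alpha = alpha)
}
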