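# FFT cross-correlation particle image velocimetry.
#
# Image convention: matrices indexed [row, col] = [y, x], y increasing
# downward; displacements are (dx, dy) in pixels with the same axes.
# Window means are subtracted before correlation (intensity-offset
# suppression) and the correlation peak is refined with a 3-point Gaussian
# fit.  Multi-pass refinement offsets the interrogation windows by the
# previous pass's (rounded) displacement prediction.

wrap_shift <- function(k, n) ifelse(k > n / 2, k - n, k)

#' Cross-correlate one interrogation window pair
#'
#' FFT cross-correlation of two equally sized windows after mean
#' subtraction; the integer peak is refined per axis with a 3-point
#' Gaussian (parabolic fallback where log is undefined).  The peak ratio
#' (primary over secondary peak outside the primary's 3x3 neighborhood)
#' measures correlation quality.
#'
#' @param winA,winB numeric matrices of identical size
#' @return list: `dx`, `dy` (px, displacement of B relative to A),
#'   `peak_ratio`, `valid`
#' @export
cross_correlate_window <- function(winA, winB) {
  stopifnot(all(dim(winA) == dim(winB)))
  nr <- nrow(winA); nc <- ncol(winA)
  a <- winA - mean(winA); b <- winB - mean(winB)
  if (sd(a) == 0 || sd(b) == 0)
    return(list(dx = NA_real_, dy = NA_real_, peak_ratio = NA_real_,
                valid = FALSE))
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    (nr * nc)
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  # secondary peak outside the 3x3 neighborhood (with wrap)
  mask <- C
  ri <- ((pk[1] - 2):(pk[1])) %% nr + 1L
  ci <- ((pk[2] - 2):(pk[2])) %% nc + 1L
  mask[ri, ci] <- -Inf
  second <- max(mask)
  peak_ratio <- if (second > 0) max(C) / second else Inf
  gauss3 <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0) {
      den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
      if (den < 0) return((log(cm) - log(cp)) / den)
    }
    den <- 2 * (cm - 2 * c0 + cp)
    if (den < 0) (cm - cp) / den else 0
  }
  at <- function(i, j) C[(i - 1L) %% nr + 1L, (j - 1L) %% nc + 1L]
  sy <- gauss3(at(pk[1] - 1L, pk[2]), at(pk[1], pk[2]), at(pk[1] + 1L, pk[2]))
  sx <- gauss3(at(pk[1], pk[2] - 1L), at(pk[1], pk[2]), at(pk[1], pk[2] + 1L))
  list(dx = as.numeric(wrap_shift(pk[2] - 1L, nc) + sx),
       dy = as.numeric(wrap_shift(pk[1] - 1L, nr) + sy),
       peak_ratio = as.numeric(peak_ratio), valid = TRUE)
}

piv_grid <- function(dims, w, overlap) {
  step <- max(1L, round(w * (1 - overlap)))
  half <- w / 2
  cy <- seq(half + 1, dims[1] - half + 1, by = step)
  cx <- seq(half + 1, dims[2] - half + 1, by = step)
  list(cx = cx, cy = cy)
}

extract_window <- function(img, cy, cx, w, offy = 0L, offx = 0L) {
  half <- w %/% 2
  r0 <- round(cy) - half + offy
  c0 <- round(cx) - half + offx
  nr <- nrow(img); nc <- ncol(img)
  if (r0 < 1L || c0 < 1L || r0 + w - 1L > nr || c0 + w - 1L > nc) return(NULL)
  img[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
}

#' Multi-pass PIV on an image pair
#'
#' Runs FFT cross-correlation over a schedule of decreasing window sizes;
#' each pass offsets the second image's windows by the previous pass's
#' displacement (rounded to integer pixels, avoiding in-plane particle
#' loss), validates vectors with the normalized-median test, and replaces
#' outliers by the local median.  The final grid is at the last pass's
#' resolution.
#'
#' @param imgA,imgB grayscale image matrices of identical size
#' @param dt inter-frame interval (s)
#' @param px_size pixel size (cm/px)
#' @param windows decreasing window side lengths (px), default 64/32/16
#' @param overlap window overlap fraction, default 0.5
#' @return tibble of class `piv_field`: `x`, `y` (px window centers),
#'   `dx`, `dy` (px), `u`, `v` (cm/s), `peak_ratio`, `valid`
#' @export
multipass_piv <- function(imgA, imgB, dt, px_size,
                          windows = c(64, 32, 16), overlap = 0.5) {
  stopifnot(all(dim(imgA) == dim(imgB)), dt > 0, px_size > 0)
  if (any(diff(windows) >= 0)) stop("window schedule must be decreasing")
  if (min(dim(imgA)) < windows[1])
    stop(sprintf("image (%d x %d) smaller than the first window (%d)",
                 nrow(imgA), ncol(imgA), windows[1]))
  pred <- NULL   # previous-pass field for window offsets
  field <- NULL
  for (w in windows) {
    g <- piv_grid(dim(imgA), w, overlap)
    rows <- expand.grid(y = g$cy, x = g$cx)
    n <- nrow(rows)
    dx <- dy <- pr <- rep(NA_real_, n)
    valid <- rep(FALSE, n)
    for (i in seq_len(n)) {
      px0 <- 0; py0 <- 0
      if (!is.null(pred)) {
        # nearest finite predictor; outliers were median-replaced already
        d2 <- (pred$x - rows$x[i])^2 + (pred$y - rows$y[i])^2
        d2[!is.finite(pred$dx)] <- Inf
        j <- which.min(d2)
        if (is.finite(d2[j])) { px0 <- round(pred$dx[j]); py0 <- round(pred$dy[j]) }
      }
      wa <- extract_window(imgA, rows$y[i], rows$x[i], w)
      wb <- extract_window(imgB, rows$y[i], rows$x[i], w, offy = py0, offx = px0)
      clipped <- FALSE
      if (is.null(wb)) {
        # predictor pushes the window off the image: fall back to the
        # unshifted window but flag the vector (in-plane loss at borders)
        clipped <- px0 != 0 || py0 != 0
        wb <- extract_window(imgB, rows$y[i], rows$x[i], w)
        px0 <- 0; py0 <- 0
      }
      if (is.null(wa) || is.null(wb)) next
      cc <- cross_correlate_window(wa, wb)
      if (!cc$valid) next
      dx[i] <- px0 + cc$dx
      dy[i] <- py0 + cc$dy
      pr[i] <- cc$peak_ratio
      valid[i] <- !clipped
    }
    field <- tibble::tibble(x = rows$x, y = rows$y, dx = dx, dy = dy,
                            peak_ratio = pr, valid = valid)
    field <- validate_vectors(field, flag_peak_ratio = w == windows[length(windows)])
    field <- replace_outliers(field)
    pred <- field
  }
  field$u <- field$dx * px_size / dt
  field$v <- field$dy * px_size / dt
  attr(field, "dt") <- dt
  attr(field, "px_size") <- px_size
  attr(field, "window") <- windows[length(windows)]
  class(field) <- c("piv_field", class(field))
  field
}

field_neighbors <- function(field, i) {
  ux <- sort(unique(field$x)); uy <- sort(unique(field$y))
  sx <- if (length(ux) > 1) min(diff(ux)) else 1
  sy <- if (length(uy) > 1) min(diff(uy)) else 1
  which(abs(field$x - field$x[i]) <= 1.5 * sx &
          abs(field$y - field$y[i]) <= 1.5 * sy &
          seq_len(nrow(field)) != i)
}

#' Flag spurious PIV vectors
#'
#' Normalized-median test (threshold 2, noise floor eps = 0.1 px) on the
#' 8-neighborhood, plus an optional weak-correlation flag for peak ratios
#' below 1.2.  Flagged vectors keep their values but `valid = FALSE`.
#'
#' @param field a `piv_field` (or compatible tibble)
#' @param threshold normalized-median threshold (default 2)
#' @param eps noise floor in px (default 0.1)
#' @param min_peak_ratio weak-correlation cutoff (default 1.2)
#' @param flag_peak_ratio apply the peak-ratio rule (default TRUE)
#' @return the field with `valid` updated
#' @export
validate_vectors <- function(field, threshold = 2, eps = 0.1,
                             min_peak_ratio = 1.2, flag_peak_ratio = TRUE) {
  n <- nrow(field)
  keep <- field$valid
  for (i in which(field$valid)) {
    nb <- field_neighbors(field, i)
    nb <- nb[field$valid[nb]]
    if (length(nb) < 3) next
    mx <- median(field$dx[nb]); my <- median(field$dy[nb])
    rx <- median(abs(field$dx[nb] - mx)); ry <- median(abs(field$dy[nb] - my))
    nrm <- sqrt((abs(field$dx[i] - mx) / (rx + eps))^2 +
                  (abs(field$dy[i] - my) / (ry + eps))^2)
    if (nrm > threshold) keep[i] <- FALSE
  }
  if (flag_peak_ratio)
    keep <- keep & (!is.finite(field$peak_ratio) |
                      field$peak_ratio >= min_peak_ratio)
  field$valid <- keep
  field
}

replace_outliers <- function(field) {
  bad <- which(!field$valid & is.finite(field$dx))
  for (i in bad) {
    nb <- field_neighbors(field, i)
    nb <- nb[field$valid[nb]]
    if (length(nb) >= 2) {
      field$dx[i] <- median(field$dx[nb])
      field$dy[i] <- median(field$dy[nb])
    }
  }
  field
}

#' Inlet velocity waveform from a PIV field sequence
#'
#' For each frame, averages the velocity component normal to the inlet
#' line over the valid vectors within a capture radius.  Frames with no
#' valid vector near the line are flagged as gaps and linearly
#' interpolated.
#'
#' @param fields list of `piv_field`s (one per frame pair)
#' @param inlet_line list with `p1`, `p2` (px endpoints of the line)
#' @param times frame times (s); defaults to `dt`-spaced from the fields
#' @param capture_radius distance from the line to include (px); default
#'   one final window size
#' @return tibble: `time`, `u_mean` (cm/s, positive along the line
#'   normal (+90 deg CCW from p1->p2)), `gap`
#' @export
extract_inlet_waveform <- function(fields, inlet_line, times = NULL,
                                   capture_radius = NULL) {
  if (is.null(capture_radius))
    capture_radius <- attr(fields[[1]], "window")
  if (is.null(times)) {
    dt <- attr(fields[[1]], "dt")
    times <- (seq_along(fields) - 1) * dt
  }
  p1 <- inlet_line$p1; p2 <- inlet_line$p2
  tv <- c(p2[1] - p1[1], p2[2] - p1[2])
  tv <- tv / sqrt(sum(tv^2))
  nv <- c(-tv[2], tv[1])
  u_mean <- vapply(fields, function(f) {
    rx <- f$x - p1[1]; ry <- f$y - p1[2]
    along <- rx * tv[1] + ry * tv[2]
    perp <- abs(rx * nv[1] + ry * nv[2])
    L <- sqrt(sum((p2 - p1)^2))
    sel <- f$valid & perp <= capture_radius & along >= -capture_radius &
      along <= L + capture_radius
    if (!any(sel)) return(NA_real_)
    mean(f$u[sel] * nv[1] + f$v[sel] * nv[2])
  }, numeric(1))
  gap <- !is.finite(u_mean)
  if (all(gap)) {
    warning("no valid vectors near the inlet line in any frame")
  } else if (any(gap)) {
    warning(sprintf("%d gap frame(s) near the inlet line; interpolating",
                    sum(gap)))
    u_mean[gap] <- approx(times[!gap], u_mean[!gap], xout = times[gap],
                          rule = 2)$y
  }
  tibble::tibble(time = times, u_mean = u_mean, gap = gap)
}
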