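# Tidiers and plots for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-step tidy summary of a simulation
#'
#' One row per stored state: time, kinetic energy, domain area and the
#' open-boundary flux, joined with the Newton convergence log.
#'
#' @param x a `cardio_sim`
#' @param ... unused
#' @return a tibble
#' @export
tidy.cardio_sim <- function(x, ...) {
  mb <- mass_balance(x)
  ke <- vapply(x$states, kinetic_energy, numeric(1), mesh = x$mesh)
  out <- tibble::tibble(time = mb$time, kinetic_energy = ke,
                        area = mb$area, flux_open = mb$flux_open,
                        dAdt = mb$dAdt)
  merge(out, x$log, by = "time", all.x = TRUE)
}

#' One-row summary of a simulation
#' @param x a `cardio_sim`
#' @param ... unused
#' @return a tibble: steps, convergence, Newton statistics, final energy
#' @export
glance.cardio_sim <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x$log),
    n_states = length(x$states),
    all_converged = all(x$log$converged),
    max_newton_iters = max(x$log$newton_iters),
    final_time = x$states[[length(x$states)]]$time,
    final_kinetic_energy = kinetic_energy(x$states[[length(x$states)]],
                                          x$mesh))
}

#' Plot a triangle mesh
#' @param object a `mesh2d`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mesh2d <- function(object, ...) {
  tri <- object$tri
  seg <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
               cbind(tri[, 3], tri[, 1]))
  seg <- unique(t(apply(seg, 1, sort)))
  d <- data.frame(x = object$coords[seg[, 1], 1],
                  y = object$coords[seg[, 1], 2],
                  xend = object$coords[seg[, 2], 1],
                  yend = object$coords[seg[, 2], 2])
  b <- data.frame(x = object$coords[object$loop, 1],
                  y = object$coords[object$loop, 2],
                  tag = object$loop_tags)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = d,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.2, color = "grey60") +
    ggplot2::geom_point(data = b,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$tag), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", color = NULL)
}

#' Plot a PIV vector field
#' @param object a `piv_field`
#' @param scale arrow length scale in px per (px displacement)
#' @param ... unused
#' @return a ggplot (y axis flipped to image convention)
#' @export
autoplot.piv_field <- function(object, scale = 3, ...) {
  d <- object[object$valid & is.finite(object$dx), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + scale * .data$dx,
                                       yend = .data$y + scale * .data$dy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "pt"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a hemodynamic time series
#' @param object a `hemodynamic_series`
#' @param ... unused
#' @return a ggplot with one panel per quantity
#' @export
autoplot.hemodynamic_series <- function(object, ...) {
  d <- as.data.frame(object)
  keep <- c("wss_peak_avg", "dP", "throat_flux")
  keep <- keep[vapply(keep, function(k) any(is.finite(d[[k]])), logical(1))]
  long <- do.call(rbind, lapply(keep, function(k)
    data.frame(time = d$time, value = d[[k]], quantity = k)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @importFrom ggplot2 .data
NULL
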