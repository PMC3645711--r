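# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.bl_timeseries <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "value", "window_mean")[c("time", "value", "window_mean") %in% names(x)]])
}

#' @exportS3Method generics::glance
glance.bl_timeseries <- function(x, ...) {
  tibble::tibble(
    mean = attr(x, "mean"), sd = attr(x, "sd"),
    n_frames = nrow(x),
    window_start = attr(x, "window")[1], window_end = attr(x, "window")[2],
    quantity = attr(x, "quantity") %||% NA_character_,
    units = attr(x, "units") %||% NA_character_
  )
}

#' @exportS3Method generics::glance
glance.bl_coordination <- function(x, ...) {
  tibble::tibble(
    mean = attr(x, "mean"), cutoff = attr(x, "cutoff"),
    exclusion = attr(x, "exclusion"), n_ref = attr(x, "n_ref"),
    n_frames = nrow(x)
  )
}

#' @exportS3Method generics::tidy
tidy.bl_kww <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "beta"),
    estimate = c(x$tau, x$beta)
  )
}

#' @exportS3Method generics::glance
glance.bl_kww <- function(x, ...) {
  tibble::tibble(
    tau = x$tau, beta = x$beta, n_points = x$n_points,
    rss = x$rss, converged = x$converged,
    fit_lo_ns = x$fit_window[1], fit_hi_ns = x$fit_window[2]
  )
}

#' @exportS3Method generics::tidy
tidy.bl_diffusion <- function(x, ...) {
  tibble::tibble(
    term = c("D_xy_A2_ns", "D_xy_cm2_s"),
    estimate = c(x$D_A2_ns, x$D_cm2_s)
  )
}

#' @exportS3Method generics::glance
glance.bl_diffusion <- function(x, ...) {
  tibble::tibble(
    D_A2_ns = x$D_A2_ns, D_cm2_s = x$D_cm2_s,
    r_squared = x$r_squared, alpha = x$alpha,
    nonlinear = x$nonlinear, negative_slope = x$negative_slope,
    fit_lo_ns = x$fit_window[1], fit_hi_ns = x$fit_window[2],
    n_points = x$n_points
  )
}

#' @exportS3Method generics::glance
glance.bl_tilt <- function(x, ...) {
  tibble::tibble(
    mean_deg = attr(x, "mean"), sd_deg = attr(x, "sd"),
    n_samples = attr(x, "n_samples")
  )
}

#' @exportS3Method generics::glance
glance.bl_summary <- function(x, ...) x$summary

#' @exportS3Method ggplot2::autoplot
autoplot.bl_timeseries <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "time (ns)",
      y = paste0(attr(object, "quantity") %||% "value",
                 " (", attr(object, "units") %||% "", ")")
    )
  if (!is.null(object$window_mean)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$window_mean), linewidth = 1)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.bl_density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z - z_center (Å)", y = "atoms / frame / Å")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bl_rdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "r (Å)", y = "g(r)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bl_scd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$carbon, y = .data$scd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "carbon number", y = expression(S[CD]))
}

#' @exportS3Method ggplot2::autoplot
autoplot.bl_raf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$raf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ns)", y = "RAF(t)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bl_msd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ns)", y = expression(MSD ~ (ring(A)^2)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.bl_tilt <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$angle, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$angle[1:2]) * 0.9) +
    ggplot2::labs(x = "tilt angle (deg)", y = "density")
}

#' @importFrom rlang .data
NULL
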