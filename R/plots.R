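#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_segment geom_abline labs facet_wrap vars coord_equal
#' @export
ggplot2::autoplot

#' @method autoplot sc_trace
#' @export
autoplot.sc_trace <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time_ms, y = .data$value)) +
    geom_line() +
    labs(x = "time (ms)", y = object$unit)
}

#' @method autoplot qepsc_sweep
#' @export
autoplot.qepsc_sweep <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::select("distance", "amplitude_pA", "rise_ms", "halfwidth_ms") |>
    tidyr::pivot_longer(-"distance", names_to = "metric")
  ggplot(long, aes(x = .data$distance, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(vars(.data$metric), scales = "free_y") +
    labs(x = "synapse distance (um)", y = NULL,
         title = "Distance dependence of the simulated qEPSC")
}

#' @method autoplot io_curve
#' @export
autoplot.io_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$linear_sum_mV, y = .data$peak_mV)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_line() + geom_point() +
    labs(x = "linear sum (mV)", y = "simulated EPSP peak (mV)",
         title = "Subthreshold input-output relationship")
}

#' @method autoplot distance_histogram
#' @export
autoplot.distance_histogram <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$bin_center, y = .data$density_per_um)) +
    geom_col(width = object$bin_hi[1] - object$bin_lo[1]) +
    labs(x = "path distance from soma (um)", y = "puncta density (1/um)")
}

#' @method autoplot mepsc_synthesis
#' @export
autoplot.mepsc_synthesis <- function(object, ...) {
  autoplot(object$trace) +
    labs(title = "Synthesized mean miniature EPSC")
}

#' Plot a morphology in the xy-plane
#'
#' @param m A [morphology()].
#' @return A ggplot.
#' @export
plot_morphology <- function(m) {
  nd <- m$nodes
  pidx <- node_parent_index(m)
  seg <- tibble::tibble(
    x = nd$x[pidx[-1]], y = nd$y[pidx[-1]],
    xend = nd$x[-1], yend = nd$y[-1], kind = nd$kind[-1]
  )
  ggplot(seg) +
    geom_segment(aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$kind)) +
    geom_point(data = nd[nd$kind == "soma", ], aes(x = .data$x, y = .data$y),
               size = 3) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)")
}
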