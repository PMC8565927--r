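#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a voltage-clamp simulation into a time/current tibble
#'
#' @param x A `vclamp_sim`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `clamp_current_pA`, `v_soma_mV`.
#' @method tidy vclamp_sim
#' @export
tidy.vclamp_sim <- function(x, ...) {
  tibble::tibble(time_ms = x$times,
                 clamp_current_pA = x$clamp_current$samples,
                 v_soma_mV = x$voltages[1, ])
}

#' @rdname tidy.vclamp_sim
#' @method glance vclamp_sim
#' @export
glance.vclamp_sim <- function(x, ...) {
  i <- x$clamp_current$samples
  tibble::tibble(
    n_compartments = nrow(x$model$compartments),
    dt_ms = x$dt, duration_ms = x$duration, hold_mV = x$hold,
    series_resistance_MOhm = x$series_resistance,
    peak_deflection_pA = max(abs(i - i[1]))
  )
}

#' Tidy a current-clamp simulation into a long voltage tibble
#'
#' @param x A `cclamp_sim`.
#' @param compartments Compartment ids to extract (default: the soma).
#' @param ... Unused.
#' @return Tibble with `time_ms`, `compartment`, `v_mV`.
#' @method tidy cclamp_sim
#' @export
tidy.cclamp_sim <- function(x, compartments = 1, ...) {
  purrr::map_dfr(compartments, function(cid) {
    idx <- which(x$model$compartments$id == cid)
    tibble::tibble(time_ms = x$times, compartment = cid,
                   v_mV = x$voltages[idx, ])
  })
}

#' @rdname tidy.cclamp_sim
#' @method glance cclamp_sim
#' @export
glance.cclamp_sim <- function(x, ...) {
  v <- x$voltages[1, ]
  tibble::tibble(n_compartments = nrow(x$model$compartments), dt_ms = x$dt,
                 duration_ms = x$duration,
                 peak_soma_epsp_mV = max(v) - v[1])
}

#' @method tidy ppr_sim
#' @export
tidy.ppr_sim <- function(x, ...) {
  tibble::tibble(ppr = x$ppr, amplitude1_pA = x$amplitude1_pA,
                 amplitude2_pA = x$amplitude2_pA,
                 distance = x$params$distance,
                 conductance_ratio = x$params$conductance_ratio,
                 interval_ms = x$params$interval)
}

#' @method glance ppr_sim
#' @export
glance.ppr_sim <- function(x, ...) tidy.ppr_sim(x)

#' @method tidy qepsc_sweep
#' @export
tidy.qepsc_sweep <- function(x, ...) {
  out <- as_tibble(x)
  out$trace <- NULL
  out
}

#' @method glance qepsc_sweep
#' @export
glance.qepsc_sweep <- function(x, ...) {
  soma <- x$amplitude_pA[x$distance == 0]
  tibble::tibble(
    n_distances = nrow(x),
    somatic_amplitude_pA = if (length(soma)) soma else NA_real_,
    min_amplitude_pA = min(x$amplitude_pA),
    max_halfwidth_ms = max(x$halfwidth_ms)
  )
}

#' @method tidy io_curve
#' @export
tidy.io_curve <- function(x, ...) {
  out <- as_tibble(x)
  out$deficit <- (out$linear_sum_mV - out$peak_mV) / out$linear_sum_mV
  out
}

#' @method tidy mepsc_synthesis
#' @export
tidy.mepsc_synthesis <- function(x, ...) as_tibble(x$trace)

#' @method glance mepsc_synthesis
#' @export
glance.mepsc_synthesis <- function(x, ...) {
  s <- x$stats
  tibble::tibble(amplitude_pA = s$amplitude, rise_ms = s$rise_10_90,
                 halfwidth_ms = s$half_width, taudecay_ms = s$tau_decay,
                 n_bins = nrow(x$weights))
}

#' @method tidy sc_trace
#' @export
tidy.sc_trace <- function(x, ...) as_tibble(x)
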