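# Simulation protocols composed from the compartmental solver: distance
# sweeps of quantal EPSCs under somatic clamp, paired-pulse stimulation,
# subthreshold input-output curves, dendritic sublinearity, and synapse-
# distribution-weighted synthesis of the mean miniature EPSC.

primary_of_nodes <- function(m) {
  nd <- m$nodes
  pidx <- node_parent_index(m)
  prim <- integer(nrow(nd))
  counter <- 0L
  for (i in seq_len(nrow(nd))[-1]) {
    if (nd$kind[i] == "dendrite" && nd$kind[pidx[i]] == "soma") {
      counter <- counter + 1L
      prim[i] <- counter
    } else {
      prim[i] <- prim[pidx[i]]
    }
  }
  prim
}

restrict_to_dendrite <- function(model, dendrite) {
  prim <- primary_of_nodes(model$morphology)
  comp_prim <- prim[model$compartments$node]
  model$compartments$id[comp_prim == dendrite | model$compartments$kind == "soma"]
}

place_synapse <- function(model, g, distance, dendrite = NULL, onset = NULL) {
  if (!is.null(dendrite)) {
    allowed <- restrict_to_dendrite(model, dendrite)
    sub <- model
    sub$compartments <- model$compartments[model$compartments$id %in% allowed, ]
    loc <- compartment_at_distance(sub, distance)
  } else {
    loc <- compartment_at_distance(model, distance)
  }
  g$location <- loc
  if (!is.null(onset)) g$onset <- onset
  g
}

#' Quantal EPSC distance sweep under ideal somatic voltage clamp
#'
#' Runs one clamp simulation per synapse distance (distance 0 places the
#' synapse on the soma), measures the clamp-current transient with the
#' standard event conventions, and records the peak local depolarization at
#' the synapse site.
#'
#' @param model A [compartmentalize()]d model.
#' @param g A [synapse_spec()] (its location/onset are set per distance).
#' @param distances Strictly increasing path distances from the soma center,
#'   um; include 0 for the somatic reference.
#' @param dendrite Optional primary-dendrite index to restrict placement to
#'   one subtree (for per-dendrite sweeps on branched trees).
#' @param hold Holding potential, mV.
#' @param dt Time step, ms.
#' @param duration Simulated time, ms.
#' @param onset Synapse onset, ms (allows a pre-event baseline).
#' @return A `qepsc_sweep` tibble: `distance`, `compartment`,
#'   `amplitude_pA`, `rise_ms`, `halfwidth_ms`, `taudecay_ms`,
#'   `local_vpeak_mV`, and a `trace` list-column of clamp-current traces.
#' @export
qepsc_distance_sweep <- function(model, g = quantal_conductance("immature"),
                                 distances = seq(0, 90, by = 10),
                                 dendrite = NULL, hold = -70, dt = 0.005,
                                 duration = 8, onset = 1) {
  if (any(distances < 0)) rlang::abort("distances must be nonnegative")
  if (length(distances) > 1 && any(diff(distances) <= 0)) {
    rlang::abort("distances must be strictly increasing")
  }
  rows <- purrr::map(distances, function(x) {
    gs <- place_synapse(model, g, x, dendrite, onset = onset)
    sim <- simulate_voltage_clamp(model, gs, hold = hold, dt = dt,
                                  duration = duration)
    st <- measure_event(sim$clamp_current, onset = onset)
    v_loc <- sim$voltages[which(model$compartments$id == gs$location), ]
    tibble::tibble(
      distance = x, compartment = gs$location,
      amplitude_pA = st$amplitude, rise_ms = st$rise_10_90,
      halfwidth_ms = st$half_width, taudecay_ms = st$tau_decay,
      local_vpeak_mV = max(v_loc) - v_loc[1],
      trace = list(sim$clamp_current)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qepsc_sweep", class(out))
  attr(out, "params") <- list(g = g, hold = hold, dt = dt,
                              duration = duration, onset = onset)
  out
}

#' Paired-pulse protocol at one synaptic site
#'
#' Two conductances at the same site, the second scaled by
#' `conductance_ratio`; the paired-pulse ratio (PPR) is the amplitude of the
#' second clamp-current deflection (measured from the decayed tail baseline
#' preceding it) over the first. At an ideally clamped soma the readout is
#' linear in conductance, so the somatic PPR equals the conductance ratio;
#' on dendrites the local depolarization during the (larger) second
#' conductance reduces driving force and PPR falls below it.
#'
#' @param model A [compartmentalize()]d model.
#' @param g1 First-pulse [synapse_spec()].
#' @param conductance_ratio Scale of the second conductance relative to the
#'   first.
#' @param interval Inter-pulse interval, ms.
#' @param distance Synapse path distance from the soma center, um (0 = soma).
#' @param dendrite Optional primary-dendrite index.
#' @param hold Holding potential, mV.
#' @param dt Time step, ms.
#' @param measure_window Peak-search window per pulse, ms; must not exceed
#'   the interval.
#' @return A `ppr_sim` list: `ppr`, `amplitude1_pA`, `amplitude2_pA`, the
#'   clamp-current `trace`, and parameters.
#' @export
simulate_ppr <- function(model, g1 = quantal_conductance("immature"),
                         conductance_ratio = 2.25, interval = 20,
                         distance = 0, dendrite = NULL, hold = -70,
                         dt = 0.005, measure_window = 5) {
  if (interval <= 0) rlang::abort("interval must be positive")
  if (measure_window > interval) {
    rlang::abort("measurement windows overlap: measure_window exceeds the interval")
  }
  onset1 <- 1
  g1p <- place_synapse(model, g1, distance, dendrite, onset = onset1)
  g2p <- g1p
  g2p$gmax <- g1p$gmax * conductance_ratio
  g2p$onset <- onset1 + interval
  sim <- simulate_voltage_clamp(model, list(g1p, g2p), hold = hold, dt = dt,
                                duration = onset1 + interval + measure_window + 2)
  s1 <- measure_event(sim$clamp_current, onset1, peak_window = measure_window)
  s2 <- measure_event(sim$clamp_current, g2p$onset, peak_window = measure_window)
  structure(list(
    ppr = s2$amplitude / s1$amplitude,
    amplitude1_pA = s1$amplitude, amplitude2_pA = s2$amplitude,
    trace = sim$clamp_current,
    params = list(conductance_ratio = conductance_ratio, interval = interval,
                  distance = distance, location = g1p$location, hold = hold,
                  dt = dt)
  ), class = "ppr_sim")
}

#' @export
print.ppr_sim <- function(x, ...) {
  cat(sprintf("<ppr_sim> PPR %.4f (A1 %.2f pA, A2 %.2f pA) at %g um, ratio %g\n",
              x$ppr, x$amplitude1_pA, x$amplitude2_pA, x$params$distance,
              x$params$conductance_ratio))
  invisible(x)
}

#' Subthreshold quantal input-output curve under current clamp
#'
#' Simulates somatically recorded EPSPs for a synaptic conductance scaled to
#' increasing numbers of quanta at one site, together with the linear
#' prediction extrapolated from a small reference conductance
#' (`reference_quanta`, a conductance to which the voltage response is
#' linearly related).
#'
#' @param model A [compartmentalize()]d model.
#' @param g_unit One-quantum [synapse_spec()].
#' @param quanta Numbers of quanta to simulate.
#' @param distance Synapse path distance, um (0 = soma).
#' @param dendrite Optional primary-dendrite index.
#' @param reference_quanta Reference conductance scale defining the linear
#'   regime.
#' @param dt Time step, ms.
#' @param duration Simulated time, ms.
#' @return An `io_curve` tibble: `quanta`, `peak_mV` (somatic EPSP peak),
#'   `linear_sum_mV`; the reference response is stored as attribute
#'   `reference`.
#' @export
quantal_io_curve <- function(model, g_unit = quantal_conductance("immature"),
                             quanta = c(1, 2, 5, 10, 15, 20), distance = 0,
                             dendrite = NULL, reference_quanta = 0.1,
                             dt = 0.01, duration = 15) {
  if (any(quanta <= 0)) rlang::abort("quanta must be positive")
  onset <- 1
  peak_for <- function(q) {
    gq <- place_synapse(model, g_unit, distance, dendrite, onset = onset)
    gq$gmax <- g_unit$gmax * q
    sim <- simulate_current_clamp(model, gq, dt = dt, duration = duration)
    v <- sim$voltages[1, ]
    max(v) - v[1]
  }
  peak_ref <- peak_for(reference_quanta)
  peaks <- vapply(quanta, peak_for, numeric(1))
  out <- tibble::tibble(quanta = quanta, peak_mV = peaks,
                        linear_sum_mV = quanta * peak_ref / reference_quanta)
  class(out) <- c("io_curve", class(out))
  attr(out, "reference") <- list(quanta = reference_quanta, peak_mV = peak_ref,
                                 distance = distance)
  out
}

#' Dendritic sublinearity from paired input-output curves
#'
#' For each number of quanta, each site's EPSP peak is normalized to its own
#' reference (per-quantum) response; the dendritic sublinearity is one minus
#' the ratio of the normalized dendritic to normalized somatic amplitude.
#'
#' @param io_soma,io_dendrite [quantal_io_curve()] results on the same
#'   quanta grid (somatic and dendritic site).
#' @return A tibble: `quanta`, `sublinearity` (fraction in `[0, 1)` for
#'   passive models).
#' @export
dendritic_sublinearity <- function(io_soma, io_dendrite) {
  if (!identical(io_soma$quanta, io_dendrite$quanta)) {
    rlang::abort("input-output curves are on different quanta grids")
  }
  ref_s <- attr(io_soma, "reference")
  ref_d <- attr(io_dendrite, "reference")
  per_quantum <- function(io, ref) {
    (io$peak_mV / io$quanta) / (ref$peak_mV / ref$quanta)
  }
  rel_s <- per_quantum(io_soma, ref_s)
  rel_d <- per_quantum(io_dendrite, ref_d)
  tibble::tibble(quanta = io_soma$quanta, sublinearity = 1 - rel_d / rel_s)
}

#' Synapse-distance weights from binned counts
#'
#' Normalizes per-bin synapse counts (soma bin included, at distance 0) into
#' relative frequencies summing to one, keyed by bin-center distance.
#'
#' @param distance Bin-representative distances, um (0 for the soma bin).
#' @param count Synapse counts per bin.
#' @return A tibble: `distance`, `weight`.
#' @export
synapse_distance_weights <- function(distance, count) {
  if (any(count < 0)) rlang::abort("counts must be nonnegative")
  if (sum(count) <= 0) rlang::abort("at least one bin must have a count")
  tibble::tibble(distance = distance, weight = count / sum(count))
}

#' Synthesize the mean miniature EPSC from distance-weighted quantal EPSCs
#'
#' Pointwise weighted average of the aligned simulated quantal EPSC traces of
#' a distance sweep, each weighted by the relative frequency of synapses at
#' that distance; this emulates miniature events arising with equal
#' probability at every synapse. With a list of per-dendrite sweeps the
#' per-dendrite syntheses are averaged pointwise (pooled mode).
#'
#' @param sweep A [qepsc_distance_sweep()] result, or a list of them (one per
#'   dendrite).
#' @param weights A tibble from [synapse_distance_weights()] whose
#'   `distance` values match the sweep's, in order.
#' @return An `mepsc_synthesis` list: `trace` (pA), `stats` (event
#'   measurements), `weights`.
#' @export
synthesize_mean_mepsc <- function(sweep, weights) {
  if (abs(sum(weights$weight) - 1) > 1e-6) {
    rlang::abort("weights must sum to 1 (tolerance 1e-6)")
  }
  one <- function(sw) {
    if (!identical(as.numeric(sw$distance), as.numeric(weights$distance))) {
      rlang::abort("sweep distances do not match the weight bins")
    }
    mat <- vapply(sw$trace, function(tr) tr$samples,
                  numeric(length(sw$trace[[1]]$samples)))
    as.vector(mat %*% weights$weight)
  }
  sweeps <- if (inherits(sweep, "qepsc_sweep")) list(sweep) else sweep
  mixed <- lapply(sweeps, one)
  avg <- Reduce(`+`, mixed) / length(mixed)
  tr0 <- sweeps[[1]]$trace[[1]]
  onset <- attr(sweeps[[1]], "params")$onset
  tr <- new_trace(avg, dt = tr0$dt, t0 = tr0$t0, unit = tr0$unit)
  structure(list(trace = tr, stats = measure_event(tr, onset = onset),
                 weights = weights),
            class = "mepsc_synthesis")
}

#' @export
print.mepsc_synthesis <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<mepsc_synthesis> amplitude %.2f pA, rise %.3f ms, half-width %.3f ms, tau_decay %.3f ms\n",
              s$amplitude, s$rise_10_90, s$half_width, s$tau_decay))
  invisible(x)
}
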