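# Internal unit system: um, ms, mV, uS, nA, nF. Boundary quantities use the
# conventional units of passive membrane parameters: Rm ohm cm^2, Ri ohm cm,
# Cm uF/cm^2. With g in uS, V in mV and C in nF, currents are in nA and
# C dV/dt is consistent without further conversion.

#' Passive membrane properties
#'
#' @param Cm Specific membrane capacitance, uF/cm^2.
#' @param Rm Specific membrane resistance, ohm cm^2.
#' @param Ri Internal (axial) resistivity, ohm cm.
#' @param E_leak Leak reversal potential, mV. Defaults to -70 mV so that the
#'   resting potential equals the conventional -70 mV holding potential.
#' @return A `passive_properties` list.
#' @export
passive_properties <- function(Cm = 0.9, Rm = 20000, Ri = 150, E_leak = -70) {
  if (Cm <= 0 || Rm <= 0 || Ri <= 0) {
    rlang::abort("Cm, Rm and Ri must all be positive")
  }
  structure(list(Cm = Cm, Rm = Rm, Ri = Ri, E_leak = E_leak),
            class = "passive_properties")
}

#' Steady-state space constant of an infinite cable
#'
#' `lambda_DC = sqrt(d Rm / (4 Ri))`: the distance over which a steady-state
#' membrane voltage decays by 1/e along an infinite uniform cable.
#'
#' @param d Cable diameter, um.
#' @param Rm Specific membrane resistance, ohm cm^2.
#' @param Ri Axial resistivity, ohm cm.
#' @return Space constant, um.
#' @export
lambda_dc <- function(d, Rm, Ri) {
  if (any(d <= 0) || any(Rm <= 0) || any(Ri <= 0)) {
    rlang::abort("d, Rm and Ri must all be positive")
  }
  1e4 * sqrt((d * 1e-4) * Rm / (4 * Ri))
}

#' Frequency-dependent space constant of an infinite cable
#'
#' Full form `lambda_AC = lambda_DC sqrt(2 / (1 + sqrt(1 + (2 pi f tau_m)^2)))`
#' with `tau_m = Rm Cm`. For signal frequencies well above 100 Hz this is
#' approximated by the simplified form `sqrt(d / (4 pi f Ri Cm))`, which no
#' longer depends on Rm.
#'
#' @param d Cable diameter, um.
#' @param Rm Specific membrane resistance, ohm cm^2 (unused in the simplified
#'   form).
#' @param Ri Axial resistivity, ohm cm.
#' @param Cm Specific membrane capacitance, uF/cm^2.
#' @param f Signal frequency, Hz.
#' @param simplified Use the high-frequency approximation.
#' @return Space constant, um.
#' @export
lambda_ac <- function(d, Rm = NULL, Ri, Cm, f, simplified = FALSE) {
  if (any(d <= 0) || any(Ri <= 0) || any(Cm <= 0) || any(f <= 0)) {
    rlang::abort("d, Ri, Cm and f must all be positive")
  }
  if (simplified) {
    return(1e4 * sqrt((d * 1e-4) / (4 * pi * f * Ri * (Cm * 1e-6))))
  }
  if (is.null(Rm) || any(Rm <= 0)) {
    rlang::abort("the full form requires a positive Rm")
  }
  tau_s <- Rm * Cm * 1e-6
  lambda_dc(d, Rm, Ri) * sqrt(2 / (1 + sqrt(1 + (2 * pi * f * tau_s)^2)))
}

#' Membrane time constant
#'
#' @param Rm Specific membrane resistance, ohm cm^2.
#' @param Cm Specific membrane capacitance, uF/cm^2.
#' @return `Rm * Cm` expressed in ms.
#' @export
membrane_time_constant <- function(Rm, Cm) {
  if (any(Rm <= 0) || any(Cm <= 0)) rlang::abort("Rm and Cm must be positive")
  Rm * Cm * 1e-3
}

#' Quantal synaptic conductance specification
#'
#' An unnormalized difference of two exponentials,
#' `g(t) = gmax (exp(-(t - onset)/tau1) - exp(-(t - onset)/tau0))`,
#' zero before `onset`. Note `gmax` is a scale, not the peak; see
#' [biexp_peak()].
#'
#' @param tau0 Rise time constant, ms.
#' @param tau1 Decay time constant, ms; must exceed `tau0`.
#' @param gmax Conductance scale, uS.
#' @param e_rev Synaptic reversal potential, mV.
#' @param onset Conductance onset time, ms.
#' @param location Compartment id carrying the synapse (set when used in a
#'   simulation).
#' @return A `synapse_spec` list.
#' @export
synapse_spec <- function(tau0 = 0.073, tau1 = 0.26, gmax = 0.004,
                         e_rev = 0, onset = 0, location = NA_integer_) {
  if (!(tau0 > 0 && tau1 > tau0)) rlang::abort("require 0 < tau0 < tau1")
  if (gmax <= 0) rlang::abort("gmax must be positive")
  structure(list(tau0 = tau0, tau1 = tau1, gmax = gmax, e_rev = e_rev,
                 onset = onset, location = location),
            class = "synapse_spec")
}

#' Quantal conductance presets
#'
#' Developmental-stage presets for the AMPA-receptor quantal conductance:
#' immature (rise 0.073 ms, decay 0.26 ms, scale 0.004 uS, peak 0.00175 uS)
#' and adult (rise 0.072 ms, decay 0.24 ms, scale 0.0032 uS, peak 0.00133 uS).
#'
#' @param stage `"immature"` or `"adult"`.
#' @param ... Overrides passed to [synapse_spec()].
#' @return A [synapse_spec()].
#' @export
quantal_conductance <- function(stage = c("immature", "adult"), ...) {
  stage <- match.arg(stage)
  defaults <- switch(stage,
    immature = list(tau0 = 0.073, tau1 = 0.26, gmax = 0.004),
    adult = list(tau0 = 0.072, tau1 = 0.24, gmax = 0.0032)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synapse_spec, args)
}

#' Evaluate a biexponential conductance waveform
#'
#' @param t Times, ms.
#' @param s A [synapse_spec()].
#' @return Conductance values, uS (zero before onset).
#' @export
biexp_conductance <- function(t, s) {
  tt <- t - s$onset
  g <- ifelse(tt <= 0, 0, s$gmax * (exp(-tt / s$tau1) - exp(-tt / s$tau0)))
  g
}

#' Peak time, peak value and half-width of a biexponential conductance
#'
#' The peak time has the closed form
#' `t_peak = tau1 tau0 / (tau1 - tau0) * log(tau1 / tau0)` (relative to
#' onset); the half-maximum crossing times are found by root finding on the
#' continuous waveform.
#'
#' @param s A [synapse_spec()].
#' @return `biexp_peak_time`: peak time after onset, ms. `biexp_peak`: peak
#'   conductance, uS. `biexp_half_width`: full width at half maximum, ms.
#' @export
biexp_peak_time <- function(s) {
  s$tau1 * s$tau0 / (s$tau1 - s$tau0) * log(s$tau1 / s$tau0)
}

#' @rdname biexp_peak_time
#' @export
biexp_peak <- function(s) {
  tp <- biexp_peak_time(s)
  s$gmax * (exp(-tp / s$tau1) - exp(-tp / s$tau0))
}

#' @rdname biexp_peak_time
#' @export
biexp_half_width <- function(s) {
  tp <- biexp_peak_time(s)
  half <- biexp_peak(s) / 2
  f <- function(t) biexp_conductance(t + s$onset, s) - half
  t_up <- stats::uniroot(f, c(1e-9, tp), tol = 1e-12)$root
  t_hi <- tp
  while (f(t_hi) > 0) t_hi <- t_hi * 2
  t_dn <- stats::uniroot(f, c(tp, t_hi), tol = 1e-12)$root
  t_dn - t_up
}

#' Discretize a morphology into a passive compartmental model
#'
#' The soma is one isopotential spherical compartment of area `pi d^2`;
#' dendrites are split into cylinders of length at most
#' `max_compartment_length`, each with the local diameter. Axial resistance
#' between compartment centers follows `4 Ri dx / (pi d^2)` composed from the
#' half-lengths on either side (the soma contributes none, being
#' isopotential).
#'
#' @param m A [morphology()].
#' @param p A [passive_properties()].
#' @param max_compartment_length Maximum cylinder length, um.
#' @return A `compartmental_model`: a list with a `compartments` tibble
#'   (geometry, membrane area in cm^2, capacitance in nF, leak and axial
#'   conductance in uS, center path distance from the soma center in um),
#'   the properties, and the source morphology.
#' @export
compartmentalize <- function(m, p, max_compartment_length = 1) {
  stopifnot(inherits(m, "morphology"), inherits(p, "passive_properties"))
  if (max_compartment_length <= 0) {
    rlang::abort("max_compartment_length must be positive")
  }
  nd <- m$nodes
  pidx <- node_parent_index(m)
  elen <- node_edge_lengths(m)
  ndist <- node_path_distances(m, "soma_center")

  soma_d <- 2 * nd$radius[1]
  rows <- vector("list", nrow(nd))
  rows[[1]] <- list(parent = 0L, kind = "soma", x = nd$x[1], y = nd$y[1], z = nd$z[1],
                    length_um = soma_d, diam_um = soma_d,
                    area_um2 = pi * soma_d^2, half_rax = 0,
                    path_distance = 0, node = 1L)
  # compartment index of the distal end of each node's edge chain
  node_comp <- integer(nrow(nd))
  node_comp[1] <- 1L
  n_comp <- 1L
  comp <- list()
  comp[[1]] <- rows[[1]]
  for (i in seq_len(nrow(nd))[-1]) {
    if (nd$kind[i] == "soma") { # contiguous soma cluster: merge into root
      node_comp[i] <- 1L
      next
    }
    L <- elen[i]
    d_um <- 2 * nd$radius[i]
    nseg <- max(1L, ceiling(L / max_compartment_length - 1e-9))
    dx <- L / nseg
    parent_comp <- node_comp[pidx[i]]
    p0 <- c(nd$x[pidx[i]], nd$y[pidx[i]], nd$z[pidx[i]])
    p1 <- c(nd$x[i], nd$y[i], nd$z[i])
    base_dist <- ndist[pidx[i]]
    for (j in seq_len(nseg)) {
      frac <- (j - 0.5) / nseg
      n_comp <- n_comp + 1L
      # half axial resistance of this cylinder, ohm (um units -> 1e4 factor)
      half_rax <- 4 * p$Ri * (dx / 2) * 1e4 / (pi * d_um^2)
      comp[[n_comp]] <- list(parent = parent_comp, kind = nd$kind[i],
                             x = p0[1] + frac * (p1[1] - p0[1]),
                             y = p0[2] + frac * (p1[2] - p0[2]),
                             z = p0[3] + frac * (p1[3] - p0[3]),
                             length_um = dx, diam_um = d_um,
                             area_um2 = pi * d_um * dx, half_rax = half_rax,
                             path_distance = base_dist + (j - 0.5) * dx,
                             node = i)
      parent_comp <- n_comp
    }
    node_comp[i] <- parent_comp
  }
  comps <- dplyr::bind_rows(lapply(comp, tibble::as_tibble_row))
  comps$id <- seq_len(nrow(comps))
  area_cm2 <- comps$area_um2 * 1e-8
  comps$area_cm2 <- area_cm2
  comps$c_nF <- area_cm2 * p$Cm * 1e3
  comps$g_leak_uS <- area_cm2 / p$Rm * 1e6
  # axial conductance to parent: series of the two half-cylinder resistances
  g_ax <- rep(NA_real_, nrow(comps))
  for (i in seq_len(nrow(comps))[-1]) {
    r_total <- comps$half_rax[i] + comps$half_rax[comps$parent[i]]
    g_ax[i] <- 1e6 / r_total
  }
  comps$g_axial_uS <- g_ax
  comps <- comps[, c("id", "parent", "kind", "node", "x", "y", "z",
                     "length_um", "diam_um", "area_cm2", "c_nF",
                     "g_leak_uS", "g_axial_uS", "path_distance")]
  model <- structure(list(compartments = comps, properties = p, morphology = m),
                     class = "compartmental_model")
  analytic <- pi * soma_d^2 * 1e-8 +
    sum(pi * 2 * nd$radius[-1][nd$kind[-1] != "soma"] * elen[-1][nd$kind[-1] != "soma"]) * 1e-8
  if (abs(sum(area_cm2) - analytic) > 1e-3 * analytic) {
    rlang::abort("discretization lost membrane area (internal error)")
  }
  model
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat(sprintf("<compartmental_model> %d compartments, total area %.4g cm^2, Rm %g, Ri %g, Cm %g\n",
              nrow(x$compartments), sum(x$compartments$area_cm2),
              x$properties$Rm, x$properties$Ri, x$properties$Cm))
  invisible(x)
}

#' Find the compartment nearest a dendritic path distance
#'
#' Synapse placement rule: the dendritic compartment whose center path
#' distance (from the soma center) is nearest to `distance_um`; ties go to
#' the more distal compartment. Distance 0 selects the soma.
#'
#' @param model A [compartmentalize()]d model.
#' @param distance_um Target path distance, um.
#' @return Compartment id.
#' @export
compartment_at_distance <- function(model, distance_um) {
  comps <- model$compartments
  if (distance_um == 0) return(comps$id[comps$kind == "soma"][1])
  dend <- comps[comps$kind == "dendrite", ]
  if (nrow(dend) == 0) rlang::abort("model has no dendritic compartments")
  if (distance_um > max(dend$path_distance) + dend$length_um[which.max(dend$path_distance)] / 2) {
    rlang::abort(sprintf("distance %.3g um beyond the longest dendrite (max center %.3g um)",
                         distance_um, max(dend$path_distance)))
  }
  err <- abs(dend$path_distance - distance_um)
  cand <- which(err < min(err) + 1e-9)
  dend$id[cand[which.max(dend$path_distance[cand])]]
}

# --- solver internals -------------------------------------------------------

# Assemble static solver arrays from a model.
solver_arrays <- function(model) {
  comps <- model$compartments
  n <- nrow(comps)
  parent <- comps$parent
  g_ax <- comps$g_axial_uS
  g_ax[1] <- 0
  g_static <- comps$g_leak_uS
  # diagonal gets each axial conductance on both sides of the edge
  for (i in seq_len(n)[-1]) {
    g_static[i] <- g_static[i] + g_ax[i]
    g_static[parent[i]] <- g_static[parent[i]] + g_ax[i]
  }
  list(n = n, parent = parent, g_ax = g_ax, g_static = g_static,
       g_leak = comps$g_leak_uS, c_nF = comps$c_nF,
       E_leak = model$properties$E_leak)
}

# One linear tree solve (Hines-ordered symmetric elimination).
# d: diagonal, u: coupling to parent (u[1] unused), rhs; fixed_root: if not
# NULL, the root voltage is clamped to this value (Dirichlet).
tree_solve <- function(d, u, parent, rhs, fixed_root = NULL) {
  n <- length(d)
  for (i in n:2) {
    p <- parent[i]
    f <- u[i] / d[i]
    d[p] <- d[p] - f * u[i]
    rhs[p] <- rhs[p] - f * rhs[i]
  }
  v <- numeric(n)
  v[1] <- if (is.null(fixed_root)) rhs[1] / d[1] else fixed_root
  if (n > 1) {
    for (i in 2:n) v[i] <- (rhs[i] - u[i] * v[parent[i]]) / d[i]
  }
  v
}

# Steady-state solve: G v = b (+ optional Dirichlet root).
steady_state <- function(arr, b, fixed_root = NULL, g_extra_diag = NULL) {
  d <- arr$g_static
  if (!is.null(g_extra_diag)) d <- d + g_extra_diag
  tree_solve(d, -arr$g_ax, arr$parent, b, fixed_root)
}

# Precompute per-synapse conductance matrices on the time grid; returns
# g_mid (evaluated at interval midpoints, n_syn x (nt-1)) and g_on
# (at sample times, n_syn x nt), plus location index and e_rev per synapse.
synapse_drive <- function(model, synapses, times) {
  if (inherits(synapses, "synapse_spec")) synapses <- list(synapses)
  if (length(synapses) == 0) {
    return(list(loc = integer(0), e_rev = numeric(0),
                g_mid = matrix(0, 0, length(times) - 1),
                g_on = matrix(0, 0, length(times))))
  }
  loc <- vapply(synapses, function(s) {
    if (is.na(s$location)) rlang::abort("synapse_spec has no location; set `location`")
    as.integer(s$location)
  }, integer(1))
  if (!all(loc %in% model$compartments$id)) {
    rlang::abort("synapse location is not a compartment id of the model")
  }
  dt <- times[2] - times[1]
  t_mid <- times[-length(times)] + dt / 2
  g_mid <- t(vapply(synapses, function(s) biexp_conductance(t_mid, s),
                    numeric(length(t_mid))))
  g_on <- t(vapply(synapses, function(s) biexp_conductance(times, s),
                   numeric(length(times))))
  e_rev <- vapply(synapses, function(s) s$e_rev, numeric(1))
  list(loc = loc, e_rev = e_rev, g_mid = g_mid, g_on = g_on)
}

# Core integrator. Crank-Nicolson via the half-step trick: a backward-Euler
# half step with midpoint coefficients, then extrapolation; the first full
# step is plain backward Euler to damp any inconsistent initial transient.
# inj: optional list(idx, current) with current a function(t_ms) -> nA.
integrate_tree <- function(arr, syn, times, v0, fixed_root = NULL,
                           g_electrode = 0, v_electrode = 0, inj = NULL) {
  n <- arr$n
  nt <- length(times)
  dt <- times[2] - times[1]
  V <- matrix(0, n, nt)
  V[, 1] <- v0
  u <- -arr$g_ax
  b_base <- arr$g_leak * arr$E_leak
  if (g_electrode > 0) b_base[1] <- b_base[1] + g_electrode * v_electrode
  g_base <- arr$g_static
  if (g_electrode > 0) g_base[1] <- g_base[1] + g_electrode
  has_syn <- length(syn$loc) > 0
  v <- v0
  for (k in seq_len(nt - 1)) {
    first <- k == 1
    cc <- if (first) arr$c_nF / dt else 2 * arr$c_nF / dt
    d <- cc + g_base
    rhs <- cc * v + b_base
    if (!is.null(inj)) {
      t_eval <- if (first) times[2] else times[k] + dt / 2
      rhs[inj$idx] <- rhs[inj$idx] + inj$current(t_eval)
    }
    if (has_syn) {
      g_now <- if (first) syn$g_on[, 2] else syn$g_mid[, k]
      for (s in seq_along(syn$loc)) {
        d[syn$loc[s]] <- d[syn$loc[s]] + g_now[s]
        rhs[syn$loc[s]] <- rhs[syn$loc[s]] + g_now[s] * syn$e_rev[s]
      }
    }
    v_half <- tree_solve(d, u, arr$parent, rhs, fixed_root)
    v <- if (first) v_half else 2 * v_half - v
    if (!is.null(fixed_root)) v[1] <- fixed_root
    V[, k + 1] <- v
  }
  if (anyNA(V) || max(abs(V)) > 1e3) {
    rlang::abort("integration diverged; use a smaller dt")
  }
  V
}

#' Simulate a compartmental model under somatic voltage clamp
#'
#' With `series_resistance = 0` (ideal clamp) the soma is held exactly at
#' `hold` as a Dirichlet boundary and the clamp current is the current
#' required to do so (sum of the axial, leak, and local synaptic currents at
#' the soma). A positive series resistance instead couples the soma to the
#' command potential through the pipette resistance, as in a real recording.
#' Synaptic current at each site is `g(t) (V_local - E_rev)`, so dendritic
#' synapses see their local, not the clamped, potential.
#'
#' @param model A [compartmentalize()]d model.
#' @param synapses A [synapse_spec()] or list of them, with `location` set.
#' @param hold Holding potential, mV.
#' @param dt Time step, ms.
#' @param duration Simulated time, ms.
#' @param series_resistance Pipette series resistance, megaohm (0 = ideal).
#' @return A `vclamp_sim` object with `clamp_current` (a trace in pA,
#'   positive = inward deflection magnitude preserved in sign: inward
#'   synaptic current appears as a negative deflection), the full voltage
#'   matrix, times, and the call parameters.
#' @export
simulate_voltage_clamp <- function(model, synapses = list(), hold = -70,
                                   dt = 0.005, duration = 8,
                                   series_resistance = 0) {
  stopifnot(inherits(model, "compartmental_model"))
  arr <- solver_arrays(model)
  times <- seq(0, duration, by = dt)
  syn <- synapse_drive(model, synapses, times)
  ideal <- series_resistance <= 0
  g_el <- if (ideal) 0 else 1 / series_resistance # MOhm -> uS
  b0 <- arr$g_leak * arr$E_leak
  if (!ideal) b0[1] <- b0[1] + g_el * hold
  v0 <- steady_state(arr, b0, fixed_root = if (ideal) hold else NULL,
                     g_extra_diag = if (ideal) NULL else c(g_el, rep(0, arr$n - 1)))
  V <- integrate_tree(arr, syn, times, v0,
                      fixed_root = if (ideal) hold else NULL,
                      g_electrode = g_el, v_electrode = hold)
  i_clamp <- clamp_current_nA(arr, syn, times, V, ideal, g_el, hold)
  structure(list(
    clamp_current = new_trace(i_clamp * 1e3, dt = dt, t0 = 0, unit = "pA"),
    voltages = V, times = times, model = model, synapses = syn,
    hold = hold, dt = dt, duration = duration,
    series_resistance = series_resistance
  ), class = "vclamp_sim")
}

clamp_current_nA <- function(arr, syn, times, V, ideal, g_el, hold) {
  n <- arr$n
  nt <- length(times)
  if (!ideal) return(g_el * (hold - V[1, ]))
  kids <- which(arr$parent == 1)
  kids <- kids[kids != 1]
  i_ax <- rep(0, nt)
  for (c_ in kids) i_ax <- i_ax + arr$g_ax[c_] * (V[1, ] - V[c_, ])
  i_leak <- arr$g_leak[1] * (V[1, ] - arr$E_leak)
  i_syn <- rep(0, nt)
  at_root <- which(syn$loc == 1)
  for (s in at_root) i_syn <- i_syn + syn$g_on[s, ] * (V[1, ] - syn$e_rev[s])
  i_ax + i_leak + i_syn
}

#' Simulate a compartmental model under current clamp
#'
#' Free membrane voltage everywhere; synaptic current uses the instantaneous
#' local driving force `g(t) (V_local - E_rev)`, the mechanism by which local
#' dendritic depolarization produces sublinear summation.
#'
#' @param model A [compartmentalize()]d model.
#' @param synapses A [synapse_spec()] or list of them.
#' @param injected Optional list `(compartment, waveform)` where `waveform`
#'   is a function of time (ms) returning injected current in nA, or a
#'   single number for a constant current.
#' @param dt Time step, ms.
#' @param duration Simulated time, ms.
#' @return A `cclamp_sim` object with the voltage matrix (mV), times, and
#'   parameters.
#' @export
simulate_current_clamp <- function(model, synapses = list(), injected = NULL,
                                   dt = 0.005, duration = 8) {
  stopifnot(inherits(model, "compartmental_model"))
  arr <- solver_arrays(model)
  times <- seq(0, duration, by = dt)
  syn <- synapse_drive(model, synapses, times)
  inj <- NULL
  if (!is.null(injected)) {
    wf <- injected$waveform
    if (is.numeric(wf)) {
      amp <- wf
      wf <- function(t) amp
    }
    idx <- which(model$compartments$id == injected$compartment)
    if (length(idx) != 1) rlang::abort("injected$compartment is not a compartment id")
    inj <- list(idx = idx, current = wf)
  }
  v0 <- rep(arr$E_leak, arr$n)
  V <- integrate_tree(arr, syn, times, v0, inj = inj)
  structure(list(voltages = V, times = times, model = model, synapses = syn,
                 dt = dt, duration = duration),
            class = "cclamp_sim")
}

#' Extract the voltage trace of one compartment from a simulation
#'
#' @param sim A `vclamp_sim` or `cclamp_sim`.
#' @param compartment Compartment id (default: the soma).
#' @return A trace (mV).
#' @export
compartment_voltage <- function(sim, compartment = 1) {
  idx <- which(sim$model$compartments$id == compartment)
  if (length(idx) != 1) rlang::abort("unknown compartment id")
  new_trace(sim$voltages[idx, ], dt = sim$dt, t0 = 0, unit = "mV")
}

#' Steady-state input resistance at a compartment
#'
#' Injects a small steady current and returns the local voltage deflection
#' over current, in megaohms.
#'
#' @param model A [compartmentalize()]d model.
#' @param at Compartment id.
#' @return Input resistance, megaohm.
#' @export
input_resistance <- function(model, at = 1) {
  arr <- solver_arrays(model)
  idx <- which(model$compartments$id == at)
  if (length(idx) != 1) rlang::abort("unknown compartment id")
  i_nA <- 1e-3
  b <- arr$g_leak * arr$E_leak
  b[idx] <- b[idx] + i_nA
  v <- steady_state(arr, b)
  (v[idx] - arr$E_leak) / i_nA
}
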