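test_that("steady-state space constant matches the closed form for thin dendrites", {
  expect_equal(lambda_dc(0.47, 20000, 100), 485, tolerance = 5e-3)
  expect_equal(lambda_dc(0.47, 20000, 200), 343, tolerance = 5e-3)
  # square-root diameter scaling
  expect_equal(lambda_dc(4 * 0.47, 20000, 150), 2 * lambda_dc(0.47, 20000, 150))
  expect_error(lambda_dc(-1, 20000, 150), "positive")
})

test_that("frequency-dependent space constant: simplified and full forms", {
  expect_equal(round(lambda_ac(0.47, Ri = 200, Cm = 0.9, f = 1000,
                               simplified = TRUE)), 46)
  expect_equal(lambda_ac(0.47, Ri = 200, Cm = 0.9, f = 1000, simplified = TRUE),
               45.58, tolerance = 1e-3)
  # full form tends to lambda_DC as f -> 0
  expect_equal(lambda_ac(0.47, 20000, 150, 0.9, 1e-6),
               lambda_dc(0.47, 20000, 150), tolerance = 1e-6)
  # direct evaluation of the full form at 1 kHz
  lam <- lambda_dc(0.47, 20000, 150)
  tau <- 20000 * 0.9e-6
  expect_equal(lambda_ac(0.47, 20000, 150, 0.9, 1000),
               lam * sqrt(2 / (1 + sqrt(1 + (2 * pi * 1000 * tau)^2))))
  expect_equal(lambda_ac(0.47, 20000, 150, 0.9, 1000), 52.4, tolerance = 1e-3)
})

test_that("membrane time constant is Rm*Cm in ms and governs the step response", {
  expect_equal(membrane_time_constant(20000, 0.9), 18)
  expect_equal(membrane_time_constant(20000, 0.85), 17)

  sphere <- compartmentalize(build_idealized_sc(8, 0), ideal_props, 1)
  sim <- simulate_current_clamp(sphere,
                                injected = list(compartment = 1, waveform = 0.002),
                                dt = 0.02, duration = 120)
  v <- sim$voltages[1, ]
  t <- sim$times
  v_inf <- v[length(v)]
  # exponential approach: fit log(v_inf - v) over the rising phase
  idx <- which(t > 1 & t < 60)
  fit <- stats::lm(log(v_inf - v[idx]) ~ t[idx])
  expect_equal(-1 / unname(stats::coef(fit)[2]), 18, tolerance = 0.01)
})

test_that("compartmentalization reproduces closed-form areas and axial resistance", {
  comps <- ideal_model$compartments
  # interior cylinder: 4 Ri dx / (pi d^2) = 8.65 MOhm for 1 um at 0.47 um
  g_int <- comps$g_axial_uS[10]
  expect_equal(1 / g_int, 8.647, tolerance = 1e-3) # MOhm
  # soma sphere area pi d^2
  expect_equal(comps$area_cm2[1] * 1e8, 201.06, tolerance = 1e-4)
  # lateral dendritic area within 0.1% of pi d L
  dend_area <- sum(comps$area_cm2[comps$kind == "dendrite"]) * 1e8
  expect_equal(dend_area, pi * 0.47 * 90, tolerance = 1e-3)
})

test_that("biexponential conductance has the printed peaks and half-widths", {
  g_imm <- quantal_conductance("immature")
  expect_equal(biexp_conductance(g_imm$onset, g_imm), 0)
  expect_equal(biexp_peak_time(g_imm),
               0.26 * 0.073 / (0.26 - 0.073) * log(0.26 / 0.073))
  expect_equal(biexp_peak_time(g_imm), 0.1289, tolerance = 1e-3)
  expect_equal(biexp_peak(g_imm), 0.00175, tolerance = 2e-3)

  g_ad <- quantal_conductance("adult")
  expect_lt(abs(biexp_peak(g_ad) - 0.00133) / 0.00133, 0.01)
})

test_that("ideal clamp holds the soma and reproduces the somatic-synapse identity", {
  # no synapse, hold at rest: clamp current identically zero
  sim0 <- simulate_voltage_clamp(ideal_model, list(), hold = -70, duration = 2)
  expect_true(all(abs(sim0$clamp_current$samples) < 1e-9))

  # isopotential compartment, synapse at the clamped soma:
  # I(t) = g(t) (hold - E_rev) exactly
  sphere <- compartmentalize(build_idealized_sc(8, 0), ideal_props, 1)
  g <- quantal_conductance("immature")
  g$location <- 1
  g$onset <- 1
  sim <- simulate_voltage_clamp(sphere, g, hold = -70, dt = 0.005, duration = 6)
  expected_pA <- biexp_conductance(sim$times, g) * (-70 - 0) * 1e3
  expect_equal(sim$clamp_current$samples, expected_pA, tolerance = 1e-12)
  # peak magnitude 122.5 pA = 0.00175 uS * 70 mV
  expect_equal(max(abs(sim$clamp_current$samples)), 122.5, tolerance = 2e-3)

  # same identity on the full model (branch currents vanish at rest)
  g$location <- compartment_at_distance(ideal_model, 0)
  simf <- simulate_voltage_clamp(ideal_model, g, hold = -70, dt = 0.005,
                                 duration = 6)
  expect_equal(simf$clamp_current$samples, expected_pA, tolerance = 1e-9)
})

test_that("dendritic qEPSCs are smaller and slower than somatic ones", {
  soma <- measure_clamp(ideal_model, imm_gsyn, 0)$stats
  dend <- measure_clamp(ideal_model, imm_gsyn, 45)$stats
  expect_lt(dend$amplitude, soma$amplitude)
  expect_gt(dend$rise_10_90, soma$rise_10_90)
  expect_gt(dend$half_width, soma$half_width)
})

test_that("current clamp matches Ohmic steady state and the sealed-cable profile", {
  sphere <- compartmentalize(build_idealized_sc(8, 0), ideal_props, 1)
  i0 <- 0.002 # nA
  sim <- simulate_current_clamp(sphere,
                                injected = list(compartment = 1, waveform = i0),
                                dt = 0.05, duration = 200)
  dv <- sim$voltages[1, ncol(sim$voltages)] + 70
  r_MOhm <- ideal_props$Rm / (sphere$compartments$area_cm2[1]) * 1e-6
  expect_equal(dv, i0 * r_MOhm, tolerance = 1e-3)

  # long uniform cable, steady current at the soma end:
  # V(x)/V(0) = cosh((L-x)/lambda)/cosh(L/lambda)
  sim2 <- simulate_current_clamp(ideal_model,
                                 injected = list(compartment = 1, waveform = 0.001),
                                 dt = 0.05, duration = 400)
  vprof <- sim2$voltages[, ncol(sim2$voltages)] + 70
  comps <- ideal_model$compartments
  lam <- lambda_dc(0.47, 20000, 150)
  x <- comps$path_distance[comps$kind == "dendrite"]
  pred <- cosh((90 - x) / lam) / cosh(90 / lam)
  obs <- vprof[comps$kind == "dendrite"] / vprof[1]
  expect_lt(max(abs(obs - pred) / pred), 0.01)
})

test_that("input resistance matches closed forms and grows toward the tip", {
  sphere <- compartmentalize(build_idealized_sc(8, 0), ideal_props, 1)
  expect_equal(input_resistance(sphere, 1) * 1e-3, 9.95, tolerance = 1e-3) # GOhm

  # soma input resistance = sphere || sealed cable R_inf coth(L/lambda)
  d_cm <- 0.47e-4
  r_inf <- (2 / (pi * d_cm^1.5)) * sqrt(ideal_props$Rm * ideal_props$Ri) # Ohm
  lam <- lambda_dc(0.47, 20000, 150)
  r_cable <- r_inf / tanh(90 / lam) * 1e-6 # MOhm
  r_soma <- ideal_props$Rm / (sphere$compartments$area_cm2[1]) * 1e-6
  pred <- 1 / (1 / r_cable + 1 / r_soma)
  expect_lt(abs(input_resistance(ideal_model, 1) - pred) / pred, 0.01)

  rins <- vapply(c(0, 20, 45, 70, 89.5), function(x) {
    input_resistance(ideal_model, compartment_at_distance(ideal_model, x))
  }, numeric(1))
  expect_true(all(diff(rins) > 0))
})

test_that("the integrator converges under dt and compartment-length refinement", {
  coarse <- measure_clamp(ideal_model, imm_gsyn, 45, dt = 0.005)$stats
  fine_model <- compartmentalize(ideal_morph, ideal_props, 0.5)
  fine <- measure_clamp(fine_model, imm_gsyn, 45, dt = 0.0025)$stats
  expect_lt(abs(fine$amplitude - coarse$amplitude) / coarse$amplitude, 0.005)
})

test_that("solver agrees with an independent dense ODE integration (two compartments)", {
  # two-compartment model: 8 um sphere + single 10 um cylinder
  m <- build_idealized_sc(8, 1, 10, 0.47, 1, 10)
  mod <- compartmentalize(m, ideal_props, 10)
  expect_equal(nrow(mod$compartments), 2)
  g <- quantal_conductance("immature")
  g$location <- 2
  g$onset <- 0.5
  arr <- scable:::solver_arrays(mod)
  deriv <- function(t, v, p) {
    gs <- biexp_conductance(t, g)
    i2 <- -arr$g_leak[2] * (v[1] - arr$E_leak) +
      arr$g_ax[2] * (-70 - v[1]) - gs * (v[1] - g$e_rev)
    list(i2 / arr$c_nF[2])
  }
  times <- seq(0, 6, by = 0.005)
  ref <- deSolve::ode(y = -70, times = times, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  v_ref <- ref[, 2]
  sim <- simulate_voltage_clamp(mod, g, dt = 0.005, duration = 6)
  v_ours <- sim$voltages[2, ]
  expect_lt(max(abs(v_ours - v_ref)), 0.02) # mV, on a ~50 mV excursion

  # charge bookkeeping: clamp-current integral equals synaptic charge minus
  # membrane leak/capacitive exchange in the dendritic compartment
  i_clamp <- sim$clamp_current$samples / 1e3 # nA
  q_clamp <- sum(i_clamp) * 0.005
  gs <- biexp_conductance(times, g)
  i_syn <- -gs * (v_ours - g$e_rev)
  i_leak <- -arr$g_leak[2] * (v_ours - arr$E_leak)
  i_cap <- c(0, diff(v_ours)) / 0.005 * arr$c_nF[2]
  q_expected <- sum(i_syn + i_leak - i_cap) * 0.005
  expect_equal(-q_clamp, q_expected, tolerance = 0.01)
})

test_that("diverging integrations are reported with advice", {
  expect_error(
    simulate_current_clamp(ideal_model,
                           injected = list(compartment = 1, waveform = 100)),
    "diverged|smaller dt")
})
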