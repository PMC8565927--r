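sweep_cached <- NULL
get_sweep <- function() {
  if (is.null(sweep_cached)) {
    sweep_cached <<- qepsc_distance_sweep(ideal_model, imm_gsyn,
                                          distances = seq(0, 90, by = 15))
  }
  sweep_cached
}

test_that("distance sweep: soma self-ratio is 100% and amplitude never increases", {
  sw <- get_sweep()
  expect_equal(sw$distance[1], 0)
  expect_equal(sw$amplitude_pA[1] / sw$amplitude_pA[1], 1)
  expect_true(all(diff(sw$amplitude_pA) <= 0))
  # rank order matches the analytic frequency-domain attenuation (monotone)
  lam <- lambda_ac(0.47, 20000, 150, 0.9, 1000)
  pred <- exp(-sw$distance / lam)
  expect_equal(order(sw$amplitude_pA), order(pred))
  # local depolarization grows with distance
  expect_true(all(diff(sw$local_vpeak_mV) >= 0))
  expect_error(qepsc_distance_sweep(ideal_model, imm_gsyn, distances = c(0, 200)),
               "beyond the longest dendrite")
})

test_that("somatic PPR equals the conductance ratio exactly; dendritic PPR is below", {
  ppr_soma <- simulate_ppr(ideal_model, imm_gsyn, distance = 0)
  expect_equal(ppr_soma$ppr, 2.25, tolerance = 1e-9)
  ppr_dend <- simulate_ppr(ideal_model, imm_gsyn, distance = 60)
  expect_lt(ppr_dend$ppr, 2.25)
  expect_error(simulate_ppr(ideal_model, imm_gsyn, interval = 3),
               "overlap")
})

test_that("clamp responses and PPR are invariant to adding resting branches", {
  # graft extra (possibly branched) dendrites onto the soma while keeping the
  # synapse-bearing dendrite unchanged
  graft <- function(base_m, n_extra, branches) {
    extra <- build_idealized_sc(8, n_extra, 90, 0.47, branches, 1)$nodes
    extra <- extra[extra$kind != "soma", ]
    off <- max(base_m$nodes$id)
    extra$id <- extra$id + off
    extra$parent_id <- ifelse(extra$parent_id == 1L, 1L, extra$parent_id + off)
    morphology(dplyr::bind_rows(base_m$nodes, extra))
  }
  base <- measure_clamp(ideal_model, imm_gsyn, 45)$stats
  for (variant in list(c(2, 1), c(2, 3), c(4, 5))) {
    m <- graft(ideal_morph, variant[1], variant[2])
    mod <- compartmentalize(m, ideal_props, 1)
    gs <- imm_gsyn
    gs$location <- compartment_at_distance(mod, 45)
    gs$onset <- 1
    # placement resolves to the original dendrite (lowest compartment ids)
    sim <- simulate_voltage_clamp(mod, gs, dt = 0.005, duration = 8)
    st <- measure_event(sim$clamp_current, onset = 1)
    expect_lt(abs(st$amplitude - base$amplitude) / base$amplitude, 0.001)
  }
  ppr1 <- simulate_ppr(ideal_model, imm_gsyn, distance = 60)
  mod3 <- compartmentalize(build_idealized_sc(8, 3, 90, 0.47, 1, 1),
                           ideal_props, 1)
  ppr3 <- simulate_ppr(mod3, imm_gsyn, distance = 60, dendrite = 1)
  expect_lt(abs(ppr3$ppr - ppr1$ppr) / ppr1$ppr, 0.005)
})

test_that("quantal input-output curves saturate sublinearly", {
  io <- quantal_io_curve(ideal_model, imm_gsyn, quanta = c(0.1, 1, 5, 20),
                         distance = 60)
  # the reference conductance is linear by construction
  expect_equal(io$peak_mV[1], io$linear_sum_mV[1], tolerance = 1e-9)
  expect_lt(io$peak_mV[4], io$linear_sum_mV[4])
  deficit <- (io$linear_sum_mV - io$peak_mV) / io$linear_sum_mV
  expect_true(all(diff(deficit) > 0))
})

test_that("dendritic sublinearity is zero for identical curves, bounded, and larger in the adult configuration", {
  io_s <- quantal_io_curve(ideal3_model, imm_gsyn, quanta = c(1, 5, 10, 20),
                           distance = 0)
  expect_true(all(abs(dendritic_sublinearity(io_s, io_s)$sublinearity) < 1e-12))

  io_d <- quantal_io_curve(ideal3_model, imm_gsyn, quanta = c(1, 5, 10, 20),
                           distance = 15)
  sub_imm <- dendritic_sublinearity(io_s, io_d)
  expect_true(all(sub_imm$sublinearity >= 0 & sub_imm$sublinearity < 1))
  expect_true(all(diff(sub_imm$sublinearity) > 0))

  io_sa <- quantal_io_curve(ideal3_model, adult_gsyn, quanta = c(1, 5, 10, 20),
                            distance = 0)
  io_da <- quantal_io_curve(ideal3_model, adult_gsyn, quanta = c(1, 5, 10, 20),
                            distance = 45)
  sub_ad <- dendritic_sublinearity(io_sa, io_da)
  expect_true(all(sub_ad$sublinearity > sub_imm$sublinearity))
  expect_error(dendritic_sublinearity(io_s, quantal_io_curve(
    ideal3_model, imm_gsyn, quanta = c(1, 2), distance = 15)),
    "quanta grids")
})

test_that("weighted mEPSC synthesis: delta weights, equal weights, and monotone mixing", {
  sw <- get_sweep()
  nb <- nrow(sw)
  # all weight on the soma bin reproduces the somatic qEPSC
  w_delta <- synapse_distance_weights(sw$distance, c(1, rep(0, nb - 1)))
  syn_delta <- synthesize_mean_mepsc(sw, w_delta)
  expect_equal(syn_delta$trace$samples, sw$trace[[1]]$samples)

  # half/half on two traces is the pointwise mean
  w_half <- synapse_distance_weights(sw$distance,
                                     c(1, rep(0, nb - 2), 1))
  syn_half <- synthesize_mean_mepsc(sw, w_half)
  expect_equal(syn_half$trace$samples,
               (sw$trace[[1]]$samples + sw$trace[[nb]]$samples) / 2)

  # shifting weight mass distally: smaller amplitude, wider half-width
  w_prox <- synapse_distance_weights(sw$distance, rev(seq_len(nb)))
  w_dist <- synapse_distance_weights(sw$distance, seq_len(nb))
  syn_prox <- synthesize_mean_mepsc(sw, w_prox)
  syn_dist <- synthesize_mean_mepsc(sw, w_dist)
  expect_lt(syn_dist$stats$amplitude, syn_prox$stats$amplitude)
  expect_gt(syn_dist$stats$half_width, syn_prox$stats$half_width)

  # synthesized amplitude bounded by the somatic and most distal qEPSCs
  for (syn in list(syn_prox, syn_dist)) {
    expect_gte(syn$stats$amplitude, min(sw$amplitude_pA))
    expect_lte(syn$stats$amplitude, max(sw$amplitude_pA))
  }
  expect_error(synthesize_mean_mepsc(sw, tibble::tibble(
    distance = sw$distance, weight = rep(0.5, nb))), "sum to 1")
})

test_that("per-dendrite sweeps pool into an averaged synthesis", {
  mod3 <- compartmentalize(build_idealized_sc(8, 2, 60, 0.47, 1, 1),
                           ideal_props, 1)
  sw1 <- qepsc_distance_sweep(mod3, imm_gsyn, distances = c(0, 30),
                              dendrite = 1)
  sw2 <- qepsc_distance_sweep(mod3, imm_gsyn, distances = c(0, 30),
                              dendrite = 2)
  w <- synapse_distance_weights(c(0, 30), c(1, 1))
  pooled <- synthesize_mean_mepsc(list(sw1, sw2), w)
  single <- synthesize_mean_mepsc(sw1, w)
  # symmetric dendrites: pooled average equals either dendrite's synthesis
  expect_equal(pooled$trace$samples, single$trace$samples, tolerance = 1e-9)
})
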