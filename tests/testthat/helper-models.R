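# Shared fixtures, built once per test run.

imm_gsyn <- quantal_conductance("immature")
adult_gsyn <- quantal_conductance("adult")

# idealized immature cell of the filtering comparison: 8 um soma, one
# unbranched 90 x 0.47 um dendrite, Ri 150
ideal_props <- passive_properties(Cm = 0.9, Rm = 20000, Ri = 150, E_leak = -70)
ideal_morph <- build_idealized_sc(8, 1, 90, 0.47, 1, 1)
ideal_model <- compartmentalize(ideal_morph, ideal_props, 1)

# the Methods' idealized cell: 9 um soma, three 90 um dendrites
ideal3_model <- compartmentalize(build_idealized_sc(9, 3, 90, 0.47, 1, 1),
                                 ideal_props, 1)

# a small random branched tree for oracle-based tests
random_tree <- function(seed = 42, n_primary = 3, depth = 2) {
  set.seed(seed)
  rows <- list(tibble::tibble(id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                              radius = 4, kind = "soma"))
  next_id <- 2L
  grow <- function(parent_id, origin, level) {
    theta <- stats::runif(1, 0, 2 * pi)
    phi <- stats::runif(1, -0.5, 0.5)
    u <- c(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
    n_seg <- sample(3:6, 1)
    pos <- origin
    pid <- parent_id
    for (j in seq_len(n_seg)) {
      step <- stats::runif(1, 2, 8)
      u <- u + stats::rnorm(3, 0, 0.1)
      u <- u / sqrt(sum(u^2))
      pos <- pos + step * u
      rows[[length(rows) + 1]] <<- tibble::tibble(
        id = next_id, parent_id = pid, x = pos[1], y = pos[2], z = pos[3],
        radius = stats::runif(1, 0.2, 0.5), kind = "dendrite")
      pid <- next_id
      next_id <<- next_id + 1L
    }
    if (level < depth) {
      for (k in 1:2) grow(pid, pos, level + 1)
    }
  }
  for (k in seq_len(n_primary)) grow(1L, c(0, 0, 0), 1)
  morphology(dplyr::bind_rows(rows))
}

# independent path-walk oracle: Euclidean step sum from the root
oracle_path_distance <- function(m, id) {
  nd <- m$nodes
  total <- 0
  while (TRUE) {
    i <- which(nd$id == id)
    pid <- nd$parent_id[i]
    if (pid == -1L) break
    j <- which(nd$id == pid)
    total <- total + sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
                          (nd$z[i] - nd$z[j])^2)
    id <- pid
  }
  total
}

measure_clamp <- function(model, g, distance, onset = 1, dt = 0.005,
                          duration = 8, rs = 0) {
  gs <- g
  gs$location <- compartment_at_distance(model, distance)
  gs$onset <- onset
  sim <- simulate_voltage_clamp(model, gs, dt = dt, duration = duration,
                                series_resistance = rs)
  list(sim = sim, stats = measure_event(sim$clamp_current, onset = onset))
}
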