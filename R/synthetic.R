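# Synthetic-data generators: every pipeline stage gets inputs with known
# ground truth. Presets encode the published group contrasts (branchier,
# longer adult arbors with unchanged primary-dendrite counts; uniform puncta
# density; mEPSC amplitude/kinetics/frequency scales) as generator defaults.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    bad <- x < lower
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generator configuration with developmental-stage presets
#'
#' Presets encode the qualitative group contrasts of developing stellate
#' cells: the adult preset has a higher branching rate, deeper branch
#' orders and longer maximal path lengths at an unchanged number of primary
#' dendrites and slightly thinner dendrites; event-train presets carry the
#' miniature-EPSC amplitude, kinetics and frequency scales of each stage.
#' All values can be overridden by name.
#'
#' @param stage `"immature"` or `"adult"`.
#' @param seed Integer seed; every generator is a deterministic function of
#'   its config.
#' @param ... Named overrides of preset entries (e.g. `n_primary`,
#'   `branch_rate`, `rate_hz`, `noise_sd`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(stage = c("immature", "adult"), seed = 1, ...) {
  stage <- match.arg(stage)
  preset <- switch(stage,
    immature = list(
      n_primary = 5, mean_path_length = 65, sd_path_length = 8,
      branch_rate = 0.012, max_branch_order = 2,
      diam_mean = 0.47, diam_sd = 0.08, diam_min = 0.2, node_spacing = 2,
      puncta_density = 0.7, n_somatic_puncta = 27,
      rate_hz = 1.37, amp_mean_pA = 48, amp_sd_pA = 10,
      tau0_ms = 0.17, tau1_ms = 0.75, noise_sd_pA = 4.8,
      dt_ms = 0.02, duration_ms = 10000
    ),
    adult = list(
      n_primary = 5, mean_path_length = 95, sd_path_length = 10,
      branch_rate = 0.015, max_branch_order = 3,
      diam_mean = 0.41, diam_sd = 0.08, diam_min = 0.2, node_spacing = 2,
      puncta_density = 0.7, n_somatic_puncta = 21,
      rate_hz = 1.14, amp_mean_pA = 24, amp_sd_pA = 5,
      tau0_ms = 0.26, tau1_ms = 1.45, noise_sd_pA = 2.4,
      dt_ms = 0.02, duration_ms = 10000
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(preset))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown generator parameter(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(preset, over)
  cfg$stage <- stage
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

#' Generate a stochastic stellate-cell-like morphology
#'
#' A soma plus `n_primary` dendrites grown in the xy-plane. Each primary
#' dendrite draws a tip path length; branch points arise along the growing
#' path as a Poisson process at `branch_rate` per um up to
#' `max_branch_order`, and each daughter grows out to the same tip path
#' length. Diameters are drawn per dendrite around the stage mean, truncated
#' positive.
#'
#' @param cfg A [generator_config()].
#' @return A [morphology()].
#' @export
generate_morphology <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_local_seed(cfg$seed, {
    rows <- list(tibble::tibble(id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                                radius = 4, kind = "soma"))
    next_id <- 2L
    for (k in seq_len(cfg$n_primary)) {
      theta <- 2 * pi * (k - 1) / cfg$n_primary + stats::runif(1, -0.2, 0.2)
      L <- rnorm_trunc(1, cfg$mean_path_length, cfg$sd_path_length, 20)
      radius <- rnorm_trunc(1, cfg$diam_mean, cfg$diam_sd, cfg$diam_min) / 2
      res <- grow_branch(next_id, 1L, c(0, 0), theta, L, radius, 1L, cfg)
      rows <- c(rows, res$rows)
      next_id <- res$next_id
    }
    morphology(dplyr::bind_rows(rows))
  })
}

# Recursive stochastic growth of one branch toward tip path length
# `remaining` beyond `origin`, wiggling direction slightly per node.
grow_branch <- function(next_id, parent_id, origin, theta, remaining, radius,
                        order, cfg) {
  rows <- list()
  to_branch <- if (order < cfg$max_branch_order && cfg$branch_rate > 0)
    stats::rexp(1, cfg$branch_rate) else Inf
  seg_len <- min(remaining, to_branch)
  n_nodes <- max(1L, ceiling(seg_len / cfg$node_spacing))
  step <- seg_len / n_nodes
  pos <- origin
  pid <- parent_id
  for (j in seq_len(n_nodes)) {
    theta <- theta + stats::runif(1, -0.15, 0.15)
    pos <- pos + step * c(cos(theta), sin(theta))
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = next_id, parent_id = pid, x = pos[1], y = pos[2],
      z = 0, radius = radius, kind = "dendrite")
    pid <- next_id
    next_id <- next_id + 1L
  }
  left <- remaining - seg_len
  if (left > cfg$node_spacing / 2 && is.finite(to_branch)) {
    for (sgn in c(-1, 1)) {
      res <- grow_branch(next_id, pid, pos, theta + sgn * stats::runif(1, 0.4, 0.9),
                         left, radius, order + 1L, cfg)
      rows <- c(rows, res$rows)
      next_id <- res$next_id
    }
  } else if (left > cfg$node_spacing / 2) {
    res <- grow_branch(next_id, pid, pos, theta, left, radius, order, cfg)
    rows <- c(rows, res$rows)
    next_id <- res$next_id
  }
  list(rows = rows, next_id = next_id)
}

#' Generate synthetic puncta along a skeleton
#'
#' Dendritic puncta follow a homogeneous Poisson point process along
#' arclength at the stated linear density, displaced radially by at most the
#' local radius plus `jitter` (guaranteeing assignment within the default
#' search radius). Diameters and intensities are drawn above the filter
#' thresholds; a configurable fraction of sub-threshold decoys exercises the
#' filters, and optional somatic puncta carry a bright soma-channel
#' intensity.
#'
#' @param s A [skeleton()].
#' @param density Linear puncta density along dendrites, per um.
#' @param seed Integer seed.
#' @param decoy_fraction Decoy spots added as a fraction of the true count.
#' @param jitter Maximal radial displacement beyond the centerline in excess
#'   of the local radius, um; keep below the assignment margin `alpha`.
#' @param n_somatic Somatic puncta placed on the soma sphere.
#' @param background_mean,background_sd Background intensity statistics the
#'   intensities are drawn against.
#' @param stack_max Soma-channel maximum of the synthetic stack.
#' @return A puncta tibble with ground-truth columns `is_decoy`,
#'   `is_somatic`, `true_path_distance`.
#' @export
generate_puncta <- function(s, density = 0.7, seed = 1, decoy_fraction = 0.2,
                            jitter = 0.1, n_somatic = 0,
                            background_mean = 100, background_sd = 10,
                            stack_max = 1000) {
  stopifnot(inherits(s, "skeleton"))
  if (density < 0) rlang::abort("density must be nonnegative")
  samples <- resample_skeleton(s, step = 0.1)
  with_local_seed(seed, {
    n_true <- stats::rpois(1, density * total_skeleton_length(s))
    mk_spot <- function(idx, decoy) {
      sm <- samples[idx, ]
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r_off <- stats::runif(1, 0, sm$radius + jitter)
      ints <- background_mean + background_sd * (6 + abs(stats::rnorm(1, 0, 2)))
      dia <- c(stats::runif(2, 0.4, 0.8), stats::runif(1, 1.2, 1.8))
      if (decoy) {
        if (stats::runif(1) < 0.5) {
          dia <- c(stats::runif(2, 0.1, 0.3), stats::runif(1, 0.5, 1.1))
        } else {
          ints <- background_mean + background_sd * stats::runif(1, 0, 3)
        }
      }
      tibble::tibble(
        x = sm$x + r_off * u[1], y = sm$y + r_off * u[2],
        z = sm$z + r_off * u[3],
        diameter_x = dia[1], diameter_y = dia[2], diameter_z = dia[3],
        peak_intensity = ints,
        soma_channel_intensity = stats::runif(1, 0, 0.45) * stack_max,
        is_decoy = decoy, is_somatic = FALSE,
        true_path_distance = sm$path_distance)
    }
    spots <- list()
    if (n_true > 0) {
      idx <- sample(nrow(samples), n_true, replace = TRUE)
      spots <- c(spots, lapply(idx, mk_spot, decoy = FALSE))
    }
    n_decoy <- round(decoy_fraction * n_true)
    if (n_decoy > 0) {
      idx <- sample(nrow(samples), n_decoy, replace = TRUE)
      spots <- c(spots, lapply(idx, mk_spot, decoy = TRUE))
    }
    if (n_somatic > 0) {
      for (i in seq_len(n_somatic)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p <- s$soma_center + s$soma_radius * u
        spots[[length(spots) + 1]] <- tibble::tibble(
          x = p[1], y = p[2], z = p[3],
          diameter_x = stats::runif(1, 0.4, 0.8),
          diameter_y = stats::runif(1, 0.4, 0.8),
          diameter_z = stats::runif(1, 1.2, 1.8),
          peak_intensity = background_mean + background_sd * (6 + abs(stats::rnorm(1, 0, 2))),
          soma_channel_intensity = stats::runif(1, 0.55, 1) * stack_max,
          is_decoy = FALSE, is_somatic = TRUE,
          true_path_distance = 0)
      }
    }
    if (length(spots) == 0) {
      return(tibble::tibble(
        x = numeric(0), y = numeric(0), z = numeric(0),
        diameter_x = numeric(0), diameter_y = numeric(0),
        diameter_z = numeric(0), peak_intensity = numeric(0),
        soma_channel_intensity = numeric(0), is_decoy = logical(0),
        is_somatic = logical(0), true_path_distance = numeric(0)))
    }
    dplyr::bind_rows(spots)
  })
}

total_skeleton_length <- function(s) {
  sum(vapply(s$branches, function(b) {
    arc <- branch_arclength(b$points)
    arc[length(arc)]
  }, numeric(1)))
}

#' Generate a synthetic miniature-EPSC recording
#'
#' A Poisson train of negative-going biexponential current events with drawn
#' amplitudes, plus white Gaussian recording noise. The ground-truth event
#' table is returned alongside the trace.
#'
#' @param cfg A [generator_config()]; uses `rate_hz`, `amp_mean_pA`,
#'   `amp_sd_pA`, `tau0_ms`, `tau1_ms`, `noise_sd_pA`, `dt_ms`,
#'   `duration_ms`, `seed`.
#' @return A list: `trace` (pA) and `events` (tibble `onset_ms`,
#'   `amplitude_pA`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$duration_ms <= 0) rlang::abort("duration must be positive")
  with_local_seed(cfg$seed + 1L, {
    nt <- floor(cfg$duration_ms / cfg$dt_ms) + 1
    t <- (seq_len(nt) - 1) * cfg$dt_ms
    n_ev <- stats::rpois(1, cfg$rate_hz * cfg$duration_ms / 1000)
    onsets <- sort(stats::runif(n_ev, 1, cfg$duration_ms - 12))
    amps <- rnorm_trunc(n_ev, cfg$amp_mean_pA, cfg$amp_sd_pA, 1)
    shape <- synapse_spec(tau0 = cfg$tau0_ms, tau1 = cfg$tau1_ms, gmax = 1)
    peak <- biexp_peak(shape)
    y <- stats::rnorm(nt, 0, cfg$noise_sd_pA)
    for (i in seq_len(n_ev)) {
      i0 <- floor(onsets[i] / cfg$dt_ms) + 1
      i1 <- min(nt, i0 + ceiling(12 / cfg$dt_ms))
      tt <- t[i0:i1] - onsets[i]
      y[i0:i1] <- y[i0:i1] - amps[i] *
        biexp_conductance(tt, shape) / peak
    }
    list(trace = new_trace(y, dt = cfg$dt_ms, t0 = 0, unit = "pA"),
         events = tibble::tibble(onset_ms = onsets, amplitude_pA = amps))
  })
}

#' Generate a Gaussian intensity line profile
#'
#' The profile's FWHM equals the requested diameter; optional additive
#' Gaussian noise as a fraction of the peak.
#'
#' @param diameter Target FWHM, um.
#' @param noise_sd Noise SD as a fraction of the peak amplitude.
#' @param spacing Sample spacing, um.
#' @param center Peak center, um.
#' @param baseline Constant baseline added to the profile.
#' @param half_range Half-extent of the sampled positions around the center,
#'   um.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A tibble: `position`, `intensity`.
#' @export
generate_line_profile <- function(diameter, noise_sd = 0, spacing = 0.02,
                                  center = 0, baseline = 0, half_range = 1.5,
                                  seed = 1) {
  if (diameter <= 0) rlang::abort("diameter must be positive")
  sigma <- diameter / (2 * sqrt(2 * log(2)))
  x <- seq(center - half_range, center + half_range, by = spacing)
  y <- baseline + exp(-(x - center)^2 / (2 * sigma^2))
  if (noise_sd > 0) {
    y <- with_local_seed(seed, y + stats::rnorm(length(x), 0, noise_sd))
  }
  tibble::tibble(position = x, intensity = y)
}
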