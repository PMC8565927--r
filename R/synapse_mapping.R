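# Puncta-to-skeleton synapse mapping: filter candidate fluorescence spots,
# resample the dendritic centerline at 100 nm, assign puncta to the nearest
# skeleton sample within the search radius (local dendritic radius + alpha),
# and summarize path-distance distributions.

#' Spot filtering criteria
#'
#' @param psf_xyz Point-spread-function FWHM per axis, um. Spots whose
#'   diameter is smaller than or equal to the PSF on any axis are rejected
#'   as unresolvable.
#' @param background_mean,background_sd Background intensity statistics;
#'   spots must exceed `background_mean + 3 background_sd` strictly.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(psf_xyz = c(0.3, 0.3, 1.1), background_mean = 0,
                            background_sd = 0) {
  if (any(psf_xyz <= 0)) rlang::abort("psf_xyz must be positive")
  if (background_sd < 0) rlang::abort("background_sd must be nonnegative")
  structure(list(psf_xyz = psf_xyz, background_mean = background_mean,
                 background_sd = background_sd),
            class = "filter_criteria")
}

puncta_required_cols <- c("x", "y", "z", "diameter_x", "diameter_y",
                          "diameter_z", "peak_intensity")

check_puncta <- function(puncta) {
  puncta <- tibble::as_tibble(puncta)
  missing <- setdiff(puncta_required_cols, names(puncta))
  if (length(missing) > 0) {
    rlang::abort(paste0("puncta table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  puncta
}

#' Filter candidate puncta by size and intensity
#'
#' A spot is accepted iff its diameter strictly exceeds the PSF on all three
#' axes and its peak intensity strictly exceeds the background mean plus
#' three background SDs. Both are strict inequalities: a spot exactly at
#' either boundary is rejected.
#'
#' @param puncta Tibble with columns `x`, `y`, `z`, `diameter_x`,
#'   `diameter_y`, `diameter_z`, `peak_intensity` (positions and diameters in
#'   um; intensities in arbitrary units).
#' @param criteria A [filter_criteria()].
#' @return The accepted subset of `puncta`.
#' @export
filter_puncta <- function(puncta, criteria) {
  puncta <- check_puncta(puncta)
  keep <- puncta$diameter_x > criteria$psf_xyz[1] &
    puncta$diameter_y > criteria$psf_xyz[2] &
    puncta$diameter_z > criteria$psf_xyz[3] &
    puncta$peak_intensity > criteria$background_mean + 3 * criteria$background_sd
  puncta[keep, ]
}

#' Select somatic puncta
#'
#' Somatic puncta must pass the size/intensity criteria of [filter_puncta()]
#' and additionally have a soma-channel intensity strictly greater than half
#' the maximum of the whole stack.
#'
#' @inheritParams filter_puncta
#' @param stack_max_soma_channel Maximum soma-channel intensity of the stack.
#' @return The somatic subset of `puncta`.
#' @export
select_somatic_puncta <- function(puncta, stack_max_soma_channel, criteria) {
  puncta <- check_puncta(puncta)
  if (!"soma_channel_intensity" %in% names(puncta)) {
    rlang::abort("puncta table lacks the soma_channel_intensity column")
  }
  passed <- filter_puncta(puncta, criteria)
  passed[passed$soma_channel_intensity > 0.5 * stack_max_soma_channel, ]
}

#' Construct a dendritic skeleton
#'
#' A skeleton is a list of branches; each branch is a polyline with local
#' radii, a parent branch (0 for branches leaving the soma), and an
#' attachment path distance (distance from the soma surface at the branch
#' start). A child branch must start at its parent's last point.
#'
#' @param branches List of lists with elements `points` (n x 3 matrix, um),
#'   `radius` (length-n vector, um), `parent` (branch index or 0), and
#'   optionally `attach_distance` (um; computed from the parent when absent).
#' @param soma_center Soma center, um.
#' @param soma_radius Soma radius, um.
#' @return A `skeleton` object.
#' @export
skeleton <- function(branches, soma_center = c(0, 0, 0), soma_radius = 0) {
  lens <- numeric(length(branches))
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    b$points <- as.matrix(b$points)
    if (ncol(b$points) != 3) rlang::abort("branch points must be n x 3")
    if (length(b$radius) != nrow(b$points)) {
      rlang::abort("branch radius must have one value per point")
    }
    if (any(b$radius <= 0)) rlang::abort("branch radii must be positive")
    if (is.null(b$parent)) b$parent <- 0L
    if (b$parent >= i) rlang::abort("parent branches must precede children")
    arc <- branch_arclength(b$points)
    lens[i] <- arc[length(arc)]
    if (is.null(b$attach_distance)) {
      b$attach_distance <- if (b$parent == 0) 0 else
        branches[[b$parent]]$attach_distance + lens[b$parent]
    }
    if (b$parent > 0) {
      pp <- branches[[b$parent]]$points
      if (sqrt(sum((b$points[1, ] - pp[nrow(pp), ])^2)) > 1e-6) {
        rlang::abort(paste0("branch ", i, " does not start at its parent's end"))
      }
    }
    branches[[i]] <- b
  }
  structure(list(branches = branches, soma_center = soma_center,
                 soma_radius = soma_radius),
            class = "skeleton")
}

branch_arclength <- function(points) {
  if (nrow(points) == 1) return(0)
  c(0, cumsum(sqrt(rowSums((points[-1, , drop = FALSE] -
                            points[-nrow(points), , drop = FALSE])^2))))
}

#' Convert a morphology to a skeleton
#'
#' Splits the dendritic tree into maximal unbranched polylines. Branches
#' leaving the soma start at the soma center with an attachment distance of
#' minus the soma radius, so resampled path distances are measured from the
#' soma surface (floored at zero); the local radius at the soma-center point
#' is taken from the first dendritic node.
#'
#' @param m A [morphology()].
#' @return A [skeleton()].
#' @export
skeleton_from_morphology <- function(m) {
  nd <- m$nodes
  pidx <- node_parent_index(m)
  n <- nrow(nd)
  children <- lapply(seq_len(n), function(i) {
    which(!is.na(pidx) & pidx == i & nd$kind == "dendrite")
  })
  branches <- list()
  # queue of (start node, parent branch index)
  queue <- lapply(children[[1]], function(k) list(start = k, parent = 0L))
  while (length(queue) > 0) {
    item <- queue[[1]]
    queue <- queue[-1]
    path <- c(if (item$parent == 0L) 1L else integer(0), item$start)
    cur <- item$start
    while (length(children[[cur]]) == 1) {
      cur <- children[[cur]]
      path <- c(path, cur)
    }
    pts <- cbind(nd$x[path], nd$y[path], nd$z[path])
    rad <- nd$radius[path]
    if (item$parent == 0L) rad[1] <- rad[2] # soma point: use dendritic radius
    bi <- length(branches) + 1L
    branches[[bi]] <- list(points = pts, radius = rad, parent = item$parent,
                           attach_distance = if (item$parent == 0L)
                             -nd$radius[1] else NULL)
    if (length(children[[cur]]) > 1) {
      for (k in children[[cur]]) {
        queue <- c(queue, list(list(start = k, parent = bi)))
      }
    }
  }
  # children branches start at parent's end node, so the constructor's
  # attachment arithmetic applies; but a mid-queue parent path starts at its
  # parent's end node: include that node as the first point
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    if (b$parent > 0) {
      pp <- branches[[b$parent]]$points
      endp <- pp[nrow(pp), ]
      if (sqrt(sum((b$points[1, ] - endp)^2)) > 1e-9) {
        b$points <- rbind(endp, b$points)
        b$radius <- c(branches[[b$parent]]$radius[nrow(pp)], b$radius)
        branches[[i]] <- b
      }
    }
  }
  skeleton(branches, soma_center = c(nd$x[1], nd$y[1], nd$z[1]),
           soma_radius = nd$radius[1])
}

#' Resample a skeleton at fixed arclength steps
#'
#' Samples each branch at path-length multiples of `step` from the branch
#' start, including 0 and the exact branch end when its length is not a
#' multiple of `step`. Radii and positions are linearly interpolated. The
#' path distance of a sample is the branch attachment distance plus the
#' within-branch arclength, floored at zero (distances are measured from the
#' soma surface).
#'
#' @param s A [skeleton()].
#' @param step Resampling interval, um (default 0.1 um = 100 nm).
#' @return A tibble: `sample_id`, `branch_id`, `x`, `y`, `z`, `radius`,
#'   `path_distance`.
#' @export
resample_skeleton <- function(s, step = 0.1) {
  stopifnot(inherits(s, "skeleton"))
  if (step <= 0) rlang::abort("step must be positive")
  out <- purrr::imap(s$branches, function(b, bi) {
    arc <- branch_arclength(b$points)
    len <- arc[length(arc)]
    ss <- seq(0, len, by = step)
    if (length(ss) == 0 || max(ss) < len - 1e-9) ss <- c(ss, len)
    xi <- stats::approx(arc, b$points[, 1], xout = ss)$y
    yi <- stats::approx(arc, b$points[, 2], xout = ss)$y
    zi <- stats::approx(arc, b$points[, 3], xout = ss)$y
    ri <- stats::approx(arc, b$radius, xout = ss)$y
    tibble::tibble(branch_id = bi, x = xi, y = yi, z = zi, radius = ri,
                   path_distance = pmax(0, b$attach_distance + ss))
  })
  out <- dplyr::bind_rows(out)
  out$sample_id <- seq_len(nrow(out))
  out[, c("sample_id", "branch_id", "x", "y", "z", "radius", "path_distance")]
}

#' Assign puncta to the nearest skeleton sample within the search radius
#'
#' A punctum is associated with the dendrite if its center lies within
#' `R_search = local radius + alpha` of some skeleton sample; it is assigned
#' to the nearest qualifying sample and inherits that sample's path distance.
#'
#' @param puncta Puncta tibble (columns `x`, `y`, `z` at minimum).
#' @param samples Resampled skeleton from [resample_skeleton()].
#' @param alpha Search-radius margin beyond the local dendritic radius, um.
#' @return `puncta` with added columns `assigned`, `sample_id`, `branch_id`,
#'   `path_distance`, `dist_to_skeleton`.
#' @export
assign_puncta <- function(puncta, samples, alpha = 0.2) {
  puncta <- tibble::as_tibble(puncta)
  if (!all(c("x", "y", "z") %in% names(puncta))) {
    rlang::abort("puncta table needs x, y, z columns")
  }
  np <- nrow(puncta)
  sid <- rep(NA_integer_, np)
  dmin <- rep(NA_real_, np)
  sx <- samples$x; sy <- samples$y; sz <- samples$z
  rsearch <- samples$radius + alpha
  for (i in seq_len(np)) {
    d2 <- (sx - puncta$x[i])^2 + (sy - puncta$y[i])^2 + (sz - puncta$z[i])^2
    d <- sqrt(d2)
    ok <- which(d <= rsearch)
    if (length(ok) > 0) {
      j <- ok[which.min(d[ok])]
      sid[i] <- samples$sample_id[j]
      dmin[i] <- d[j]
    }
  }
  puncta$assigned <- !is.na(sid)
  puncta$sample_id <- sid
  pos <- match(sid, samples$sample_id)
  puncta$branch_id <- samples$branch_id[pos]
  puncta$path_distance <- samples$path_distance[pos]
  puncta$dist_to_skeleton <- dmin
  puncta
}

#' Path-distance histogram of assigned puncta and skeleton segments
#'
#' Counts assigned puncta and resampled skeleton samples in half-open
#' `[lo, hi)` distance bins and estimates the linear puncta density as
#' puncta per micrometre of dendrite (`count / (segments * step)`); the
#' per-segment ratio is also reported.
#'
#' @param assignments Output of [assign_puncta()].
#' @param samples The resampled skeleton used for the assignment.
#' @param bin_width Bin width, um.
#' @param step Resampling step used for `samples`, um.
#' @return A `distance_histogram` tibble: `bin_lo`, `bin_hi`, `bin_center`,
#'   `puncta_count`, `segment_count`, `density_per_um`,
#'   `density_per_segment`.
#' @export
distance_histogram <- function(assignments, samples, bin_width = 10,
                               step = 0.1) {
  d_p <- assignments$path_distance[assignments$assigned]
  d_s <- samples$path_distance
  top <- max(c(d_p, d_s, bin_width))
  edges <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  bin_of <- function(x) pmin(findInterval(x, edges, left.open = FALSE), length(lo))
  pc <- tabulate(bin_of(d_p), nbins = length(lo))
  sc <- tabulate(bin_of(d_s), nbins = length(lo))
  out <- tibble::tibble(
    bin_lo = lo, bin_hi = hi, bin_center = (lo + hi) / 2,
    puncta_count = pc, segment_count = sc,
    density_per_um = ifelse(sc > 0, pc / (sc * step), NA_real_),
    density_per_segment = ifelse(sc > 0, pc / sc, NA_real_)
  )
  class(out) <- c("distance_histogram", class(out))
  attr(out, "step") <- step
  out
}

#' Cumulative distribution of puncta path distances
#'
#' Empirical CDF sampled on a uniform distance grid.
#'
#' @param distances Path distances of assigned puncta, um (or an
#'   [assign_puncta()] result, from which assigned distances are taken).
#' @param step Grid step, um.
#' @return A tibble: `distance`, `cumulative`.
#' @export
cumulative_distribution <- function(distances, step = 1) {
  if (is.data.frame(distances)) {
    distances <- distances$path_distance[distances$assigned]
  }
  if (length(distances) == 0) rlang::abort("no assigned puncta")
  grid <- seq(0, ceiling(max(distances) / step) * step, by = step)
  f <- stats::ecdf(distances)
  tibble::tibble(distance = grid, cumulative = f(grid))
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' @param a,b Numeric vectors of path distances (or [assign_puncta()]
#'   results).
#' @return A tibble: `ks_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(a, b) {
  take <- function(x) if (is.data.frame(x)) x$path_distance[x$assigned] else x
  a <- take(a); b <- take(b)
  if (length(a) == 0 || length(b) == 0) rlang::abort("empty distance set")
  kt <- suppressWarnings(stats::ks.test(a, b))
  tibble::tibble(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(a), n_b = length(b))
}

#' Pearson's median skewness
#'
#' `3 (mean - median) / SD` with the sample (n - 1) standard deviation; a
#' robust summary of distribution asymmetry.
#'
#' @param values Numeric vector (at least 2 values, nonzero dispersion).
#' @return Skewness coefficient.
#' @export
pearson_median_skewness <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) rlang::abort("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) rlang::abort("zero dispersion")
  3 * (mean(values) - stats::median(values)) / s
}
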