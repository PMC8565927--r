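#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

swc_kind_from_type <- function(type) {
  kind <- rep("dendrite", length(type))
  kind[type == 1] <- "soma"
  kind[type == 2] <- "axon"
  kind
}

swc_type_from_kind <- function(kind) {
  c(soma = 1L, axon = 2L, dendrite = 3L)[kind]
}

#' Construct a morphology from a node table
#'
#' A morphology is a rooted tree of 3D nodes with radii and structure kinds
#' (`soma`, `dendrite`, `axon`). Coordinates and radii are in micrometres.
#' The root is the soma node whose `parent_id` is `-1`; every other node
#' points to a parent that precedes it in the table.
#'
#' @param nodes A data frame with columns `id`, `parent_id`, `x`, `y`, `z`,
#'   `radius`, `kind`.
#' @return A `morphology` object: a list with the validated `nodes` tibble
#'   (topologically ordered) and `soma_surface_offset`, the soma radius used
#'   when measuring path distances from the soma surface.
#' @export
morphology <- function(nodes) {
  nodes <- as_tibble(nodes)
  required <- c("id", "parent_id", "x", "y", "z", "radius", "kind")
  missing <- setdiff(required, names(nodes))
  if (length(missing) > 0) {
    abort(paste0("morphology nodes lack column(s): ", paste(missing, collapse = ", ")))
  }
  nodes <- nodes[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id)) {
    abort(paste0("duplicated node id: ", nodes$id[anyDuplicated(nodes$id)]))
  }
  bad_r <- which(!is.finite(nodes$radius) | nodes$radius <= 0)
  if (length(bad_r) > 0) {
    abort(paste0("nonpositive radius at node id ", nodes$id[bad_r[1]]))
  }
  if (!all(nodes$kind %in% c("soma", "dendrite", "axon"))) {
    abort("node kind must be one of 'soma', 'dendrite', 'axon'")
  }
  roots <- which(nodes$parent_id == -1L)
  if (length(roots) != 1L) {
    abort(paste0("morphology must have exactly one root, found ", length(roots)))
  }
  orphan <- which(nodes$parent_id != -1L & !(nodes$parent_id %in% nodes$id))
  if (length(orphan) > 0) {
    abort(paste0("node id ", nodes$id[orphan[1]], " references undefined parent id ",
                 nodes$parent_id[orphan[1]]))
  }
  if (nodes$kind[roots] != "soma") {
    abort("root node must be of kind 'soma'")
  }
  nodes <- topo_sort_nodes(nodes, roots)
  structure(
    list(nodes = nodes, soma_surface_offset = nodes$radius[1]),
    class = "morphology"
  )
}

# Reorder so parents precede children; detects cycles / disconnected nodes.
topo_sort_nodes <- function(nodes, root_pos) {
  n <- nrow(nodes)
  idx <- match(nodes$parent_id, nodes$id) # NA for root
  children <- split(seq_len(n), idx)
  order <- integer(n)
  order[1] <- root_pos
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    cur <- order[head]
    kids <- children[[as.character(cur)]]
    if (!is.null(kids)) {
      order[(tail + 1L):(tail + length(kids))] <- kids
      tail <- tail + length(kids)
    }
    head <- head + 1L
  }
  if (tail < n) {
    stray <- setdiff(seq_len(n), order[seq_len(tail)])
    abort(paste0("cycle or disconnected subtree involving node id ", nodes$id[stray[1]]))
  }
  nodes[order, ]
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<morphology> %d nodes (%d soma, %d dendrite, %d axon), total dendritic length %.1f um\n",
              nrow(nd), sum(nd$kind == "soma"), sum(nd$kind == "dendrite"),
              sum(nd$kind == "axon"), total_dendritic_length(x)))
  invisible(x)
}

#' @method as_tibble morphology
#' @export
as_tibble.morphology <- function(x, ...) x$nodes

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC dialect: `id type x y z radius parent`, radius (not
#' diameter) in micrometres, `#` comments, parent `-1` for the root. Type
#' codes 1 (soma), 2 (axon) and 3/4 (dendrite) are recognised; other codes
#' are treated as dendrite.
#'
#' @param source Path to an SWC file, or a character vector of SWC lines.
#' @return A [morphology()] object.
#' @export
read_swc <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("SWC source contains no records")
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    abort(paste0("malformed SWC record (expected 7 columns): '", lines[which(nf != 7)[1]], "'"))
  }
  rec <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(rec)) abort("non-numeric field in SWC record")
  morphology(tibble(
    id = as.integer(rec[, 1]),
    parent_id = as.integer(rec[, 7]),
    x = rec[, 3], y = rec[, 4], z = rec[, 5],
    radius = rec[, 6],
    kind = swc_kind_from_type(as.integer(rec[, 2]))
  ))
}

#' Write a morphology to an SWC file
#'
#' @param m A [morphology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  nd <- m$nodes
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   nd$id, swc_type_from_kind(nd$kind), nd$x, nd$y, nd$z,
                   nd$radius, nd$parent_id)
  writeLines(c("# SWC written by scable", lines), path)
  invisible(path)
}

#' Build an idealized stellate-cell morphology
#'
#' A spherical soma with `n_dendrites` straight dendrites of uniform diameter
#' radiating in the xy-plane, each of total path length `dendrite_length`
#' measured from the soma center. `branches_per_dendrite` of 3 or 5 adds one
#' or two bifurcations per dendrite at equal length fractions of the primary
#' path; daughter branches share the dendritic diameter and run to the same
#' tip path length.
#'
#' @param soma_diameter Soma diameter, um. The default 8 um matches confocal
#'   estimates of immature stellate-cell somata; 9 um is the alternative used
#'   in some idealized models.
#' @param n_dendrites Number of primary dendrites (0 allowed).
#' @param dendrite_length Tip path length of each dendrite from the soma
#'   center, um.
#' @param dendrite_diameter Uniform dendritic diameter, um.
#' @param branches_per_dendrite 1 (unbranched), 3 or 5 terminal branches.
#' @param node_spacing Inter-node sampling step along dendrites, um.
#' @return A [morphology()].
#' @export
build_idealized_sc <- function(soma_diameter = 8, n_dendrites = 1,
                               dendrite_length = 90, dendrite_diameter = 0.47,
                               branches_per_dendrite = 1, node_spacing = 1) {
  if (soma_diameter <= 0) abort("soma_diameter must be positive")
  if (n_dendrites < 0) abort("n_dendrites must be >= 0")
  rows <- list(tibble(id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                      radius = soma_diameter / 2, kind = "soma"))
  next_id <- 2L
  if (n_dendrites > 0) {
    if (dendrite_length <= 0 || dendrite_diameter <= 0) {
      abort("dendrite dimensions must be positive")
    }
    if (!branches_per_dendrite %in% c(1, 3, 5)) {
      abort("branches_per_dendrite must be 1, 3 or 5")
    }
    if (node_spacing <= 0) abort("node_spacing must be positive")
    for (k in seq_len(n_dendrites)) {
      theta <- 2 * pi * (k - 1) / n_dendrites
      u <- c(cos(theta), sin(theta))
      res <- grow_ideal_dendrite(next_id, 1L, u, dendrite_length,
                                 dendrite_diameter / 2, branches_per_dendrite,
                                 node_spacing, theta)
      rows <- c(rows, res$rows)
      next_id <- res$next_id
    }
  }
  morphology(dplyr::bind_rows(rows))
}

# Straight run of nodes from `from` (exclusive) toward direction u, covering
# path lengths (s0, s1] at steps of `spacing` plus the exact endpoint.
straight_nodes <- function(next_id, parent_id, origin, u, s0, s1, spacing, radius) {
  ds <- seq(spacing, s1 - s0, by = spacing)
  if (length(ds) == 0 || max(ds) < (s1 - s0) - 1e-9) ds <- c(ds, s1 - s0)
  n <- length(ds)
  ids <- seq.int(next_id, length.out = n)
  tibble(
    id = ids,
    parent_id = c(parent_id, ids[-n]),
    x = origin[1] + ds * u[1],
    y = origin[2] + ds * u[2],
    z = 0,
    radius = radius,
    kind = "dendrite"
  )
}

grow_ideal_dendrite <- function(next_id, soma_id, u, L, radius, branches, spacing, theta) {
  n_bif <- (branches - 1) / 2
  split_at <- if (n_bif > 0) L * seq_len(n_bif) / (n_bif + 1) else numeric(0)
  rows <- list()
  origin <- c(0, 0)
  parent <- soma_id
  s_prev <- 0
  for (s in c(split_at, L)) {
    seg <- straight_nodes(next_id, parent, origin, u, s_prev, s, spacing, radius)
    rows <- c(rows, list(seg))
    next_id <- max(seg$id) + 1L
    parent <- seg$id[nrow(seg)]
    origin <- c(seg$x[nrow(seg)], seg$y[nrow(seg)])
    if (s < L) {
      # side daughter from the bifurcation to tip path length L
      v_theta <- theta + pi / 4.5 * (if (s == split_at[1]) 1 else -1)
      v <- c(cos(v_theta), sin(v_theta))
      daughter <- straight_nodes(next_id, parent, origin, v, s, L, spacing, radius)
      rows <- c(rows, list(daughter))
      next_id <- max(daughter$id) + 1L
    }
    s_prev <- s
  }
  list(rows = rows, next_id = next_id)
}

node_parent_index <- function(m) {
  match(m$nodes$parent_id, m$nodes$id)
}

node_edge_lengths <- function(m) {
  nd <- m$nodes
  pi_ <- node_parent_index(m)
  len <- numeric(nrow(nd))
  has_p <- !is.na(pi_)
  len[has_p] <- sqrt((nd$x[has_p] - nd$x[pi_[has_p]])^2 +
                     (nd$y[has_p] - nd$y[pi_[has_p]])^2 +
                     (nd$z[has_p] - nd$z[pi_[has_p]])^2)
  len
}

node_path_distances <- function(m, origin = c("soma_center", "soma_surface")) {
  origin <- match.arg(origin)
  nd <- m$nodes
  pi_ <- node_parent_index(m)
  len <- node_edge_lengths(m)
  d <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))[-1]) d[i] <- d[pi_[i]] + len[i]
  if (origin == "soma_surface") d <- pmax(0, d - m$soma_surface_offset)
  d
}

#' Path distance from the soma to nodes of a morphology
#'
#' Sum of Euclidean inter-node step lengths along the unique path from the
#' root. With `origin = "soma_surface"` the soma radius is subtracted
#' (floored at zero), matching distances measured from the soma surface.
#'
#' @param m A [morphology()].
#' @param node_id Node id(s); default all nodes.
#' @param origin `"soma_center"` (default) or `"soma_surface"`.
#' @return If `node_id` is given, a numeric vector of distances (um);
#'   otherwise a tibble with columns `id`, `path_distance`.
#' @export
path_distance <- function(m, node_id = NULL,
                          origin = c("soma_center", "soma_surface")) {
  stopifnot(inherits(m, "morphology"))
  d <- node_path_distances(m, origin)
  if (is.null(node_id)) {
    return(tibble(id = m$nodes$id, path_distance = d))
  }
  pos <- match(node_id, m$nodes$id)
  if (anyNA(pos)) {
    abort(paste0("unknown node id: ", node_id[which(is.na(pos))[1]]))
  }
  d[pos]
}

#' Sholl analysis
#'
#' Counts dendritic segments crossing concentric spheres centered on the soma
#' center. A segment contributes one crossing per intersection of the sphere
#' with the open-closed parameter interval (0, 1] along the segment, so
#' shared endpoints are not double-counted.
#'
#' @param m A [morphology()].
#' @param radii Strictly increasing sphere radii, um.
#' @return A tibble with columns `radius`, `crossings`.
#' @export
sholl_analysis <- function(m, radii) {
  stopifnot(inherits(m, "morphology"))
  if (length(radii) > 1 && any(diff(radii) <= 0)) {
    abort("radii must be strictly increasing")
  }
  nd <- m$nodes
  center <- c(nd$x[1], nd$y[1], nd$z[1])
  pi_ <- node_parent_index(m)
  is_edge <- !is.na(pi_) & nd$kind == "dendrite"
  p2 <- cbind(nd$x, nd$y, nd$z)
  counts <- vapply(radii, function(r) {
    total <- 0L
    for (i in which(is_edge)) {
      w <- p2[pi_[i], ] - center
      v <- p2[i, ] - p2[pi_[i], ]
      a <- sum(v * v)
      if (a == 0) next
      b <- 2 * sum(w * v)
      c0 <- sum(w * w) - r^2
      disc <- b^2 - 4 * a * c0
      if (disc < 0) next
      t12 <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      total <- total + sum(t12 > 1e-12 & t12 <= 1)
    }
    total
  }, integer(1))
  tibble(radius = radii, crossings = counts)
}

#' Branch statistics of a morphology
#'
#' Primary dendrites are dendrites rooted at the soma. A bifurcation counts
#' as a branch point only when at least two daughter subtrees extend further
#' than `min_branch_length` beyond it (short twigs are ignored);
#' multifurcations with k qualifying daughters count k - 1 points.
#' `max_dendritic_length` is the greatest tip-to-soma path distance.
#'
#' @param m A [morphology()].
#' @param min_branch_length Minimum daughter subtree path length for a branch
#'   point to count, um.
#' @param origin Path-distance origin for `max_dendritic_length`.
#' @return One-row tibble: `n_primary`, `n_branch_points`,
#'   `branch_points_per_primary`, `max_dendritic_length`.
#' @export
branch_statistics <- function(m, min_branch_length = 10,
                              origin = c("soma_center", "soma_surface")) {
  stopifnot(inherits(m, "morphology"))
  origin <- match.arg(origin)
  nd <- m$nodes
  n <- nrow(nd)
  pi_ <- node_parent_index(m)
  len <- node_edge_lengths(m)
  dend <- nd$kind == "dendrite"
  n_primary <- sum(dend & !is.na(pi_) & nd$kind[pmax(pi_, 1)] == "soma", na.rm = TRUE)

  # downward extent of each dendritic subtree (max path length below node)
  extent <- numeric(n)
  for (i in rev(seq_len(n))) {
    if (is.na(pi_[i]) || !dend[i]) next
    p <- pi_[i]
    extent[p] <- max(extent[p], extent[i] + len[i])
  }
  n_bp <- 0L
  for (i in which(dend)) {
    kids <- which(!is.na(pi_) & pi_ == i & dend)
    if (length(kids) < 2) next
    q <- sum(extent[kids] + len[kids] > min_branch_length)
    if (q >= 2) n_bp <- n_bp + (q - 1L)
  }
  d <- node_path_distances(m, origin)
  is_tip <- dend & !(seq_len(n) %in% pi_)
  max_len <- if (any(is_tip)) max(d[is_tip]) else 0
  tibble(
    n_primary = n_primary,
    n_branch_points = n_bp,
    branch_points_per_primary = if (n_primary > 0) n_bp / n_primary else NA_real_,
    max_dendritic_length = max_len
  )
}

total_dendritic_length <- function(m) {
  len <- node_edge_lengths(m)
  sum(len[m$nodes$kind == "dendrite"])
}

#' Estimate a dendritic diameter from an intensity line profile
#'
#' Fits a Gaussian with baseline, `I(x) = b + a exp(-(x - mu)^2 / (2 sigma^2))`,
#' by nonlinear least squares and returns the full width at half maximum,
#' `2 sqrt(2 ln 2) sigma`, the standard diameter proxy for sub-resolution
#' structures in fluorescence line profiles.
#'
#' @param profile Data frame with columns `position` (um) and `intensity`
#'   (arbitrary units); at least 7 samples spanning the peak.
#' @return Estimated diameter (FWHM), um.
#' @export
estimate_diameter_fwhm <- function(profile) {
  profile <- as.data.frame(profile)
  if (!all(c("position", "intensity") %in% names(profile))) {
    names(profile)[1:2] <- c("position", "intensity")
  }
  x <- profile$position
  y <- profile$intensity
  if (length(x) < 7) abort("need at least 7 samples spanning the peak")
  b0 <- min(y)
  a0 <- max(y) - b0
  if (a0 <= 0) abort("profile is flat: no peak to fit")
  mu0 <- x[which.max(y)]
  above <- x[y > b0 + a0 / 2]
  # deliberately rough starts: an exact-Gaussian profile with moment-perfect
  # starts gives nlsLM a degenerate initial model
  s0 <- 1.3 * max(diff(range(above)), diff(range(x)) / 10) / 2.3548
  start <- list(b = b0 + 0.05 * a0, a = 0.9 * a0,
                mu = mu0 + 0.25 * stats::median(diff(x)), s = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - mu)^2 / (2 * s^2)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("Gaussian fit failed: ", conditionMessage(e)))
  )
  cf <- stats::coef(fit)
  if (cf[["a"]] <= 0 || cf[["s"]] <= 0) {
    abort(sprintf(
      "profile is not peaked (fitted amplitude %.3g, sigma %.3g); residual SD %.3g",
      cf[["a"]], cf[["s"]], stats::sd(stats::resid(fit))))
  }
  2 * sqrt(2 * log(2)) * abs(cf[["s"]])
}
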