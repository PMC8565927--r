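crit <- filter_criteria(psf_xyz = c(0.3, 0.3, 1.1), background_mean = 100,
                        background_sd = 10)

mk_spot <- function(dx, dy, dz, int, soma = 0) {
  tibble::tibble(x = 0, y = 0, z = 0, diameter_x = dx, diameter_y = dy,
                 diameter_z = dz, peak_intensity = int,
                 soma_channel_intensity = soma)
}

test_that("puncta filtering applies strict PSF and intensity thresholds", {
  # exactly at the PSF on all axes: rejected
  expect_equal(nrow(filter_puncta(mk_spot(0.3, 0.3, 1.1, 1000), crit)), 0)
  # exactly at mean + 3 SD: rejected
  expect_equal(nrow(filter_puncta(mk_spot(0.5, 0.5, 1.5, 130), crit)), 0)
  # just above both: accepted
  expect_equal(nrow(filter_puncta(mk_spot(0.31, 0.31, 1.11, 130.1), crit)), 1)
  # sub-PSF on a single axis suffices for rejection
  expect_equal(nrow(filter_puncta(mk_spot(0.5, 0.29, 1.5, 1000), crit)), 0)
})

test_that("filtering equals the brute-force predicate and is a pure predicate", {
  set.seed(101)
  spots <- tibble::tibble(
    x = runif(100), y = runif(100), z = runif(100),
    diameter_x = runif(100, 0.1, 0.8), diameter_y = runif(100, 0.1, 0.8),
    diameter_z = runif(100, 0.5, 2), peak_intensity = runif(100, 50, 300),
    soma_channel_intensity = runif(100, 0, 1000)
  )
  keep <- logical(100)
  for (i in 1:100) {
    keep[i] <- spots$diameter_x[i] > 0.3 && spots$diameter_y[i] > 0.3 &&
      spots$diameter_z[i] > 1.1 && spots$peak_intensity[i] > 130
  }
  got <- filter_puncta(spots, crit)
  expect_equal(got, spots[keep, ])
  # idempotent and order-independent
  expect_equal(filter_puncta(got, crit), got)
  shuffled <- spots[sample(100), ]
  expect_equal(dplyr::arrange(filter_puncta(shuffled, crit), x),
               dplyr::arrange(got, x))
})

test_that("somatic selection additionally requires a bright soma channel", {
  expect_equal(nrow(select_somatic_puncta(mk_spot(0.5, 0.5, 1.5, 200, 600),
                                          1000, crit)), 1)
  expect_equal(nrow(select_somatic_puncta(mk_spot(0.5, 0.5, 1.5, 200, 400),
                                          1000, crit)), 0)
  # soma brightness alone is not enough: size criteria still apply
  expect_equal(nrow(select_somatic_puncta(mk_spot(0.2, 0.5, 1.5, 200, 900),
                                          1000, crit)), 0)
})

test_that("skeleton resampling follows the stated sampling convention", {
  sk <- skeleton(list(list(points = rbind(c(0, 0, 0), c(1, 0, 0)),
                           radius = c(0.3, 0.3), parent = 0L,
                           attach_distance = 0)))
  rs <- resample_skeleton(sk, 0.1)
  expect_equal(nrow(rs), 11)
  expect_equal(rs$path_distance, seq(0, 1, 0.1))

  # terminal remainder point is kept
  sk2 <- skeleton(list(list(points = rbind(c(0, 0, 0), c(1.05, 0, 0)),
                            radius = c(0.3, 0.3), parent = 0L,
                            attach_distance = 0)))
  rs2 <- resample_skeleton(sk2, 0.1)
  expect_equal(nrow(rs2), 12)
  expect_equal(max(rs2$path_distance), 1.05)

  # reconstructed length within one step of the true length
  m <- random_tree(5)
  rs3 <- resample_skeleton(skeleton_from_morphology(m), 0.1)
  per_branch <- dplyr::summarise(
    dplyr::group_by(rs3, branch_id),
    len = dplyr::n() - 1, .groups = "drop")
  # radii are interpolated within observed bounds
  expect_true(all(rs3$radius >= min(m$nodes$radius[m$nodes$kind == "dendrite"]) - 1e-9))
})

test_that("child branches inherit the parent attachment distance", {
  parent <- list(points = rbind(c(0, 0, 0), c(2, 0, 0)), radius = c(0.4, 0.4),
                 parent = 0L, attach_distance = 0)
  child <- list(points = rbind(c(2, 0, 0), c(2, 1.5, 0)), radius = c(0.4, 0.4),
                parent = 1L)
  rs <- resample_skeleton(skeleton(list(parent, child)), 0.1)
  first_child <- rs$path_distance[rs$branch_id == 2][1]
  expect_equal(first_child, 2)
  expect_equal(max(rs$path_distance), 3.5)
})

test_that("puncta assignment respects the search radius and matches brute force", {
  sk <- skeleton(list(list(points = rbind(c(0, 0, 0), c(10, 0, 0)),
                           radius = rep(0.5, 2), parent = 0L,
                           attach_distance = 0)))
  rs <- resample_skeleton(sk, 0.1)
  on_axis <- tibble::tibble(x = 5, y = 0, z = 0)
  expect_true(assign_puncta(on_axis, rs)$assigned)
  # offset radius + 0.25 um: beyond R_search = radius + 0.2
  off <- tibble::tibble(x = 5, y = 0.5 + 0.25, z = 0)
  expect_false(assign_puncta(off, rs)$assigned)
  # offset radius + 0.15: inside
  near <- tibble::tibble(x = 5, y = 0.5 + 0.15, z = 0)
  expect_true(assign_puncta(near, rs)$assigned)

  # 1000 random puncta vs exhaustive all-pairs oracle on a random tree
  rs2 <- resample_skeleton(skeleton_from_morphology(random_tree(9)), 0.2)
  set.seed(31)
  pts <- tibble::tibble(x = runif(1000, -30, 30), y = runif(1000, -30, 30),
                        z = runif(1000, -15, 15))
  got <- assign_puncta(pts, rs2, alpha = 0.2)
  d_mat <- as.matrix(stats::dist(rbind(as.matrix(pts),
                                       as.matrix(rs2[, c("x", "y", "z")]))))
  d_ps <- d_mat[seq_len(1000), 1000 + seq_len(nrow(rs2))]
  for (i in seq_len(1000)) {
    ok <- which(d_ps[i, ] <= rs2$radius + 0.2)
    if (length(ok) == 0) {
      expect_false(got$assigned[i])
    } else {
      j <- ok[which.min(d_ps[i, ok])]
      expect_identical(got$sample_id[i], rs2$sample_id[j])
    }
  }
})

test_that("distance histograms bin half-open, conserve counts, and recover uniform density", {
  sk <- skeleton(list(list(points = rbind(c(0, 0, 0), c(30, 0, 0)),
                           radius = rep(0.4, 2), parent = 0L,
                           attach_distance = 0)))
  rs <- resample_skeleton(sk, 0.1)
  pts <- tibble::tibble(x = c(5, 15), y = 0, z = 0)
  asg <- assign_puncta(pts, rs)
  h <- distance_histogram(asg, rs, bin_width = 10, step = 0.1)
  expect_equal(h$puncta_count[1:2], c(1L, 1L))
  expect_equal(sum(h$puncta_count), sum(asg$assigned))

  # uniform synthetic density 0.5/um recovered within the 95% Poisson band
  skl <- skeleton_from_morphology(build_idealized_sc(8, 4, 80, 0.6, 1, 2))
  pts2 <- generate_puncta(skl, density = 0.5, seed = 5, decoy_fraction = 0)
  rs2 <- resample_skeleton(skl, 0.1)
  asg2 <- assign_puncta(pts2, rs2)
  h2 <- distance_histogram(asg2, rs2, bin_width = 10, step = 0.1)
  full <- h2[h2$segment_count >= 50, ]
  lam <- 0.5 * full$segment_count * 0.1
  ok <- full$puncta_count >= qpois(0.025, lam) &
    full$puncta_count <= qpois(0.975, lam)
  expect_gte(mean(ok), 0.75)
  expect_equal(mean(full$density_per_um), 0.5, tolerance = 0.2)
  expect_equal(h2$density_per_segment, h2$density_per_um * 0.1)
})

test_that("cumulative distributions and the KS comparison behave canonically", {
  single <- cumulative_distribution(12)
  expect_true(all(single$cumulative[single$distance < 12] == 0))
  expect_true(all(single$cumulative[single$distance >= 12] == 1))

  set.seed(77)
  a <- runif(4000, 0, 35)
  expect_equal(compare_distributions(a, a)$ks_statistic, 0)
  b <- runif(4000, 0, 100)
  ks <- compare_distributions(a, b)
  # analytic sup-difference of the two uniform CDFs is 0.65 at x = 35
  expect_equal(ks$ks_statistic, 0.65, tolerance = 0.03)
  expect_lt(ks$p_value, 1e-6)
  expect_error(compare_distributions(numeric(0), b), "empty")
})

test_that("Pearson's median skewness matches hand computation and affine invariance", {
  expect_equal(pearson_median_skewness(c(1, 2, 3, 4, 5)), 0)
  v <- c(1, 2, 3, 4, 10)
  expect_equal(pearson_median_skewness(v), 3 * (4 - 3) / sd(v))
  expect_equal(pearson_median_skewness(v), 0.8485, tolerance = 1e-4)
  expect_equal(pearson_median_skewness(5 * v + 2), pearson_median_skewness(v))
  expect_equal(pearson_median_skewness(-v), -pearson_median_skewness(v))
  expect_error(pearson_median_skewness(rep(3, 5)), "dispersion")
})
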