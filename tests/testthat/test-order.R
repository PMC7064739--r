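test_that("O(r) reproduces the parallel/perpendicular/anti-parallel anchors", {
  for (case in list(list(theta = 0, o = 1), list(theta = 90, o = -0.5),
                    list(theta = 180, o = 1))) {
    cfg <- generate_pair(theta = case$theta, r = 5)
    op <- order_profile(trajectory(cfg), bin_width = 0.5, r_max = 20)
    occupied <- which(op$pair_counts > 0)
    expect_length(occupied, 1)
    expect_equal(op$bin_edges[occupied + 1], 5)  # bin (4.5, 5] holds r = 5
    expect_equal(op$o_values[occupied], case$o, tolerance = 1e-12)
  }
})

test_that("isotropic ensembles give O(r) = 0 within 3 SE in every bin", {
  traj <- generate_aligned(generator_spec(
    n_molecules = 1000, order_target = 0, box = c(120, 120, 120),
    rod_length = 5, min_separation = 0, seed = 41))
  op <- order_profile(traj, bin_width = 5, r_max = 60)
  # Var(P2) = 1/5 for isotropic pairs
  for (b in which(op$pair_counts > 30)) {
    se <- sqrt(1 / 5 / op$pair_counts[b])
    expect_lt(abs(op$o_values[b]), 4 * se)
  }
})

test_that("aligned ensembles give O(r) near S^2 in populated bins", {
  traj <- generate_aligned(generator_spec(
    n_molecules = 500, order_target = 0.8, box = c(100, 100, 100),
    rod_length = 5, min_separation = 0, seed = 43, frames = 4))
  op <- order_profile(traj, bin_width = 10, r_max = 50)
  big <- which(op$pair_counts > 5000)
  expect_gt(length(big), 2)
  expect_lt(max(abs(op$o_values[big] - 0.64)), 0.03)
})

test_that("order profile equals a naive double-loop oracle on one frame", {
  set.seed(47)
  b <- box(60, 60, 60)
  n <- 40
  coms <- matrix(stats::runif(n * 3, 0, 60), n)
  axes <- t(replicate(n, rand_unit()))
  cfg <- rod_config(coms, axes, b, len = 4)
  bw <- 2; rmax <- 30
  op <- order_profile(trajectory(cfg), bin_width = bw, r_max = rmax)
  nb <- length(op$o_values)
  sums <- numeric(nb); counts <- numeric(nb)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- oracle_min_image_dist(coms[i, ], coms[j, ], b)
    if (d <= rmax && d > 0) {
      bin <- min(nb, ceiling(d / bw))
      sums[bin] <- sums[bin] + legendre_p2(sum(axes[i, ] * axes[j, ]))
      counts[bin] <- counts[bin] + 1
    }
  }
  expect_equal(op$pair_counts, counts)
  got <- op$o_values[counts > 0]
  expect_equal(got, sums[counts > 0] / counts[counts > 0], tolerance = 1e-12)
  expect_true(all(got >= -0.5 - 1e-12 & got <= 1 + 1e-12))
  expect_true(all(is.na(op$o_values[counts == 0])))
})

test_that("O(r) is invariant under global rotations and axis sign flips", {
  set.seed(53)
  # keep all molecules in a central cluster so no pair wraps: the torus
  # metric is only rotation invariant when minimum image = direct image
  coms <- matrix(stats::runif(90, 22, 38), 30)
  axes <- t(replicate(30, rand_unit()))
  cfg <- rod_config(coms, axes, box(60), len = 5)
  traj <- trajectory(cfg)
  op <- order_profile(traj, bin_width = 3, r_max = 30)
  R <- rand_rotation()
  ctr <- c(30, 30, 30)
  rot <- transform_config(cfg, R, ctr - as.numeric(R %*% ctr))
  op_rot <- order_profile(trajectory(rot), bin_width = 3, r_max = 30)
  expect_equal(op_rot$o_values, op$o_values, tolerance = 1e-9)
  # flipping head/tail of some molecules cannot change P2
  flipped <- cfg
  for (i in seq(1, 30, by = 3)) {
    m <- flipped$molecules[[i]]
    flipped$molecules[[i]] <- molecule(m$id, m$xyz, m$masses,
                                       head = m$tail, tail = m$head)
  }
  op_flip <- order_profile(trajectory(flipped), bin_width = 3, r_max = 30)
  expect_equal(op_flip$o_values, op$o_values, tolerance = 1e-12)
})

test_that("pooled and per-frame averaging agree for equal per-frame counts", {
  cfgs <- lapply(c(0, 90), function(th) generate_pair(th, r = 5))
  traj <- trajectory(cfgs)
  pooled <- order_profile(traj, bin_width = 0.5, r_max = 10)
  perfr <- order_profile(traj, bin_width = 0.5, r_max = 10,
                         average = "per_frame")
  occ <- which(pooled$pair_counts > 0)
  expect_equal(pooled$o_values[occ], perfr$o_values[occ])
  expect_equal(pooled$o_values[occ], (1 + (-0.5)) / 2)
})

test_that("r_max beyond the half box and empty trajectories are rejected", {
  cfg <- generate_pair(0, 5)
  expect_error(order_profile(trajectory(cfg), r_max = 60), "half the smallest")
  expect_error(trajectory(list()), "at least one frame")
})

test_that("angle distribution: parallel fixture concentrates in the first bin", {
  traj <- generate_aligned(generator_spec(n_molecules = 20, order_target = 1,
                                          box = c(40, 40, 40), rod_length = 5,
                                          min_separation = 0, seed = 61))
  ad <- angle_distribution(traj, r_max = 20, bin_width = 5)
  expect_equal(sum(ad$density * ad$bin_width), 1, tolerance = 1e-9)
  expect_equal(ad$density[1] * ad$bin_width, 1)
})

test_that("isotropic axes follow the sin(theta) solid-angle law", {
  traj <- generate_aligned(generator_spec(
    n_molecules = 400, order_target = 0, box = c(60, 60, 60),
    rod_length = 5, min_separation = 0, seed = 67))
  ad <- angle_distribution(traj, r_max = 30, bin_width = 5)
  expect_gt(ad$pair_count, 5000)
  sin_cdf <- function(theta_deg) (1 - cos(theta_deg * pi / 180)) / 2
  ks <- suppressWarnings(stats::ks.test(ad$angles, sin_cdf))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(ad$density * ad$bin_width), 1, tolerance = 1e-9)
})

test_that("parallel/anti-parallel mixtures put their mass at the extremes", {
  set.seed(71)
  n <- 40
  coms <- matrix(stats::runif(n * 3, 0, 50), n)
  axes <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  axes[seq(2, n, 2), 3] <- -1  # half anti-parallel
  # small angular jitter so angles are near, not exactly at, 0 and 180
  for (i in 1:n) {
    v <- axes[i, ] + stats::rnorm(3, sd = 0.08)
    axes[i, ] <- v / sqrt(sum(v^2))
  }
  cfg <- rod_config(coms, axes, box(50), len = 4)
  ad <- angle_distribution(trajectory(cfg), r_max = 25, bin_width = 5)
  extreme <- ad$angles < 60 | ad$angles > 120
  expect_gte(mean(extreme), 0.95)
})

test_that("angle distribution demands qualifying pairs and warns when unoriented", {
  cfg <- generate_pair(0, r = 40, box = c(100, 100, 100))
  expect_error(angle_distribution(trajectory(cfg), r_max = 10),
               "no molecule pairs")
  m1 <- molecule("A", rbind(c(0, 0, 0), c(4, 0, 0)))
  m2 <- molecule("B", rbind(c(0, 5, 0), c(4, 5, 0)))
  cfg2 <- configuration(list(m1, m2), box(30))
  expect_warning(ad <- angle_distribution(trajectory(cfg2), r_max = 10),
                 "folding")
  expect_equal(max(ad$bin_edges), 90)
})

test_that("g(r) of a uniform gas is 1 within sampling error over 3-40 A", {
  traj <- generate_aligned(generator_spec(
    n_molecules = 2000, order_target = 0, box = c(100, 100, 100),
    rod_length = 2, min_separation = 0, seed = 73))
  rdf <- com_rdf(traj, bin_width = 1, r_max = 45)
  sel <- rdf$bin_edges[-1] > 3 & rdf$bin_edges[-1] <= 40
  g <- rdf$g_values[sel]
  se <- stats::sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 1), 3 * se)
  # per-bin Poisson check at 4 sigma
  expected <- rdf$counts[sel] / pmax(g, 1e-12)
  expect_true(all(abs(g - 1) < 4 / sqrt(expected)))
})

test_that("two molecules at distance d give the closed-form shell value", {
  cfg <- generate_pair(0, r = 8, box = c(50, 50, 50))
  rdf <- com_rdf(trajectory(cfg), bin_width = 1, r_max = 20)
  occ <- which(rdf$counts > 0)
  expect_length(occ, 1)
  shell <- 4 / 3 * pi * (8^3 - 7^3)
  expect_equal(rdf$g_values[occ], 1 / (1 * shell / 50^3))
})

test_that("a planted first-neighbor shell peaks below 10 A", {
  set.seed(79)
  n <- 30
  b <- box(100)
  centers <- matrix(stats::runif(n / 2 * 3, 10, 90), n / 2)
  coms <- centers
  for (i in seq_len(n / 2))  # partner at exactly 8 A
    coms <- rbind(coms, centers[i, ] + 8 * rand_unit())
  axes <- t(replicate(n, rand_unit()))
  rdf <- com_rdf(trajectory(rod_config(coms, axes, b, len = 4)),
                 bin_width = 1, r_max = 45)
  within10 <- rdf$bin_edges[-1] <= 10
  expect_equal(which.max(rdf$g_values), which.max(rdf$g_values[within10]))
  expect_lte(rdf$bin_edges[which.max(rdf$g_values) + 1], 10)
})

test_that("first-neighbor cutoff finds the basin edge of the first peak", {
  mk_rdf <- function(g, counts = round(100 * g)) {
    structure(list(bin_edges = seq(0, length(g)), g_values = g,
                   counts = counts, n_molecules = 10, box_volume = 1000,
                   frames_used = 1, bin_width = 1, homogeneous = TRUE),
              class = "rdf_profile")
  }
  single <- mk_rdf(c(0, 0, 0, 0, 0, 0, 1, 2.5, 1.2, 0.3, 0, 0, 0, 0))
  cut1 <- first_neighbor_cutoff(single)
  expect_gte(cut1, 8); expect_lte(cut1, 12)
  two_shell <- mk_rdf(c(0, 0, 0, 0, 0, 0.5, 1.5, 2.5, 1.5, 0.6, 0.4, 0.8,
                        1.6, 2.0, 1.4, 0.8, 1, 1, 1, 1))
  cut2 <- first_neighbor_cutoff(two_shell)
  expect_gte(cut2, 8); expect_lte(cut2, 13)
  flat <- mk_rdf(rep(1, 15))
  expect_error(first_neighbor_cutoff(flat), "monotone|no first minimum|no local")
})
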