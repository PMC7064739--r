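test_that("generation is deterministic in the seed and varies across seeds", {
  spec <- generator_spec(n_molecules = 8, seed = 5, frames = 2)
  t1 <- generate_aligned(spec)
  t2 <- generate_aligned(spec)
  expect_identical(t1, t2)
  t3 <- generate_aligned(generator_spec(n_molecules = 8, seed = 6, frames = 2))
  expect_false(isTRUE(all.equal(axis_frame(t1[[1]])$com,
                                axis_frame(t3[[1]])$com)))
})

test_that("perfect alignment (S = 1) gives axes exactly along the director", {
  traj <- generate_aligned(generator_spec(n_molecules = 12, order_target = 1,
                                          seed = 2))
  af <- axis_frame(traj[[1]])
  expect_equal(af$axis, matrix(c(0, 0, 1), 12, 3, byrow = TRUE))
  op <- order_profile(traj, bin_width = 1, r_max = 40)
  expect_equal(unique(op$o_values[op$pair_counts > 0]), 1)
})

test_that("realized single-molecule order matches the target within 3 SE", {
  for (S in c(0, 0.5, 0.8)) {
    traj <- generate_aligned(generator_spec(
      n_molecules = 2000, order_target = S, box = c(200, 200, 200),
      seed = 31 + round(10 * S)))
    af <- axis_frame(traj[[1]])
    p2 <- legendre_p2(af$axis %*% c(0, 0, 1))
    se <- stats::sd(p2) / sqrt(length(p2))
    expect_lt(abs(mean(p2) - S), 3 * max(se, 1e-12) + 1e-12)
  }
})

test_that("pairwise order recovers S^2 (Legendre addition theorem)", {
  S <- 0.8
  traj <- generate_aligned(generator_spec(
    n_molecules = 2000, order_target = S, box = c(200, 200, 200),
    frames = 2, seed = 37))
  expect_lt(abs(pairwise_order(traj) - S^2), 0.02)
})

test_that("slab mode confines centers of mass; box mode stays in the box", {
  spec <- generator_spec(n_molecules = 40, slab_thickness = 12,
                         box = c(80, 80, 80), rod_length = 8, seed = 8)
  traj <- generate_aligned(spec)
  z <- axis_frame(traj[[1]])$com[, 3]
  expect_true(all(abs(z - 40) <= 6 + 1e-9))
  com <- axis_frame(generate_aligned(generator_spec(
    n_molecules = 40, box = c(50, 50, 50), rod_length = 8, seed = 9))[[1]])$com
  expect_true(all(com >= 0 & com <= 50))
})

test_that("min_separation is respected under the minimum image convention", {
  spec <- generator_spec(n_molecules = 60, box = c(40, 40, 40),
                         rod_length = 5, min_separation = 4, seed = 12)
  com <- axis_frame(generate_aligned(spec)[[1]])$com
  for (i in 1:59) for (j in (i + 1):60)
    expect_gte(minimum_image_distance(com[i, ], com[j, ], box(40)), 4)
})

test_that("infeasible packing fails loudly instead of overlapping", {
  spec <- generator_spec(n_molecules = 30, box = c(10, 10, 10),
                         rod_length = 4, min_separation = 6, seed = 1)
  expect_error(generate_aligned(spec), "infeasible packing")
})

test_that("planted clusters round-trip exactly through cluster detection", {
  spec <- generator_spec(
    n_molecules = 10, planted_clusters = list(c(2, 10), c(2, 10), c(2, 10)),
    n_isolated = 4, box = c(200, 200, 200), seed = 21, frames = 3)
  gen <- generate_clustered(spec, cutoff = 17)
  expect_equal(100 * sum(!is.na(gen$ground_truth)) / 10, 60)
  for (f in seq_along(gen$trajectory)) {
    ca <- find_clusters(gen$trajectory[[f]], cluster_params(17, 2))
    expect_identical(unname(ca$labels), gen$ground_truth)
    expect_equal(ca$membership_fraction, 60)
  }
})

test_that("a planted five-member cluster is recovered as one cluster", {
  spec <- generator_spec(n_molecules = 15,
                         planted_clusters = list(c(5, 12)), n_isolated = 10,
                         box = c(150, 150, 150), seed = 22)
  gen <- generate_clustered(spec, cutoff = 17)
  ca <- find_clusters(gen$trajectory[[1]], cluster_params(17, 2))
  expect_equal(ca$cluster_sizes, 5L)
  expect_equal(ca$membership_fraction, 100 * 5 / 15)
})

test_that("clustered generation validates its geometry preconditions", {
  expect_error(generator_spec(n_molecules = 5,
                              planted_clusters = list(c(2, 10)),
                              n_isolated = 4),
               "must equal the planted total")
  spec <- generator_spec(n_molecules = 4, planted_clusters = list(c(4, 20)),
                         box = c(60, 60, 60), seed = 1)
  expect_error(generate_clustered(spec, cutoff = 17), "below the cutoff")
  cramped <- generator_spec(n_molecules = 12,
                            planted_clusters = rep(list(c(2, 10)), 6),
                            box = c(40, 40, 40), seed = 1)
  expect_error(generate_clustered(cramped, cutoff = 17), "infeasib")
})

test_that("two-rod fixtures have exact separations and angles", {
  for (theta in c(0, 30, 90, 180)) {
    cfg <- generate_pair(theta = theta, r = 5)
    af <- axis_frame(cfg)
    expect_equal(minimum_image_distance(af$com[1, ], af$com[2, ], cfg$box), 5)
    expect_equal(pair_angle(af$axis[1, ], af$axis[2, ], oriented = TRUE),
                 theta, tolerance = 1e-9)
  }
  expect_error(generate_pair(theta = 0, r = 60), "half the smallest box edge")
  expect_error(generate_pair(theta = 200, r = 5), "0, 180")
})
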