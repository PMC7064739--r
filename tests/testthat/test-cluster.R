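test_that("transitive linkage joins chains; isolated gases stay unclustered", {
  b <- box(100)
  coms <- rbind(c(10, 50, 50), c(26, 50, 50), c(42, 50, 50))  # 0, 16, 32
  axes <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  ca <- find_clusters(rod_config(coms, axes, b), cluster_params(17, 2))
  expect_equal(unname(ca$labels), c(1L, 1L, 1L))  # A-C linked through B
  expect_equal(ca$cluster_sizes, 3L)

  far <- rbind(c(10, 10, 10), c(50, 50, 50), c(90, 10, 90))
  ca2 <- find_clusters(rod_config(far, axes, b), cluster_params(17, 2))
  expect_true(all(is.na(ca2$labels)))
  expect_equal(ca2$membership_fraction, 0)
  expect_equal(length(ca2$cluster_sizes), 0)
})

test_that("linkage honors the minimum image convention across the boundary", {
  b <- box(100)
  coms <- rbind(c(1, 50, 50), c(99, 50, 50))  # wrapped distance 2
  axes <- matrix(c(0, 0, 1), 2, 3, byrow = TRUE)
  ca <- find_clusters(rod_config(coms, axes, b), cluster_params(17, 2))
  expect_equal(unname(ca$labels), c(1L, 1L))
  expect_equal(oracle_min_image_dist(coms[1, ], coms[2, ], b), 2)
})

test_that("labels match the igraph + 27-image oracle on random configurations", {
  set.seed(83)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    L <- stats::runif(1, 40, 80)
    b <- box(L)
    cutoff <- stats::runif(1, 5, min(20, L / 2 - 1))
    coms <- matrix(stats::runif(n * 3, 0, L), n)
    axes <- t(vapply(seq_len(n), function(i) rand_unit(), numeric(3)))
    ca <- find_clusters(rod_config(coms, axes, b, len = 4),
                        cluster_params(cutoff, 2))
    expect_identical(unname(ca$labels), oracle_clusters(coms, b, cutoff))
  }
})

test_that("membership is monotone in the cutoff and bounded in [0, 100]", {
  set.seed(89)
  b <- box(80)
  coms <- matrix(stats::runif(25 * 3, 0, 80), 25)
  axes <- t(replicate(25, rand_unit()))
  cfg <- rod_config(coms, axes, b, len = 4)
  fracs <- vapply(c(5, 8, 12, 16, 20, 25, 30),
                  function(cut) find_clusters(cfg, cluster_params(cut, 2))$membership_fraction,
                  numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_true(all(fracs >= 0 & fracs <= 100))
  # everything within cutoff -> full membership
  tight <- rod_config(matrix(stats::runif(12, 40, 44), 4), axes[1:4, ], b,
                      len = 2)
  expect_equal(find_clusters(tight, cluster_params(17, 2))$membership_fraction,
               100)
})

test_that("relabeling molecules permutes labels without changing sizes", {
  set.seed(97)
  b <- box(60)
  coms <- matrix(stats::runif(20 * 3, 0, 60), 20)
  axes <- t(replicate(20, rand_unit()))
  cfg <- rod_config(coms, axes, b, len = 4)
  perm <- sample(20)
  cfg_p <- configuration(cfg$molecules[perm], b)
  ca <- find_clusters(cfg, cluster_params(15, 2))
  ca_p <- find_clusters(cfg_p, cluster_params(15, 2))
  expect_equal(ca$membership_fraction, ca_p$membership_fraction)
  expect_equal(sort(ca$cluster_sizes), sort(ca_p$cluster_sizes))
  # the same molecules end up together regardless of input order
  part <- unname(lapply(split(names(ca$labels), ca$labels), sort))
  part_p <- unname(lapply(split(names(ca_p$labels), ca_p$labels), sort))
  expect_true(setequal(part, part_p))
})

test_that("membership series averages per-frame percentages", {
  spec3 <- generator_spec(
    n_molecules = 10, planted_clusters = list(c(2, 10), c(2, 10), c(2, 10)),
    n_isolated = 4, box = c(200, 200, 200), seed = 3, frames = 4)
  gen <- generate_clustered(spec3, cutoff = 17)
  ser <- membership_fraction_series(gen$trajectory, cluster_params(17, 2))
  expect_equal(ser$per_frame, rep(60, 4))
  expect_equal(ser$average, 60)
  expect_equal(mean(c(50, 70)), 60)  # arithmetic of the time average
})

test_that("cluster-size histograms pool frames and report the maximum", {
  spec <- generator_spec(
    n_molecules = 9, planted_clusters = list(c(2, 10), c(2, 10), c(5, 12)),
    n_isolated = 0, box = c(220, 220, 220), seed = 5, frames = 2)
  gen <- generate_clustered(spec, cutoff = 17)
  h <- cluster_size_histogram(gen$trajectory, cluster_params(17, 2))
  expect_equal(h$histogram, data.frame(size = c(2L, 5L), count = c(4L, 2L)))
  expect_equal(h$max_size, 5L)

  lone <- generate_aligned(generator_spec(n_molecules = 3, min_separation = 30,
                                          box = c(100, 100, 100), seed = 11))
  h0 <- cluster_size_histogram(lone, cluster_params(17, 2))
  expect_equal(nrow(h0$histogram), 0)
  expect_equal(h0$max_size, 0L)
})

test_that("oversized cutoffs and bad parameters are rejected", {
  cfg <- generate_pair(0, 5)
  expect_error(find_clusters(cfg, cluster_params(60, 2)), "half the smallest")
  expect_error(cluster_params(17, 1), "min_size")
  expect_error(cluster_params(-1, 2), "cutoff")
})
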