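# Shared fixtures and independent oracles.  Oracles deliberately use a
# different route than the package code: direct sums, explicit 27-image
# enumeration, SVD, and igraph graph traversal.

# uniform random unit vector
rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random proper rotation matrix (QR of a Gaussian matrix, det fixed)
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to every atom of every molecule of a configuration
transform_config <- function(config, R = diag(3), t = c(0, 0, 0)) {
  mols <- lapply(config$molecules, function(m)
    molecule(m$id, t(R %*% t(m$xyz)) + matrix(t, nrow(m$xyz), 3, byrow = TRUE),
             masses = m$masses, head = m$head, tail = m$tail))
  configuration(mols, config$box, config$frame_index)
}

# rod molecule through `com` along unit `axis` (3 atoms, oriented)
test_rod <- function(id, com, axis, len = 6) {
  s <- c(-len / 2, 0, len / 2)
  molecule(id, outer(s, axis) + matrix(com, 3, 3, byrow = TRUE),
           masses = rep(1, 3), head = 1, tail = 3)
}

# configuration of rods at given COMs (n x 3) with given axes (n x 3)
rod_config <- function(coms, axes, box, len = 6) {
  mols <- lapply(seq_len(nrow(coms)), function(i)
    test_rod(paste0("M", i), coms[i, ], axes[i, ], len))
  configuration(mols, box)
}

# --- independent oracles ------------------------------------------------

# direct-sum center of mass
oracle_com <- function(xyz, masses) {
  out <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) out <- out + masses[i] * xyz[i, ]
  out / sum(masses)
}

# full 27-image enumeration of the periodic distance
oracle_min_image_dist <- function(a, b, box) {
  L <- unclass(box)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- b + c(i, j, k) * L - a
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# long axis via SVD of mass-weighted centered coordinates (up to sign)
oracle_axis <- function(xyz, masses) {
  com <- oracle_com(xyz, masses)
  x <- sweep(xyz, 2, com) * sqrt(masses)
  svd(x)$v[, 1]
}

# single-linkage clusters via igraph over 27-image distances
oracle_clusters <- function(coms, box, cutoff, min_size = 2) {
  n <- nrow(coms)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <-
      oracle_min_image_dist(coms[i, ], coms[j, ], box) <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  labels <- rep(NA_integer_, n)
  keep <- which(comp$csize >= min_size)
  # order kept components by smallest member index
  first <- vapply(keep, function(k) min(which(comp$membership == k)),
                  integer(1))
  keep <- keep[order(first)]
  for (k in seq_along(keep)) labels[comp$membership == keep[k]] <- k
  labels
}
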