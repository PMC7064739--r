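# Distance-cutoff (single-linkage) cluster detection and membership
# statistics.  Two molecules are linked when their minimum-image
# center-of-mass separation is at most the cutoff; clusters are the
# connected components of the linkage graph with at least `min_size`
# members.

#' Cluster detection parameters
#'
#' Defaults follow the standard first-plus-second-neighbor convention
#' for dye clusters: a 17 Angstrom linkage cutoff and a minimum cluster
#' size of 2 (a dimer is the smallest aggregate).
#'
#' @param cutoff linkage distance, Angstrom (> 0; default 17).
#' @param min_size smallest molecule count that counts as a cluster
#'   (>= 2; default 2).
#' @return object of class `"cluster_params"`.
#' @export
cluster_params <- function(cutoff = 17, min_size = 2) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_size < 2) stop("min_size must be >= 2")
  structure(list(cutoff = cutoff, min_size = as.integer(min_size)),
            class = "cluster_params")
}

#' Single-linkage cluster assignment at a distance cutoff
#'
#' Labels every molecule of a configuration by its cluster (connected
#' component of the graph linking pairs with minimum-image COM distance
#' at most `cutoff`), keeping only components with at least `min_size`
#' members.  Labels are deterministic: clusters are numbered 1, 2, ...
#' in order of their smallest member index; unclustered molecules carry
#' `NA`.
#'
#' @param config a [configuration()].
#' @param params a [cluster_params()].
#' @return object of class `"cluster_assignment"`: `labels` (integer or
#'   `NA` per molecule, named by molecule id), `cluster_sizes` (integer
#'   vector, one entry per cluster label), `membership_fraction`
#'   (percent of molecules in clusters), `params`, `n_molecules`.
#' @examples
#' gen <- generate_clustered(generator_spec(
#'   n_molecules = 10, planted_clusters = list(c(2, 10), c(2, 10), c(2, 10)),
#'   n_isolated = 4, box = c(200, 200, 200), seed = 7))
#' find_clusters(gen$trajectory[[1]], cluster_params(cutoff = 17))
#' @export
find_clusters <- function(config, params = cluster_params()) {
  stopifnot(inherits(config, "configuration"), inherits(params, "cluster_params"))
  if (params$cutoff >= half_min_edge(config$box))
    stop("cutoff (", params$cutoff, ") must be below half the smallest ",
         "box edge (", signif(half_min_edge(config$box), 6), ")")
  af <- axis_frame(config)
  n <- nrow(af$com)
  D <- min_image_dist_matrix(af$com, af$box)
  adj <- D <= params$cutoff
  # union-find over linked pairs
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- which(adj[i, (i + 1):n]) + i
      for (j in js) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp_sizes <- table(root)
  keep_roots <- as.integer(names(comp_sizes))[comp_sizes >= params$min_size]
  keep_roots <- sort(keep_roots)  # smallest member id first
  labels <- rep(NA_integer_, n)
  for (k in seq_along(keep_roots)) labels[root == keep_roots[k]] <- k
  sizes <- if (length(keep_roots)) as.integer(table(labels)) else integer(0)
  names(labels) <- af$ids
  structure(list(labels = labels, cluster_sizes = sizes,
                 membership_fraction = 100 * sum(!is.na(labels)) / n,
                 params = params, n_molecules = n),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "clusters at cutoff %g Angstrom (min size %d): %d cluster(s)%s; %.1f%% of %d molecules in clusters\n",
    x$params$cutoff, x$params$min_size, length(x$cluster_sizes),
    if (length(x$cluster_sizes))
      paste0(" of sizes {", paste(x$cluster_sizes, collapse = ", "), "}")
    else "",
    x$membership_fraction, x$n_molecules))
  invisible(x)
}

#' Per-frame cluster-membership percentages and their time average
#'
#' @param traj a [trajectory()] or [configuration()].
#' @param params a [cluster_params()].
#' @return list with `per_frame` (percent per frame) and `average`
#'   (unweighted mean across frames).
#' @export
membership_fraction_series <- function(traj, params = cluster_params()) {
  traj <- trajectory(traj)
  pf <- vapply(traj, function(fr)
    find_clusters(fr, params)$membership_fraction, numeric(1))
  list(per_frame = pf, average = mean(pf))
}

#' Cluster-size histogram pooled over frames
#'
#' @inheritParams membership_fraction_series
#' @return list with `histogram` (data.frame `size`, `count`) and
#'   `max_size` (0 when no cluster was ever found).
#' @export
cluster_size_histogram <- function(traj, params = cluster_params()) {
  traj <- trajectory(traj)
  sizes <- unlist(lapply(traj, function(fr)
    find_clusters(fr, params)$cluster_sizes))
  if (length(sizes) == 0)
    return(list(histogram = data.frame(size = integer(0), count = integer(0)),
                max_size = 0L))
  tab <- table(sizes)
  list(histogram = data.frame(size = as.integer(names(tab)),
                              count = as.integer(tab)),
       max_size = max(sizes))
}
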