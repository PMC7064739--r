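# Distance-resolved pairwise orientational order, close-pair angle
# distributions and the center-of-mass radial distribution function.

# Bin index for a distance: right-closed bins ((i-1)w, iw], with a small
# tolerance so separations constructed to sit exactly on an edge do not
# spill into the next bin through floating-point noise.
dist_bin <- function(d, width, nb) {
  pmin(nb, pmax(1L, ceiling(d / width - 1e-9)))
}

# Pool pairwise quantities over frames: returns per-frame list of
# (dist vector, cos-theta vector, oriented flag) for all unordered pairs.
frame_pairs <- function(config) {
  af <- axis_frame(config)
  n <- nrow(af$com)
  if (n < 2) stop("need at least two molecules per frame")
  D <- min_image_dist_matrix(af$com, af$box)
  C <- clamp1(af$axis %*% t(af$axis))
  ut <- upper.tri(D)
  list(dist = D[ut], costh = C[ut], oriented = af$oriented)
}

#' Distance-resolved pairwise orientational order parameter O(r)
#'
#' For every unordered molecule pair in every frame, the second Legendre
#' polynomial P2(cos theta) of the angle between the two long axes is
#' accumulated into the distance bin of the pair's minimum-image
#' center-of-mass separation.  A bin's value is the pooled mean over all
#' pair observations (ensemble and time average); O(r) is 1 for parallel
#' or anti-parallel axes, 0 for random orientation, and -0.5 for
#' perpendicular axes.  Bins with no pairs are reported as `NA`, never 0.
#'
#' @param traj a [trajectory()] (or single [configuration()]).
#' @param bin_width bin width in Angstrom (default 0.5).
#' @param r_max largest separation analysed; must not exceed half the
#'   smallest box edge (default: half the smallest box edge).
#' @param average `"pooled"` (every pair observation equal weight,
#'   default) or `"per_frame"` (mean of per-frame bin means).
#' @return object of class `"order_profile"`: list with `bin_edges`,
#'   `o_values`, `pair_counts`, `frames_used`.
#' @export
order_profile <- function(traj, bin_width = 0.5, r_max = NULL,
                          average = c("pooled", "per_frame")) {
  traj <- trajectory(traj)
  average <- match.arg(average)
  hmin <- half_min_edge(traj[[1]]$box)
  if (is.null(r_max)) r_max <- hmin
  if (r_max > hmin + 1e-9)
    stop("r_max (", r_max, ") exceeds half the smallest box edge (",
         signif(hmin, 6), ")")
  if (bin_width <= 0) stop("bin_width must be positive")
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  sums <- counts <- numeric(nb)
  pf_means <- matrix(NA_real_, length(traj), nb)
  for (f in seq_along(traj)) {
    pr <- frame_pairs(traj[[f]])
    keep <- pr$dist <= r_max & pr$dist > 0
    if (!any(keep)) next
    bin <- dist_bin(pr$dist[keep], bin_width, nb)
    p2 <- legendre_p2(pr$costh[keep])
    fsum <- numeric(nb)
    agg <- rowsum(p2, bin)
    fsum[as.integer(rownames(agg))] <- agg[, 1]
    fcnt <- tabulate(bin, nbins = nb)
    sums <- sums + fsum
    counts <- counts + fcnt
    pf_means[f, ] <- ifelse(fcnt > 0, fsum / fcnt, NA_real_)
  }
  o_values <- switch(average,
    pooled = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
    per_frame = colMeans(pf_means, na.rm = TRUE))
  o_values[counts == 0] <- NA_real_
  structure(list(bin_edges = edges, o_values = o_values,
                 pair_counts = counts, frames_used = length(traj),
                 bin_width = bin_width, r_max = r_max, average = average),
            class = "order_profile")
}

#' @export
print.order_profile <- function(x, ...) {
  occ <- sum(x$pair_counts > 0)
  cat(sprintf("O(r) profile: %d/%d occupied bins of %g Angstrom, %d frame(s), %d pairs\n",
              occ, length(x$o_values), x$bin_width, x$frames_used,
              sum(x$pair_counts)))
  invisible(x)
}

#' Tidy data frame of a binned profile
#'
#' @param x an `order_profile`, `angle_distribution` or `rdf_profile`.
#' @param ... unused.
#' @return data.frame with `bin_left`, `bin_right`, `value`, `count`.
#' @export
as.data.frame.order_profile <- function(x, ...) {
  nb <- length(x$o_values)
  data.frame(bin_left = x$bin_edges[-(nb + 1)], bin_right = x$bin_edges[-1],
             value = x$o_values, count = x$pair_counts)
}

#' Distribution of inter-axis angles between close molecule pairs
#'
#' Histogram (per-degree probability density) of the angles between the
#' long axes of molecule pairs whose minimum-image center-of-mass
#' separation is at most `r_max`, pooled over frames.  With oriented
#' axes (head/tail convention on every molecule) the angle runs over
#' \[0, 180\] degrees; otherwise it is folded to \[0, 90\] and a warning
#' is issued.
#'
#' @param traj a [trajectory()] or [configuration()].
#' @param r_max pair-inclusion distance, Angstrom (default 10, the
#'   first-neighbor shell).
#' @param bin_width histogram bin width in degrees (default 5).
#' @return object of class `"angle_distribution"`: `bin_edges`
#'   (degrees), `density` (per degree), `pair_count`, `r_max`,
#'   `angles` (the raw pooled pair angles, degrees).
#' @export
angle_distribution <- function(traj, r_max = 10, bin_width = 5) {
  traj <- trajectory(traj)
  if (r_max <= 0) stop("r_max must be positive")
  angles <- numeric(0)
  oriented <- TRUE
  for (f in seq_along(traj)) {
    pr <- frame_pairs(traj[[f]])
    oriented <- oriented && pr$oriented
    keep <- pr$dist <= r_max & pr$dist > 0
    angles <- c(angles, acos(pr$costh[keep]) * DEG)
  }
  if (length(angles) == 0)
    stop("no molecule pairs within r_max = ", r_max,
         " Angstrom (0 qualifying pairs over ", length(traj), " frame(s))")
  amax <- 180
  if (!oriented) {
    warning("axes are not oriented (no head/tail convention); folding ",
            "angles to [0, 90] degrees")
    angles <- ifelse(angles > 90, 180 - angles, angles)
    amax <- 90
  }
  nb <- ceiling(amax / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  cnt <- tabulate(pmin(nb, pmax(1, ceiling(angles / bin_width))), nbins = nb)
  structure(list(bin_edges = edges,
                 density = cnt / (sum(cnt) * bin_width),
                 pair_count = sum(cnt), r_max = r_max,
                 bin_width = bin_width, oriented = oriented,
                 angles = angles),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("angle distribution (%s): %d pairs within %g Angstrom, %g-degree bins\n",
              if (x$oriented) "0-180 deg" else "folded 0-90 deg",
              x$pair_count, x$r_max, x$bin_width))
  invisible(x)
}

#' @export
as.data.frame.angle_distribution <- function(x, ...) {
  nb <- length(x$density)
  cnt <- round(x$density * x$pair_count * x$bin_width)
  data.frame(bin_left = x$bin_edges[-(nb + 1)], bin_right = x$bin_edges[-1],
             value = x$density, count = cnt)
}

#' Center-of-mass radial distribution function g(r)
#'
#' Standard homogeneous-fluid normalization: the pooled pair count in
#' each spherical shell divided by the ideal-gas expectation
#' `N(N-1)/2 * 4 pi r^2 dr / V` per frame.  Distances use the minimum
#' image convention.  Note the normalization assumes 3D homogeneity;
#' for slab-confined (bilayer-adsorbed) systems the absolute scale of
#' g(r) is biased, which is flagged in the returned metadata.
#'
#' @inheritParams order_profile
#' @return object of class `"rdf_profile"`: `bin_edges`, `g_values`,
#'   `counts`, `n_molecules`, `box_volume`, `homogeneous` flag.
#' @export
com_rdf <- function(traj, bin_width = 0.5, r_max = NULL) {
  traj <- trajectory(traj)
  hmin <- half_min_edge(traj[[1]]$box)
  if (is.null(r_max)) r_max <- hmin
  if (r_max > hmin + 1e-9)
    stop("r_max exceeds half the smallest box edge")
  if (bin_width <= 0) stop("bin_width must be positive")
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  counts <- numeric(nb)
  n <- length(traj[[1]]$molecules)
  if (n < 2) stop("need at least two molecules")
  for (f in seq_along(traj)) {
    pr <- frame_pairs(traj[[f]])
    keep <- pr$dist <= r_max & pr$dist > 0
    if (any(keep))
      counts <- counts + tabulate(dist_bin(pr$dist[keep], bin_width, nb),
                                  nbins = nb)
  }
  V <- box_volume(traj[[1]]$box)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  ideal <- n * (n - 1) / 2 * shell / V * length(traj)
  structure(list(bin_edges = edges, g_values = counts / ideal,
                 counts = counts, n_molecules = n, box_volume = V,
                 frames_used = length(traj), bin_width = bin_width,
                 homogeneous = TRUE),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("g(r): %d bins of %g Angstrom, %d molecules, %d frame(s)\n",
              length(x$g_values), x$bin_width, x$n_molecules, x$frames_used))
  invisible(x)
}

#' @export
as.data.frame.rdf_profile <- function(x, ...) {
  nb <- length(x$g_values)
  data.frame(bin_left = x$bin_edges[-(nb + 1)], bin_right = x$bin_edges[-1],
             value = x$g_values, count = x$counts)
}

#' First-neighbor cutoff from a radial distribution function
#'
#' Locates the first local maximum of the (lightly smoothed) g(r) and
#' returns the right edge of its basin -- the first local minimum (or
#' first empty bin) after the peak.  This is the data-driven distance
#' that separates first neighbors from the rest, used to justify a
#' cluster cutoff rather than hard-coding one.
#'
#' @param rdf an `rdf_profile` from [com_rdf()].
#' @param smooth half-width (bins) of the moving-average smoother
#'   (default 1, i.e. a 3-bin window).
#' @return distance in Angstrom.
#' @export
first_neighbor_cutoff <- function(rdf, smooth = 1) {
  stopifnot(inherits(rdf, "rdf_profile"))
  g <- rdf$g_values
  nb <- length(g)
  if (smooth > 0) {
    k <- 2 * smooth + 1
    g <- stats::filter(g, rep(1 / k, k), sides = 2)
    g[is.na(g)] <- rdf$g_values[is.na(g)]
    g <- as.numeric(g)
  }
  peak <- NA_integer_
  for (i in seq_len(nb - 1)) {  # a peak in the last bin has no basin
    lo <- if (i > 1) g[i - 1] else -Inf
    if (g[i] > 0 && g[i] >= lo && g[i] > g[i + 1]) { peak <- i; break }
  }
  if (is.na(peak))
    stop("no local maximum found in g(r): monotone or featureless profile")
  for (j in (peak + 1):nb) {
    if (rdf$counts[j] == 0) return(rdf$bin_edges[j + 1])
    nxt <- if (j < nb) g[j + 1] else Inf
    if (g[j] <= nxt) return(rdf$bin_edges[j + 1])
  }
  stop("g(r) decreases monotonically beyond the first peak up to r_max; ",
       "no first minimum found within the profile")
}
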