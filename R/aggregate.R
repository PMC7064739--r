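# Geometric J- vs H-aggregate classification of close molecule pairs.
# In the point-dipole exciton picture, a dimer of near-parallel
# transition dipoles is J-type (red-shifted, allowed lowest state) when
# the stacking angle between the dipole direction and the line joining
# the molecular centers is below the magic angle 54.7 degrees -- the
# zero of P2(cos theta) -- and H-type (blue-shifted) between 54.7 and
# 90 degrees.  The long geometric axis serves as the dipole-direction
# proxy for polymethine dyes.

#' Magic-angle boundary between J- and H-aggregates, degrees
#' @export
JH_BOUNDARY_DEG <- 54.7

#' Geometry of a close molecule pair
#'
#' Computes, for two molecules in a periodic box: the inter-axis angle;
#' the stacking angle, defined as the angle between the mean molecular
#' axis (normalized bisector of the two sign-aligned long axes) and the
#' inter-center unit vector, folded to \[0, 90\] degrees; and the
#' minimum-image center-of-mass separation.  The bisector construction
#' makes the stacking angle symmetric in the two molecules and robust
#' for near-parallel pairs; for inter-axis angles above 30 degrees the
#' near-parallel-dipole assumption of the exciton convention is
#' stretched, and the result is flagged `noncoplanar`.
#'
#' @param mol_i,mol_j [molecule()] objects.
#' @param box a [box()].
#' @return object of class `"pair_geometry"`: `inter_axis_angle`,
#'   `stacking_angle` (degrees), `separation` (Angstrom),
#'   `noncoplanar` (logical).
#' @examples
#' cfg <- generate_pair(theta = 0, r = 5)
#' pair_geometry(cfg$molecules[[1]], cfg$molecules[[2]], cfg$box)
#' @export
pair_geometry <- function(mol_i, mol_j, box) {
  box <- as_box(box)
  ai <- longest_principal_axis(mol_i)
  aj <- longest_principal_axis(mol_j)
  oriented <- attr(ai, "oriented") && attr(aj, "oriented")
  inter <- pair_angle(as.numeric(ai), as.numeric(aj), oriented = oriented)
  # sign-align for the bisector (J/H geometry is invariant to axis sign)
  bi <- as.numeric(ai); bj <- as.numeric(aj)
  if (sum(bi * bj) < 0) bj <- -bj
  u <- bi + bj
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9)
    stop("axes exactly perpendicular after sign alignment: mean axis ",
         "undefined")
  u <- u / nu
  rvec <- minimum_image_vector(center_of_mass(mol_i),
                               center_of_mass(mol_j), box)
  sep <- sqrt(sum(rvec^2))
  if (sep <= 0) stop("coincident centers of mass")
  stack <- acos(clamp1(abs(sum(u * rvec / sep)))) * DEG
  fold_inter <- if (inter > 90) 180 - inter else inter
  structure(list(inter_axis_angle = inter, stacking_angle = stack,
                 separation = sep, noncoplanar = fold_inter > 30),
            class = "pair_geometry")
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf(
    "pair geometry: inter-axis %.2f deg, stacking %.2f deg, separation %.2f Angstrom%s\n",
    x$inter_axis_angle, x$stacking_angle, x$separation,
    if (x$noncoplanar) " [non-coplanar: inter-axis angle > 30 deg]" else ""))
  invisible(x)
}

#' Classify a pair geometry as J- or H-aggregate
#'
#' Pure threshold on the stacking angle: `"J"` strictly below the magic
#' angle 54.7 degrees, `"H"` at or above it (the boundary itself is
#' assigned to H, following the strict "< 54.7" convention for J).
#'
#' @param geom a [pair_geometry()] (or a bare stacking angle in degrees).
#' @return `"J"` or `"H"`.
#' @export
classify_pair <- function(geom) {
  theta <- if (inherits(geom, "pair_geometry")) geom$stacking_angle
           else as.numeric(geom)
  if (theta < 0 || theta > 90)
    stop("stacking angle must lie in [0, 90] degrees, got ", theta)
  if (theta < JH_BOUNDARY_DEG) "J" else "H"
}

#' Classify detected clusters as J, H or mixed
#'
#' For every cluster of a [find_clusters()] assignment, classifies all
#' linked member pairs (minimum-image COM separation at most the
#' assignment's cutoff) and labels the cluster `"J"` if every linked
#' pair is J, `"H"` if every pair is H, `"mixed"` otherwise.
#'
#' @param config the [configuration()] the assignment was computed from.
#' @param assignment a `cluster_assignment` from [find_clusters()] on
#'   the same configuration.
#' @return data.frame with one row per cluster: `cluster`, `size`,
#'   `n_pairs`, `j_fraction`, `label`.
#' @export
classify_clusters <- function(config, assignment) {
  stopifnot(inherits(config, "configuration"),
            inherits(assignment, "cluster_assignment"))
  if (assignment$n_molecules != length(config$molecules) ||
      !identical(names(assignment$labels),
                 vapply(config$molecules, function(m) m$id, character(1))))
    stop("assignment does not match the configuration (molecule ids differ)")
  nclust <- length(assignment$cluster_sizes)
  out <- data.frame(cluster = integer(0), size = integer(0),
                    n_pairs = integer(0), j_fraction = numeric(0),
                    label = character(0))
  if (nclust == 0) return(out)
  af <- axis_frame(config)
  D <- min_image_dist_matrix(af$com, af$box)
  cutoff <- assignment$params$cutoff
  for (k in seq_len(nclust)) {
    members <- which(!is.na(assignment$labels) & assignment$labels == k)
    cls <- character(0)
    for (a in seq_along(members)) {
      for (b in seq_len(a - 1)) {
        i <- members[a]; j <- members[b]
        if (D[i, j] <= cutoff) {
          g <- pair_geometry(config$molecules[[i]], config$molecules[[j]],
                             config$box)
          cls <- c(cls, classify_pair(g))
        }
      }
    }
    jf <- mean(cls == "J")
    lab <- if (all(cls == "J")) "J" else if (all(cls == "H")) "H" else "mixed"
    out <- rbind(out, data.frame(cluster = k, size = length(members),
                                 n_pairs = length(cls), j_fraction = jf,
                                 label = lab))
  }
  out
}

#' J/H boundary angle from the pairwise order parameter
#'
#' Finds, by bisection, the inter-axis angle at which the pairwise
#' orientational order parameter of a two-rod fixture changes sign on
#' \[0, 90\] degrees.  Each evaluation builds the fixture with
#' [generate_pair()] and reads the occupied bin of [order_profile()],
#' so the result is tied to the full analysis path; it converges to the
#' magic angle acos(1/sqrt(3)) = 54.7356 degrees, the classification
#' boundary used by [classify_pair()] to one decimal.
#'
#' @param tol bisection tolerance in degrees (default 1e-6).
#' @return boundary angle in degrees.
#' @export
jh_boundary_angle <- function(tol = 1e-6) {
  f <- function(theta) {
    cfg <- generate_pair(theta = theta, r = 5, box = c(100, 100, 100))
    op <- order_profile(trajectory(cfg), bin_width = 0.5, r_max = 10)
    op$o_values[which(op$pair_counts > 0)[1]]
  }
  lo <- 0; hi <- 90
  flo <- f(lo)
  if (flo <= 0) stop("order parameter not positive at 0 degrees")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
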