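# Synthetic rod-configuration generator.  Stands in for MD frames of
# rod-like dye molecules (15 dyes near a bilayer, in the motivating
# system) with known ground-truth order and clustering, so every
# analysis stage can be validated without trajectory output.

#' Generator specification
#'
#' Parameters of the synthetic rod ensembles.  Defaults emulate the
#' simulated dye/bilayer systems that motivate the package: 15 rod-like
#' dye molecules in a 100 Angstrom orthorhombic cell, each a rigid rod
#' of 5 equally spaced, equal-mass pseudo-atoms spanning 20 Angstrom
#' (the extended polymethine backbone of indocyanine green is about
#' 2 nm long).
#'
#' @param n_molecules number of molecules (default 15).
#' @param atoms_per_molecule atoms per rod, >= 2 (default 5).
#' @param rod_length rod end-to-end length, Angstrom (default 20).
#' @param director unit reference axis of preferred alignment
#'   (default z, the bilayer normal surrogate).
#' @param order_target single-molecule nematic order parameter S in
#'   \[0, 1\] (default 0, isotropic control).
#' @param box periodic cell, a [box()] or three edge lengths
#'   (default 100 Angstrom cube).
#' @param slab_thickness optional slab, Angstrom: centers of mass are
#'   confined to |z - lz/2| <= slab_thickness/2, an implicit-bilayer
#'   surrogate (default `NULL`, whole box).
#' @param planted_clusters optional list of `c(size, intra_sep)` pairs:
#'   each plants a cluster of `size >= 2` molecules whose pairwise
#'   center-of-mass separations are at most `intra_sep` Angstrom.
#' @param n_isolated number of molecules guaranteed isolated from every
#'   cluster (only used with `planted_clusters`).
#' @param min_separation minimum center-of-mass separation between any
#'   two molecules, Angstrom (default 3; set 0 to disable).
#' @param frames number of independently redrawn frames (i.i.d.
#'   stand-in for an ensemble and time average; default 1).
#' @param seed integer RNG seed.
#' @return object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_molecules = 15, atoms_per_molecule = 5,
                           rod_length = 20, director = c(0, 0, 1),
                           order_target = 0, box = c(100, 100, 100),
                           slab_thickness = NULL, planted_clusters = NULL,
                           n_isolated = 0, min_separation = 3,
                           frames = 1, seed = 1) {
  box <- as_box(box)
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  if (atoms_per_molecule < 2) stop("atoms_per_molecule must be >= 2")
  if (rod_length <= 0) stop("rod_length must be positive")
  if (rod_length > half_min_edge(box))
    stop("rod_length exceeds half the smallest box edge; molecules would ",
         "be ambiguous under the minimum image convention")
  if (order_target < 0 || order_target > 1)
    stop("order_target (S) must lie in [0, 1], got ", order_target)
  if (!is.null(slab_thickness)) {
    if (slab_thickness <= 0 || slab_thickness > box[3])
      stop("slab_thickness must be in (0, lz]")
  }
  if (!is.null(planted_clusters)) {
    planted_clusters <- lapply(planted_clusters, function(pc) {
      pc <- as.numeric(pc)
      if (length(pc) != 2) stop("each planted cluster is c(size, intra_sep)")
      if (pc[1] < 2) stop("planted cluster sizes must be >= 2")
      if (pc[2] <= 0) stop("intra-cluster separation must be positive")
      pc
    })
    total <- sum(vapply(planted_clusters, `[`, numeric(1), 1)) + n_isolated
    if (total != n_molecules)
      stop("n_molecules (", n_molecules, ") must equal the planted total ",
           "sum(sizes) + n_isolated (", total, ")")
  }
  if (n_isolated < 0 || frames < 1) stop("counts must be non-negative")
  if (min_separation < 0) stop("min_separation must be >= 0")
  structure(list(n_molecules = as.integer(n_molecules),
                 atoms_per_molecule = as.integer(atoms_per_molecule),
                 rod_length = rod_length,
                 director = director / sqrt(sum(director^2)),
                 order_target = order_target, box = box,
                 slab_thickness = slab_thickness,
                 planted_clusters = planted_clusters,
                 n_isolated = as.integer(n_isolated),
                 min_separation = min_separation,
                 frames = as.integer(frames), seed = as.integer(seed)),
            class = "generator_spec")
}

# Rejection budget per placement before declaring the packing infeasible.
REJECTION_BUDGET <- 1e5

# Vectorized minimum-image distances from point p to the rows of `set`.
min_image_dist_to_set <- function(p, set, box) {
  L <- unclass(as_box(box))
  d <- sweep(set, 2, p)
  d <- d - sweep(ceiling(sweep(d, 2, L, "/") - 0.5), 2, L, "*")
  sqrt(rowSums(d * d))
}

# Draw one COM uniform in the box (or slab), respecting min_separation to
# all rows of `placed` (minimum image) and an optional extra predicate.
draw_com <- function(spec, placed, accept = NULL) {
  L <- unclass(spec$box)
  for (i in seq_len(REJECTION_BUDGET)) {
    p <- stats::runif(3) * L
    if (!is.null(spec$slab_thickness)) {
      z0 <- L[3] / 2
      p[3] <- z0 + (stats::runif(1) - 0.5) * spec$slab_thickness
    }
    if (!is.null(accept) && !accept(p)) next
    if (spec$min_separation > 0 && nrow(placed) > 0) {
      if (min(min_image_dist_to_set(p, placed, spec$box)) <
          spec$min_separation) next
    }
    return(p)
  }
  stop("infeasible packing: rejection budget (", format(REJECTION_BUDGET),
       " attempts) exceeded at density ",
       signif(spec$n_molecules / box_volume(spec$box), 3),
       " molecules/Angstrom^3 with min_separation ", spec$min_separation,
       " Angstrom")
}

# Draw one COM uniform in the ball of radius `radius` around `center`,
# wrapped into the box, respecting min_separation and the slab.
draw_com_in_ball <- function(spec, center, radius, placed) {
  L <- unclass(spec$box)
  for (i in seq_len(REJECTION_BUDGET)) {
    u <- runif_sphere(1)[1, ]
    p <- center + u * radius * stats::runif(1)^(1 / 3)
    p <- p - L * floor(p / L)
    if (!is.null(spec$slab_thickness)) {
      if (abs(p[3] - L[3] / 2) > spec$slab_thickness / 2) next
    }
    if (spec$min_separation > 0 && nrow(placed) > 0) {
      if (min(min_image_dist_to_set(p, placed, spec$box)) <
          spec$min_separation) next
    }
    return(p)
  }
  stop("infeasible packing: cannot fit cluster members of min_separation ",
       spec$min_separation, " Angstrom in a ball of radius ", radius,
       " Angstrom")
}

# Build a rigid rod molecule: atoms_per_molecule equal masses equally
# spaced along `axis` through `com`; head = first atom, tail = last, so
# the oriented long axis is +axis.
make_rod <- function(id, com, axis, length, n_atoms) {
  s <- seq(-length / 2, length / 2, length.out = n_atoms)
  xyz <- outer(s, axis) + matrix(com, n_atoms, 3, byrow = TRUE)
  molecule(id, xyz, masses = rep(12.011, n_atoms), head = 1L, tail = n_atoms)
}

#' Generate aligned rod ensembles with prescribed nematic order
#'
#' Each frame contains `n_molecules` rigid rods whose axes are drawn
#' independently so that the single-molecule order parameter
#' `<P2(a . director)>` equals `order_target` (see [sample_axes()] for
#' the mixture recipe), with centers of mass uniform in the box (or
#' slab) and rejection-sampled to respect `min_separation` under the
#' minimum image convention.  Deterministic given `seed`.
#'
#' @param spec a [generator_spec()] without planted clusters.
#' @return a [trajectory()].
#' @examples
#' traj <- generate_aligned(generator_spec(n_molecules = 10, seed = 42))
#' pairwise_order(traj)
#' @export
generate_aligned <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$planted_clusters))
    stop("generate_aligned is alignment mode: use generate_clustered for ",
         "planted clusters")
  set.seed(spec$seed)
  frames <- vector("list", spec$frames)
  for (f in seq_len(spec$frames)) {
    axes <- sample_axes(spec$n_molecules, spec$order_target, spec$director)
    placed <- matrix(numeric(0), 0, 3)
    mols <- vector("list", spec$n_molecules)
    for (i in seq_len(spec$n_molecules)) {
      p <- draw_com(spec, placed)
      placed <- rbind(placed, p)
      mols[[i]] <- make_rod(paste0("M", i), p, axes[i, ],
                            spec$rod_length, spec$atoms_per_molecule)
    }
    frames[[f]] <- configuration(mols, spec$box, frame_index = f)
  }
  trajectory(frames)
}

#' Generate configurations with planted clusters and known labels
#'
#' Plants the clusters of `spec$planted_clusters` plus `spec$n_isolated`
#' isolated molecules such that the returned ground-truth labels are
#' exactly the single-linkage decomposition at `cutoff`: members of one
#' cluster sit inside a ball of diameter `intra_sep < cutoff` (so all
#' pairs are directly linked), while molecules of different clusters,
#' and isolated molecules, are kept farther than `cutoff` apart with a
#' safety margin.
#'
#' @param spec a [generator_spec()] with non-empty `planted_clusters`.
#' @param cutoff linkage distance the ground truth refers to, Angstrom
#'   (default 17, first-plus-second-neighbor shell).
#' @return list with `trajectory` and `ground_truth`: integer cluster
#'   label per molecule (`NA` for isolated), identical across frames.
#' @export
generate_clustered <- function(spec, cutoff = 17) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(spec$planted_clusters) || length(spec$planted_clusters) == 0)
    stop("generate_clustered requires planted_clusters in the spec")
  sizes <- vapply(spec$planted_clusters, `[`, numeric(1), 1)
  intra <- vapply(spec$planted_clusters, `[`, numeric(1), 2)
  if (any(intra >= cutoff))
    stop("intra-cluster separations must be below the cutoff (",
         cutoff, " Angstrom)")
  if (cutoff >= half_min_edge(spec$box))
    stop("cutoff must be below half the smallest box edge")
  if (spec$min_separation >= min(intra))
    stop("min_separation must be below the smallest intra-cluster separation")
  margin <- 0.5
  set.seed(spec$seed)
  labels <- rep(NA_integer_, spec$n_molecules)
  idx <- 1L
  for (k in seq_along(sizes)) {
    labels[idx:(idx + sizes[k] - 1L)] <- k
    idx <- idx + as.integer(sizes[k])
  }
  frames <- vector("list", spec$frames)
  for (f in seq_len(spec$frames)) {
    axes <- sample_axes(spec$n_molecules, spec$order_target, spec$director)
    centers <- matrix(numeric(0), 0, 3)
    # cluster centers: far enough apart that no inter-cluster pair links
    for (k in seq_along(sizes)) {
      ok <- function(p) {
        if (nrow(centers) == 0) return(TRUE)
        d <- min_image_dist_to_set(p, centers, spec$box)
        all(d > cutoff + intra[k] / 2 + intra[seq_len(nrow(centers))] / 2 + margin)
      }
      p <- tryCatch(draw_com(spec, matrix(numeric(0), 0, 3), accept = ok),
                    error = function(e)
                      stop("geometric infeasibility: cannot keep ",
                           length(sizes), " clusters separated by > ",
                           cutoff, " Angstrom in this box", call. = FALSE))
      centers <- rbind(centers, p)
    }
    placed <- matrix(numeric(0), 0, 3)
    coms <- matrix(NA_real_, spec$n_molecules, 3)
    i <- 1L
    for (k in seq_along(sizes)) {
      for (m in seq_len(sizes[k])) {
        p <- draw_com_in_ball(spec, centers[k, ], intra[k] / 2, placed)
        placed <- rbind(placed, p); coms[i, ] <- p; i <- i + 1L
      }
    }
    for (m in seq_len(spec$n_isolated)) {
      ok <- function(p) {
        d <- min_image_dist_to_set(p, centers, spec$box)
        if (any(d <= cutoff + intra / 2 + margin)) return(FALSE)
        iso_rows <- placed[seq_len(nrow(placed)) > sum(sizes), , drop = FALSE]
        if (nrow(iso_rows) > 0 &&
            any(min_image_dist_to_set(p, iso_rows, spec$box) <=
                cutoff + margin)) return(FALSE)
        TRUE
      }
      p <- tryCatch(draw_com(spec, placed, accept = ok),
                    error = function(e)
                      stop("geometric infeasibility: cannot place isolated ",
                           "molecules > ", cutoff,
                           " Angstrom from all clusters in this box",
                           call. = FALSE))
      placed <- rbind(placed, p); coms[i, ] <- p; i <- i + 1L
    }
    mols <- lapply(seq_len(spec$n_molecules), function(j)
      make_rod(paste0("M", j), coms[j, ], axes[j, ],
               spec$rod_length, spec$atoms_per_molecule))
    frames[[f]] <- configuration(mols, spec$box, frame_index = f)
  }
  list(trajectory = trajectory(frames), ground_truth = labels)
}

#' Generate a two-rod fixture with exact separation and inter-axis angle
#'
#' Two identical rods: the first axis along x, the second rotated by
#' `theta` in the xy plane, centers of mass separated by exactly `r`
#' along z (perpendicular to both axes).  Head/tail atoms are set, so
#' the oriented inter-axis angle equals `theta` including the
#' anti-parallel case `theta = 180`.
#'
#' @param theta inter-axis angle, degrees, in \[0, 180\].
#' @param r center-of-mass separation, Angstrom; must be below half the
#'   smallest box edge.
#' @param box a [box()] (default 100 Angstrom cube).
#' @param rod_length,atoms_per_molecule rod geometry (defaults 10, 3).
#' @return a [configuration()] with two molecules.
#' @examples
#' cfg <- generate_pair(theta = 90, r = 5)
#' order_profile(trajectory(cfg), bin_width = 0.5, r_max = 20)
#' @export
generate_pair <- function(theta, r, box = c(100, 100, 100),
                          rod_length = 10, atoms_per_molecule = 3) {
  box <- as_box(box)
  if (theta < 0 || theta > 180)
    stop("theta must lie in [0, 180] degrees")
  if (r <= 0 || r >= half_min_edge(box))
    stop("r must lie in (0, half the smallest box edge): minimum-image ",
         "ambiguity beyond ", half_min_edge(box), " Angstrom")
  th <- theta / DEG
  a1 <- c(1, 0, 0)
  a2 <- c(cos(th), sin(th), 0)
  center <- unclass(box) / 2
  m1 <- make_rod("M1", center - c(0, 0, r / 2), a1, rod_length,
                 atoms_per_molecule)
  m2 <- make_rod("M2", center + c(0, 0, r / 2), a2, rod_length,
                 atoms_per_molecule)
  configuration(list(m1, m2), box)
}
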