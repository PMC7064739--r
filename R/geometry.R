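# Per-molecule reductions and periodic-boundary primitives shared by all
# analyses.  Everything is in Angstrom; angles are reported in degrees.

DEG <- 180 / pi

clamp1 <- function(x) {  # preserves dim, unlike pmin(1, pmax(-1, x))
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

#' Second Legendre polynomial P2(x) = (3x^2 - 1) / 2
#'
#' The kernel of the pairwise orientational order parameter: 1 at
#' x = +/-1 (parallel/anti-parallel axes), -0.5 at x = 0 (perpendicular),
#' expectation 0 for x = cos(theta) of isotropically random axis pairs.
#'
#' @param x numeric, typically a cosine in \[-1, 1\].
#' @return numeric of the same shape.
#' @export
legendre_p2 <- function(x) (3 * x^2 - 1) / 2

#' Center of mass of a molecule
#'
#' Mass-weighted mean atom position.  Atoms are assumed whole (already
#' unwrapped within the molecule).
#'
#' @param mol a [molecule()].
#' @return numeric length-3 vector, Angstrom.
#' @export
center_of_mass <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  mtot <- sum(mol$masses)
  if (mtot <= 0) stop("zero total mass")
  colSums(mol$xyz * mol$masses) / mtot
}

#' Longest principal axis of a molecule
#'
#' Unit eigenvector of the mass-weighted gyration (second-moment) tensor
#' belonging to its largest eigenvalue, i.e. the direction of largest
#' spatial extent -- for a rigid rod this coincides with the
#' smallest-moment-of-inertia axis.  If the molecule carries a head/tail
#' atom pair the sign is chosen so that `axis . (tail - head) > 0` and
#' the result is flagged oriented; otherwise the sign is canonicalized
#' (first component of magnitude > 1e-12 made positive) and the axis is
#' only defined up to sign.
#'
#' @param mol a [molecule()] with at least two non-coincident atoms.
#' @param degeneracy_tol relative gap between the two largest gyration
#'   eigenvalues below which the long axis is declared degenerate
#'   (default 1e-6).
#' @return unit length-3 vector with attribute `oriented` (logical).
#' @export
longest_principal_axis <- function(mol, degeneracy_tol = 1e-6) {
  stopifnot(inherits(mol, "molecule"))
  if (nrow(mol$xyz) < 2) stop("need at least two atoms to define an axis")
  com <- center_of_mass(mol)
  x <- sweep(mol$xyz, 2, com)
  g <- crossprod(x * sqrt(mol$masses)) / sum(mol$masses)
  if (max(abs(g)) < 1e-20) stop("all atoms coincident: no defined axis")
  e <- eigen(g, symmetric = TRUE)
  if ((e$values[1] - e$values[2]) / e$values[1] < degeneracy_tol)
    stop("degenerate longest axis: the two largest gyration eigenvalues ",
         "differ by less than a relative ", degeneracy_tol,
         " (symmetric mass distribution)")
  a <- e$vectors[, 1]
  oriented <- FALSE
  if (!is.null(mol$head)) {
    d <- mol$xyz[mol$tail, ] - mol$xyz[mol$head, ]
    s <- sum(a * d)
    if (abs(s) < 1e-12)
      stop("head -> tail direction is perpendicular to the long axis; ",
           "cannot orient")
    if (s < 0) a <- -a
    oriented <- TRUE
  } else {
    nz <- which(abs(a) > 1e-12)[1]
    if (a[nz] < 0) a <- -a
  }
  a <- a / sqrt(sum(a^2))
  attr(a, "oriented") <- oriented
  a
}

#' Minimum-image displacement between two points
#'
#' Component-wise nearest-image displacement `b - a` in an orthorhombic
#' periodic box; each component lies in (-L/2, L/2\].
#'
#' @param a,b numeric length-3 positions, Angstrom.
#' @param box a [box()].
#' @return length-3 displacement vector.
#' @export
minimum_image_vector <- function(a, b, box) {
  box <- as_box(box)
  d <- as.numeric(b) - as.numeric(a)
  L <- unname(unclass(box))
  d - L * ceiling(d / L - 0.5)
}

#' Minimum-image distance between two points
#'
#' @inheritParams minimum_image_vector
#' @return scalar distance, Angstrom.
#' @export
minimum_image_distance <- function(a, b, box) {
  sqrt(sum(minimum_image_vector(a, b, box)^2))
}

# Vectorized minimum-image distance matrix between rows of an n x 3 COM
# matrix.  Used by all pairwise analyses; O(n^2) memory.
min_image_dist_matrix <- function(com, box) {
  L <- unclass(as_box(box))
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(com[, k], com[, k], "-")
    dk <- dk - L[k] * ceiling(dk / L[k] - 0.5)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Angle between two molecular axes
#'
#' For oriented axes (head/tail convention applied) the full angle
#' `acos(a . b)` on \[0, 180\] degrees is returned; for unoriented axes,
#' where each axis is only defined up to sign, the angle is folded to
#' \[0, 90\] degrees.
#'
#' @param axis_i,axis_j unit length-3 vectors.
#' @param oriented logical; are the axis signs physically meaningful?
#' @param tol tolerance on the unit-norm check (default 1e-6).
#' @return angle in degrees.
#' @export
pair_angle <- function(axis_i, axis_j, oriented = FALSE, tol = 1e-6) {
  ni <- sqrt(sum(axis_i^2)); nj <- sqrt(sum(axis_j^2))
  if (abs(ni - 1) > tol || abs(nj - 1) > tol)
    stop("pair_angle expects unit vectors (norms ", signif(ni, 6), ", ",
         signif(nj, 6), ")")
  ang <- acos(clamp1(sum(axis_i * axis_j))) * DEG
  if (!oriented && ang > 90) ang <- 180 - ang
  ang
}

#' Per-frame reduction to centers of mass and long axes
#'
#' Computes, for every molecule of a configuration, the center of mass
#' and the unit long axis.  The frame is flagged oriented only if every
#' molecule carries a head/tail convention.
#'
#' @param config a [configuration()].
#' @return An object of class `"axis_frame"`: list with `ids`, `com`
#'   (n x 3), `axis` (n x 3), `oriented` (logical), `box`.
#' @export
axis_frame <- function(config) {
  stopifnot(inherits(config, "configuration"))
  n <- length(config$molecules)
  com <- matrix(NA_real_, n, 3)
  ax <- matrix(NA_real_, n, 3)
  oriented <- logical(n)
  for (i in seq_len(n)) {
    m <- config$molecules[[i]]
    com[i, ] <- center_of_mass(m)
    a <- longest_principal_axis(m)
    oriented[i] <- attr(a, "oriented")
    ax[i, ] <- a
  }
  structure(list(ids = vapply(config$molecules, function(m) m$id, character(1)),
                 com = com, axis = ax, oriented = all(oriented),
                 box = config$box),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat(sprintf("axis frame: %d molecules, %soriented axes\n",
              nrow(x$com), if (x$oriented) "" else "un"))
  invisible(x)
}
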