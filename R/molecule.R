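#' Molecule record
#'
#' A molecule is a set of atom positions with masses, plus an optional
#' head/tail atom pair that fixes the sign of its long axis (so that
#' oriented inter-axis angles on \[0, 180\] degrees are well defined).
#' Atoms are assumed whole, i.e. not split across periodic images.
#'
#' @param id molecule identifier (coerced to character).
#' @param xyz numeric matrix, n_atoms x 3, positions in Angstrom.
#' @param masses numeric vector of atomic masses (amu), length n_atoms;
#'   all positive.  Defaults to unit masses.
#' @param head,tail optional atom indices defining the head -> tail
#'   direction used to orient the long axis; must differ when both set.
#' @return An object of class `"molecule"`.
#' @examples
#' m <- molecule("ICG1", rbind(c(0, 0, 0), c(2, 0, 0)), masses = c(1, 1))
#' center_of_mass(m)
#' @export
molecule <- function(id, xyz, masses = NULL, head = NULL, tail = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  n <- nrow(xyz)
  if (n < 1) stop("molecule needs at least one atom")
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  if (is.null(masses)) masses <- rep(1, n)
  masses <- as.numeric(masses)
  if (length(masses) != n) stop("masses length must match atom count")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all atomic masses must be positive and finite")
  if (!is.null(head) || !is.null(tail)) {
    if (is.null(head) || is.null(tail))
      stop("head and tail must be set together")
    head <- as.integer(head); tail <- as.integer(tail)
    if (head < 1 || head > n || tail < 1 || tail > n)
      stop("head/tail atom index out of range")
    if (head == tail) stop("head and tail atoms must differ")
  }
  structure(list(id = as.character(id), xyz = xyz, masses = masses,
                 head = head, tail = tail),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule %s: %d atoms, total mass %.3f amu%s\n",
              x$id, nrow(x$xyz), sum(x$masses),
              if (!is.null(x$head)) sprintf(", head %d -> tail %d", x$head, x$tail) else ""))
  invisible(x)
}

#' Single-frame configuration
#'
#' A configuration is one frame: a list of molecules plus the periodic
#' box.  Validation checks that molecule ids are unique and that every
#' molecule is whole, i.e. no intra-molecular atom pair spans more than
#' half the smallest box edge (which would make the minimum-image
#' convention ambiguous for its center of mass).
#'
#' @param molecules list of [molecule()] objects.
#' @param box a [box()] (or three edge lengths).
#' @param frame_index frame number (1-based).
#' @return An object of class `"configuration"`.
#' @export
configuration <- function(molecules, box, frame_index = 1L) {
  if (length(molecules) < 1) stop("configuration needs at least one molecule")
  if (!all(vapply(molecules, inherits, logical(1), "molecule")))
    stop("molecules must be a list of molecule objects")
  box <- as_box(box)
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    stop("molecule ids must be unique within a frame: duplicated ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hmin <- half_min_edge(box)
  for (m in molecules) {
    if (nrow(m$xyz) > 1) {
      ext <- max(apply(m$xyz, 2, function(v) diff(range(v))))
      if (ext > hmin)
        stop("molecule ", m$id, " spans ", signif(ext, 4),
             " Angstrom, more than half the smallest box edge (",
             signif(hmin, 4), "); molecules must be whole (unwrapped)")
    }
  }
  structure(list(molecules = molecules, box = box,
                 frame_index = as.integer(frame_index)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration (frame %d): %d molecules in ",
              x$frame_index, length(x$molecules)))
  print(x$box)
  invisible(x)
}

#' Multi-frame trajectory
#'
#' A trajectory is an ordered list of [configuration()] frames over the
#' same molecule set.  A single configuration is promoted to a one-frame
#' trajectory.
#'
#' @param frames a [configuration()] or list of configurations.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  if (inherits(frames, "trajectory")) return(frames)
  if (length(frames) < 1) stop("trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "configuration")))
    stop("frames must be configuration objects")
  for (i in seq_along(frames)) frames[[i]]$frame_index <- i
  structure(frames, class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frame(s), %d molecules/frame\n",
              length(x), length(x[[1]]$molecules)))
  invisible(x)
}

n_frames <- function(traj) length(traj)
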