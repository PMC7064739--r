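#' Orthorhombic periodic box
#'
#' Construct the periodic cell used by all distance calculations.  Only
#' orthorhombic (rectangular) cells are supported; triclinic vectors must
#' be rejected upstream.
#'
#' @param lx,ly,lz edge lengths in Angstrom; all must be positive and
#'   finite.
#' @return An object of class `"box"`: a named numeric vector
#'   `c(lx, ly, lz)`.
#' @examples
#' box(100, 100, 100)
#' @export
box <- function(lx, ly = lx, lz = lx) {
  edges <- c(lx = as.numeric(lx), ly = as.numeric(ly), lz = as.numeric(lz))
  if (any(!is.finite(edges)) || any(edges <= 0))
    stop("box edges must be positive and finite, got (",
         paste(signif(edges, 6), collapse = ", "), ")")
  structure(edges, class = "box")
}

#' @export
print.box <- function(x, ...) {
  cat(sprintf("orthorhombic box: %g x %g x %g Angstrom\n", x[1], x[2], x[3]))
  invisible(x)
}

is_box <- function(x) inherits(x, "box")

as_box <- function(x) {
  if (is_box(x)) return(x)
  x <- as.numeric(x)
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop("a box needs three edge lengths")
  box(x[1], x[2], x[3])
}

box_volume <- function(b) prod(unclass(b))

half_min_edge <- function(b) min(unclass(b)) / 2
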