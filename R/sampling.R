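# Axis sampling with a prescribed nematic order parameter, and the
# pooled pairwise order statistic used throughout the tests.

# n uniform unit vectors (rows).
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Sample molecular axes with a target nematic order parameter
#'
#' Draws `n` unit axes whose single-molecule order parameter
#' `<P2(a . director)>` equals `order_target` in expectation.  The
#' sampling recipe is a two-component mixture: with probability
#' `f = order_target` the axis is exactly the director, otherwise it is
#' uniform on the sphere.  Since P2 = 1 on the director and has mean 0
#' under the isotropic component, `<P2> = f` exactly; for independent
#' axes the addition theorem then gives a pairwise order of
#' `order_target^2`.
#'
#' Uses the current RNG state; seed management belongs to the caller
#' (the generators call [set.seed()] themselves).
#'
#' @param n number of axes.
#' @param order_target nematic order parameter S in \[0, 1\].
#' @param director unit reference axis (default z).
#' @return n x 3 matrix of unit vectors.
#' @export
sample_axes <- function(n, order_target = 0, director = c(0, 0, 1)) {
  if (order_target < 0 || order_target > 1)
    stop("order_target must lie in [0, 1], got ", order_target)
  director <- director / sqrt(sum(director^2))
  ax <- runif_sphere(n)
  par <- stats::runif(n) < order_target
  if (any(par)) ax[par, ] <- matrix(director, sum(par), 3, byrow = TRUE)
  ax
}

#' Pooled pairwise orientational order
#'
#' Mean of P2(cos theta) over all unordered molecule pairs, pooled over
#' frames, ignoring distances.  This is the r-integrated counterpart of
#' [order_profile()]; for an ensemble with independent axes of
#' single-molecule order S it converges to S^2.
#'
#' @param x a [trajectory()], [configuration()], or an n x 3 matrix of
#'   unit axes.
#' @return scalar in \[-0.5, 1\].
#' @export
pairwise_order <- function(x) {
  axes_list <- if (is.matrix(x)) {
    list(x)
  } else {
    traj <- trajectory(x)
    lapply(traj, function(fr) axis_frame(fr)$axis)
  }
  s <- 0; np <- 0
  for (a in axes_list) {
    n <- nrow(a)
    if (n < 2) stop("need at least two molecules per frame")
    cth <- clamp1(a %*% t(a))
    p2 <- legendre_p2(cth)
    ut <- upper.tri(p2)
    s <- s + sum(p2[ut])
    np <- np + sum(ut)
  }
  s / np
}

#' Mean pairwise order of randomly matched axis pairs
#'
#' Draws `n_pairs` independent pairs of unit vectors uniform on the
#' sphere and returns the sample mean of P2(cos theta) between the
#' members of each pair.  The population value is exactly 0; the sample
#' standard error is sqrt(1/5 / n_pairs).
#'
#' @param n_pairs number of independent axis pairs.
#' @return list with `mean`, `se`, `n_pairs`.
#' @export
random_pair_order <- function(n_pairs) {
  a <- runif_sphere(n_pairs)
  b <- runif_sphere(n_pairs)
  p2 <- legendre_p2(clamp1(rowSums(a * b)))
  list(mean = mean(p2), se = stats::sd(p2) / sqrt(n_pairs),
       n_pairs = as.integer(n_pairs))
}
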