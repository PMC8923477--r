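# Discrete differential operators on the pixel grid.
#
# Convention: images are numeric matrices; the first index i is the image row,
# the second index j the column, matching matrix indexing. Boundaries are
# reflecting (homogeneous Neumann): the forward difference across the last
# row/column is zero, and the backward divergence uses the one-sided stencil
# that makes it the exact negative adjoint of the forward gradient, so
# <grad+ u, p> + <u, div- p> = 0 holds to machine precision.

# row/column difference kernels ---------------------------------------------

.dx1_forward <- function(u) {
  h <- nrow(u)
  rbind(u[-1L, , drop = FALSE] - u[-h, , drop = FALSE],
        matrix(0, 1L, ncol(u)))
}

.dx2_forward <- function(u) {
  w <- ncol(u)
  cbind(u[, -1L, drop = FALSE] - u[, -w, drop = FALSE],
        matrix(0, nrow(u), 1L))
}

.div1_backward <- function(a) {
  h <- nrow(a)
  rbind(a[1L, , drop = FALSE],
        a[2:(h - 1L), , drop = FALSE] - a[1:(h - 2L), , drop = FALSE],
        -a[h - 1L, , drop = FALSE])
}

.div2_backward <- function(a) {
  w <- ncol(a)
  cbind(a[, 1L, drop = FALSE],
        a[, 2:(w - 1L), drop = FALSE] - a[, 1:(w - 2L), drop = FALSE],
        -a[, w - 1L, drop = FALSE])
}

.dx1_central <- function(u) {
  h <- nrow(u)
  rbind(u[2L, , drop = FALSE] - u[1L, , drop = FALSE],
        (u[3:h, , drop = FALSE] - u[1:(h - 2L), , drop = FALSE]) / 2,
        u[h, , drop = FALSE] - u[h - 1L, , drop = FALSE])
}

.dx2_central <- function(u) {
  w <- ncol(u)
  cbind(u[, 2L, drop = FALSE] - u[, 1L, drop = FALSE],
        (u[, 3:w, drop = FALSE] - u[, 1:(w - 2L), drop = FALSE]) / 2,
        u[, w, drop = FALSE] - u[, w - 1L, drop = FALSE])
}

#' Forward-difference gradient of an image
#'
#' Computes the discrete gradient with forward differences and a reflecting
#' boundary: the last row of the row-derivative and the last column of the
#' column-derivative are zero.
#'
#' @param u Numeric matrix (at least 3x3, all values finite); the image.
#' @return A list with matrices `comp1` (difference along rows,
#'   `u[i+1,j] - u[i,j]`) and `comp2` (difference along columns,
#'   `u[i,j+1] - u[i,j]`), each the same shape as `u`.
#' @seealso [backward_divergence()], its exact negative adjoint.
#' @export
#' @examples
#' u <- matrix(as.numeric(1:12), 4, 3)
#' forward_gradient(u)
forward_gradient <- function(u) {
  assert_image(u, "u")
  list(comp1 = .dx1_forward(u), comp2 = .dx2_forward(u))
}

#' Backward-difference divergence of a vector field
#'
#' Discrete divergence using backward differences, with the boundary
#' convention (first row keeps `comp1[1,j]`, last row takes
#' `-comp1[h-1,j]`, analogously for columns) that makes this operator the
#' exact negative adjoint of [forward_gradient()]:
#' `sum(grad(u)$comp1 * p$comp1 + grad(u)$comp2 * p$comp2) ==
#'  -sum(u * backward_divergence(p))` to machine precision.
#'
#' @param p Vector field: list with matrices `comp1`, `comp2` of equal shape.
#' @return Numeric matrix of the same shape.
#' @export
backward_divergence <- function(p) {
  assert_field(p)
  assert_image(p$comp1, "comp1")
  assert_image(p$comp2, "comp2")
  .div1_backward(p$comp1) + .div2_backward(p$comp2)
}

#' Central-difference gradient and divergence
#'
#' Half-differences of the two neighbours in the interior, one-sided full
#' differences on the boundary rows/columns. Exact on affine images in the
#' interior.
#'
#' @inheritParams forward_gradient
#' @return `central_gradient`: a list with `comp1`, `comp2`;
#'   `central_divergence`: a matrix.
#' @export
central_gradient <- function(u) {
  assert_image(u, "u")
  list(comp1 = .dx1_central(u), comp2 = .dx2_central(u))
}

#' @rdname central_gradient
#' @param p Vector field: list with matrices `comp1`, `comp2` of equal shape.
#' @export
central_divergence <- function(p) {
  assert_field(p)
  assert_image(p$comp1, "comp1")
  assert_image(p$comp2, "comp2")
  .dx1_central(p$comp1) + .dx2_central(p$comp2)
}

#' Discrete mean curvature of the level lines of an image
#'
#' Computes `kappa(u) = div-( grad+ u / |grad+ u|_eps )`, the backward
#' divergence of the normalized forward gradient, with the gradient magnitude
#' regularized as `sqrt(d1^2 + d2^2 + eps^2)` so flat regions do not divide
#' by zero. `kappa` vanishes in the interior wherever `u` is affine
#' (straight level lines), and approximates `1/R` on a circular level line
#' of radius `R` pixels.
#'
#' @inheritParams forward_gradient
#' @param eps Positive regularization added (squared) inside the gradient
#'   magnitude. Default `1e-8`, negligible on the nominal `[0, 255]`
#'   intensity scale.
#' @return Numeric matrix, the curvature field.
#' @export
curvature <- function(u, eps = 1e-8) {
  assert_image(u, "u")
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop_param("eps must be a positive number")
  d1 <- .dx1_forward(u)
  d2 <- .dx2_forward(u)
  mag <- sqrt(d1 * d1 + d2 * d2 + eps * eps)
  .div1_backward(d1 / mag) + .div2_backward(d2 / mag)
}

#' Pointwise dual constraint radius for the elastica regularizer
#'
#' The elastica energy `integral (a + b*kappa^2) |grad u|` enters the dual
#' formulation through the pointwise bound `|p| <= g` with
#' `g = a + b * kappa(u)^2`. `a` weighs level-line length (the TV limit when
#' `b = 0`), `b` weighs squared level-line curvature.
#'
#' @inheritParams curvature
#' @param a Non-negative length weight.
#' @param b Non-negative curvature weight.
#' @return Numeric matrix `g` with `g >= a` everywhere.
#' @export
elastica_bound <- function(u, a, b, eps = 1e-8) {
  assert_nonneg(a, "a")
  assert_nonneg(b, "b")
  if (b == 0) {
    assert_image(u, "u")
    return(matrix(a, nrow(u), ncol(u)))
  }
  k <- curvature(u, eps)
  a + b * k * k
}

# Solver-facing scheme dispatch: the default "adjoint" pairing
# (forward gradient / backward divergence) preserves the discrete
# saddle-point structure; "central" follows the printed central-difference
# stencil, which admits checkerboard modes.
.grad_fun <- function(scheme) {
  switch(scheme, adjoint = forward_gradient, central = central_gradient)
}

.div_fun <- function(scheme) {
  switch(scheme, adjoint = backward_divergence, central = central_divergence)
}
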