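# Dual (projection-type) total-variation baseline.
#
# The TV saddle problem  min_u max_{|p| <= gamma}  1/2 (f-u)^2 + (div p) u
# is the b = 0 limit of the elastica formulation: the curvature-dependent
# bound g = a + b*kappa^2 collapses to the constant gamma. tv_restore
# therefore runs the same alternating core with a constant bound field, so
# the iterate-level reduction holds by construction.

#' Solver parameters for the dual TV baseline
#'
#' @param gamma Positive regularization weight; it is both the weight in the
#'   u-update `u = f + gamma * div(p)` and the radius of the dual constraint
#'   `|p| <= gamma`.
#' @param step Positive dual ascent step t.
#' @param tol Positive relative-energy stopping tolerance.
#' @param max_iter Maximum number of iterations.
#' @param scheme Difference scheme, as in [elastica_params()].
#' @return A list of class `"tv_params"`.
#' @export
tv_params <- function(gamma = 1, step = 0.0125, tol = 0.001,
                      max_iter = 500L, scheme = c("adjoint", "central")) {
  assert_positive(gamma, "gamma")
  assert_positive(step, "step")
  assert_positive(tol, "tol")
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1)
    stop_param("max_iter must be a positive integer")
  structure(list(gamma = gamma, step = step, tol = tol,
                 max_iter = as.integer(max_iter),
                 scheme = match_scheme(scheme)),
            class = "tv_params")
}

#' Denoise or inpaint with the dual TV model
#'
#' Alternates the closed-form u-update `u = f + gamma * div(p)` (explicit
#' steps on damaged pixels when a mask is given) with dual ascent
#' `p <- p + step * grad(u)` followed by radial projection onto
#' `|p| <= gamma`, until the relative-energy criterion or `max_iter`.
#'
#' Equivalent, iterate by iterate, to [denoise()] with `b = 0` and
#' `a = gamma` (for `gamma = 1` this is the `a = 1` TV limit of the
#' elastica bound).
#'
#' @param f Observed image, numeric matrix.
#' @param mask Optional binary inpainting mask (1 = known, 0 = damaged).
#' @param params A [tv_params()] object.
#' @return A list of class `"restore_result"` with `u`, `p` (satisfying
#'   `|p| <= gamma` pointwise), `trace` and `stop_reason`.
#' @export
tv_restore <- function(f, mask = NULL, params = tv_params()) {
  assert_image(f, "f")
  if (!is.null(mask)) assert_mask(mask, dim(f))
  if (!inherits(params, "tv_params"))
    stop_param("params must be created by tv_params()")
  gamma <- params$gamma
  bound_fun <- function(u) matrix(gamma, nrow(u), ncol(u))
  .dual_restore(f, mask, gamma, params$step, params$tol, params$max_iter,
                hole_step = params$step, scheme = params$scheme,
                bound_fun = bound_fun)
}
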