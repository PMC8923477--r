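# Two-phase Chan-Vese segmentation with the elastica regularizer, solved by
# the dual method: alternate region means, a projected-descent update of the
# relaxed indicator u in [0,1], and the curvature-bounded dual projection.

#' Solver parameters for dual elastica segmentation
#'
#' Defaults are `(a, b, gamma, t) = (0.001, 5, 2, 0.0125)` with tolerance
#' `0.001`: a nearly pure curvature regularizer (tiny length weight).
#'
#' @inheritParams elastica_params
#' @param alpha1,alpha2 Positive weights of the foreground/background terms
#'   in the region field `Q = alpha1*(c1-f)^2 - alpha2*(c2-f)^2`.
#' @param u_step Positive descent step for the relaxed indicator; the
#'   default 1 makes the update near-assignment on the `[0,255]` scale
#'   (the region term dominates and clipping binds immediately).
#' @param threshold Binarization level for the final mask, strictly in
#'   `(0, 1)`.
#' @return A list of class `"seg_params"`.
#' @export
seg_params <- function(a = 0.001, b = 5, gamma = 2, step = 0.0125,
                       tol = 0.001, max_iter = 200L, eps = 1e-8,
                       alpha1 = 1, alpha2 = 1, u_step = 1, threshold = 0.5,
                       scheme = c("adjoint", "central")) {
  assert_nonneg(a, "a")
  assert_nonneg(b, "b")
  assert_positive(gamma, "gamma")
  assert_positive(step, "step")
  assert_positive(tol, "tol")
  assert_positive(eps, "eps")
  assert_positive(alpha1, "alpha1")
  assert_positive(alpha2, "alpha2")
  assert_positive(u_step, "u_step")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop_param("threshold must lie strictly inside (0, 1)")
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1)
    stop_param("max_iter must be a positive integer")
  structure(list(a = a, b = b, gamma = gamma, step = step, tol = tol,
                 max_iter = as.integer(max_iter), eps = eps,
                 alpha1 = alpha1, alpha2 = alpha2, u_step = u_step,
                 threshold = threshold, scheme = match_scheme(scheme)),
            class = "seg_params")
}

#' Circular initial contour
#'
#' @param center_row,center_col Center of the circle in pixels (1-based
#'   matrix indices).
#' @param radius Radius in pixels.
#' @return An object of class `"contour_init"`.
#' @export
contour_circle <- function(center_row, center_col, radius) {
  assert_positive(radius, "radius")
  structure(list(kind = "circle", center = c(center_row, center_col),
                 radius = radius),
            class = "contour_init")
}

#' Rectangular initial contour
#'
#' @param row0,col0,row1,col1 Corner coordinates in pixels (1-based,
#'   inclusive).
#' @return An object of class `"contour_init"`.
#' @export
contour_rectangle <- function(row0, col0, row1, col1) {
  if (row1 < row0 || col1 < col0)
    stop_param("rectangle corners must satisfy row1 >= row0, col1 >= col0")
  structure(list(kind = "rectangle", corners = c(row0, col0, row1, col1)),
            class = "contour_init")
}

# Build the initial relaxed indicator (1 inside the contour) and validate
# that the geometry lies inside the image.
.init_indicator <- function(init, h, w) {
  if (is.null(init))
    init <- contour_circle((h + 1) / 2, (w + 1) / 2, min(h, w) / 4)
  if (is.matrix(init)) {
    if (!identical(dim(init), c(h, w)))
      stop_invalid("explicit initial field must match the image shape")
    if (!all(is.finite(init)) || any(init < 0) || any(init > 1))
      stop_invalid("explicit initial field must have values in [0, 1]")
    return(init)
  }
  if (!inherits(init, "contour_init"))
    stop_invalid("init must be NULL, a [0,1] matrix, or a contour_init")
  if (init$kind == "circle") {
    cr <- init$center[1]; cc <- init$center[2]; r <- init$radius
    if (cr < 1 || cr > h || cc < 1 || cc > w ||
        cr - r < 0.5 || cr + r > h + 0.5 || cc - r < 0.5 || cc + r > w + 0.5)
      stop_param("initial circle (", cr, ",", cc, ",r=", r,
                 ") does not fit inside the ", h, "x", w, " image")
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    return(((rows - cr)^2 + (cols - cc)^2 <= r^2) + 0)
  }
  co <- init$corners
  if (co[1] < 1 || co[2] < 1 || co[3] > h || co[4] > w)
    stop_param("initial rectangle does not fit inside the image")
  u0 <- matrix(0, h, w)
  u0[co[1]:co[3], co[2]:co[4]] <- 1
  u0
}

#' Soft region means of the two phases
#'
#' Weighted averages of the image under the relaxed indicator:
#' `c1 = sum(f*u)/sum(u)` (foreground), `c2 = sum(f*(1-u))/sum(1-u)`
#' (background).
#'
#' @param f Image, numeric matrix.
#' @param u Relaxed indicator, same shape, values in `[0, 1]`.
#' @return A list with numbers `c1` and `c2`.
#' @export
update_means <- function(f, u) {
  assert_image(f, "f")
  if (!identical(dim(u), dim(f)))
    stop_invalid("u and f must have the same shape")
  su <- sum(u)
  sv <- sum(1 - u)
  if (su <= 0 || sv <= 0)
    stop_degenerate("relaxed indicator is entirely one phase; ",
                    "both regions must contain mass")
  list(c1 = sum(f * u) / su, c2 = sum(f * (1 - u)) / sv)
}

#' Pointwise region competition field
#'
#' `Q = alpha1*(c1 - f)^2 - alpha2*(c2 - f)^2`: negative where the pixel is
#' (weighted) closer to the foreground mean `c1`, positive where it fits the
#' background mean `c2` better.
#'
#' @param f Image.
#' @param c1,c2 Foreground/background means.
#' @param alpha1,alpha2 Positive region weights.
#' @return Numeric matrix of the same shape as `f`.
#' @export
region_term <- function(f, c1, c2, alpha1 = 1, alpha2 = 1) {
  assert_image(f, "f")
  assert_positive(alpha1, "alpha1")
  assert_positive(alpha2, "alpha2")
  alpha1 * (c1 - f)^2 - alpha2 * (c2 - f)^2
}

#' Projected-descent update of the relaxed indicator
#'
#' One explicit step on the segmentation objective, which is linear in `u`:
#' `u <- clip(u_prev - u_step * (Q + gamma * div(p)), 0, 1)`. Pixels with
#' `Q < 0` (foreground-like) are driven toward 1.
#'
#' @param u_prev Current indicator, values in `[0, 1]`.
#' @param Q Region field from [region_term()].
#' @param p Dual vector field.
#' @param gamma Regularization weight.
#' @param u_step Positive descent step.
#' @param scheme Difference scheme for the divergence.
#' @return The updated indicator, clipped to `[0, 1]`.
#' @export
update_u_seg <- function(u_prev, Q, p, gamma = 2, u_step = 1,
                         scheme = "adjoint") {
  assert_image(u_prev, "u_prev")
  if (!identical(dim(Q), dim(u_prev)))
    stop_invalid("Q and u_prev must have the same shape")
  assert_field(p, dim(u_prev))
  assert_positive(u_step, "u_step")
  divp <- .div_fun(match_scheme(scheme))(p)
  pmin(pmax(u_prev - u_step * (Q + gamma * divp), 0), 1)
}

#' Two-phase segmentation with the dual elastica method
#'
#' Alternates `{(c1,c2) <- update_means; Q <- region_term;
#' u <- update_u_seg; g <- elastica_bound(u); p <- update_p}` from an
#' initial indicator (default: centered circle of radius `min(h,w)/4`) and
#' `p = 0`, monitoring the objective `sum(Q*u) + gamma*sum(div(p)*u)` with
#' the relative-change criterion. The final mask is `u >= threshold`.
#'
#' @param f Image to segment, numeric matrix on the `[0, 255]` scale.
#' @param init `NULL` (default centered circle), a [contour_circle()] /
#'   [contour_rectangle()], or an explicit `[0,1]` matrix.
#' @param params A [seg_params()] object.
#' @return A list of class `"seg_result"`: `mask` (binary 0/1 matrix),
#'   `state` (list with `u`, `c1`, `c2`, `Q`, `p`), `trace`
#'   (a [convergence_trace()]), `stop_reason`, and `phi = u - threshold`
#'   (a level-set-style display field whose zero level is the contour).
#' @export
#' @examples
#' ph <- make_phantom("disk", size = c(48, 48))
#' res <- segment(ph$clean)
#' dice(res$mask, ph$mask)
segment <- function(f, init = NULL, params = seg_params()) {
  assert_image(f, "f")
  if (!inherits(params, "seg_params"))
    stop_param("params must be created by seg_params()")
  if (max(f) == min(f))
    stop_degenerate("image is constant; the two region means coincide ",
                    "and no two-phase partition exists")
  h <- nrow(f); w <- ncol(f)
  u <- .init_indicator(init, h, w)
  if (sum(u) == 0 || sum(1 - u) == 0)
    stop_degenerate("initial contour covers nothing or everything")
  zero <- matrix(0, h, w)
  p <- list(comp1 = zero, comp2 = zero)
  divf <- .div_fun(params$scheme)
  energies <- numeric(params$max_iter)
  feas <- numeric(params$max_iter)
  stop_reason <- "max_iter"
  c1 <- c2 <- NA_real_
  Q <- NULL
  k <- 0L
  while (k < params$max_iter) {
    k <- k + 1L
    m <- update_means(f, u)
    c1 <- m$c1; c2 <- m$c2
    Q <- region_term(f, c1, c2, params$alpha1, params$alpha2)
    u <- update_u_seg(u, Q, p, params$gamma, params$u_step, params$scheme)
    g <- elastica_bound(u, params$a, params$b, params$eps)
    p <- update_p(p, u, g, params$step, params$scheme)
    energies[k] <- sum(Q * u) + params$gamma * sum(divf(p) * u)
    feas[k] <- max(sqrt(p$comp1^2 + p$comp2^2) - g)
    if (check_convergence(energies[seq_len(k)], params$tol)) {
      stop_reason <- "tolerance"
      break
    }
  }
  mask <- (u >= params$threshold) + 0
  structure(
    list(mask = mask,
         state = list(u = u, c1 = c1, c2 = c2, Q = Q, p = p),
         trace = convergence_trace(energies[seq_len(k)], feas[seq_len(k)]),
         stop_reason = stop_reason,
         phi = u - params$threshold),
    class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat("<seg_result> ", nrow(x$mask), "x", ncol(x$mask),
      " image, c1 = ", format(x$state$c1), ", c2 = ", format(x$state$c2),
      ", ", x$trace$iterations, " iterations (", x$stop_reason, ")\n",
      sep = "")
  invisible(x)
}
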