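# Independent double-loop reference implementations of the grid operators
# and update rules, used as oracles against the vectorized package code.

rand_img <- function(h, w, seed, lo = 0, hi = 255) {
  withr::with_seed(seed, matrix(stats::runif(h * w, lo, hi), h, w))
}

rand_field <- function(h, w, seed, scale = 1) {
  withr::with_seed(seed, list(
    comp1 = matrix(stats::rnorm(h * w, 0, scale), h, w),
    comp2 = matrix(stats::rnorm(h * w, 0, scale), h, w)))
}

oracle_forward_gradient <- function(u) {
  h <- nrow(u); w <- ncol(u)
  c1 <- matrix(0, h, w); c2 <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    if (i < h) c1[i, j] <- u[i + 1, j] - u[i, j]
    if (j < w) c2[i, j] <- u[i, j + 1] - u[i, j]
  }
  list(comp1 = c1, comp2 = c2)
}

oracle_backward_divergence <- function(p) {
  h <- nrow(p$comp1); w <- ncol(p$comp1)
  d <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    d1 <- if (i == 1) p$comp1[1, j]
          else if (i < h) p$comp1[i, j] - p$comp1[i - 1, j]
          else -p$comp1[h - 1, j]
    d2 <- if (j == 1) p$comp2[i, 1]
          else if (j < w) p$comp2[i, j] - p$comp2[i, j - 1]
          else -p$comp2[i, w - 1]
    d[i, j] <- d1 + d2
  }
  d
}

oracle_central_gradient <- function(u) {
  h <- nrow(u); w <- ncol(u)
  c1 <- matrix(0, h, w); c2 <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    c1[i, j] <- if (i == 1) u[2, j] - u[1, j]
                else if (i == h) u[h, j] - u[h - 1, j]
                else (u[i + 1, j] - u[i - 1, j]) / 2
    c2[i, j] <- if (j == 1) u[i, 2] - u[i, 1]
                else if (j == w) u[i, w] - u[i, w - 1]
                else (u[i, j + 1] - u[i, j - 1]) / 2
  }
  list(comp1 = c1, comp2 = c2)
}

oracle_central_divergence <- function(p) {
  oracle_central_gradient(p$comp1)$comp1 +
    oracle_central_gradient(p$comp2)$comp2
}

oracle_curvature <- function(u, eps = 1e-8) {
  g <- oracle_forward_gradient(u)
  mag <- sqrt(g$comp1^2 + g$comp2^2 + eps^2)
  oracle_backward_divergence(list(comp1 = g$comp1 / mag,
                                  comp2 = g$comp2 / mag))
}

oracle_update_p <- function(p, u, g, step) {
  gu <- oracle_forward_gradient(u)
  h <- nrow(u); w <- ncol(u)
  out <- list(comp1 = matrix(0, h, w), comp2 = matrix(0, h, w))
  for (i in 1:h) for (j in 1:w) {
    q1 <- p$comp1[i, j] + step * gu$comp1[i, j]
    q2 <- p$comp2[i, j] + step * gu$comp2[i, j]
    m <- sqrt(q1^2 + q2^2)
    sc <- if (max(g[i, j], m) > 0) g[i, j] / max(g[i, j], m) else 0
    out$comp1[i, j] <- q1 * sc
    out$comp2[i, j] <- q2 * sc
  }
  out
}

oracle_restore_energy <- function(u, p, f, mask, gamma) {
  divp <- oracle_backward_divergence(p)
  tot <- 0
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) {
    eta <- if (is.null(mask)) 1 else mask[i, j]
    tot <- tot + eta * (f[i, j] - u[i, j])^2 / 2 +
      gamma * divp[i, j] * u[i, j]
  }
  tot
}

oracle_means <- function(f, u) {
  n1 <- 0; d1 <- 0; n2 <- 0; d2 <- 0
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) {
    n1 <- n1 + f[i, j] * u[i, j];       d1 <- d1 + u[i, j]
    n2 <- n2 + f[i, j] * (1 - u[i, j]); d2 <- d2 + (1 - u[i, j])
  }
  list(c1 = n1 / d1, c2 = n2 / d2)
}

field_mag <- function(p) sqrt(p$comp1^2 + p$comp2^2)

ramp_image <- function(h, w, ai = 1, aj = 0, c0 = 0) {
  outer(seq_len(h), seq_len(w), function(i, j) ai * i + aj * j + c0)
}
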