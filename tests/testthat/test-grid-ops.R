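test_that("forward gradient matches definition and loop oracle", {
  const <- matrix(7, 5, 5)
  g <- forward_gradient(const)
  expect_equal(g$comp1, matrix(0, 5, 5))
  expect_equal(g$comp2, matrix(0, 5, 5))

  ramp <- ramp_image(5, 4, ai = 1, aj = 0)
  g <- forward_gradient(ramp)
  expect_equal(g$comp1[1:4, ], matrix(1, 4, 4))
  expect_equal(g$comp1[5, ], rep(0, 4))
  expect_equal(g$comp2, matrix(0, 5, 4))

  u <- rand_img(5, 5, seed = 11)
  expect_identical(forward_gradient(u), oracle_forward_gradient(u))
})

test_that("backward divergence matches loop oracle and kills ramp interior", {
  zero <- list(comp1 = matrix(0, 4, 4), comp2 = matrix(0, 4, 4))
  expect_equal(backward_divergence(zero), matrix(0, 4, 4))

  p <- rand_field(6, 5, seed = 3)
  expect_identical(backward_divergence(p), oracle_backward_divergence(p))

  p <- forward_gradient(ramp_image(6, 6))
  d <- backward_divergence(p)
  expect_equal(d[2:5, 2:5], matrix(0, 4, 4))
})

test_that("forward gradient and backward divergence are negative adjoints", {
  for (s in 1:100) {
    u <- rand_img(7, 6, seed = s)
    p <- rand_field(7, 6, seed = 1000 + s)
    lhs <- sum(forward_gradient(u)$comp1 * p$comp1 +
               forward_gradient(u)$comp2 * p$comp2)
    rhs <- sum(u * backward_divergence(p))
    expect_lt(abs(lhs + rhs), 1e-10 * max(1, abs(lhs)))
  }
})

test_that("central differences are exact on linear fields and match oracle", {
  expect_equal(central_gradient(matrix(3, 4, 4))$comp1, matrix(0, 4, 4))
  expect_equal(central_divergence(list(comp1 = matrix(1, 4, 4),
                                       comp2 = matrix(2, 4, 4))),
               matrix(0, 4, 4))

  u <- ramp_image(6, 7, ai = 3, aj = 2)
  g <- central_gradient(u)
  expect_equal(g$comp1[2:5, ], matrix(3, 4, 7))
  expect_equal(g$comp2[, 2:6], matrix(2, 6, 5))

  u <- rand_img(5, 5, seed = 21)
  expect_identical(central_gradient(u), oracle_central_gradient(u))
  p <- rand_field(5, 5, seed = 22)
  expect_identical(central_divergence(p), oracle_central_divergence(p))
})

test_that("gradient and divergence operators are linear", {
  u <- rand_img(6, 6, seed = 31)
  v <- rand_img(6, 6, seed = 32)
  a <- 2.5; b <- -1.25
  for (op in list(forward_gradient, central_gradient)) {
    lhs <- op(a * u + b * v)
    expect_equal(lhs$comp1, a * op(u)$comp1 + b * op(v)$comp1,
                 tolerance = 1e-10)
    expect_equal(lhs$comp2, a * op(u)$comp2 + b * op(v)$comp2,
                 tolerance = 1e-10)
  }
  p <- rand_field(6, 6, seed = 33)
  q <- rand_field(6, 6, seed = 34)
  pq <- list(comp1 = a * p$comp1 + b * q$comp1,
             comp2 = a * p$comp2 + b * q$comp2)
  for (op in list(backward_divergence, central_divergence))
    expect_equal(op(pq), a * op(p) + b * op(q), tolerance = 1e-10)
})

test_that("curvature vanishes on affine images and matches the loop oracle", {
  u <- ramp_image(7, 7, ai = 3, aj = 2, c0 = 1)
  k <- curvature(u)
  expect_equal(k[2:6, 2:6], matrix(0, 5, 5), tolerance = 1e-10)

  u <- rand_img(6, 6, seed = 41)
  expect_equal(curvature(u), oracle_curvature(u), tolerance = 1e-12)
})

test_that("curvature of a smoothed disk edge approximates 1/R", {
  h <- 80; R <- 30
  rows <- matrix(seq_len(h), h, h)
  cols <- matrix(seq_len(h), h, h, byrow = TRUE)
  d <- sqrt((rows - 40.5)^2 + (cols - 40.5)^2)
  u <- 255 / (1 + exp((d - R) / 2))       # smooth radial transition
  k <- curvature(u)
  ring <- abs(d - R) < 1
  expect_gt(sum(ring), 50)
  med <- stats::median(abs(k[ring]))
  expect_lt(abs(med - 1 / R), 0.3 / R)
})

test_that("elastica bound is a + b*kappa^2 with floor a", {
  u <- rand_img(6, 6, seed = 51)
  expect_equal(elastica_bound(u, a = 4, b = 0), matrix(4, 6, 6))

  aff <- ramp_image(6, 6, ai = 3, aj = 2, c0 = 1)
  g <- elastica_bound(aff, a = 3, b = 1)
  expect_equal(g[2:5, 2:5], matrix(3, 4, 4), tolerance = 1e-9)

  g <- elastica_bound(u, a = 0.001, b = 5)
  k <- curvature(u)
  expect_equal(g - 0.001, 5 * k^2, tolerance = 1e-12)
  expect_true(all(g >= 0.001))
})

test_that("grid operators reject invalid inputs", {
  bad <- matrix(c(1, NA, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  expect_error(forward_gradient(bad), class = "dualelastica_invalid_input")
  expect_error(forward_gradient(matrix(1, 2, 5)),
               class = "dualelastica_invalid_input")
  u <- matrix(1, 4, 4)
  expect_error(curvature(u, eps = 0), class = "dualelastica_parameter_error")
  expect_error(curvature(u, eps = -1), class = "dualelastica_parameter_error")
  expect_error(elastica_bound(u, a = -1, b = 1),
               class = "dualelastica_parameter_error")
  expect_error(elastica_bound(u, a = 1, b = -2),
               class = "dualelastica_parameter_error")
})
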