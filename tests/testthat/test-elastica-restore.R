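test_that("update_u applies the closed form on known pixels", {
  f <- rand_img(5, 5, seed = 61)
  zero <- list(comp1 = matrix(0, 5, 5), comp2 = matrix(0, 5, 5))
  expect_equal(update_u(f, zero), f)

  mask <- matrix(1, 5, 5); mask[2:3, 2:3] <- 0
  u_prev <- rand_img(5, 5, seed = 62)
  out <- update_u(f, zero, mask, u_prev)
  expect_equal(out[mask == 0], u_prev[mask == 0])
  expect_equal(out[mask == 1], f[mask == 1])

  p <- rand_field(5, 5, seed = 63)
  expect_equal(update_u(f, p, gamma = 1),
               f + oracle_backward_divergence(p))
})

test_that("update_p projects radially onto the bound field", {
  # constant u, zero p: stays zero
  u <- matrix(4, 5, 5)
  zero <- list(comp1 = matrix(0, 5, 5), comp2 = matrix(0, 5, 5))
  out <- update_p(zero, u, matrix(2, 5, 5), step = 0.1)
  expect_equal(out$comp1, zero$comp1)
  expect_equal(out$comp2, zero$comp2)

  # an infeasible vector is rescaled to magnitude g, direction preserved
  p <- zero
  p$comp1[3, 3] <- 6; p$comp2[3, 3] <- 8   # |p| = 10
  out <- update_p(p, u, matrix(3, 5, 5), step = 1)
  expect_equal(field_mag(out)[3, 3], 3)
  expect_equal(out$comp2[3, 3] / out$comp1[3, 3], 8 / 6)

  # loop oracle + idempotence of the projection
  u <- rand_img(6, 6, seed = 71)
  p <- rand_field(6, 6, seed = 72, scale = 2)
  g <- matrix(withr::with_seed(73, stats::runif(36, 0, 3)), 6, 6)
  out <- update_p(p, u, g, step = 0.0125)
  expect_equal(out, oracle_update_p(p, u, g, 0.0125), tolerance = 1e-12)
  # projecting the result again (zero ascent on constant u) changes nothing
  again <- update_p(out, matrix(1, 6, 6), g, step = 1)
  expect_equal(again, out, tolerance = 1e-12)
  expect_true(all(field_mag(out) <= g + 1e-12))
})

test_that("restore energy matches its closed forms and the loop oracle", {
  f <- rand_img(5, 5, seed = 81)
  zero <- list(comp1 = matrix(0, 5, 5), comp2 = matrix(0, 5, 5))
  expect_equal(restore_energy(f, zero, f), 0)
  expect_equal(restore_energy(f + 2, zero, f), 2 * 25)

  p <- rand_field(5, 5, seed = 82)
  u <- rand_img(5, 5, seed = 83)
  mask <- matrix(1, 5, 5); mask[2, 2] <- 0
  expect_equal(restore_energy(u, p, f, mask, gamma = 1.5),
               oracle_restore_energy(u, p, f, mask, 1.5),
               tolerance = 1e-12)
})

test_that("the relative-change stopping rule follows the printed criterion", {
  expect_true(check_convergence(c(100, 100), tol = 0.001))
  expect_false(check_convergence(c(100, 99), tol = 0.001))   # Sigma = 0.01
  # absolute-difference guard at vanishing energy
  expect_false(check_convergence(c(0, 1e-6), tol = 1e-9))
  expect_true(check_convergence(c(0, 1e-6), tol = 1e-5))
  # not ready with fewer than two energies
  expect_false(check_convergence(numeric(0), tol = 0.001))
  expect_false(check_convergence(100, tol = 0.001))
  expect_true(check_convergence(convergence_trace(c(50, 50)), tol = 0.001))
})

test_that("denoising a constant image returns it at the first check", {
  f <- matrix(77, 8, 8)
  res <- denoise(f)
  expect_equal(res$u, f)
  expect_equal(res$stop_reason, "tolerance")
  expect_equal(res$trace$iterations, 2L)
})

test_that("elastica denoising improves PSNR and stops via the criterion", {
  ph <- make_phantom("triangle", size = c(64, 64))
  f <- add_gaussian_noise(ph$clean, sigma = 15, seed = 4)
  res <- denoise(f)
  expect_gt(psnr(res$u, ph$clean), psnr(f, ph$clean))
  expect_equal(res$stop_reason, "tolerance")
  expect_lte(res$trace$iterations, 500L)
  # convergence flagging is consistent with the trace
  n <- res$trace$iterations
  expect_lte(res$trace$sigmas[n - 1], 0.001)
})

test_that("dual feasibility holds after every elastica iteration", {
  ph <- make_phantom("disk", size = c(32, 32))
  f <- add_gaussian_noise(ph$clean, sigma = 15, seed = 6)
  res <- denoise(f, elastica_params(max_iter = 80, tol = 1e-9))
  expect_true(all(res$trace$feasibility <= 1e-10))
  g <- elastica_bound(res$u, 3, 1)
  expect_true(all(field_mag(res$p) <= g + 1e-10))
})

test_that("known pixels satisfy the closed-form anchor at every iteration", {
  ph <- make_phantom("disk", size = c(32, 32))
  mask <- make_damage_mask(c(32, 32), "block", blocks = list(c(5, 5, 6, 6)))
  f <- add_gaussian_noise(ph$clean, sigma = 10, seed = 8)
  u <- f
  p <- list(comp1 = matrix(0, 32, 32), comp2 = matrix(0, 32, 32))
  for (k in 1:30) {
    u <- update_u(f, p, mask, u, gamma = 10)
    anchor <- (u - f) - 10 * backward_divergence(p)
    expect_lt(max(abs(anchor[mask == 1])), 1e-10)
    g <- elastica_bound(u, 3, 1)
    p <- update_p(p, u, g, 0.0125)
  }
})

test_that("the solver is deterministic", {
  ph <- make_phantom("triangle", size = c(32, 32))
  f <- add_gaussian_noise(ph$clean, sigma = 15, seed = 10)
  r1 <- denoise(f, elastica_params(max_iter = 40))
  r2 <- denoise(f, elastica_params(max_iter = 40))
  expect_identical(r1$u, r2$u)
  expect_identical(r1$trace$energies, r2$trace$energies)
})

test_that("inpainting with an all-ones mask equals denoising", {
  ph <- make_phantom("disk", size = c(32, 32))
  f <- add_gaussian_noise(ph$clean, sigma = 10, seed = 12)
  pr <- elastica_params(gamma = 1, max_iter = 30, tol = 1e-12)
  r_in <- inpaint(f, matrix(1, 32, 32), pr)
  r_de <- denoise(f, pr)
  expect_identical(r_in$u, r_de$u)
})

test_that("inpainting error in the hole decreases over the iteration schedule", {
  ph <- make_phantom("disk", size = c(96, 96))
  mask <- make_damage_mask(c(96, 96), "block", blocks = list(c(41, 41, 14, 14)))
  f <- ph$clean * mask + 255 * (1 - mask)   # white block damage
  hole <- mask == 0
  maes <- vapply(c(100, 200, 300, 400, 500), function(n) {
    r <- inpaint(f, mask, elastica_params(gamma = 10, max_iter = n,
                                          tol = 1e-15))
    mean(abs(r$u[hole] - ph$clean[hole]))
  }, numeric(1))
  expect_true(all(diff(maes) <= 0))
})

test_that("a hole inside a constant region fills with that constant", {
  mask <- make_damage_mask(c(48, 48), "block", blocks = list(c(21, 21, 6, 6)))
  f <- matrix(50, 48, 48)
  f[mask == 0] <- 255
  res <- inpaint(f, mask, elastica_params(gamma = 10, max_iter = 4000,
                                          tol = 1e-15))
  expect_lt(max(abs(res$u[mask == 0] - 50)), 1)
})

test_that("restoration rejects invalid masks and parameters", {
  f <- matrix(1:16 * 1.0, 4, 4)
  expect_error(inpaint(f, matrix(0, 4, 4)),
               class = "dualelastica_invalid_input")
  expect_error(inpaint(f, matrix(0.5, 4, 4)),
               class = "dualelastica_invalid_input")
  expect_error(elastica_params(gamma = -1),
               class = "dualelastica_parameter_error")
  expect_error(elastica_params(a = -0.1),
               class = "dualelastica_parameter_error")
  expect_error(denoise(f, params = list(a = 1)),
               class = "dualelastica_parameter_error")
})
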