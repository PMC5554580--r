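zero_flow <- function(h, w) flow_field(matrix(0, h, w), matrix(0, h, w))

zero_grads <- function(h, w) {
  z <- matrix(0, h, w)
  structure(list(Ix = z, Iy = z, It = z), class = "gradient_triple")
}

test_that("zero gradients leave zero and constant flow unchanged (both updates)", {
  g <- zero_grads(6, 6)
  z <- zero_flow(6, 6)
  cst <- flow_field(matrix(1.3, 6, 6), matrix(-0.4, 6, 6))
  for (upd in list(hs_update, tv_update)) {
    f0 <- upd(z, g)
    expect_equal(f0$u, z$u)
    expect_equal(f0$v, z$v)
    f1 <- upd(cst, g)
    expect_equal(f1$u, cst$u, tolerance = 1e-12)
    expect_equal(f1$v, cst$v, tolerance = 1e-12)
  }
})

test_that("identical frames give exactly zero flow in every mode", {
  s <- analytic_pair(24, 24, 0, 0)
  for (m in c("hs", "tv", "adaptive")) {
    fl <- solve_flow(s, 1, solver_config(mode = m))
    expect_identical(fl$u, matrix(0, 24, 24))
    expect_identical(fl$v, matrix(0, 24, 24))
    expect_true(attr(fl, "converged"))
  }
})

test_that("constant-intensity frames with any nominal motion return zero flow", {
  f <- matrix(0.6, 16, 16)
  fl <- solve_flow(image_sequence(list(f, f)), 1, solver_config())
  expect_identical(fl$u, matrix(0, 16, 16))
})

test_that("the quadratic energy is non-increasing across iterations", {
  set.seed(31)
  h <- 10; w <- 12
  grads <- list(
    Ix = matrix(rnorm(h * w, sd = 2), h, w),
    Iy = matrix(rnorm(h * w, sd = 2), h, w),
    It = matrix(rnorm(h * w, sd = 0.5), h, w)
  )
  class(grads) <- "gradient_triple"
  for (gamma in c(0.1, 1, 10)) {
    cfg <- solver_config(mode = "hs", gamma = gamma)
    fl <- zero_flow(h, w)
    e_prev <- hs_energy(fl$u, fl$v, grads, cfg$alpha)
    for (it in 1:60) {
      fl <- hs_update(fl, grads, cfg)
      e <- hs_energy(fl$u, fl$v, grads, cfg$alpha)
      expect_lte(e, e_prev + 1e-9)
      e_prev <- e
    }
  }
})

test_that("converged quadratic flow matches the direct sparse Euler-Lagrange solve", {
  skip_if_not_installed("Matrix")
  s <- analytic_pair(16, 16, 0.3, -0.2)
  cfg <- solver_config(mode = "hs", gamma = 5, max_iter = 50000, tol = 1e-13)
  fl <- suppressWarnings(solve_flow(s, 1, cfg))
  grads <- compute_derivatives(s, 1)
  grads$Ix <- grads$Ix * cfg$intensity_scale
  grads$Iy <- grads$Iy * cfg$intensity_scale
  grads$It <- grads$It * cfg$intensity_scale
  ref <- direct_hs_solve(grads, cfg$alpha)
  expect_lt(max(abs(fl$u - ref$u)), 1e-4)
  expect_lt(max(abs(fl$v - ref$v)), 1e-4)
})

test_that("adaptive mode equals quadratic mode when the image is flat (p = 2)", {
  f1 <- matrix(0.5, 12, 12)
  f2 <- matrix(0.5, 12, 12)
  s <- image_sequence(list(f1, f2))
  fa <- solve_flow(s, 1, solver_config(mode = "adaptive"))
  fh <- solve_flow(s, 1, solver_config(mode = "hs"))
  expect_equal(fa$u, fh$u, tolerance = 1e-10)
  expect_equal(fa$v, fh$v, tolerance = 1e-10)
  expect_equal(max(abs(unclass(attr(fa, "p_map")) - 2)), 0)
})

test_that("translation of a textured pattern is recovered by the adaptive solver", {
  s <- analytic_pair(48, 48, 0.5, 0)
  fl <- suppressWarnings(
    solve_flow(s, 1, solver_config(mode = "adaptive", max_iter = 3000, tol = 1e-7))
  )
  interior <- 6:42
  epe <- sqrt((fl$u[interior, interior] - 0.5)^2 + fl$v[interior, interior]^2)
  expect_lt(mean(epe), 0.15)
  expect_lt(abs(mean(fl$u[interior, interior]) - 0.5), 0.1)
})

test_that("mirroring both frames mirrors the flow field", {
  s <- analytic_pair(32, 32, 0.4, 0.2)
  mir <- function(m) m[, rev(seq_len(ncol(m)))]
  sm <- image_sequence(lapply(s$frames, mir))
  cfg <- solver_config(mode = "adaptive", max_iter = 2000, tol = 1e-7)
  fl <- suppressWarnings(solve_flow(s, 1, cfg))
  flm <- suppressWarnings(solve_flow(sm, 1, cfg))
  interior <- 5:28
  # the cube derivative stencil is staggered by half a pixel, so compare on
  # the interior with a loose tolerance
  expect_lt(mean(abs(mir(flm$u)[interior, interior] + fl$u[interior, interior])), 0.08)
  expect_lt(mean(abs(mir(flm$v)[interior, interior] - fl$v[interior, interior])), 0.08)
})

test_that("non-convergence is reported via attribute and warning, not an error", {
  s <- analytic_pair(24, 24, 0.4, 0)
  expect_warning(
    fl <- solve_flow(s, 1, solver_config(max_iter = 3, tol = 1e-12)),
    "did not reach"
  )
  expect_false(attr(fl, "converged"))
  expect_equal(attr(fl, "iterations"), 3)
})

test_that("solver_config validates its parameters", {
  expect_error(solver_config(alpha = 0))
  expect_error(solver_config(gauss_size = 4))
  expect_error(solver_config(tol = 0))
  expect_error(solver_config(mode = "nope"))
})
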