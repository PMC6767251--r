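test_that("images satisfying A u = g are SART fixed points", {
  geom <- scan_geometry("parallel", n_views = 8, n_bins = 12, bin_size = 0.7)
  grid <- image_grid(4, 4, 1)
  set.seed(2)
  u <- matrix(runif(16), 4)
  g <- forward_project(u, geom, grid)
  expect_equal(sart_iteration(u, g, grid), u, tolerance = 1e-12)
})

test_that("SART converges to the dense pseudo-inverse solution", {
  geom <- scan_geometry("parallel", n_views = 8, n_bins = 12, bin_size = 0.7)
  grid <- image_grid(4, 4, 1)
  A <- dense_system_matrix(grid, geom)
  expect_equal(qr(A)$rank, 16)             # full column rank: unique solution
  set.seed(2)
  u_true <- matrix(runif(16), 4)
  g <- forward_project(u_true, geom, grid)
  x_ls <- MASS::ginv(A) %*% as.vector(g$values)
  u <- matrix(0, 4, 4)
  for (i in 1:200) u <- sart_iteration(u, g, grid)
  expect_lt(sqrt(mean((as.vector(u) - x_ls)^2)), 1e-4)
})

test_that("the SART residual is non-increasing on a consistent system", {
  geom <- scan_geometry("parallel", n_views = 8, n_bins = 12, bin_size = 0.7)
  grid <- image_grid(4, 4, 1)
  set.seed(4)
  g <- forward_project(matrix(runif(16), 4), geom, grid)
  u <- matrix(0, 4, 4)
  res <- numeric(10)
  for (i in 1:10) {
    u <- sart_iteration(u, g, grid)
    res[i] <- sqrt(sum((forward_project(u, geom, grid)$values - g$values)^2))
  }
  expect_true(all(diff(res) <= 1e-10))
  # all-deleted mask is an error
  bad <- g; bad$valid_mask[] <- FALSE
  expect_error(sart_iteration(u, bad, grid), "mask")
})

test_that("tv_descent leaves constants alone and strictly reduces TV", {
  flat <- matrix(3, 16, 16)
  expect_equal(tv_descent(flat, 10), flat)
  img <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  expect_identical(tv_descent(img, 0), img)
  set.seed(3)
  noisy <- img + matrix(rnorm(1024, 0, 0.1), 32)
  # direct-summation TV oracle, independent of the package helper
  tv_direct <- function(m) {
    s <- 0
    for (r in 1:(nrow(m) - 1)) for (cc in 1:ncol(m))
      s <- s + abs(m[r + 1, cc] - m[r, cc])
    for (r in 1:nrow(m)) for (cc in 1:(ncol(m) - 1))
      s <- s + abs(m[r, cc + 1] - m[r, cc])
    s
  }
  tvs <- vapply(0:10, function(k)
    tv_direct(tv_descent(noisy, k, 0.01, 0.95)), numeric(1))
  expect_true(all(diff(tvs) < 0))
  expect_equal(tvs[1], total_variation(noisy))
})

test_that("SART-TV beats FBP on a complete noiseless piecewise phantom", {
  geom <- scan_geometry("parallel", n_views = 180, n_bins = 128,
                        bin_size = 1)
  grid <- image_grid(128, 128, 1)
  ph <- make_phantom("random_ellipses", grid, seed = 5)
  sino <- forward_project(ph, geom, grid)
  r_fbp <- filtered_back_project(sino, grid)
  r_stv <- sart_tv(sino, grid, recon_params(15L, 10L, 0.01, 0.95))
  expect_lte(rmse(ph, r_stv), rmse(ph, r_fbp))
  expect_gte(min(r_stv), 0)
  # full-pipeline determinism
  expect_identical(r_stv, sart_tv(sino, grid, recon_params(15L, 10L)))
})

test_that("recon_params validates and carries the documented defaults", {
  p <- recon_params()
  expect_identical(p$n_iterations, 15L)
  expect_identical(p$tv_steps, 10L)
  expect_equal(p$alpha, 0.01)
  expect_equal(p$alpha_s, 0.95)
  expect_error(recon_params(alpha = 0))
  expect_error(recon_params(alpha_s = 1.5))
  base <- recon_params(50L, 15L)
  expect_identical(base$n_iterations, 50L)
})
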