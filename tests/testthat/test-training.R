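test_that("cgan_loss reproduces the symmetric and optimal cases", {
  half <- matrix(0.5, 4, 4)
  l <- cgan_loss(half, half)
  expect_equal(l$d_term, log(0.5) + log(0.5), tolerance = 1e-12)
  expect_equal(l$d_term, -1.386294, tolerance = 1e-6)
  # perfect discriminator: d_term -> 0 from below
  perf <- cgan_loss(matrix(1, 3, 3), matrix(0, 3, 3))
  expect_lte(perf$d_term, 0)
  expect_gt(perf$d_term, -1e-5)
  # random maps match an elementwise scalar-loop oracle
  set.seed(8)
  dr <- matrix(runif(12, 0.05, 0.95), 3)
  df <- matrix(runif(12, 0.05, 0.95), 3)
  acc_r <- 0; acc_f <- 0; acc_g <- 0
  for (i in seq_along(dr)) {
    acc_r <- acc_r + log(dr[i]) / length(dr)
    acc_f <- acc_f + log(1 - df[i]) / length(df)
    acc_g <- acc_g - log(df[i]) / length(df)
  }
  l2 <- cgan_loss(dr, df)
  expect_equal(l2$d_term, acc_r + acc_f, tolerance = 1e-12)
  expect_equal(l2$g_term, acc_g, tolerance = 1e-12)
  expect_equal(cgan_loss(dr, df, mode = "saturating")$g_term, acc_f,
               tolerance = 1e-12)
})

test_that("sinogram_loss is the mean absolute error", {
  a <- matrix(runif(24), 4)
  expect_equal(sinogram_loss(a, a), 0)
  expect_equal(sinogram_loss(matrix(0, 4, 6), matrix(1, 4, 6)), 1)
  set.seed(9)
  b <- matrix(runif(24), 4)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i]) / length(a)
  expect_equal(sinogram_loss(a, b), acc, tolerance = 1e-12)
  expect_error(sinogram_loss(a, matrix(0, 2, 2)), "differ")
})

test_that("reconstruction_loss is zero at equality and exactly linear", {
  geom <- scan_geometry("parallel", n_views = 32, n_bins = 32, bin_size = 1)
  grid <- image_grid(32, 32, 1)
  set.seed(10)
  y <- matrix(runif(32 * 32), 32)
  expect_equal(reconstruction_loss(y, y, geom, grid), 0)
  # an impulse perturbation: loss(y + delta, y) = mean |phi(delta)|
  delta <- matrix(0, 32, 32); delta[7, 19] <- 1e-3
  phid <- filtered_back_project(sinogram(delta, geom), grid)
  expect_equal(reconstruction_loss(y + delta, y, geom, grid),
               mean(abs(phid)), tolerance = 1e-10)
})

test_that("reconstruction-loss gradients match finite differences", {
  geom <- scan_geometry("parallel", n_views = 32, n_bins = 32, bin_size = 1)
  grid <- image_grid(32, 32, 1)
  set.seed(11)
  y <- matrix(runif(32 * 32), 32)
  e <- matrix(runif(32 * 32), 32)
  rl <- reconstruction_loss(e, y, geom, grid, gradient = TRUE)
  eps <- 1e-6
  idx <- cbind(c(3, 17, 30, 9, 24), c(5, 12, 28, 31, 2))
  for (r in seq_len(nrow(idx))) {
    ep <- e; ep[idx[r, 1], idx[r, 2]] <- ep[idx[r, 1], idx[r, 2]] + eps
    em <- e; em[idx[r, 1], idx[r, 2]] <- em[idx[r, 1], idx[r, 2]] - eps
    fd <- (reconstruction_loss(ep, y, geom, grid) -
             reconstruction_loss(em, y, geom, grid)) / (2 * eps)
    expect_equal(rl$grad[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-4)
  }
})

test_that("the total objective is the weighted loss combination", {
  cfg <- train_config(lambda1 = 120, lambda2 = 1e-5)
  expect_equal(total_objective(list(l_cgan = 0.5, l_sino = 0.01,
                                    l_recon = 100), cfg),
               1.701, tolerance = 1e-12)
  cfg0 <- train_config(lambda1 = 0, lambda2 = 0)
  expect_equal(total_objective(list(l_cgan = 0.37, l_sino = 5, l_recon = 9),
                               cfg0), 0.37)
  expect_equal(total_objective(list(l_cgan = 0, l_sino = 0, l_recon = 0),
                               cfg), 0)
})

test_that("the learning rate is constant then decays linearly to zero", {
  cfg <- train_config(epochs = 30)
  lrs <- vapply(1:30, function(e) lr_at_epoch(cfg, e), numeric(1))
  expect_true(all(lrs[1:15] == 0.002))
  expect_true(all(diff(lrs[15:30]) <= 0))
  expect_true(all(diff(lrs[16:30]) < 0))
  expect_lte(lrs[30], 0.002 / 30 * 2)
  expect_gt(lrs[30], 0)
})

test_that("micro training runs, logs the loss identity and reproduces", {
  ds <- micro_dataset(n_img = 2L, size = 32L)
  ck <- micro_train(ds, epochs = 2L)
  expect_s3_class(ck, "sigan_checkpoint")
  h <- ck$history
  expect_identical(nrow(h), 2L)
  expect_equal(h$l_total, h$l_cgan + 120 * h$l_sino + 1e-5 * h$l_recon,
               tolerance = 1e-10)
  expect_true(all(is.finite(as.matrix(h[, -1]))))
  # bit-reproducible under the same seed
  ck2 <- micro_train(ds, epochs = 2L)
  expect_equal(ck$history, ck2$history, tolerance = 1e-12)
  # lambda2 = 0 disables the reconstruction term
  ck0 <- micro_train(ds, epochs = 1L, lambda2 = 0)
  expect_true(all(ck0$history$l_recon == 0))
})

test_that("inpaint pastes measured views and enforces geometry", {
  ds <- micro_dataset(n_img = 2L, size = 32L)
  ck <- micro_train(ds, epochs = 2L)
  smp <- ds[[3]]
  est <- inpaint(ck, smp$input_sino)
  m <- smp$input_sino$valid_mask
  expect_identical(est$values[m, ], smp$input_sino$values[m, ])
  expect_true(all(est$valid_mask))
  # the generated block is clipped to [0, 1]; measured views are pasted
  # bit-exactly (and may carry noise slightly outside the range)
  expect_gte(min(est$values[!m, ]), 0)
  expect_lte(max(est$values[!m, ]), 1)
  # without pasting the measured region is the model's own estimate
  raw <- inpaint(ck, smp$input_sino, paste_measured = FALSE)
  expect_false(identical(raw$values[m, ], smp$input_sino$values[m, ]))
  # geometry mismatch
  other <- micro_dataset(n_img = 1L, size = 16L)
  expect_error(inpaint(ck, other[[1]]$input_sino), "geometry")
})
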