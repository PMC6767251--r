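test_that("phantom generation is canonical, seeded and degenerate-safe", {
  grid <- image_grid(128, 128, 1)
  sl <- make_phantom("shepp_logan", grid)
  expect_equal(dim(sl), c(128, 128))
  expect_gte(min(sl), 0)
  expect_lte(max(sl), 1)
  expect_gt(sum(sl > 0), 1000)             # the head ellipse fills the grid
  expect_equal(sl, make_phantom("shepp_logan", grid))
  r1 <- make_phantom("random_ellipses", grid, seed = 5)
  expect_equal(r1, make_phantom("random_ellipses", grid, seed = 5))
  expect_false(identical(r1, make_phantom("random_ellipses", grid, seed = 6)))
  expect_equal(make_phantom("random_ellipses", grid, seed = 1,
                            n_ellipses = 0),
               matrix(0, 128, 128))
  expect_error(make_phantom("nope", grid))
})

test_that("normalize_image rescales to [0, 0.255] and is idempotent", {
  img <- matrix(seq(0, 100, length.out = 64), 8)
  n <- normalize_image(img)
  expect_equal(max(n), 0.255)
  expect_equal(min(n), 0)
  expect_equal(normalize_image(n), n, tolerance = 1e-12)
  expect_equal(normalize_image(matrix(7, 4, 4)), matrix(0, 4, 4))
})

test_that("analytic ellipse sinograms obey symmetry, additivity and mode", {
  geom <- scan_geometry("parallel", n_views = 12, n_bins = 64, bin_size = 1)
  circ <- ellipse_spec(c(0, 0), c(20, 20), 0, 1)
  s <- analytic_ellipse_sinogram(list(circ), geom)$values
  off <- (seq_len(64) - 1 - 63 / 2) * 1
  chord <- 2 * sqrt(pmax(20^2 - off^2, 0))
  for (v in c(1, 5, 12)) expect_equal(s[v, ], chord, tolerance = 1e-10)
  expect_equal(analytic_ellipse_sinogram(list(), geom)$values,
               matrix(0, 12, 64))
  e1 <- ellipse_spec(c(-15, 4), c(6, 3), 30, 0.7)
  e2 <- ellipse_spec(c(14, -6), c(5, 8), -10, 0.4)
  expect_equal(analytic_ellipse_sinogram(list(e1, e2), geom)$values,
               analytic_ellipse_sinogram(list(e1), geom)$values +
                 analytic_ellipse_sinogram(list(e2), geom)$values)
  expect_error(analytic_ellipse_sinogram(list(circ), tiny_fan_geom()),
               "parallel")
})

test_that("analytic sinogram cross-validates the ray-traced projector", {
  geom <- scan_geometry("parallel", n_views = 10, n_bins = 512, bin_size = 1)
  grid <- image_grid(512, 512, 1)
  es <- list(ellipse_spec(c(-40, 30), c(120, 90), 15, 0.8),
             ellipse_spec(c(60, -50), c(50, 70), -25, 0.5))
  proj <- forward_project(rasterize_ellipses(es, grid), geom, grid)$values
  oracle <- analytic_ellipse_sinogram(es, geom)$values
  expect_lt(sqrt(mean((proj - oracle)^2)) / sqrt(mean(oracle^2)), 0.01)
})

test_that("add_noise is seeded, additive and validates variance", {
  geom <- tiny_parallel_geom()
  s <- forward_project(matrix(runif(256), 16), geom, image_grid(16, 16, 1))
  expect_identical(add_noise(s, noise_model(0))$values, s$values)
  n1 <- add_noise(s, noise_model(2e-6, seed = 3))
  expect_identical(n1$values, add_noise(s, noise_model(2e-6, seed = 3))$values)
  expect_identical(n1$valid_mask, s$valid_mask)
  expect_error(noise_model(-1), "non-negative")
})

test_that("views_in_window reproduces the printed deleted-view counts", {
  g512 <- scan_geometry("parallel", n_views = 512, n_bins = 8, bin_size = 1)
  expect_identical(views_in_window(g512, deletion_window(1, 120)), 341L)
  expect_identical(views_in_window(g512, deletion_window(16, 120)), 341L)
  expect_identical(views_in_window(g512, deletion_window(31, 100)), 284L)
  expect_identical(views_in_window(g512, deletion_window(1, 0)), 0L)
  expect_identical(
    views_in_window(tiny_parallel_geom(64L), deletion_window(1, 0)), 0L)
  expect_error(deletion_window(100, 120), "fit")
})

test_that("make_limited_angle zero-fills the exact printed view blocks", {
  g512 <- scan_geometry("parallel", n_views = 512, n_bins = 4, bin_size = 1)
  full <- sinogram(matrix(runif(512 * 4), 512), g512)
  lim <- make_limited_angle(full, deletion_window(1, 120))
  expect_true(all(lim$values[1:341, ] == 0))
  expect_identical(which(!lim$valid_mask), 1:341)
  expect_identical(lim$values[342:512, ], full$values[342:512, ])
  last <- make_limited_angle(full, deletion_window(61, 120))
  expect_identical(which(!last$valid_mask), 171:511)
  expect_identical(make_limited_angle(full, deletion_window(5, 0)), full)
  expect_error(make_limited_angle(lim, deletion_window(1, 120)), "complete")
})

test_that("paired samples keep input and label identical on measured views", {
  ds <- micro_dataset(n_img = 1L, size = 16L)
  smp <- ds[[1]]
  m <- smp$input_sino$valid_mask
  expect_identical(smp$input_sino$values[m, ], smp$label_sino$values[m, ])
  expect_true(all(smp$input_sino$values[!m, ] == 0))
  bad <- smp$input_sino
  bad$values[which(m)[1], 1] <- bad$values[which(m)[1], 1] + 1
  expect_error(paired_sample(bad, smp$label_sino, smp$source_image,
                             smp$window), "measured")
})

test_that("build_dataset emits images x windows pairs, bit-reproducibly", {
  grid <- image_grid(24, 24, 1)
  geom <- scan_geometry("parallel", n_views = 24, n_bins = 24, bin_size = 1)
  imgs <- lapply(1:3, function(i)
    make_phantom("random_ellipses", grid, seed = i))
  ds <- build_dataset(imgs, geom, standard_windows(), noise_model(2e-6, 0, 9))
  expect_length(ds, 15)
  ds2 <- build_dataset(imgs, geom, standard_windows(),
                       noise_model(2e-6, 0, 9))
  expect_identical(lapply(ds, function(s) s$label_sino$values),
                   lapply(ds2, function(s) s$label_sino$values))
  one <- build_dataset(imgs[1], geom, list(deletion_window(46, 120)),
                       noise_model(2e-6))
  expect_length(one, 1)
  expect_error(build_dataset(imgs, geom, list()), "window")
  # label sinograms are normalised to [0, 1] with recoverable scale
  expect_gte(min(ds[[1]]$label_sino$values), -0.01)
  expect_lte(max(ds[[1]]$label_sino$values), 1.01)
  expect_true(is.numeric(attr(ds[[1]]$label_sino, "srange")))
})
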