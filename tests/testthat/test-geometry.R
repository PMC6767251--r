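test_that("siddon_trace handles axis-aligned rays, misses and errors", {
  grid <- image_grid(4, 4, 1)
  # horizontal ray through the middle of row 2 (y = 0.5)
  tr <- siddon_trace(grid, c(-3, 0.5), c(3, 0.5))
  expect_equal(nrow(tr$pixel_indices), 4)
  expect_true(all(tr$pixel_indices[, "row"] == 2))
  expect_equal(sort(tr$pixel_indices[, "col"]), 1:4)
  expect_equal(tr$intersection_lengths, rep(1, 4))
  # ray missing the grid entirely
  miss <- siddon_trace(grid, c(-10, 5), c(10, 5))
  expect_equal(length(miss$intersection_lengths), 0)
  # degenerate ray
  expect_error(siddon_trace(grid, c(1, 1), c(1, 1)), "degenerate")
})

test_that("siddon_trace matches a per-pixel segment-clipping oracle", {
  # oracle: clip the segment against every pixel rectangle independently
  clip_length <- function(x0, y0, x1, y1, xlo, xhi, ylo, yhi) {
    dx <- x1 - x0; dy <- y1 - y0
    tmin <- 0; tmax <- 1
    for (s in list(c(dx, xlo - x0, xhi - x0), c(dy, ylo - y0, yhi - y0))) {
      if (s[1] == 0) {
        if (s[2] > 0 || s[3] < 0) return(0)
      } else {
        t1 <- s[2] / s[1]; t2 <- s[3] / s[1]
        if (t1 > t2) { tt <- t1; t1 <- t2; t2 <- tt }
        tmin <- max(tmin, t1); tmax <- min(tmax, t2)
      }
    }
    if (tmax <= tmin) return(0)
    (tmax - tmin) * sqrt(dx^2 + dy^2)
  }
  grid <- image_grid(8, 8, 0.7)
  h <- grid$pixel_size
  set.seed(42)
  for (rep in 1:20) {
    ang <- runif(1, 0, 2 * pi)
    p0 <- c(cos(ang), sin(ang)) * 6 + runif(2, -1, 1)
    p1 <- -c(cos(ang), sin(ang)) * 6 + runif(2, -1, 1)
    tr <- siddon_trace(grid, p0, p1)
    oracle <- matrix(0, 8, 8)
    for (r in 1:8) for (cc in 1:8) {
      xlo <- (cc - 1 - 4) * h; xhi <- (cc - 4) * h
      yhi <- (4 - (r - 1)) * h; ylo <- (4 - r) * h
      oracle[r, cc] <- clip_length(p0[1], p0[2], p1[1], p1[2],
                                   xlo, xhi, ylo, yhi)
    }
    got <- matrix(0, 8, 8)
    if (nrow(tr$pixel_indices) > 0)
      got[tr$pixel_indices] <- tr$intersection_lengths
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_true(all(tr$intersection_lengths >= 0))
    expect_lte(sum(tr$intersection_lengths), sqrt(2) * 8 * h + 1e-9)
  }
})

test_that("forward projection is linear and matches single-pixel traces", {
  grid <- image_grid(6, 6, 1)
  geom <- tiny_parallel_geom(5L, 10L)
  expect_equal(forward_project(matrix(0, 6, 6), geom, grid)$values,
               matrix(0, 5, 10))
  # one unit pixel: every sinogram entry equals that pixel's traced length
  img <- matrix(0, 6, 6); img[3, 4] <- 1
  sino <- forward_project(img, geom, grid)
  th <- view_angles_deg(geom) * pi / 180
  for (v in 1:5) for (b in c(1, 4, 7)) {
    s <- (b - 1 - (10 - 1) / 2) * geom$bin_size
    p <- c(s * cos(th[v]), s * sin(th[v]))
    u <- c(-sin(th[v]), cos(th[v]))
    tr <- siddon_trace(grid, p - 10 * u, p + 10 * u)
    hit <- tr$pixel_indices[, "row"] == 3 & tr$pixel_indices[, "col"] == 4
    expect_equal(sino$values[v, b], sum(tr$intersection_lengths[hit]),
                 tolerance = 1e-12)
  }
  # shape mismatch
  expect_error(forward_project(matrix(0, 4, 4), geom, grid), "match")
})

test_that("parallel projection of a disk matches the chord-length formula", {
  geom <- scan_geometry("parallel", n_views = 16, n_bins = 512, bin_size = 1)
  grid <- image_grid(512, 512, 1)
  disk <- list(ellipse_spec(c(0, 0), c(100, 100), 0, 1))
  proj <- forward_project(rasterize_ellipses(disk, grid), geom, grid)$values
  oracle <- analytic_ellipse_sinogram(disk, geom)$values
  rel <- sqrt(mean((proj - oracle)^2)) / sqrt(mean(oracle^2))
  expect_lt(rel, 0.01)
})

test_that("back projection is the exact adjoint of forward projection", {
  for (geom in list(tiny_parallel_geom(), tiny_fan_geom())) {
    grid <- image_grid(16, 16, 1)
    set.seed(7)
    v <- matrix(rnorm(256), 16)
    w <- matrix(rnorm(geom$n_views * geom$n_bins), geom$n_views)
    lhs <- sum(forward_project(v, geom, grid)$values * w)
    rhs <- sum(v * back_project(sinogram(w, geom), grid))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("back projection matches the dense-matrix oracle and masks views", {
  geom <- tiny_parallel_geom(4L, 8L)
  grid <- image_grid(5, 5, 1)
  A <- dense_system_matrix(grid, geom)
  set.seed(1)
  w <- matrix(rnorm(32), 4)
  expect_equal(as.vector(back_project(sinogram(w, geom), grid)),
               as.vector(t(A) %*% as.vector(w)), tolerance = 1e-10)
  # zero sinogram and single-entry support
  expect_equal(back_project(sinogram(matrix(0, 4, 8), geom), grid),
               matrix(0, 5, 5))
  one <- matrix(0, 4, 8); one[2, 5] <- 1
  img <- back_project(sinogram(one, geom), grid)
  ray <- matrix(A[(5 - 1) * 4 + 2, ], 5, 5)
  expect_equal(img, ray, tolerance = 1e-12)
  # invalid views contribute nothing
  msk <- sinogram(w, geom, valid_mask = c(TRUE, FALSE, TRUE, FALSE))
  w0 <- w; w0[c(2, 4), ] <- 0
  expect_equal(back_project(msk, grid),
               back_project(sinogram(w0, geom), grid))
})

test_that("ramp filtering matches a direct-DFT ramp oracle", {
  geom <- scan_geometry("parallel", n_views = 4, n_bins = 16, bin_size = 0.5)
  z <- matrix(0, 4, 16)
  expect_equal(ramp_filter(sinogram(z, geom))$values, z)
  # unit impulse response vs an explicit DFT |omega| oracle
  imp <- z; imp[2, 9] <- 1
  got <- ramp_filter(sinogram(imp, geom))$values
  np <- 32; ds <- 0.5
  ramp <- pmin(0:(np - 1), np - (0:(np - 1))) / (np * ds)
  x <- c(imp[2, ], rep(0, np - 16))
  idx <- 0:(np - 1)
  Fx <- vapply(idx, function(k)
    sum(x * exp(-2i * pi * k * idx / np)), complex(1))
  y <- Re(vapply(idx, function(n)
    mean(Fx * ramp * exp(2i * pi * idx * n / np)), complex(1)))
  expect_lt(max(abs(got[2, ] - y[1:16])), 1e-8)
  expect_equal(got[c(1, 3, 4), ], z[c(1, 3, 4), ])  # views independent
})

test_that("the ramp kernel removes the DC component", {
  geom <- scan_geometry("parallel", n_views = 2, n_bins = 64, bin_size = 1)
  con <- matrix(1, 2, 64)
  f <- ramp_filter(sinogram(con, geom))$values
  # zero DC gain: the filtered constant is near zero relative to the
  # unfiltered energy (edge effects from padding only)
  expect_lt(abs(sum(f[1, ])), 0.05 * sum(con[1, ]))
  expect_lt(max(abs(f[1, 16:48])), 0.01)  # interior essentially zero
})

test_that("FBP is linear and reconstructs a disk within tolerance", {
  geom <- scan_geometry("parallel", n_views = 256, n_bins = 128,
                        bin_size = 1)
  grid <- image_grid(128, 128, 1)
  expect_equal(
    filtered_back_project(sinogram(matrix(0, 256, 128), geom), grid),
    matrix(0, 128, 128))
  set.seed(3)
  g1 <- matrix(rnorm(256 * 128), 256)
  g2 <- matrix(rnorm(256 * 128), 256)
  lin <- filtered_back_project(sinogram(2 * g1 - 3 * g2, geom), grid)
  sep <- 2 * filtered_back_project(sinogram(g1, geom), grid) -
    3 * filtered_back_project(sinogram(g2, geom), grid)
  expect_equal(lin, sep, tolerance = 1e-10)
  # round trip on a centred disk: RMSE below 10% of the disk amplitude
  disk <- rasterize_ellipses(list(ellipse_spec(c(0, 0), c(40, 40), 0, 1)),
                             grid)
  rec <- filtered_back_project(forward_project(disk, geom, grid), grid)
  expect_lt(sqrt(mean((rec - disk)^2)), 0.1)
})

test_that("FBP error strictly decreases as views double", {
  grid <- image_grid(128, 128, 1)
  ph <- rasterize_ellipses(list(ellipse_spec(c(0, 10), c(45, 30), 20, 0.8)),
                           grid)
  errs <- vapply(c(64, 128, 256), function(nv) {
    geom <- scan_geometry("parallel", n_views = nv, n_bins = 128,
                          bin_size = 1)
    rec <- filtered_back_project(forward_project(ph, geom, grid), grid)
    sqrt(mean((rec - ph)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("fbp_adjoint is the transpose of filtered_back_project", {
  for (geom in list(tiny_parallel_geom(6L, 16L), tiny_fan_geom(6L, 16L))) {
    grid <- image_grid(12, 12, 1)
    set.seed(11)
    g <- matrix(rnorm(6 * 16), 6)
    v <- matrix(rnorm(144), 12)
    lhs <- sum(filtered_back_project(sinogram(g, geom), grid) * v)
    rhs <- sum(g * fbp_adjoint(v, geom, grid))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("constructors validate their invariants", {
  expect_error(image_grid(0, 4), "n_rows")
  expect_error(scan_geometry("fan", source_to_object = 900,
                             source_to_detector = 800))
  expect_error(sinogram(matrix(0, 3, 3), tiny_parallel_geom()), "match")
  g <- tiny_parallel_geom(4L, 6L)
  s <- sinogram(matrix(0, 4, 6), g)
  expect_true(all(s$valid_mask))
  expect_equal(s$angles_deg, c(0, 45, 90, 135))
})
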