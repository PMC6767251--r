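#' Ellipse specification for analytic phantoms
#'
#' @param center Length-2 numeric (x, y), physical units.
#' @param semi_axes Length-2 numeric (a, b), both positive.
#' @param rotation_deg Rotation of the a-axis, degrees counter-clockwise.
#' @param intensity Additive attenuation value inside the ellipse.
#' @return An object of class `ellipse_spec`.
#' @export
ellipse_spec <- function(center, semi_axes, rotation_deg = 0, intensity = 1) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation_deg = as.numeric(rotation_deg),
                 intensity = as.numeric(intensity)),
            class = "ellipse_spec")
}

# The canonical 10-ellipse head phantom (modified contrast variant), in
# coordinates of the unit disk; scaled to the grid by the caller.
shepp_logan_ellipses <- function() {
  p <- list(
    c( 0,      0,      0.69,   0.92,    0,  1.0),
    c( 0,     -0.0184, 0.6624, 0.874,   0, -0.8),
    c( 0.22,   0,      0.11,   0.31,  -18, -0.2),
    c(-0.22,   0,      0.16,   0.41,   18, -0.2),
    c( 0,      0.35,   0.21,   0.25,    0,  0.1),
    c( 0,      0.1,    0.046,  0.046,   0,  0.1),
    c( 0,     -0.1,    0.046,  0.046,   0,  0.1),
    c(-0.08,  -0.605,  0.046,  0.023,   0,  0.1),
    c( 0,     -0.605,  0.023,  0.023,   0,  0.1),
    c( 0.06,  -0.605,  0.023,  0.046,   0,  0.1))
  lapply(p, function(e)
    ellipse_spec(center = e[1:2], semi_axes = e[3:4],
                 rotation_deg = e[5], intensity = e[6]))
}

scale_ellipses <- function(ellipses, grid) {
  half <- 0.5 * min(grid$n_rows, grid$n_cols) * grid$pixel_size
  lapply(ellipses, function(e) {
    e$center <- e$center * half
    e$semi_axes <- e$semi_axes * half
    e
  })
}

#' Rasterise a list of ellipses onto a grid
#'
#' Pixel-centre membership test; intensities are additive where ellipses
#' overlap.
#'
#' @param ellipses List of [ellipse_spec()].
#' @param grid An [image_grid()].
#' @return Numeric `n_rows x n_cols` matrix.
#' @export
rasterize_ellipses <- function(ellipses, grid) {
  h <- grid$pixel_size
  xc <- (seq_len(grid$n_cols) - (grid$n_cols + 1) / 2) * h
  yr <- ((grid$n_rows + 1) / 2 - seq_len(grid$n_rows)) * h
  img <- matrix(0, grid$n_rows, grid$n_cols)
  X <- matrix(xc, grid$n_rows, grid$n_cols, byrow = TRUE)
  Y <- matrix(yr, grid$n_rows, grid$n_cols)
  for (e in ellipses) {
    phi <- e$rotation_deg * pi / 180
    dx <- X - e$center[1]; dy <- Y - e$center[2]
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    inside <- (u / e$semi_axes[1])^2 + (v / e$semi_axes[2])^2 <= 1
    img <- img + e$intensity * inside
  }
  img
}

#' Generate a synthetic phantom image
#'
#' Either the canonical 10-ellipse head phantom (`"shepp_logan"`, values in
#' \[0, 1\]) or a seeded random composition of 5-12 non-negative ellipses
#' (`"random_ellipses"`), the stand-in for clinical training slices.
#' Deterministic for a fixed seed. Intended to be rescaled afterwards by
#' [normalize_image()].
#'
#' @param kind `"shepp_logan"` or `"random_ellipses"`.
#' @param grid An [image_grid()].
#' @param seed Integer seed (used by `"random_ellipses"`).
#' @param n_ellipses Optional fixed ellipse count for `"random_ellipses"`
#'   (default: drawn uniformly from 5-12; 0 gives an all-zero image).
#' @return Numeric `n_rows x n_cols` matrix with non-negative values.
#' @export
make_phantom <- function(kind = c("shepp_logan", "random_ellipses"), grid,
                         seed = 1L, n_ellipses = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "image_grid"))
  if (kind == "shepp_logan") {
    img <- rasterize_ellipses(scale_ellipses(shepp_logan_ellipses(), grid),
                              grid)
    return(pmax(img, 0))
  }
  half <- 0.5 * min(grid$n_rows, grid$n_cols) * grid$pixel_size
  with_seed(seed, {
    n <- if (is.null(n_ellipses)) sample(5:12, 1) else as.integer(n_ellipses)
    if (n == 0) {
      matrix(0, grid$n_rows, grid$n_cols)
    } else {
      es <- lapply(seq_len(n), function(i) {
        ellipse_spec(center = runif(2, -0.55, 0.55) * half,
                     semi_axes = runif(2, 0.06, 0.35) * half,
                     rotation_deg = runif(1, 0, 180),
                     intensity = runif(1, 0.1, 1))
      })
      pmax(rasterize_ellipses(es, grid), 0)
    }
  })
}

#' Min-max rescale of an image to \[0, 0.255\]
#'
#' The value-normalisation step applied to every CT image before sinogram
#' simulation. A constant image (degenerate range) maps to all zeros.
#'
#' @param image Numeric matrix with finite values.
#' @return Rescaled matrix with range \[0, 0.255\].
#' @export
normalize_image <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0, nrow(image), ncol(image)))
  (image - rng[1]) / (rng[2] - rng[1]) * 0.255
}

#' Analytic parallel-beam sinogram of ellipses
#'
#' Exact chord-length line integrals, summed over ellipses: for a view at
#' angle theta and detector offset s, an ellipse with half-axes (a, b),
#' rotation phi and centre c contributes
#' `2 a b sqrt(w^2 - (s - s0)^2) / w^2` with
#' `w^2 = a^2 cos^2(theta - phi) + b^2 sin^2(theta - phi)` and
#' `s0 = c . (cos theta, sin theta)`. Used as the closed-form oracle that
#' cross-validates the ray-traced projector.
#'
#' @param ellipses List of [ellipse_spec()].
#' @param geometry A parallel-mode [scan_geometry()].
#' @return A [sinogram()].
#' @export
analytic_ellipse_sinogram <- function(ellipses, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (geometry$mode != "parallel")
    stop("analytic ellipse sinograms are only available in parallel mode")
  th <- view_angles_deg(geometry) * pi / 180
  s <- (seq_len(geometry$n_bins) - 1 - (geometry$n_bins - 1) / 2) *
    geometry$bin_size
  vals <- matrix(0, geometry$n_views, geometry$n_bins)
  for (e in ellipses) {
    phi <- e$rotation_deg * pi / 180
    a <- e$semi_axes[1]; b <- e$semi_axes[2]
    w2 <- a^2 * cos(th - phi)^2 + b^2 * sin(th - phi)^2
    s0 <- e$center[1] * cos(th) + e$center[2] * sin(th)
    d2 <- outer(-s0, s, `+`)^2          # (s - s0)^2, views x bins
    vals <- vals + 2 * e$intensity * a * b *
      sqrt(pmax(w2 - d2, 0)) / w2
  }
  sinogram(vals, geometry)
}

#' Additive Gaussian measurement noise model
#'
#' Zero-mean i.i.d. Gaussian noise per sinogram entry with variance
#' `variance` (default 2e-6, meaningful on the \[0, 1\] normalised sinogram
#' scale).
#'
#' @param variance Noise variance, `>= 0`.
#' @param mean Noise mean (0; kept for completeness).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(variance = 2e-6, mean = 0, seed = 1L) {
  if (variance < 0) stop("noise variance must be non-negative")
  structure(list(variance = as.numeric(variance), mean = as.numeric(mean),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Add Gaussian noise to a sinogram
#'
#' Adds independent `N(mean, variance)` noise to every entry; the validity
#' mask is unchanged. Deterministic for a fixed model seed, and the identity
#' when `variance = 0`.
#'
#' @param sino A [sinogram()].
#' @param noise A [noise_model()].
#' @return A noisy [sinogram()].
#' @export
add_noise <- function(sino, noise) {
  stopifnot(inherits(sino, "sinogram"), inherits(noise, "noise_model"))
  if (noise$variance == 0 && noise$mean == 0) return(sino)
  out <- sino
  out$values <- sino$values + with_seed(noise$seed,
    matrix(rnorm(length(sino$values), noise$mean, sqrt(noise$variance)),
           nrow(sino$values), ncol(sino$values)))
  out
}

#' Contiguous angular deletion window
#'
#' Start positions use the 1-based degree labels of the dataset recipe (the
#' five training windows are 1-120, 16-135, 31-150, 46-165 and 61-180
#' degrees, each spanning 120 degrees and leaving a 60-degree scan).
#'
#' @param start_deg First deleted degree (1-based label, `>= 1`).
#' @param span_deg Width of the deleted block in degrees (`>= 0`; must fit
#'   inside \[1, 180\]).
#' @return An object of class `deletion_window`.
#' @export
deletion_window <- function(start_deg, span_deg = 120) {
  stopifnot(start_deg >= 1, span_deg >= 0)
  if (start_deg + span_deg - 1 > 180)
    stop("deletion window [", start_deg, ", ", start_deg + span_deg - 1,
         "] does not fit within [1, 180] degrees")
  structure(list(start_deg = as.numeric(start_deg),
                 span_deg = as.numeric(span_deg)),
            class = "deletion_window")
}

#' The five standard 120-degree training deletion windows
#'
#' @return List of [deletion_window()] with starts 1, 16, 31, 46, 61 degrees.
#' @export
standard_windows <- function() {
  lapply(c(1, 16, 31, 46, 61), deletion_window, span_deg = 120)
}

#' Number of views deleted by a window
#'
#' `round(n_views * span_deg / angular_range_deg)`: a 120-degree window on a
#' 512-view, 180-degree scan deletes 341 views; a 100-degree window deletes
#' 284.
#'
#' @param geometry A [scan_geometry()].
#' @param window A [deletion_window()].
#' @return Integer count of contiguous deleted views.
#' @export
views_in_window <- function(geometry, window) {
  stopifnot(inherits(geometry, "scan_geometry"),
            inherits(window, "deletion_window"))
  if (window$span_deg >= geometry$angular_range_deg && window$span_deg > 0)
    stop("deletion span must be smaller than the angular range")
  as.integer(round(geometry$n_views * window$span_deg /
                     geometry$angular_range_deg))
}

#' Delete a contiguous block of views from a complete sinogram
#'
#' The deleted block starts at view index
#' `floor((start_deg - 1) * n_views / angular_range_deg)` (0-based) and spans
#' [views_in_window()] views; deleted views are zero-filled with their mask
#' set `FALSE`, while measured views are kept bit-identical. A zero-span
#' window is the identity.
#'
#' @param sino A [sinogram()] with an all-`TRUE` mask.
#' @param window A [deletion_window()].
#' @return The limited-angle [sinogram()].
#' @export
make_limited_angle <- function(sino, window) {
  stopifnot(inherits(sino, "sinogram"), inherits(window, "deletion_window"))
  if (!all(sino$valid_mask))
    stop("make_limited_angle expects a complete (all-valid) sinogram")
  n_del <- views_in_window(sino$geometry, window)
  if (n_del == 0) return(sino)
  g <- sino$geometry
  start0 <- floor((window$start_deg - 1) * g$n_views / g$angular_range_deg)
  del <- start0 + seq_len(n_del)          # 1-based view indices
  if (max(del) > g$n_views)
    stop("deletion window extends past the scanned range")
  out <- sino
  out$values[del, ] <- 0
  out$valid_mask[del] <- FALSE
  out
}

#' A paired limited-angle / complete sinogram training sample
#'
#' @param input_sino Limited-angle [sinogram()] (deleted views zero-filled,
#'   mask `FALSE` there).
#' @param label_sino Complete 180-degree [sinogram()].
#' @param source_image The grid values the sinograms were simulated from.
#' @param window The [deletion_window()] applied.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(input_sino, label_sino, source_image, window) {
  stopifnot(inherits(input_sino, "sinogram"),
            inherits(label_sino, "sinogram"))
  if (!identical(dim(input_sino$values), dim(label_sino$values)))
    stop("input and label sinogram shapes differ")
  m <- input_sino$valid_mask
  if (!identical(input_sino$values[m, ], label_sino$values[m, ]))
    stop("input must equal label on all measured views")
  structure(list(input_sino = input_sino, label_sino = label_sino,
                 source_image = source_image, window = window),
            class = "paired_sample")
}

#' Build a paired limited-angle/complete sinogram dataset
#'
#' For every image: value-normalise to \[0, 0.255\], forward-project under
#' `geometry`, min-max normalise the sinogram to \[0, 1\] (the normalisation
#' scale is kept as attributes `smin`/`srange` for later de-normalisation),
#' add Gaussian noise, then emit one pair per deletion window by zero-filling
#' the window. Produces `length(images) * length(windows)` pairs (1000 images
#' x the five standard windows = 5000 pairs). All randomness derives from
#' `noise$seed`; rebuilds are bit-identical.
#'
#' @param images List of numeric matrices (phantoms or CT slices).
#' @param geometry A [scan_geometry()].
#' @param windows Non-empty list of [deletion_window()].
#' @param noise A [noise_model()]; per-image noise seeds are derived from its
#'   seed.
#' @return A list of [paired_sample()] of class `paired_dataset`.
#' @export
build_dataset <- function(images, geometry, windows = standard_windows(),
                          noise = noise_model()) {
  stopifnot(length(images) > 0)
  if (length(windows) == 0) stop("at least one deletion window is required")
  grid0 <- NULL
  out <- vector("list", length(images) * length(windows))
  k <- 0L
  for (i in seq_along(images)) {
    img <- normalize_image(images[[i]])
    if (is.null(grid0) || nrow(img) != grid0$n_rows ||
        ncol(img) != grid0$n_cols)
      grid0 <- image_grid(nrow(img), ncol(img))
    sino <- forward_project(img, geometry, grid0)
    rng <- range(sino$values)
    srange <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    sino$values <- (sino$values - rng[1]) / srange
    sino <- add_noise(sino, noise_model(noise$variance, noise$mean,
                                        noise$seed + i))
    attr(sino, "smin") <- rng[1]
    attr(sino, "srange") <- srange
    for (w in windows) {
      k <- k + 1L
      out[[k]] <- paired_sample(make_limited_angle(sino, w), sino, img, w)
    }
  }
  structure(out, class = "paired_dataset")
}
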