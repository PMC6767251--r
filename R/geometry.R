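#' Discretised 2D reconstruction domain
#'
#' Describes the pixel grid holding the object `u` of the discrete imaging
#' model `g = A u`: `n_rows` x `n_cols` square pixels of physical side
#' `pixel_size`, centred on the rotation axis (the grid centre is the origin).
#'
#' @param n_rows,n_cols Grid dimensions in pixels (default 512 x 512, the
#'   standard medical CT reconstruction size).
#' @param pixel_size Physical pixel side length (same length unit as the
#'   detector bin size and the source distances).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(n_rows = 512L, n_cols = 512L, pixel_size = 1) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, pixel_size > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_size = as.numeric(pixel_size),
                 origin = c(0, 0)),
            class = "image_grid")
}

#' Scanner geometry defining the system matrix
#'
#' Parallel- or fan-beam acquisition over `n_views` angles
#' `theta_k = k * angular_range / n_views`, `k = 0 .. n_views - 1` (half-open
#' `[0, angular_range)`), with a flat detector of `n_bins` elements of size
#' `bin_size` whose centres are symmetric about the projection of the rotation
#' centre. For fan mode the source orbits at distance `source_to_object` and
#' the detector sits at `source_to_detector` from the source. Defaults follow
#' the training geometry of the real-scanner study: 512 views over 180
#' degrees, 512 bins of 0.831 mm, SOD 483.41 mm, SDD 796.49 mm.
#'
#' @param mode `"parallel"` or `"fan"`.
#' @param n_views Number of projection angles.
#' @param angular_range_deg Angular span in degrees (default 180).
#' @param n_bins Number of detector elements.
#' @param bin_size Detector element size.
#' @param source_to_object,source_to_detector Fan-beam distances (SOD, SDD).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(mode = c("fan", "parallel"), n_views = 512L,
                          angular_range_deg = 180, n_bins = 512L,
                          bin_size = 0.831, source_to_object = 483.41,
                          source_to_detector = 796.49) {
  mode <- match.arg(mode)
  n_views <- as.integer(n_views); n_bins <- as.integer(n_bins)
  stopifnot(n_views >= 1L, n_bins >= 1L, bin_size > 0, angular_range_deg > 0)
  if (mode == "fan") {
    stopifnot(source_to_object > 0, source_to_detector > source_to_object)
  }
  structure(list(mode = mode, n_views = n_views,
                 angular_range_deg = as.numeric(angular_range_deg),
                 n_bins = n_bins, bin_size = as.numeric(bin_size),
                 source_to_object = as.numeric(source_to_object),
                 source_to_detector = as.numeric(source_to_detector)),
            class = "scan_geometry")
}

#' View angles of a scan geometry
#'
#' @param geometry A [scan_geometry()].
#' @return Numeric vector of view angles in degrees,
#'   `theta_k = k * angular_range / n_views`, k 0-based.
#' @export
view_angles_deg <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  (seq_len(geometry$n_views) - 1) * geometry$angular_range_deg /
    geometry$n_views
}

#' Sinogram container
#'
#' A `n_views x n_bins` matrix of line integrals with its geometry, per-view
#' angles and a validity mask (`TRUE` = measured view, `FALSE` =
#' deleted/estimated). A complete 180-degree sinogram has an all-`TRUE` mask.
#'
#' @param values `n_views x n_bins` numeric matrix.
#' @param geometry The [scan_geometry()] the values were measured under.
#' @param valid_mask Logical vector of length `n_views`.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry,
                     valid_mask = rep(TRUE, geometry$n_views)) {
  stopifnot(inherits(geometry, "scan_geometry"), is.matrix(values))
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_bins)
    stop("sinogram values (", nrow(values), " x ", ncol(values),
         ") do not match geometry (", geometry$n_views, " views x ",
         geometry$n_bins, " bins)")
  stopifnot(is.logical(valid_mask), length(valid_mask) == geometry$n_views)
  structure(list(values = values, angles_deg = view_angles_deg(geometry),
                 valid_mask = valid_mask, geometry = geometry),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat("<sinogram> ", x$geometry$n_views, " views x ", x$geometry$n_bins,
      " bins (", x$geometry$mode, ", ",
      sum(x$valid_mask), " measured views)\n", sep = "")
  invisible(x)
}

check_sino_grid <- function(sino, grid) {
  stopifnot(inherits(sino, "sinogram"), inherits(grid, "image_grid"))
  invisible(TRUE)
}

#' Exact pixel intersection lengths of a ray (Siddon's algorithm)
#'
#' Traces the segment from `ray_start` to `ray_end` through the grid and
#' returns, for every pixel crossed, its (row, col) index and the exact
#' intersection length; these are the nonzero entries of one row of the system
#' matrix A. Pixels not crossed are absent. A ray missing the grid yields an
#' empty trace.
#'
#' @param grid An [image_grid()].
#' @param ray_start,ray_end Numeric length-2 physical coordinates (x, y) of
#'   the segment endpoints, which must lie outside or on the grid boundary.
#' @return A list of class `ray_trace` with `pixel_indices` (two-column
#'   integer matrix, 1-based rows/cols) and `intersection_lengths`.
#' @export
siddon_trace <- function(grid, ray_start, ray_end) {
  stopifnot(inherits(grid, "image_grid"),
            length(ray_start) == 2, length(ray_end) == 2)
  if (all(ray_start == ray_end))
    stop("degenerate ray: start and end coincide")
  tr <- cpp_siddon_trace(grid$n_rows, grid$n_cols, grid$pixel_size,
                         ray_start[1], ray_start[2], ray_end[1], ray_end[2])
  structure(list(pixel_indices = cbind(row = tr$rows, col = tr$cols),
                 intersection_lengths = tr$lengths),
            class = "ray_trace")
}

geom_mode_int <- function(geometry) if (geometry$mode == "parallel") 0L else 1L

#' Forward projection (the discrete imaging model g = A u)
#'
#' Computes the Siddon-weighted line integral of `image` for every
#' (view, bin) ray of `geometry`. Linear in the image; rays that miss the grid
#' contribute zero.
#'
#' @param image Numeric matrix of grid values (`n_rows x n_cols`).
#' @param geometry A [scan_geometry()].
#' @param grid An [image_grid()]; defaults to a unit-pixel grid of the image's
#'   shape.
#' @return A [sinogram()] with an all-`TRUE` mask.
#' @export
forward_project <- function(image, geometry,
                            grid = image_grid(nrow(image), ncol(image))) {
  stopifnot(is.matrix(image), inherits(geometry, "scan_geometry"),
            inherits(grid, "image_grid"))
  if (nrow(image) != grid$n_rows || ncol(image) != grid$n_cols)
    stop("image shape does not match grid")
  th <- view_angles_deg(geometry) * pi / 180
  vals <- cpp_forward_project(image, geom_mode_int(geometry), th,
                              geometry$n_bins, geometry$bin_size,
                              geometry$source_to_object,
                              geometry$source_to_detector, grid$pixel_size)
  sinogram(vals, geometry)
}

#' Back-projection (the exact adjoint A^T)
#'
#' Smears every sinogram entry back along its ray with the same Siddon
#' weights used by [forward_project()], so that `<A v, w> = <v, A^T w>` holds
#' exactly (up to floating-point rounding) for all images `v` and sinograms
#' `w`. Views flagged invalid are zero-filled by construction and contribute
#' nothing.
#'
#' @param sino A [sinogram()].
#' @param grid An [image_grid()].
#' @return Numeric `n_rows x n_cols` matrix.
#' @export
back_project <- function(sino, grid) {
  check_sino_grid(sino, grid)
  vals <- sino$values
  if (!all(sino$valid_mask)) vals[!sino$valid_mask, ] <- 0
  th <- sino$angles_deg * pi / 180
  g <- sino$geometry
  cpp_back_project(vals, geom_mode_int(g), th, g$bin_size,
                   g$source_to_object, g$source_to_detector,
                   grid$n_rows, grid$n_cols, grid$pixel_size)
}

# Effective detector sampling at the rotation centre (fan rays are magnified
# by SDD/SOD between the centre and the detector).
effective_bin <- function(geometry) {
  if (geometry$mode == "fan")
    geometry$bin_size * geometry$source_to_object / geometry$source_to_detector
  else geometry$bin_size
}

# Per-bin cosine weights for flat-detector fan-beam filtering; identity for
# parallel mode.
cosine_weights <- function(geometry) {
  if (geometry$mode != "fan") return(rep(1, geometry$n_bins))
  s <- (seq_len(geometry$n_bins) - 1 - (geometry$n_bins - 1) / 2) *
    geometry$bin_size
  geometry$source_to_detector /
    sqrt(geometry$source_to_detector^2 + s^2)
}

ramp_response <- function(n_pad, ds) {
  k <- c(0:(n_pad / 2), (n_pad / 2 - 1):1)
  k / (n_pad * ds)
}

#' Ram-Lak ramp filtering of a sinogram
#'
#' Convolves each view independently with the discrete Ram-Lak kernel,
#' realised in the frequency domain as the ideal ramp `|omega|` after
#' zero-padding each view to the next power of two at least `2 * n_bins`
#' (suppressing interperiod convolution). No apodisation window is applied.
#' The ramp removes the DC component, so a constant view filters to
#' (numerically) zero.
#'
#' @param sino A [sinogram()] with at least 2 bins.
#' @return A [sinogram()] of filtered views (mask and geometry preserved).
#' @export
ramp_filter <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  if (g$n_bins < 2) stop("ramp filtering needs at least 2 detector bins")
  out <- sino
  out$values <- ramp_filter_values(sino$values, effective_bin(g))
  out
}

ramp_filter_values <- function(values, ds) {
  nb <- ncol(values)
  n_pad <- 2^ceiling(log2(2 * nb))
  ramp <- ramp_response(n_pad, ds)
  m <- matrix(0, n_pad, nrow(values))
  m[seq_len(nb), ] <- t(values)
  fr <- mvfft(m) * ramp
  t(Re(mvfft(fr, inverse = TRUE)) / n_pad)[, seq_len(nb), drop = FALSE]
}

fbp_scale <- function(sino, grid) {
  g <- sino$geometry
  (pi / g$n_views) * effective_bin(g) / grid$pixel_size^2
}

#' Filtered back-projection reconstruction
#'
#' Classic FBP: each view is (for fan mode) cosine pre-weighted, Ram-Lak
#' filtered, then back-projected with angular weighting `pi / n_views` and the
#' discretisation scale `bin / pixel_size^2` that makes the Siddon adjoint
#' approximate the continuous back-projection integral. Deterministic and
#' linear in the sinogram. Invalid (deleted) views are treated as zero-filled.
#'
#' @param sino A complete or zero-filled [sinogram()].
#' @param grid An [image_grid()].
#' @return Numeric `n_rows x n_cols` reconstruction.
#' @export
filtered_back_project <- function(sino, grid) {
  check_sino_grid(sino, grid)
  g <- sino$geometry
  vals <- sino$values
  if (!all(sino$valid_mask)) vals[!sino$valid_mask, ] <- 0
  vals <- sweep(vals, 2, cosine_weights(g), `*`)
  q <- ramp_filter_values(vals, effective_bin(g))
  th <- sino$angles_deg * pi / 180
  img <- cpp_back_project(q, geom_mode_int(g), th, g$bin_size,
                          g$source_to_object, g$source_to_detector,
                          grid$n_rows, grid$n_cols, grid$pixel_size)
  img * fbp_scale(sino, grid)
}

#' Adjoint of filtered back-projection
#'
#' FBP is linear in the sinogram, `phi(g) = c * A^T F C g` (cosine weights C,
#' symmetric ramp filter F, Siddon adjoint A^T); its transpose
#' `phi^T(v) = c * C F A v` is needed to propagate image-domain gradients back
#' into the sinogram domain when the reconstruction loss is trained through
#' FBP.
#'
#' @param image Numeric matrix (an image-domain gradient).
#' @param geometry A [scan_geometry()].
#' @param grid An [image_grid()].
#' @return `n_views x n_bins` matrix of sinogram-domain gradients.
#' @export
fbp_adjoint <- function(image, geometry, grid) {
  stopifnot(is.matrix(image), inherits(geometry, "scan_geometry"),
            inherits(grid, "image_grid"))
  th <- view_angles_deg(geometry) * pi / 180
  p <- cpp_forward_project(image, geom_mode_int(geometry), th,
                           geometry$n_bins, geometry$bin_size,
                           geometry$source_to_object,
                           geometry$source_to_detector, grid$pixel_size)
  q <- ramp_filter_values(p, effective_bin(geometry))
  q <- sweep(q, 2, cosine_weights(geometry), `*`)
  q * fbp_scale(sinogram(p, geometry), grid)
}
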