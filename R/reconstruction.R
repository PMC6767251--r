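#' SART-TV control parameters
#'
#' Defaults follow the settings used to reconstruct estimated (inpainted)
#' sinograms: 15 outer iterations, each one SART data-fidelity sweep followed
#' by 10 total-variation descent steps with initial step scale `alpha = 0.01`
#' decayed by `alpha_s = 0.95` after each step. For limited-angle baselines
#' (reconstructing directly from the truncated sinogram) use
#' `n_iterations = 50`, `tv_steps = 15`, `alpha = 0.01` (or 0.015 for
#' real-scanner-like data).
#'
#' @param n_iterations Outer iterations (`>= 0`).
#' @param tv_steps TV descent steps per outer iteration (`>= 0`).
#' @param alpha Initial TV step scale, `> 0`.
#' @param alpha_s Per-step decay of the TV step, in (0, 1].
#' @param relaxation SART relaxation factor (default 1, standard SART).
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(n_iterations = 15L, tv_steps = 10L, alpha = 0.01,
                         alpha_s = 0.95, relaxation = 1) {
  stopifnot(n_iterations >= 0, tv_steps >= 0, alpha > 0,
            alpha_s > 0, alpha_s <= 1, relaxation > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 tv_steps = as.integer(tv_steps),
                 alpha = as.numeric(alpha), alpha_s = as.numeric(alpha_s),
                 relaxation = as.numeric(relaxation)),
            class = "recon_params")
}

#' One SART update sweep
#'
#' Simultaneous algebraic reconstruction step
#' `u <- u + relaxation * W_c A^T W_r (g - A u)` with row (per-ray
#' intersection-length sum) and column (per-pixel weight sum) normalisation.
#' Only views flagged valid contribute; rays that miss the grid are skipped.
#' Images satisfying `A u = g` on the valid views are fixed points, and on
#' consistent systems the iteration converges to the least-squares solution.
#'
#' @param image Current `n_rows x n_cols` estimate.
#' @param sino A [sinogram()] (deleted views ignored via its mask).
#' @param grid An [image_grid()].
#' @param relaxation Relaxation factor.
#' @return Updated image matrix.
#' @export
sart_iteration <- function(image, sino, grid, relaxation = 1) {
  check_sino_grid(sino, grid)
  stopifnot(is.matrix(image))
  if (nrow(image) != grid$n_rows || ncol(image) != grid$n_cols)
    stop("image shape does not match grid")
  if (!any(sino$valid_mask))
    stop("no measured views: the sinogram mask is all FALSE")
  g <- sino$geometry
  cpp_sart_sweep(image, sino$values, sino$valid_mask, geom_mode_int(g),
                 sino$angles_deg * pi / 180, g$bin_size,
                 g$source_to_object, g$source_to_detector,
                 grid$pixel_size, relaxation)
}

#' Anisotropic total variation of an image
#'
#' Sum of absolute forward differences along rows and columns (reflective
#' boundary: boundary differences are dropped).
#'
#' @param image Numeric matrix.
#' @return Scalar TV value.
#' @export
total_variation <- function(image) {
  sum(abs(diff(image))) + sum(abs(t(diff(t(image)))))
}

# Subgradient of the smoothed anisotropic TV (forward differences, reflective
# boundary), eps keeps |d| differentiable at 0.
tv_gradient <- function(image, eps = 1e-8) {
  nr <- nrow(image); nc <- ncol(image)
  g <- matrix(0, nr, nc)
  dv <- image[-1, , drop = FALSE] - image[-nr, , drop = FALSE]
  sv <- dv / sqrt(dv * dv + eps)
  g[-nr, ] <- g[-nr, , drop = FALSE] - sv
  g[-1, ] <- g[-1, , drop = FALSE] + sv
  dh <- image[, -1, drop = FALSE] - image[, -nc, drop = FALSE]
  sh <- dh / sqrt(dh * dh + eps)
  g[, -nc] <- g[, -nc, drop = FALSE] - sh
  g[, -1] <- g[, -1, drop = FALSE] + sh
  g
}

#' Steepest-descent total-variation minimisation steps
#'
#' Performs `steps` normalised-gradient descent steps on the anisotropic TV.
#' In the adaptive-steepest-descent convention, the step length starts at
#' `alpha * step_ref` -- where `step_ref` is the norm of the preceding
#' data-fidelity update (supplied by [sart_tv()]) and defaults to the image
#' norm when used standalone -- and is multiplied by `alpha_s` after each
#' step. A constant image (zero TV gradient) and `steps = 0` are identities.
#'
#' @param image Numeric matrix.
#' @param steps Number of descent steps (`>= 0`).
#' @param alpha Initial step scale.
#' @param alpha_s Per-step decay in (0, 1].
#' @param step_ref Reference magnitude for the step length (default
#'   `sqrt(sum(image^2))`).
#' @return The TV-reduced image.
#' @export
tv_descent <- function(image, steps = 10L, alpha = 0.01, alpha_s = 0.95,
                       step_ref = NULL) {
  stopifnot(is.matrix(image), steps >= 0)
  if (is.null(step_ref)) step_ref <- sqrt(sum(image^2))
  dtvg <- alpha * step_ref
  for (k in seq_len(steps)) {
    gr <- tv_gradient(image)
    ng <- sqrt(sum(gr^2))
    if (ng == 0 || dtvg == 0) break
    image <- image - dtvg * gr / ng
    dtvg <- dtvg * alpha_s
  }
  image
}

#' SART-TV iterative reconstruction
#'
#' Alternates, `n_iterations` times, one [sart_iteration()] data-fidelity
#' sweep with `tv_steps` TV descent steps whose step reference is the norm of
#' the image change produced by the SART sweep (the TV step scale `alpha` is
#' reset at every outer iteration and decayed by `alpha_s` within it), then
#' projects onto the non-negative orthant. Deterministic: identical inputs
#' give bit-identical reconstructions.
#'
#' @param sino A [sinogram()]; only mask-valid views drive the data term.
#' @param grid An [image_grid()].
#' @param params A [recon_params()].
#' @param image Optional warm-start image (default all-zero).
#' @return The reconstructed `n_rows x n_cols` image, clipped to `>= 0`.
#' @export
sart_tv <- function(sino, grid, params = recon_params(), image = NULL) {
  check_sino_grid(sino, grid)
  stopifnot(inherits(params, "recon_params"))
  if (is.null(image)) image <- matrix(0, grid$n_rows, grid$n_cols)
  for (it in seq_len(params$n_iterations)) {
    prev <- image
    image <- sart_iteration(image, sino, grid, params$relaxation)
    d_data <- sqrt(sum((image - prev)^2))
    image <- tv_descent(image, params$tv_steps, params$alpha, params$alpha_s,
                        step_ref = d_data)
    image <- pmax(image, 0)
  }
  image
}
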