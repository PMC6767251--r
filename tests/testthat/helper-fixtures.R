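# Shared fixtures for the test suite. Everything is generated in code.

tiny_parallel_geom <- function(n_views = 8L, n_bins = 24L, bin_size = 1) {
  scan_geometry("parallel", n_views = n_views, n_bins = n_bins,
                bin_size = bin_size)
}

tiny_fan_geom <- function(n_views = 8L, n_bins = 24L) {
  scan_geometry("fan", n_views = n_views, n_bins = n_bins, bin_size = 1,
                source_to_object = 40, source_to_detector = 80)
}

# Materialise the dense system matrix A ((n_views*n_bins) x n_pixels) row by
# row from siddon_trace; the independent oracle for adjointness and SART.
dense_system_matrix <- function(grid, geometry) {
  n_pix <- grid$n_rows * grid$n_cols
  A <- matrix(0, geometry$n_views * geometry$n_bins, n_pix)
  for (p in seq_len(n_pix)) {
    e <- matrix(0, grid$n_rows, grid$n_cols)
    e[p] <- 1
    A[, p] <- as.vector(forward_project(e, geometry, grid)$values)
  }
  A
}

# A tiny training set for micro-scale GAN runs: `n_img` random phantoms at
# `size` x `size`, five standard windows.
micro_dataset <- function(n_img = 4L, size = 32L, seed = 1L) {
  grid <- image_grid(size, size, 1)
  geom <- scan_geometry("parallel", n_views = size, n_bins = size,
                        bin_size = 1)
  imgs <- lapply(seq_len(n_img), function(i)
    make_phantom("random_ellipses", grid, seed = seed + i))
  build_dataset(imgs, geom, standard_windows(),
                noise_model(2e-6, seed = seed))
}

micro_train <- function(dataset, size = 32L, depth = 3L, epochs = 2L,
                        batch = 4L, seed = 1L, lambda2 = 1e-5) {
  train(dataset, generator_spec(c(size, size), depth = depth),
        discriminator_spec(),
        train_config(lambda2 = lambda2, batch_size = batch, epochs = epochs,
                     seed = seed))
}
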