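#' Desk-scale pipeline profile
#'
#' A CPU-tractable end-to-end configuration: 64 x 64 parallel-beam sinograms
#' (64 views over 180 degrees, unit pixels and bins), 40 random-ellipse
#' training phantoms x the five standard 120-degree deletion windows = 200
#' training pairs, a depth-6 generator, batch size 8 and 30 epochs, with the
#' published loss weights (`lambda1 = 120`, `lambda2 = 1e-5`). Held-out test
#' phantoms use the mid-range 46-165 degree window.
#'
#' @param n_train_images,n_test_images Phantom counts.
#' @param epochs,batch_size Training schedule.
#' @param size Sinogram/grid side (views = bins = pixels).
#' @param depth Generator depth.
#' @param lambda1,lambda2 Loss weights.
#' @return A named list of pipeline settings.
#' @export
smoke_profile <- function(n_train_images = 40L, n_test_images = 4L,
                          epochs = 30L, batch_size = 8L, size = 64L,
                          depth = 6L, lambda1 = 120, lambda2 = 1e-5) {
  list(size = as.integer(size), depth = as.integer(depth),
       n_train_images = as.integer(n_train_images),
       n_test_images = as.integer(n_test_images),
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lambda1 = lambda1, lambda2 = lambda2,
       geometry = scan_geometry("parallel", n_views = size,
                                n_bins = size, bin_size = 1),
       grid = image_grid(size, size, 1),
       train_windows = standard_windows(),
       test_window = deletion_window(46, 120),
       noise = noise_model(2e-6),
       recon_estimated = recon_params(15L, 10L, 0.01, 0.95),
       recon_limited = recon_params(50L, 15L, 0.01, 0.95))
}

#' Full-scale (published) pipeline profile
#'
#' The publication-scale settings: 512 x 512 fan-beam sinograms under the
#' real-scanner training geometry, 1000 training images x 5 windows = 5000
#' pairs, depth-9 generator, batch 64, 400 epochs. Provided for completeness;
#' at this scale training requires GPU-class resources.
#'
#' @return A named list of pipeline settings.
#' @export
paper_profile <- function() {
  p <- smoke_profile(n_train_images = 1000L, n_test_images = 200L,
                     epochs = 400L, batch_size = 64L, size = 512L,
                     depth = 9L)
  p$geometry <- scan_geometry("fan")
  p$grid <- image_grid(512L, 512L, 0.831 * 483.41 / 796.49)
  p
}

pipeline_phantoms <- function(profile, seed, n, offset = 0L) {
  lapply(seq_len(n), function(i)
    make_phantom("random_ellipses", profile$grid, seed = seed + offset + i))
}

masked_region_mae <- function(est, label, valid_mask) {
  mean(abs(sino_values(est)[!valid_mask, ] -
             sino_values(label)[!valid_mask, ]))
}

masked_region_rmse <- function(est, label, valid_mask) {
  sqrt(mean((sino_values(est)[!valid_mask, ] -
               sino_values(label)[!valid_mask, ])^2))
}

denormalize_sino <- function(sino, like) {
  out <- sino
  out$values <- sino$values * attr(like, "srange") + attr(like, "smin")
  out
}

#' Run the full sinogram-inpainting pipeline
#'
#' Prepare -> train -> inpaint -> reconstruct -> evaluate: generates
#' phantoms, builds the paired limited/complete sinogram dataset, trains the
#' GAN, inpaints held-out limited-angle sinograms, reconstructs them with
#' FBP and SART-TV, and tabulates RMSE/NMAD/PSNR/SSIM against the ground
#' truth phantoms for four methods: zero-filled FBP, limited-angle SART-TV,
#' inpainting + FBP and inpainting + SART-TV. Fully deterministic given
#' `seed`.
#'
#' @param profile A profile list from [smoke_profile()]/[paper_profile()].
#' @param seed Integer seed for phantoms, noise and training.
#' @param verbose Print progress.
#' @return List of class `sigan_pipeline` with the trained `model`, the
#'   methods x metrics `summary` data.frame, per-sample metric rows
#'   (`per_sample`), sinogram-domain statistics (`sino_stats`) and the
#'   held-out test samples.
#' @export
run_pipeline <- function(profile = smoke_profile(), seed = 1L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("[prepare] generating ", profile$n_train_images, " + ",
      profile$n_test_images, " phantoms")
  train_imgs <- pipeline_phantoms(profile, seed, profile$n_train_images)
  test_imgs <- pipeline_phantoms(profile, seed, profile$n_test_images,
                                 offset = profile$n_train_images)
  train_set <- build_dataset(train_imgs, profile$geometry,
                             profile$train_windows,
                             noise_model(profile$noise$variance,
                                         seed = seed))
  test_set <- build_dataset(test_imgs, profile$geometry,
                            list(profile$test_window),
                            noise_model(profile$noise$variance,
                                        seed = seed + 10^6))
  say("[train] ", length(train_set), " pairs, ", profile$epochs, " epochs")
  cfg <- train_config(lambda1 = profile$lambda1, lambda2 = profile$lambda2,
                      batch_size = profile$batch_size,
                      epochs = profile$epochs, seed = seed)
  model <- train(train_set, generator_spec(rep(profile$size, 2),
                                           depth = profile$depth),
                 discriminator_spec(), cfg, verbose = verbose)
  say("[evaluate] ", length(test_set), " held-out samples")
  per_sample <- list()
  sino_rows <- list()
  for (i in seq_along(test_set)) {
    smp <- test_set[[i]]
    truth <- smp$source_image
    est <- inpaint(model, smp$input_sino)
    sino_rows[[i]] <- data.frame(
      sample = i,
      mae_zero_fill = masked_region_mae(smp$input_sino, smp$label_sino,
                                        smp$input_sino$valid_mask),
      mae_inpainted = masked_region_mae(est, smp$label_sino,
                                        smp$input_sino$valid_mask),
      rmse_zero_fill = masked_region_rmse(smp$input_sino, smp$label_sino,
                                          smp$input_sino$valid_mask),
      rmse_inpainted = masked_region_rmse(est, smp$label_sino,
                                          smp$input_sino$valid_mask))
    lim_den <- denormalize_sino(smp$input_sino, smp$label_sino)
    est_den <- denormalize_sino(est, smp$label_sino)
    recons <- list(
      "FBP" = filtered_back_project(lim_den, profile$grid),
      "SART-TV" = sart_tv(lim_den, profile$grid, profile$recon_limited),
      "SI-GAN + FBP" = filtered_back_project(est_den, profile$grid),
      "SI-GAN + SART-TV" = sart_tv(est_den, profile$grid,
                                   profile$recon_estimated))
    for (m in names(recons)) {
      rep_ <- metrics_report(truth, recons[[m]])
      per_sample[[length(per_sample) + 1]] <- data.frame(
        sample = i, method = m, psnr = rep_$psnr, rmse = rep_$rmse,
        nmad = rep_$nmad, ssim = rep_$ssim)
    }
  }
  per_sample <- do.call(rbind, per_sample)
  summary <- do.call(rbind, lapply(split(per_sample, per_sample$method),
    function(df) data.frame(method = df$method[1], psnr = mean(df$psnr),
                            rmse = mean(df$rmse), nmad = mean(df$nmad),
                            ssim = mean(df$ssim))))
  summary <- summary[order(match(summary$method,
    c("FBP", "SART-TV", "SI-GAN + FBP", "SI-GAN + SART-TV"))), ]
  rownames(summary) <- NULL
  structure(list(model = model, summary = summary, per_sample = per_sample,
                 sino_stats = do.call(rbind, sino_rows),
                 test_set = test_set, profile = profile, seed = seed),
            class = "sigan_pipeline")
}

#' @export
print.sigan_pipeline <- function(x, ...) {
  cat("<sigan_pipeline> seed", x$seed, "-",
      nrow(x$sino_stats), "test samples\n\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Grid search over the loss weights lambda1, lambda2
#'
#' Trains one model per (lambda1, lambda2) pair at the given profile scale
#' and evaluates the average sinogram RMSE of the inpainted estimates on a
#' held-out subset (default 10 sinograms), producing the table behind the
#' weight-selection heatmap. Deterministic given `seed`.
#'
#' @param lambda1_list,lambda2_list Numeric vectors of weights to cross.
#' @param profile Pipeline profile (use a small one; each cell trains a
#'   model).
#' @param seed Integer seed shared by all cells.
#' @param n_eval Number of held-out sinograms to average over.
#' @return Data.frame with `lambda1`, `lambda2`, `rmse` per grid cell.
#' @export
lambda_grid_search <- function(lambda1_list = 120,
                               lambda2_list = c(0, 1e-5),
                               profile = smoke_profile(), seed = 1L,
                               n_eval = 10L) {
  n_eval <- min(n_eval, profile$n_test_images)
  train_imgs <- pipeline_phantoms(profile, seed, profile$n_train_images)
  test_imgs <- pipeline_phantoms(profile, seed, n_eval,
                                 offset = profile$n_train_images)
  train_set <- build_dataset(train_imgs, profile$geometry,
                             profile$train_windows,
                             noise_model(profile$noise$variance, seed = seed))
  test_set <- build_dataset(test_imgs, profile$geometry,
                            list(profile$test_window),
                            noise_model(profile$noise$variance,
                                        seed = seed + 10^6))
  rows <- list()
  for (l1 in lambda1_list) for (l2 in lambda2_list) {
    cfg <- train_config(lambda1 = l1, lambda2 = l2,
                        batch_size = profile$batch_size,
                        epochs = profile$epochs, seed = seed)
    model <- train(train_set, generator_spec(rep(profile$size, 2),
                                             depth = profile$depth),
                   discriminator_spec(), cfg)
    r <- mean(vapply(test_set, function(smp)
      rmse(smp$label_sino$values, inpaint(model, smp$input_sino)$values),
      numeric(1)))
    rows[[length(rows) + 1]] <- data.frame(lambda1 = l1, lambda2 = l2,
                                           rmse = r)
  }
  do.call(rbind, rows)
}
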