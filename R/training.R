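#' Training configuration for the sinogram-inpainting GAN
#'
#' Defaults are the published profile: sinogram-loss weight
#' `lambda1 = 120`, reconstruction-loss weight `lambda2 = 1e-5`, Adam with
#' `beta1 = 0.5`, `beta2 = 0.999`, learning rate 0.002 held constant for the
#' first half of training then decayed linearly to 0, batch size 64 and 400
#' epochs. Desk-scale runs use the same weights with a smaller batch and
#' epoch count (see [smoke_profile()]).
#'
#' @param lambda1 Weight of the sinogram-domain L1 loss (`>= 0`).
#' @param lambda2 Weight of the image-domain (FBP) L1 loss (`>= 0`).
#' @param lr Initial learning rate (`> 0`).
#' @param adam_beta1,adam_beta2 Adam moment decay rates, in \[0, 1).
#' @param batch_size Samples per optimisation step.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling initialisation, shuffling and noise.
#' @param adversarial `"non_saturating"` (default; the generator maximises
#'   `log D`) or `"saturating"` (the literal min-max form).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lambda1 = 120, lambda2 = 1e-5, lr = 0.002,
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         batch_size = 64L, epochs = 400L, seed = 1L,
                         adversarial = c("non_saturating", "saturating")) {
  adversarial <- match.arg(adversarial)
  stopifnot(lambda1 >= 0, lambda2 >= 0, lr > 0,
            adam_beta1 >= 0, adam_beta1 < 1, adam_beta2 >= 0, adam_beta2 < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 adversarial = adversarial),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Constant at `lr` for the first half of training, then linearly decayed to
#' 0 by the final epoch.
#'
#' @param cfg A [train_config()].
#' @param epoch Epoch number (1-based).
#' @return Scalar learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  half <- floor(cfg$epochs / 2)
  if (epoch <= half || cfg$epochs == 1) cfg$lr
  else cfg$lr * (cfg$epochs - epoch + 1) / (cfg$epochs - half)
}

CLAMP_EPS <- 1e-7

#' Conditional-GAN adversarial loss terms
#'
#' From patch probability maps `D(x, y)` (real) and `D(x, G(x, z))` (fake):
#' the discriminator term is `mean log D(x,y) + mean log(1 - D(x,G(x,z)))`
#' (to be maximised); the generator term is the non-saturating
#' `-mean log D(x,G(x,z))` by default, or the literal saturating
#' `mean log(1 - D(x,G(x,z)))` (to be minimised). Probabilities at exactly 0
#' or 1 are clamped away from the boundary by `1e-7`.
#'
#' @param d_real,d_fake Patch probability maps (values in (0, 1)).
#' @param mode `"non_saturating"` or `"saturating"`.
#' @return List with `g_term` and `d_term`.
#' @export
cgan_loss <- function(d_real, d_fake,
                      mode = c("non_saturating", "saturating")) {
  mode <- match.arg(mode)
  dr <- pmin(pmax(d_real, CLAMP_EPS), 1 - CLAMP_EPS)
  df <- pmin(pmax(d_fake, CLAMP_EPS), 1 - CLAMP_EPS)
  d_term <- mean(log(dr)) + mean(log(1 - df))
  g_term <- if (mode == "non_saturating") -mean(log(df))
            else mean(log(1 - df))
  list(g_term = g_term, d_term = d_term)
}

sino_values <- function(x) if (inherits(x, "sinogram")) x$values else x

#' Sinogram-domain L1 loss
#'
#' Mean absolute error between the estimated and label sinograms.
#'
#' @param estimated,label Sinograms or numeric matrices/arrays of equal
#'   shape.
#' @return Scalar mean absolute error.
#' @export
sinogram_loss <- function(estimated, label) {
  e <- sino_values(estimated); l <- sino_values(label)
  if (!identical(dim(e), dim(l))) stop("sinogram shapes differ")
  mean(abs(l - e))
}

#' Image-domain (reconstruction) L1 loss through differentiable FBP
#'
#' Mean absolute error between the filtered back-projections of the label and
#' estimated sinograms, `mean |phi(y) - phi(x_hat)|`. Because FBP is linear,
#' the exact gradient with respect to the estimated sinogram is
#' `phi^T(sign(phi(x_hat) - phi(y))) / N` (computed by [fbp_adjoint()]), and
#' is returned when `gradient = TRUE`.
#'
#' @param estimated,label Sinograms or `n_views x n_bins` matrices.
#' @param geometry The [scan_geometry()] of the sinograms.
#' @param grid The [image_grid()] on which the loss is evaluated.
#' @param gradient Also return the gradient w.r.t. `estimated`.
#' @return Scalar loss, or `list(value, grad)` when `gradient = TRUE`.
#' @export
reconstruction_loss <- function(estimated, label, geometry, grid,
                                gradient = FALSE) {
  e <- sino_values(estimated); l <- sino_values(label)
  if (!identical(dim(e), dim(l))) stop("sinogram shapes differ")
  fe <- filtered_back_project(sinogram(e, geometry), grid)
  fl <- filtered_back_project(sinogram(l, geometry), grid)
  value <- mean(abs(fl - fe))
  if (!gradient) return(value)
  g <- fbp_adjoint(sign(fe - fl), geometry, grid) / length(fe)
  list(value = value, grad = g)
}

#' Total training objective
#'
#' `L = L_cGAN + lambda1 * L_sino + lambda2 * L_recon`.
#'
#' @param losses List with components `l_cgan`, `l_sino`, `l_recon` (e.g. a
#'   `loss_values` record).
#' @param cfg A [train_config()] providing `lambda1`, `lambda2`.
#' @return Scalar objective.
#' @export
total_objective <- function(losses, cfg) {
  losses$l_cgan + cfg$lambda1 * losses$l_sino + cfg$lambda2 * losses$l_recon
}

loss_values <- function(l_cgan, l_sino, l_recon, d_loss, cfg) {
  list(l_cgan = l_cgan, l_sino = l_sino, l_recon = l_recon,
       l_total = l_cgan + cfg$lambda1 * l_sino + cfg$lambda2 * l_recon,
       d_loss = d_loss)
}

stack_sinos <- function(dataset, field) {
  v0 <- dataset[[1]][[field]]$values
  arr <- array(0, c(1L, nrow(v0), ncol(v0), length(dataset)))
  for (i in seq_along(dataset)) arr[1, , , i] <- dataset[[i]][[field]]$values
  arr
}

#' Train the sinogram-inpainting GAN
#'
#' Alternating adversarial optimisation: per batch, one discriminator Adam
#' step on the paired (limited-angle, complete) sinograms -- real pairs
#' `(x, y)` versus fake pairs `(x, G(x, z))` -- followed by one generator
#' Adam step on the combined objective (adversarial + `lambda1` * sinogram L1
#' + `lambda2` * FBP image L1, the image term back-propagated through the
#' package's differentiable FBP). The learning rate follows
#' [lr_at_epoch()]. All randomness (initialisation, shuffling, dropout
#' noise) derives from `cfg$seed`; reruns with the same seed reproduce the
#' loss history. Non-finite losses abort with a diagnostic.
#'
#' @param dataset A `paired_dataset` from [build_dataset()].
#' @param g_spec A [generator_spec()] matching the sinogram size.
#' @param d_spec A [discriminator_spec()].
#' @param cfg A [train_config()].
#' @param recon_grid Optional [image_grid()] for the image-domain loss
#'   (default: square grid of `n_bins` pixels at the effective bin size).
#' @param verbose Print per-epoch losses.
#' @return A checkpoint of class `sigan_checkpoint`: trained generator and
#'   discriminator, config, geometry and a per-epoch `history` data.frame
#'   with columns `epoch`, `l_cgan`, `l_sino`, `l_recon`, `l_total`,
#'   `d_loss`, `lr`.
#' @export
train <- function(dataset, g_spec, d_spec, cfg = train_config(),
                  recon_grid = NULL, verbose = FALSE) {
  stopifnot(length(dataset) > 0, inherits(g_spec, "generator_spec"),
            inherits(d_spec, "discriminator_spec"),
            inherits(cfg, "train_config"))
  geometry <- dataset[[1]]$label_sino$geometry
  x_all <- stack_sinos(dataset, "input_sino")
  y_all <- stack_sinos(dataset, "label_sino")
  n <- dim(x_all)[4]
  use_recon <- cfg$lambda2 > 0
  if (use_recon && is.null(recon_grid))
    recon_grid <- image_grid(geometry$n_bins, geometry$n_bins,
                             effective_bin(geometry))
  phi_y <- NULL
  if (use_recon) {
    phi_y <- vector("list", n)
    for (i in seq_len(n))
      phi_y[[i]] <- filtered_back_project(
        sinogram(y_all[1, , , i], geometry), recon_grid)
  }
  with_seed(cfg$seed, {
    G <- attach_store(build_generator(g_spec, seed = sample.int(1e6, 1)))
    D <- attach_store(build_discriminator(d_spec, seed = sample.int(1e6, 1)))
    g_t <- 0L; d_t <- 0L
    b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
    history <- vector("list", cfg$epochs)
    n_batches <- max(1L, floor(n / cfg$batch_size))
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample.int(n)
      ep <- c(l_cgan = 0, l_sino = 0, l_recon = 0, d_loss = 0)
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1) * cfg$batch_size + 1):
                     min(bi * cfg$batch_size, n)]
        x <- x_all[, , , idx, drop = FALSE]
        y <- y_all[, , , idx, drop = FALSE]
        gf <- generator_forward(G, x, train = TRUE)
        fake <- gf$out
        G$params[names(gf$updates)] <- gf$updates
        ## discriminator step: gradients of both the real and the fake
        ## pair accumulate in the float store
        fr <- discriminator_forward(D, pair_input(x, y), train = TRUE)
        D$params[names(fr$updates)] <- fr$updates
        ff <- discriminator_forward(D, pair_input(x, fake), train = TRUE)
        D$params[names(ff$updates)] <- ff$updates
        pr <- pmin(pmax(fr$out, CLAMP_EPS), 1 - CLAMP_EPS)
        pf <- pmin(pmax(ff$out, CLAMP_EPS), 1 - CLAMP_EPS)
        d_loss <- -(mean(log(pr)) + mean(log(1 - pf)))
        cpp_store_zero_grads(D$store)
        discriminator_backward(D, fr$cache, -1 / (length(pr) * pr))
        discriminator_backward(D, ff$cache, 1 / (length(pf) * (1 - pf)))
        ## generator step (adversarial gradient through the same, pre-update
        ## discriminator forward pass; simultaneous-style update)
        if (cfg$adversarial == "non_saturating") {
          adv <- -mean(log(pf))
          dp2 <- -1 / (length(pf) * pf)
        } else {
          adv <- mean(log(1 - pf))
          dp2 <- -1 / (length(pf) * (1 - pf))
        }
        dfake <- split_channels(
          discriminator_backward(D, ff$cache, dp2, want_dx = TRUE,
                                 want_dw = FALSE)$dx, 1)[[2]]
        d_t <- d_t + 1L
        cpp_store_adam(D$store, lr, b1, b2, 1 - b1^d_t, 1 - b2^d_t, 1e-8)
        l_sino <- mean(abs(y - fake))
        dfake <- dfake + cfg$lambda1 * sign(fake - y) / length(fake)
        l_recon <- 0
        if (use_recon) {
          for (s in seq_along(idx)) {
            fe <- filtered_back_project(
              sinogram(fake[1, , , s], geometry), recon_grid)
            fl <- phi_y[[idx[s]]]
            l_recon <- l_recon + mean(abs(fl - fe))
            gs <- fbp_adjoint(sign(fe - fl), geometry, recon_grid) /
              length(fe)
            dfake[1, , , s] <- dfake[1, , , s] +
              cfg$lambda2 * gs / length(idx)
          }
          l_recon <- l_recon / length(idx)
        }
        cpp_store_zero_grads(G$store)
        generator_backward(G, gf$cache, dfake)
        g_t <- g_t + 1L
        cpp_store_adam(G$store, lr, b1, b2, 1 - b1^g_t, 1 - b2^g_t, 1e-8)
        step_losses <- loss_values(adv, l_sino, l_recon, d_loss, cfg)
        if (!all(vapply(step_losses, is.finite, logical(1))))
          stop("training diverged at epoch ", epoch, ", batch ", bi,
               ": non-finite loss (cgan=", adv, ", sino=", l_sino,
               ", recon=", l_recon, ", d=", d_loss, ")")
        ep <- ep + c(adv, l_sino, l_recon, d_loss)
      }
      ep <- ep / n_batches
      history[[epoch]] <- data.frame(
        epoch = epoch, l_cgan = ep[1], l_sino = ep[2], l_recon = ep[3],
        l_total = ep[1] + cfg$lambda1 * ep[2] + cfg$lambda2 * ep[3],
        d_loss = ep[4], lr = lr)
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.5f  G_adv %.4f  L1 %.5f  recon %.5f  D %.4f",
          epoch, lr, ep[1], ep[2], ep[3], ep[4]))
    }
    G <- detach_store(G)
    D <- detach_store(D)
    structure(list(generator = G, discriminator = D, config = cfg,
                   geometry = geometry, recon_grid = recon_grid,
                   history = do.call(rbind, history), seed = cfg$seed),
              class = "sigan_checkpoint")
  })
}

#' Inpaint a limited-angle sinogram with a trained model
#'
#' Runs the generator on the zero-filled limited-angle sinogram to estimate
#' the complete 180-degree sinogram (noise injection off; output clipped to
#' \[0, 1\]). By default the measured views are pasted back bit-exactly over
#' the estimate, so only the deleted block is generated.
#'
#' @param model A `sigan_checkpoint` from [train()] (or a bare
#'   `sigan_generator`).
#' @param limited A limited-angle [sinogram()] with a validity mask.
#' @param paste_measured Replace mask-valid views by the measured values
#'   (default `TRUE`).
#' @param batch_stats Normalise with the input's own batch statistics (the
#'   image-to-image cGAN inference convention) instead of the running
#'   averages accumulated in training; default `FALSE` (running averages,
#'   which measured slightly better on held-out phantoms here).
#' @return The estimated complete [sinogram()] (all-`TRUE` mask).
#' @export
inpaint <- function(model, limited, paste_measured = TRUE,
                    batch_stats = FALSE) {
  G <- if (inherits(model, "sigan_checkpoint")) model$generator else model
  stopifnot(inherits(G, "sigan_generator"), inherits(limited, "sinogram"))
  if (inherits(model, "sigan_checkpoint")) {
    tg <- model$geometry
    lg <- limited$geometry
    if (tg$n_views != lg$n_views || tg$n_bins != lg$n_bins)
      stop("sinogram geometry (", lg$n_views, " x ", lg$n_bins,
           ") does not match the training geometry (", tg$n_views, " x ",
           tg$n_bins, ")")
  }
  est <- generator_forward(G, limited$values, train = FALSE,
                           batch_stats = batch_stats)$out[1, , , 1]
  est <- pmin(pmax(est, 0), 1)
  if (paste_measured) est[limited$valid_mask, ] <-
      limited$values[limited$valid_mask, ]
  out <- limited
  out$values <- est
  out$valid_mask <- rep(TRUE, length(limited$valid_mask))
  out
}
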