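#' U-Net generator specification
#'
#' The sinogram-inpainting generator: a `depth`-level encoder of stride-2
#' 4 x 4 convolutions (leaky-rectifier slope 0.2) mirrored by a decoder of
#' stride-2 4 x 4 transposed convolutions with skip connections between
#' encoder level `i` and decoder level `depth - i + 1`, so decoder layers see
#' twice the channels of the matching encoder layer. At full scale
#' (`depth = 9`) the encoder channels are 64, 128, 256 then 512 for the
#' remaining six layers, and the decoder mirrors them; a reduced `depth`
#' keeps the head (64, 128, 256) and the 512-channel tail of the pattern. A
#' final 1 x 1 convolution maps the 64-channel last decoder output
#' to the 1-channel sinogram with a sigmoid keeping values in \[0, 1\].
#' Batch normalisation (on all but the first encoder and last decoder layer)
#' and the noise-injection mode for `z` are configurable; `"dropout"` (rate
#' 0.5 in the first three decoder layers, active during training) is the
#' default, `"channel"` adds Gaussian noise at the bottleneck, `"none"`
#' disables injection.
#'
#' @param input_size Length-2 integer (H, W); both must be divisible by
#'   `2^depth`.
#' @param depth Number of encoder/decoder levels (default 9; full scale).
#' @param noise_mode `"dropout"`, `"channel"` or `"none"`.
#' @param batchnorm Use batch normalisation (default `TRUE`).
#' @param kernel,stride,leaky_slope Fixed architecture constants (4, 2, 0.2).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = c(512L, 512L), depth = 9L,
                           noise_mode = c("dropout", "channel", "none"),
                           batchnorm = TRUE, kernel = 4L, stride = 2L,
                           leaky_slope = 0.2) {
  noise_mode <- match.arg(noise_mode)
  depth <- as.integer(depth)
  stopifnot(depth >= 1L, length(input_size) == 2)
  head <- c(64L, 128L, 256L)
  enc <- if (depth <= 3L) head[seq_len(depth)]
         else c(head, rep(512L, depth - 3L))
  structure(list(input_size = as.integer(input_size), depth = depth,
                 encoder_channels = enc, decoder_channels = rev(enc),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 leaky_slope = leaky_slope, noise_mode = noise_mode,
                 batchnorm = isTRUE(batchnorm)),
            class = "generator_spec")
}

#' Patch discriminator specification
#'
#' Five 4 x 4 convolution layers with 64, 128, 256, 512 and 1 filters and
#' strides 2, 2, 2, 1, 1, rectifier activations between layers and a final
#' sigmoid. The input is the channel-concatenated (conditioning, candidate)
#' sinogram pair; the output is an N x N map of per-patch real/fake
#' probabilities (the design patch size is 64 x 64), averaged by
#' [discriminator_decision()].
#'
#' @param channels Filter counts per layer.
#' @param strides Stride per layer.
#' @param kernel Kernel size (4).
#' @param batchnorm Batch-normalise the middle layers (default `TRUE`).
#' @param patch_size Nominal receptive-field patch size (64).
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(channels = c(64L, 128L, 256L, 512L, 1L),
                               strides = c(2L, 2L, 2L, 1L, 1L),
                               kernel = 4L, batchnorm = TRUE,
                               patch_size = 64L) {
  stopifnot(length(channels) == length(strides),
            channels[length(channels)] == 1L)
  structure(list(layers = length(channels), channels = as.integer(channels),
                 strides = as.integer(strides), kernel = as.integer(kernel),
                 batchnorm = isTRUE(batchnorm),
                 patch_size = as.integer(patch_size)),
            class = "discriminator_spec")
}

# Per-layer channel bookkeeping used by both the builders and the parameter
# counter.
generator_layout <- function(spec) {
  d <- spec$depth
  enc <- spec$encoder_channels; dec <- spec$decoder_channels
  rows <- list()
  for (i in seq_len(d)) {
    rows[[length(rows) + 1]] <- list(
      name = paste0("enc", i), op = "conv",
      c_in = if (i == 1) 1L else enc[i - 1], c_out = enc[i],
      kernel = spec$kernel, stride = spec$stride,
      bn = spec$batchnorm && i > 1, dropout = FALSE)
  }
  for (j in seq_len(d)) {
    c_in <- if (j == 1) enc[d] else dec[j - 1] + enc[d - j + 1]
    rows[[length(rows) + 1]] <- list(
      name = paste0("dec", j), op = "convt",
      c_in = c_in, c_out = dec[j],
      kernel = spec$kernel, stride = spec$stride,
      bn = spec$batchnorm && j < d,
      dropout = spec$noise_mode == "dropout" && j <= 3)
  }
  rows[[length(rows) + 1]] <- list(
    name = "out", op = "conv", c_in = dec[d], c_out = 1L,
    kernel = 1L, stride = 1L, bn = FALSE, dropout = FALSE)
  do.call(rbind, lapply(rows, as.data.frame))
}

discriminator_layout <- function(spec) {
  n <- spec$layers
  rows <- lapply(seq_len(n), function(i) {
    list(name = paste0("d", i), op = "conv",
         c_in = if (i == 1) 2L else spec$channels[i - 1],
         c_out = spec$channels[i],
         kernel = spec$kernel, stride = spec$strides[i],
         bn = spec$batchnorm && i > 1 && i < n, dropout = FALSE)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

init_layer_params <- function(layout, params) {
  for (r in seq_len(nrow(layout))) {
    l <- layout[r, ]
    kk <- l$kernel^2
    if (l$op == "conv") {
      params[[paste0(l$name, "_W")]] <- init_conv_w(l$c_out, l$c_in * kk)
    } else {
      params[[paste0(l$name, "_W")]] <- init_conv_w(l$c_in, l$c_out * kk)
    }
    params[[paste0(l$name, "_b")]] <- numeric(l$c_out)
    if (l$bn) {
      params[[paste0(l$name, "_g")]] <- rnorm(l$c_out, 1, 0.02)
      params[[paste0(l$name, "_be")]] <- numeric(l$c_out)
      params[[paste0(l$name, "_rm")]] <- numeric(l$c_out)
      params[[paste0(l$name, "_rv")]] <- rep(1, l$c_out)
    }
  }
  params
}

trainable_names <- function(params)
  names(params)[!grepl("_(rm|rv)$", names(params))]

#' Build the U-Net generator
#'
#' Initialises all weights from `N(0, 0.02)` (batch-norm scales from
#' `N(1, 0.02)`) under the given seed; identical seeds give identical
#' initialisations.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return A model list (spec, layout, params) of class `sigan_generator`.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  check_generator_size(spec, spec$input_size)
  layout <- generator_layout(spec)
  params <- with_seed(seed, init_layer_params(layout, list()))
  structure(list(spec = spec, layout = layout, params = params, seed = seed),
            class = "sigan_generator")
}

check_generator_size <- function(spec, hw) {
  div <- 2^spec$depth
  if (any(hw %% div != 0))
    stop("generator input size ", hw[1], " x ", hw[2],
         " is not divisible by 2^depth = ", div,
         "; choose a size that halves cleanly through all ", spec$depth,
         " encoder levels or reduce depth")
  invisible(TRUE)
}

#' Build the patch discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed.
#' @return A model list of class `sigan_discriminator`.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  layout <- discriminator_layout(spec)
  params <- with_seed(seed, init_layer_params(layout, list()))
  structure(list(spec = spec, layout = layout, params = params, seed = seed),
            class = "sigan_discriminator")
}

# Read a (small) parameter either from the R list or the float store.
param_of <- function(model, nm) {
  if (is.null(model$store)) model$params[[nm]]
  else cpp_store_get(model$store, nm)
}

# Move the trainable parameters of a model into a C++ float store (training
# fast path); detach copies them back into the R list.
attach_store <- function(model) {
  st <- cpp_store_create()
  for (nm in trainable_names(model$params)) {
    p <- model$params[[nm]]
    if (is.matrix(p)) cpp_store_set(st, nm, as.numeric(p), nrow(p), ncol(p),
                                    FALSE)
    else cpp_store_set(st, nm, as.numeric(p), length(p), 1L, TRUE)
  }
  model$store <- st
  model
}

detach_store <- function(model) {
  for (nm in trainable_names(model$params))
    model$params[[nm]] <- cpp_store_get(model$store, nm)
  model$store <- NULL
  model
}

as_batch_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x), 1L))
  stopifnot(length(dim(x)) == 4)
  x
}

#' Run the generator forward
#'
#' @param model A `sigan_generator` from [build_generator()].
#' @param x Input sinogram: matrix or `(1, H, W, B)` array with H, W
#'   divisible by `2^depth`.
#' @param train Training mode (dropout/noise active, running statistics
#'   updated).
#' @param return_logits Return the pre-sigmoid output.
#' @param batch_stats Normalise with the statistics of the current batch
#'   rather than the running averages (the image-to-image cGAN convention,
#'   also used at inference; default follows `train`).
#' @return List with `out` (same shape as `x`), a backward `cache` and
#'   updated batch-norm running statistics (`updates`).
#' @export
generator_forward <- function(model, x, train = FALSE,
                              return_logits = FALSE, batch_stats = train) {
  spec <- model$spec
  p <- model$params
  st <- model$store
  x <- as_batch_array(x)
  d <- spec$depth
  check_generator_size(spec, dim(x)[2:3])
  stopifnot(dim(x)[1] == 1)
  layout <- model$layout
  cache <- list(enc_in = vector("list", d), enc_z = vector("list", d),
                enc_bn = vector("list", d), enc_out = vector("list", d),
                dec_in = vector("list", d), dec_z = vector("list", d),
                dec_bn = vector("list", d), dec_mask = vector("list", d))
  updates <- list()
  h <- x
  for (i in seq_len(d)) {
    nm <- paste0("enc", i)
    cache$enc_in[[i]] <- h
    z <- if (is.null(st))
      nn_conv_fwd(h, dim(h), p[[paste0(nm, "_W")]],
                  p[[paste0(nm, "_b")]], spec$kernel, spec$stride, 1L)
    else nn_conv_fwd_s(h, dim(h), st, paste0(nm, "_W"), paste0(nm, "_b"),
                       spec$kernel, spec$stride, 1L)
    if (layout$bn[i]) {
      bn <- bn_fwd(z, param_of(model, paste0(nm, "_g")),
                   param_of(model, paste0(nm, "_be")),
                   p[[paste0(nm, "_rm")]], p[[paste0(nm, "_rv")]],
                   batch_stats, update_running = train)
      z <- bn$y
      cache$enc_bn[[i]] <- bn$cache
      updates[[paste0(nm, "_rm")]] <- bn$run_mean
      updates[[paste0(nm, "_rv")]] <- bn$run_var
    }
    cache$enc_z[[i]] <- z
    h <- leaky_relu_fwd(z, spec$leaky_slope)
    cache$enc_out[[i]] <- h
  }
  u <- h
  if (spec$noise_mode == "channel" && train)
    u <- u + array(rnorm(length(u), 0, 0.1), dim(u))
  for (j in seq_len(d)) {
    r <- d + j
    nm <- paste0("dec", j)
    if (j > 1) u <- concat_channels(u, cache$enc_out[[d - j + 1]])
    cache$dec_in[[j]] <- u
    z <- if (is.null(st))
      nn_convt_fwd(u, dim(u), p[[paste0(nm, "_W")]],
                   p[[paste0(nm, "_b")]], spec$kernel, spec$stride, 1L)
    else nn_convt_fwd_s(u, dim(u), st, paste0(nm, "_W"), paste0(nm, "_b"),
                        spec$kernel, spec$stride, 1L)
    if (layout$bn[r]) {
      bn <- bn_fwd(z, param_of(model, paste0(nm, "_g")),
                   param_of(model, paste0(nm, "_be")),
                   p[[paste0(nm, "_rm")]], p[[paste0(nm, "_rv")]],
                   batch_stats, update_running = train)
      z <- bn$y
      cache$dec_bn[[j]] <- bn$cache
      updates[[paste0(nm, "_rm")]] <- bn$run_mean
      updates[[paste0(nm, "_rv")]] <- bn$run_var
    }
    if (layout$dropout[r] && train) {
      dr <- dropout_fwd(z)
      z <- dr$y
      cache$dec_mask[[j]] <- dr$mask
    }
    cache$dec_z[[j]] <- z
    u <- relu_fwd(z)
  }
  cache$out_in <- u
  o <- if (is.null(st)) nn_conv_fwd(u, dim(u), p$out_W, p$out_b, 1L, 1L, 0L)
       else nn_conv_fwd_s(u, dim(u), st, "out_W", "out_b", 1L, 1L, 0L)
  y <- sigmoid_fwd(o)
  cache$out_y <- y
  list(out = if (return_logits) o else y, cache = cache, updates = updates)
}

# Backward pass through the generator; `dout` is the gradient w.r.t. the
# sigmoid output. Returns named parameter gradients.
generator_backward <- function(model, cache, dout) {
  spec <- model$spec
  p <- model$params
  st <- model$store
  d <- spec$depth
  layout <- model$layout
  grads <- list()
  do <- sigmoid_bwd(cache$out_y, dout)
  if (is.null(st)) {
    bw <- nn_conv_bwd(cache$out_in, dim(cache$out_in), p$out_W, do,
                      1L, 1L, 0L, TRUE)
    grads$out_W <- bw$dW; grads$out_b <- bw$db
    du <- bw$dx
  } else {
    du <- nn_conv_bwd_s(cache$out_in, dim(cache$out_in), st, "out_W",
                        "out_b", do, 1L, 1L, 0L, TRUE, TRUE)
  }
  denc <- vector("list", d)  # gradients flowing into encoder outputs
  for (j in rev(seq_len(d))) {
    r <- d + j
    nm <- paste0("dec", j)
    dz <- relu_bwd(cache$dec_z[[j]], du)
    if (layout$dropout[r] && !is.null(cache$dec_mask[[j]]))
      dz <- dz * cache$dec_mask[[j]]
    if (layout$bn[r]) {
      bb <- bn_bwd(cache$dec_bn[[j]], dz)
      dz <- bb$dx
      if (is.null(st)) {
        grads[[paste0(nm, "_g")]] <- bb$dgamma
        grads[[paste0(nm, "_be")]] <- bb$dbeta
      } else {
        cpp_store_add_grad(st, paste0(nm, "_g"), bb$dgamma)
        cpp_store_add_grad(st, paste0(nm, "_be"), bb$dbeta)
      }
    }
    u_in <- cache$dec_in[[j]]
    if (is.null(st)) {
      bw <- nn_convt_bwd(u_in, dim(u_in), p[[paste0(nm, "_W")]], dz,
                         spec$kernel, spec$stride, 1L, TRUE)
      grads[[paste0(nm, "_W")]] <- bw$dW
      grads[[paste0(nm, "_b")]] <- bw$db
      dxj <- bw$dx
    } else {
      dxj <- nn_convt_bwd_s(u_in, dim(u_in), st, paste0(nm, "_W"),
                            paste0(nm, "_b"), dz, spec$kernel, spec$stride,
                            1L, TRUE)
    }
    if (j > 1) {
      c_prev <- dim(u_in)[1] - dim(cache$enc_out[[d - j + 1]])[1]
      sp <- split_channels(dxj, c_prev)
      du <- sp[[1]]
      k <- d - j + 1
      denc[[k]] <- if (is.null(denc[[k]])) sp[[2]] else denc[[k]] + sp[[2]]
    } else {
      denc[[d]] <- if (is.null(denc[[d]])) dxj else denc[[d]] + dxj
    }
  }
  dh <- NULL
  for (i in rev(seq_len(d))) {
    nm <- paste0("enc", i)
    dtot <- denc[[i]]
    if (!is.null(dh)) dtot <- if (is.null(dtot)) dh else dtot + dh
    dz <- leaky_relu_bwd(cache$enc_z[[i]], dtot, spec$leaky_slope)
    if (layout$bn[i]) {
      bb <- bn_bwd(cache$enc_bn[[i]], dz)
      dz <- bb$dx
      if (is.null(st)) {
        grads[[paste0(nm, "_g")]] <- bb$dgamma
        grads[[paste0(nm, "_be")]] <- bb$dbeta
      } else {
        cpp_store_add_grad(st, paste0(nm, "_g"), bb$dgamma)
        cpp_store_add_grad(st, paste0(nm, "_be"), bb$dbeta)
      }
    }
    h_in <- cache$enc_in[[i]]
    if (is.null(st)) {
      bw <- nn_conv_bwd(h_in, dim(h_in), p[[paste0(nm, "_W")]], dz,
                        spec$kernel, spec$stride, 1L, i > 1)
      grads[[paste0(nm, "_W")]] <- bw$dW
      grads[[paste0(nm, "_b")]] <- bw$db
      dh <- bw$dx
    } else {
      dh <- nn_conv_bwd_s(h_in, dim(h_in), st, paste0(nm, "_W"),
                          paste0(nm, "_b"), dz, spec$kernel, spec$stride,
                          1L, i > 1, TRUE)
    }
  }
  grads
}

#' Pair a conditioning and a candidate sinogram for the discriminator
#'
#' @param conditioning,candidate Arrays `(1, H, W, B)` or matrices of equal
#'   shape.
#' @return A `(2, H, W, B)` array.
#' @export
pair_input <- function(conditioning, candidate) {
  a <- as_batch_array(conditioning); b <- as_batch_array(candidate)
  if (!identical(dim(a), dim(b)))
    stop("conditioning and candidate sinogram shapes differ")
  concat_channels(a, b)
}

#' Run the patch discriminator forward
#'
#' @param model A `sigan_discriminator` from [build_discriminator()].
#' @param x A `(2, H, W, B)` array from [pair_input()].
#' @param train Training mode (batch statistics).
#' @return List with the patch probability map `out` (`(1, N1, N2, B)`,
#'   entries in (0, 1)), a backward `cache` and running-statistic `updates`.
#' @export
discriminator_forward <- function(model, x, train = FALSE) {
  spec <- model$spec
  p <- model$params
  st <- model$store
  layout <- model$layout
  stopifnot(length(dim(x)) == 4, dim(x)[1] == 2)
  n <- spec$layers
  cache <- list(lin = vector("list", n), z = vector("list", n),
                bn = vector("list", n))
  updates <- list()
  h <- x
  for (i in seq_len(n)) {
    nm <- paste0("d", i)
    cache$lin[[i]] <- h
    z <- if (is.null(st))
      nn_conv_fwd(h, dim(h), p[[paste0(nm, "_W")]],
                  p[[paste0(nm, "_b")]], spec$kernel, spec$strides[i], 1L)
    else nn_conv_fwd_s(h, dim(h), st, paste0(nm, "_W"), paste0(nm, "_b"),
                       spec$kernel, spec$strides[i], 1L)
    if (layout$bn[i]) {
      bn <- bn_fwd(z, param_of(model, paste0(nm, "_g")),
                   param_of(model, paste0(nm, "_be")),
                   p[[paste0(nm, "_rm")]], p[[paste0(nm, "_rv")]], train)
      z <- bn$y
      cache$bn[[i]] <- bn$cache
      updates[[paste0(nm, "_rm")]] <- bn$run_mean
      updates[[paste0(nm, "_rv")]] <- bn$run_var
    }
    cache$z[[i]] <- z
    h <- if (i < n) relu_fwd(z) else sigmoid_fwd(z)
  }
  cache$out <- h
  list(out = h, cache = cache, updates = updates)
}

discriminator_backward <- function(model, cache, dout, want_dx = FALSE,
                                   want_dw = TRUE) {
  spec <- model$spec
  p <- model$params
  st <- model$store
  layout <- model$layout
  n <- spec$layers
  grads <- list()
  dh <- dout
  for (i in rev(seq_len(n))) {
    nm <- paste0("d", i)
    dz <- if (i < n) relu_bwd(cache$z[[i]], dh)
          else sigmoid_bwd(cache$out, dh)
    if (layout$bn[i]) {
      bb <- bn_bwd(cache$bn[[i]], dz)
      dz <- bb$dx
      if (want_dw) {
        if (is.null(st)) {
          grads[[paste0(nm, "_g")]] <- bb$dgamma
          grads[[paste0(nm, "_be")]] <- bb$dbeta
        } else {
          cpp_store_add_grad(st, paste0(nm, "_g"), bb$dgamma)
          cpp_store_add_grad(st, paste0(nm, "_be"), bb$dbeta)
        }
      }
    }
    h_in <- cache$lin[[i]]
    if (is.null(st)) {
      bw <- nn_conv_bwd(h_in, dim(h_in), p[[paste0(nm, "_W")]], dz,
                        spec$kernel, spec$strides[i], 1L,
                        i > 1 || want_dx, want_dw)
      if (want_dw) {
        grads[[paste0(nm, "_W")]] <- bw$dW
        grads[[paste0(nm, "_b")]] <- bw$db
      }
      dh <- bw$dx
    } else {
      dh <- nn_conv_bwd_s(h_in, dim(h_in), st, paste0(nm, "_W"),
                          paste0(nm, "_b"), dz, spec$kernel,
                          spec$strides[i], 1L, i > 1 || want_dx, want_dw)
    }
  }
  list(grads = grads, dx = if (want_dx) dh else NULL)
}

#' Average patch probability
#'
#' The discriminator's decision: the arithmetic mean of all per-patch
#' real/fake probabilities.
#'
#' @param patch_map Numeric array/matrix of patch probabilities (non-empty).
#' @return Scalar probability.
#' @export
discriminator_decision <- function(patch_map) {
  if (length(patch_map) == 0) stop("empty patch map")
  mean(patch_map)
}

#' Count trainable parameters
#'
#' Exact per-layer ledger of trainable scalars (convolution weights, biases,
#' batch-norm scales/shifts) for a network spec or a built model. At full
#' scale the printed layer table is reproduced and the total is logged so it
#' can be compared with the published headline parameter count; any
#' discrepancy from unstated bias/normalisation choices is visible per layer
#' rather than forced to agree.
#'
#' @param x A [generator_spec()], [discriminator_spec()], built model, or a
#'   list of several of these (e.g. `list(generator, discriminator)`).
#' @return A data.frame of class `model_params` with one row per layer
#'   (columns `name`, `op`, `c_in`, `c_out`, `kernel`, `n_weights`,
#'   `n_bias`, `n_bn`, `n_total`) and attribute `total`.
#' @export
count_parameters <- function(x) {
  layout <- if (inherits(x, "generator_spec")) generator_layout(x)
    else if (inherits(x, "discriminator_spec")) discriminator_layout(x)
    else if (inherits(x, c("sigan_generator", "sigan_discriminator")))
      x$layout
    else if (is.list(x) && !is.null(x$generator) && !is.null(x$discriminator))
      return(count_parameters(list(x$generator, x$discriminator)))
    else if (is.list(x)) {
      tabs <- lapply(x, count_parameters)
      out <- do.call(rbind, tabs)
      attr(out, "total") <- sum(vapply(tabs, attr, numeric(1), "total"))
      class(out) <- c("model_params", "data.frame")
      return(out)
    } else stop("cannot count parameters of ", class(x)[1])
  n_w <- layout$c_in * layout$c_out * layout$kernel^2
  n_b <- layout$c_out
  n_bn <- ifelse(layout$bn, 2L * layout$c_out, 0L)
  out <- data.frame(name = layout$name, op = layout$op,
                    c_in = layout$c_in, c_out = layout$c_out,
                    kernel = layout$kernel,
                    n_weights = n_w, n_bias = n_b, n_bn = n_bn,
                    n_total = n_w + n_b + n_bn)
  attr(out, "total") <- sum(out$n_total)
  class(out) <- c("model_params", "data.frame")
  out
}

#' @export
print.model_params <- function(x, ...) {
  print.data.frame(x, ...)
  cat("total trainable parameters:", format(attr(x, "total"), big.mark = ","),
      "\n")
  invisible(x)
}
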