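# Layer primitives for the inpainting networks. Tensors are R arrays with
# dim (C, H, W, B); convolutions run through the compiled im2col/GEMM kernels.

leaky_relu_fwd <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_bwd <- function(x, dy, slope) dy * ifelse(x > 0, 1, slope)
relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)
sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(y, dy) dy * y * (1 - y)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch norm over (H, W, B) per channel. `batch_stats` selects the current
# batch's statistics (training, and the cGAN-style inference convention)
# versus the running averages; the running averages advance only when
# `update_running` (a training step). Returns y, a backward cache and the
# updated running statistics.
bn_fwd <- function(x, gamma, beta, run_mean, run_var, batch_stats,
                   update_running = batch_stats) {
  d <- dim(x); C <- d[1]; N <- prod(d[-1])
  xm <- matrix(x, C, N)
  if (batch_stats) {
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m * m
    v <- pmax(v, 0)
    if (update_running) {
      run_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * m
      run_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
    }
  } else {
    m <- run_mean; v <- run_var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - m) * ivar
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y,
       cache = if (update_running) list(xhat = xhat, ivar = ivar,
                                        gamma = gamma, dims = d) else NULL,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(cache, dy) {
  d <- cache$dims; C <- d[1]; N <- prod(d[-1])
  dym <- matrix(dy, C, N)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * cache$gamma
  dx <- cache$ivar *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(x, rate = 0.5) {
  mask <- (array(runif(length(x)), dim(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

# Channel concatenation of two (C, H, W, B) arrays (C is the fastest dim, so
# this is a per-column rbind).
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  out <- rbind(matrix(a, da[1], prod(da[-1])),
               matrix(b, db[1], prod(db[-1])))
  dim(out) <- c(da[1] + db[1], da[2], da[3], da[4])
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  m <- matrix(x, d[1], prod(d[-1]))
  a <- m[seq_len(c1), , drop = FALSE]
  b <- m[-seq_len(c1), , drop = FALSE]
  dim(a) <- c(c1, d[2], d[3], d[4])
  dim(b) <- c(d[1] - c1, d[2], d[3], d[4])
  list(a, b)
}

init_conv_w <- function(c_out_rows, c_cols, sd = 0.02) {
  matrix(rnorm(c_out_rows * c_cols, 0, sd), c_out_rows, c_cols)
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
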