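# Conv-net building blocks over the compiled kernels. Parameters live in a
# flat named list of arrays so the Adam state can mirror the structure.

conv_fwd <- function(x, W, b, stride = 1L, pad = 1L)
  .cpp_conv2d_fwd(x, W, b, as.integer(stride), as.integer(pad))

conv_bwd <- function(x, W, dy, stride = 1L, pad = 1L)
  .cpp_conv2d_bwd(x, W, dy, as.integer(stride), as.integer(pad))

lrelu <- function(x, alpha = 0.2) { x[x < 0] <- alpha * x[x < 0]; x }
lrelu_bwd <- function(dy, x, alpha = 0.2) { dy[x < 0] <- alpha * dy[x < 0]; dy }

# He-scaled Gaussian initialization for a (k, k, Cin, Cout) kernel.
init_conv <- function(k, cin, cout) {
  list(W = array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout)),
       b = numeric(cout))
}

gen_channels <- function(depth, base) base * 2^(seq_len(depth) - 1L)

#' Generator architecture specification
#'
#' A U-Net: `depth` encoder levels (3x3 conv + leaky ReLU + 2x2 max pool), a
#' bottleneck conv, and mirrored decoder levels (nearest-neighbour upsample,
#' skip concatenation, 3x3 conv + ReLU) with dropout in every decoder block
#' except the finest. Two input channels (T1-w, non-fs T2-w), one tanh output
#' channel in `[-1, 1]`; output shape equals input shape.
#'
#' @param depth Number of down/up-sampling levels.
#' @param base_channels Channels at the finest level (doubled per level).
#' @param dropout_rate Dropout probability in the coarse decoder blocks.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(depth = 3L, base_channels = 16L, dropout_rate = 0.5) {
  stopifnot(depth >= 1L, base_channels >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, in_channels = 2L),
            class = "generator_spec")
}

#' Patch discriminator specification
#'
#' Strided 3x3 conv blocks (leaky ReLU) over the channel concatenation of the
#' conditioning inputs (T1, T2) and the candidate T2fs, followed by a 1-channel
#' conv producing a grid of per-patch real/synthetic logits.
#'
#' @param n_blocks Number of stride-2 blocks.
#' @param base_channels Channels of the first block (doubled per block).
#' @return A list of class `discriminator_spec`.
#' @export
discriminator_spec <- function(n_blocks = 3L, base_channels = 16L) {
  stopifnot(n_blocks >= 1L, base_channels >= 1L)
  structure(list(n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels), in_channels = 3L),
            class = "discriminator_spec")
}

init_generator <- function(spec, seed) {
  with_seed_(seed, {
    ch <- gen_channels(spec$depth, spec$base_channels)
    p <- list()
    cin <- spec$in_channels
    for (i in seq_len(spec$depth)) {
      p[[paste0("enc", i)]] <- init_conv(3L, cin, ch[i])
      cin <- ch[i]
    }
    p[["bott"]] <- init_conv(3L, cin, 2L * cin)
    for (i in rev(seq_len(spec$depth)))
      p[[paste0("dec", i)]] <- init_conv(3L, 3L * ch[i], ch[i])
    p[["out"]] <- init_conv(3L, ch[1], 1L)
    p
  })
}

init_discriminator <- function(spec, seed) {
  with_seed_(seed, {
    p <- list()
    cin <- spec$in_channels
    ch <- spec$base_channels * 2^(seq_len(spec$n_blocks) - 1L)
    for (i in seq_len(spec$n_blocks)) {
      p[[paste0("blk", i)]] <- init_conv(3L, cin, ch[i])
      cin <- ch[i]
    }
    p[["out"]] <- init_conv(3L, cin, 1L)
    p
  })
}

# Generator forward pass. Returns the output and (optionally) the cache
# needed for backprop. Dropout masks are drawn from the current RNG stream.
gen_forward <- function(params, spec, x, training = FALSE, keep_cache = training,
                        use_dropout = training) {
  d <- spec$depth
  cache <- list(x = x, skip = vector("list", d), pre = vector("list", d),
                arg = vector("list", d), drop = vector("list", d))
  h <- x
  for (i in seq_len(d)) {
    z <- conv_fwd(h, params[[paste0("enc", i)]]$W, params[[paste0("enc", i)]]$b)
    cache$pre[[i]] <- z
    a <- lrelu(z)
    cache$skip[[i]] <- a
    mp <- .cpp_maxpool2_fwd(a)
    cache$arg[[i]] <- mp$argmax
    cache[[paste0("pool_in_dim", i)]] <- dim(a)
    h <- mp$y
  }
  zb <- conv_fwd(h, params$bott$W, params$bott$b)
  cache$bott_in <- h; cache$bott_pre <- zb
  h <- lrelu(zb)
  for (i in rev(seq_len(d))) {
    u <- .cpp_upsample2_fwd(h)
    cc <- c_concat(u, cache$skip[[i]])
    z <- conv_fwd(cc, params[[paste0("dec", i)]]$W, params[[paste0("dec", i)]]$b)
    a <- lrelu(z, 0)
    if (use_dropout && spec$dropout_rate > 0 && i > 1L) {
      keep <- 1 - spec$dropout_rate
      mask <- array((runif(length(a)) < keep) / keep, dim = dim(a))
      a <- a * mask
      cache$drop[[i]] <- mask
    }
    cache[[paste0("dec_in", i)]] <- cc
    cache[[paste0("dec_pre", i)]] <- z
    cache[[paste0("up_in_ch", i)]] <- dim(u)[3]
    h <- a
  }
  zo <- conv_fwd(h, params$out$W, params$out$b)
  y <- tanh(zo)
  cache$out_in <- h; cache$y <- y
  list(y = y, cache = if (keep_cache) cache else NULL)
}

c_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Backprop through the generator; returns parameter gradients.
gen_backward <- function(params, spec, cache, dy) {
  d <- spec$depth
  grads <- list()
  dz <- dy * (1 - cache$y^2) # tanh'
  bw <- conv_bwd(cache$out_in, params$out$W, dz)
  grads$out <- list(W = bw$dw, b = bw$db)
  dh <- bw$dx
  dskip <- vector("list", d)
  for (i in seq_len(d)) {
    if (!is.null(cache$drop[[i]])) dh <- dh * cache$drop[[i]]
    dz <- lrelu_bwd(dh, cache[[paste0("dec_pre", i)]], 0)
    bw <- conv_bwd(cache[[paste0("dec_in", i)]], params[[paste0("dec", i)]]$W, dz)
    grads[[paste0("dec", i)]] <- list(W = bw$dw, b = bw$db)
    ncu <- cache[[paste0("up_in_ch", i)]]
    du <- bw$dx[, , seq_len(ncu), , drop = FALSE]
    dskip[[i]] <- bw$dx[, , ncu + seq_len(dim(bw$dx)[3] - ncu), , drop = FALSE]
    dh <- .cpp_upsample2_bwd(du)
  }
  dz <- lrelu_bwd(dh, cache$bott_pre)
  bw <- conv_bwd(cache$bott_in, params$bott$W, dz)
  grads$bott <- list(W = bw$dw, b = bw$db)
  dh <- bw$dx
  for (i in rev(seq_len(d))) {
    da <- .cpp_maxpool2_bwd(dh, cache$arg[[i]], cache[[paste0("pool_in_dim", i)]])
    da <- da + dskip[[i]]
    dz <- lrelu_bwd(da, cache$pre[[i]])
    x_in <- if (i == 1L) cache$x else cache$skip[[i - 1L]]
    if (i > 1L) {
      # encoder input i is the pooled activation of level i-1
      x_in <- .cpp_maxpool2_fwd(cache$skip[[i - 1L]])$y
    }
    bw <- conv_bwd(x_in, params[[paste0("enc", i)]]$W, dz)
    grads[[paste0("enc", i)]] <- list(W = bw$dw, b = bw$db)
    dh <- bw$dx
  }
  grads
}

disc_forward <- function(params, spec, x, keep_cache = FALSE) {
  cache <- list(ins = list(), pres = list())
  h <- x
  for (i in seq_len(spec$n_blocks)) {
    cache$ins[[i]] <- h
    z <- conv_fwd(h, params[[paste0("blk", i)]]$W, params[[paste0("blk", i)]]$b,
                  stride = 2L)
    cache$pres[[i]] <- z
    h <- lrelu(z)
  }
  cache$out_in <- h
  logits <- conv_fwd(h, params$out$W, params$out$b)
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

disc_backward <- function(params, spec, cache, dlogits) {
  grads <- list()
  bw <- conv_bwd(cache$out_in, params$out$W, dlogits)
  grads$out <- list(W = bw$dw, b = bw$db)
  dh <- bw$dx
  for (i in rev(seq_len(spec$n_blocks))) {
    dz <- lrelu_bwd(dh, cache$pres[[i]])
    bw <- conv_bwd(cache$ins[[i]], params[[paste0("blk", i)]]$W, dz, stride = 2L)
    grads[[paste0("blk", i)]] <- list(W = bw$dw, b = bw$db)
    dh <- bw$dx
  }
  list(grads = grads, dx = dh)
}

# --- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  zero_like <- function(p) lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.5, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    for (fld in names(params[[nm]])) {
      g <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- b1 * state$m[[nm]][[fld]] + (1 - b1) * g
      state$v[[nm]][[fld]] <- b2 * state$v[[nm]][[fld]] + (1 - b2) * g^2
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * (state$m[[nm]][[fld]] / c1) /
          (sqrt(state$v[[nm]][[fld]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}
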