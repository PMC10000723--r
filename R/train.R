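#' Training configuration
#'
#' Defaults follow the method's stated optimization protocol — joint loss
#' weight `lambda_adv = 50`, Adam with learning rate `2e-4`, 25 epochs,
#' slices revisited in a fresh random order each epoch — with desk-scale
#' architecture sizes (see [generator_spec()]).
#'
#' @param lambda_adv Weight of the adversarial loss term.
#' @param learning_rate Adam learning rate for both networks.
#' @param epochs Number of passes over the training slices.
#' @param batch_size Slices per update.
#' @param betas Adam moment decay rates.
#' @param seed Integer seed; all training randomness derives from it.
#' @param generator [generator_spec()].
#' @param discriminator [discriminator_spec()].
#' @param augmentation Augmentation parameters, see [default_augmentation()];
#'   set `flip_prob = 0` etc. to disable individual transforms.
#' @param use_augmentation Logical; apply augmentations during training.
#' @param ssim SSIM parameters for the loss, see [ssim_params()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda_adv = 50, learning_rate = 2e-4, epochs = 25L,
                         batch_size = 8L, betas = c(0.5, 0.999), seed = 1L,
                         generator = generator_spec(),
                         discriminator = discriminator_spec(),
                         augmentation = default_augmentation(),
                         use_augmentation = TRUE,
                         ssim = ssim_params()) {
  stopifnot(lambda_adv > 0, epochs >= 1L, learning_rate > 0, batch_size >= 1L)
  structure(list(lambda_adv = lambda_adv, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 betas = betas, seed = as.integer(seed), generator = generator,
                 discriminator = discriminator, augmentation = augmentation,
                 use_augmentation = isTRUE(use_augmentation), ssim = ssim),
            class = "train_config")
}

# Stack slice matrices (possibly padded to a multiple of 2^depth) into a
# (H, W, C, N) batch array.
pad_to_multiple <- function(m, mult) {
  H <- nrow(m); W <- ncol(m)
  Hp <- ceiling(H / mult) * mult; Wp <- ceiling(W / mult) * mult
  if (Hp == H && Wp == W) return(m)
  # reflective padding on the bottom/right
  ri <- c(seq_len(H), H - seq_len(Hp - H))
  ci <- c(seq_len(W), W - seq_len(Wp - W))
  m[ri, ci, drop = FALSE]
}

batch_arrays <- function(records, mult) {
  t1 <- lapply(records, function(r) pad_to_multiple(r$t1, mult))
  t2 <- lapply(records, function(r) pad_to_multiple(r$t2, mult))
  fs <- lapply(records, function(r) if (is.null(r$t2fs)) NULL
               else pad_to_multiple(r$t2fs, mult))
  H <- nrow(t1[[1]]); W <- ncol(t1[[1]]); N <- length(records)
  x <- array(0, dim = c(H, W, 2L, N))
  y <- if (is.null(fs[[1]])) NULL else array(0, dim = c(H, W, 1L, N))
  for (n in seq_len(N)) {
    x[, , 1L, n] <- t1[[n]]
    x[, , 2L, n] <- t2[[n]]
    if (!is.null(y)) y[, , 1L, n] <- fs[[n]]
  }
  list(x = x, y = y, orig = c(nrow(records[[1]]$t1), ncol(records[[1]]$t1)))
}

dataset_records <- function(dataset) {
  lapply(seq_len(nrow(dataset)), function(i)
    list(t1 = dataset$t1[[i]], t2 = dataset$t2[[i]], t2fs = dataset$t2fs[[i]]))
}

#' Train the generator/discriminator pair
#'
#' Alternating adversarial training: per batch, one discriminator update
#' (BCE on real vs synthetic patches, conditioned on the inputs by channel
#' concatenation) followed by one generator update on the joint loss
#' `(1 - SSIM) + lambda_adv * BCE(1, D(synthetic))`. Slices are visited in a
#' seed-determined random order redrawn every epoch. Fully deterministic
#' given the config seed (single-threaded).
#'
#' @param dataset A `paired_slice_dataset` with non-empty `t2fs` targets.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list with `checkpoint` (class `gan_checkpoint`: generator and
#'   discriminator parameters, specs, config, seed) and `history` (tibble of
#'   per-epoch mean losses and term decomposition, one row per epoch).
#' @export
train <- function(dataset, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "paired_slice_dataset"))
  if (nrow(dataset) == 0L) abort("training dataset is empty")
  records <- dataset_records(dataset)
  if (any(vapply(records, function(r) is.null(r$t2fs), logical(1))))
    abort("every training record needs a T2fs target slice")

  gspec <- config$generator; dspec <- config$discriminator
  mult <- 2L^gspec$depth
  gp <- init_generator(gspec, derive_seed(config$seed, "init-g"))
  dp <- init_discriminator(dspec, derive_seed(config$seed, "init-d"))
  g_adam <- adam_state(gp); d_adam <- adam_state(dp)
  wts <- ssim_window_weights(config$ssim)

  hist <- vector("list", config$epochs)
  n <- length(records)
  g_updates <- 0L

  for (epoch in seq_len(config$epochs)) {
    ep_seed <- derive_seed(config$seed, "epoch", epoch)
    order <- with_seed_(ep_seed, sample.int(n))
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    ep <- c(g = 0, ssim_term = 0, adv = 0, d = 0); nb <- 0L

    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      recs <- records[idx]
      if (config$use_augmentation)
        recs <- lapply(seq_along(recs), function(j)
          augment(recs[[j]], config$augmentation,
                  seed = derive_seed(ep_seed, "aug", idx[j])))
      ba <- batch_arrays(recs, mult)
      N <- length(idx)

      # generator forward (dropout active), seeded per batch
      gfw <- with_seed_(derive_seed(ep_seed, "dropout", bi),
                        gen_forward(gp, gspec, ba$x, training = TRUE))
      synth <- gfw$y

      # ---- discriminator update ----
      d_in_real <- c_concat(ba$x, ba$y)
      d_in_fake <- c_concat(ba$x, synth)
      fr <- disc_forward(dp, dspec, d_in_real, keep_cache = TRUE)
      ff <- disc_forward(dp, dspec, d_in_fake, keep_cache = TRUE)
      d_loss <- bce_logits_target1(fr$logits) + bce_logits_target0(ff$logits)
      if (!is.finite(d_loss)) abort("discriminator loss diverged (non-finite)")
      Pr <- length(fr$logits)
      dr <- (sigmoid(fr$logits) - 1) / Pr
      dfk <- sigmoid(ff$logits) / Pr
      gr <- disc_backward(dp, dspec, fr$cache, dr)$grads
      gf <- disc_backward(dp, dspec, ff$cache, dfk)$grads
      gsum <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                     gr, gf, SIMPLIFY = FALSE)
      upd <- adam_step(dp, gsum, d_adam, config$learning_rate, config$betas)
      dp <- upd$params; d_adam <- upd$state

      # ---- generator update ----
      ff2 <- disc_forward(dp, dspec, d_in_fake, keep_cache = TRUE)
      adv_loss <- bce_logits_target0(-ff2$logits) # BCE(1, sigmoid(z))
      P2 <- length(ff2$logits)
      dlog <- config$lambda_adv * (sigmoid(ff2$logits) - 1) / P2
      d_syn_adv <- disc_backward(dp, dspec, ff2$cache, dlog)$dx
      d_syn_adv <- d_syn_adv[, , 3L, , drop = FALSE] # candidate channel only

      ssim_vals <- numeric(N)
      d_syn_ssim <- array(0, dim = dim(synth))
      for (k in seq_len(N)) {
        sg <- ssim_with_grad(matrix(synth[, , 1L, k], dim(synth)[1]),
                             matrix(ba$y[, , 1L, k], dim(synth)[1]),
                             config$ssim, wts)
        ssim_vals[k] <- sg$value
        d_syn_ssim[, , 1L, k] <- -sg$grad / N # d(1 - mean SSIM)/dsynth
      }
      d_syn <- d_syn_ssim + d_syn_adv
      g_loss <- (1 - mean(ssim_vals)) + config$lambda_adv * adv_loss
      if (!is.finite(g_loss)) abort("generator loss diverged (non-finite)")
      ggr <- gen_backward(gp, gspec, gfw$cache, d_syn)
      upd <- adam_step(gp, ggr, g_adam, config$learning_rate, config$betas)
      gp <- upd$params; g_adam <- upd$state
      g_updates <- g_updates + 1L

      ep <- ep + c(g_loss, 1 - mean(ssim_vals),
                   config$lambda_adv * adv_loss, d_loss)
      nb <- nb + 1L
    }
    ep <- ep / nb
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, g_loss = ep[["g"]], g_ssim_term = ep[["ssim_term"]],
      g_adv_term = ep[["adv"]], d_loss = ep[["d"]]
    )
    if (verbose)
      message(sprintf("epoch %02d  G %.4f (ssim %.4f, adv %.4f)  D %.4f",
                      epoch, ep[["g"]], ep[["ssim_term"]], ep[["adv"]], ep[["d"]]))
  }

  history <- dplyr::bind_rows(hist)
  checkpoint <- structure(
    list(generator = gp, discriminator = dp, generator_spec = gspec,
         discriminator_spec = dspec, config = config, seed = config$seed,
         g_updates = g_updates, epochs_trained = config$epochs),
    class = "gan_checkpoint"
  )
  list(checkpoint = checkpoint, history = history)
}

#' @export
print.gan_checkpoint <- function(x, ...) {
  cat(sprintf("<gan_checkpoint  depth %d  base %d  %d epochs  seed %d>\n",
              x$generator_spec$depth, x$generator_spec$base_channels,
              x$epochs_trained, x$seed))
  invisible(x)
}

#' Save or load a generator checkpoint
#'
#' Checkpoints are self-describing: architecture specs, both networks'
#' weights, the full training config and seed travel together.
#'
#' @param checkpoint A `gan_checkpoint`.
#' @param path File path (`.rds`).
#' @return `load_checkpoint()` returns the checkpoint; `save_checkpoint()`
#'   its path, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path),
                 error = function(e) abort("file does not hold a gan_checkpoint"))
  if (!inherits(ck, "gan_checkpoint")) abort("file does not hold a gan_checkpoint")
  ck
}

#' Plot a training loss history
#'
#' @param history The `history` tibble returned by [train()].
#' @return A ggplot of the loss terms over epochs.
#' @export
plot_training_history <- function(history) {
  long <- tidyr::pivot_longer(history, -"epoch",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
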