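#' Joint generator loss: structural dissimilarity plus adversarial term
#'
#' `(1 - SSIM(real, synthetic)) + lambda_adv * BCE(1, d_scores)`, the
#' adversarial binary cross-entropy averaged over the discriminator's patch
#' grid. The loss is 0 exactly when the synthetic image reproduces the real
#' one and the discriminator scores every patch as real.
#'
#' @param real,synthetic Image matrices in `[-1, 1]`, identical shape.
#' @param d_scores Patch grid of discriminator scores in `(0, 1)`.
#' @param lambda_adv Weight of the adversarial term (default 50).
#' @param params SSIM parameters, see [ssim_params()].
#' @return Scalar loss with attributes `ssim_term` and `adv_term`.
#' @export
#' @examples
#' x <- matrix(runif(144, -1, 1), 12)
#' generator_loss(x, x, matrix(1, 2, 2), lambda_adv = 50)
generator_loss <- function(real, synthetic, d_scores, lambda_adv = 50,
                           params = ssim_params()) {
  if (!all(is.finite(d_scores))) abort("discriminator scores must be finite")
  if (any(d_scores <= 0) || any(d_scores >= 1))
    abort("discriminator scores must lie strictly in (0, 1)")
  s <- ssim(real, synthetic, params)
  adv <- mean(-log(d_scores))
  structure((1 - s) + lambda_adv * adv,
            ssim_term = 1 - s, adv_term = lambda_adv * adv)
}

#' Discriminator loss
#'
#' Patch-averaged `BCE(1, scores_real) + BCE(0, scores_synth)`: the
#' discriminator is pushed to score real patches towards 1 and synthetic
#' patches towards 0.
#'
#' @param scores_real,scores_synth Patch grids of scores in `(0, 1)`.
#' @return Non-negative scalar.
#' @export
discriminator_loss <- function(scores_real, scores_synth) {
  if (!all(is.finite(scores_real)) || !all(is.finite(scores_synth)))
    abort("discriminator scores must be finite")
  if (any(scores_real <= 0) || any(scores_real >= 1) ||
      any(scores_synth <= 0) || any(scores_synth >= 1))
    abort("discriminator scores must lie strictly in (0, 1)")
  mean(-log(scores_real)) + mean(-log(1 - scores_synth))
}

# Numerically stable logit-space BCE used inside the training loop.
# softplus(x) = log(1 + exp(x)) without overflow.
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

bce_logits_target1 <- function(z) mean(softplus(-z)) # -log(sigmoid(z))
bce_logits_target0 <- function(z) mean(softplus(z))  # -log(1 - sigmoid(z))

#' Apply training augmentations to a paired slice record
#'
#' Spatial augmentations (horizontal flip, small rotation) are applied
#' identically to the input channels and the target; intensity augmentations
#' (Gaussian smoothing, additive noise) are applied to the input channels
#' only, emulating acquisition variability the target is not subject to.
#' Deterministic given `seed`.
#'
#' @param record List with matrices `t1`, `t2` and optionally `t2fs`.
#' @param params List with `flip_prob`, `rotation_range` (deg, <= 15),
#'   `smooth_sigma_range`, `noise_sd_range`.
#' @param seed Integer seed.
#' @return The augmented record.
#' @export
augment <- function(record, params = default_augmentation(), seed = 0L) {
  stopifnot(is.list(record), is.matrix(record$t1), is.matrix(record$t2))
  if (params$rotation_range > 15)
    abort("rotation_range outside the configured limit of 15 degrees")
  with_seed_(derive_seed(seed, "augment"), {
    do_flip <- runif(1) < params$flip_prob
    ang <- runif(1, -params$rotation_range, params$rotation_range)
    sig <- runif(1, params$smooth_sigma_range[1], params$smooth_sigma_range[2])
    nsd <- runif(1, params$noise_sd_range[1], params$noise_sd_range[2])
    spatial <- function(m) {
      if (is.null(m)) return(NULL)
      if (do_flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
      if (abs(ang) > 1e-12)
        m <- apply_rigid_2d(m, rigid_transform_2d(ang, c(0, 0)), fill = -1)
      m
    }
    intensity <- function(m) {
      m <- blur_matrix(m, sig)
      if (nsd > 0) m <- m + matrix(rnorm(length(m), sd = nsd), nrow(m))
      m
    }
    out <- record
    out$t1 <- intensity(spatial(record$t1))
    out$t2 <- intensity(spatial(record$t2))
    out$t2fs <- spatial(record$t2fs)
    out
  })
}

#' @rdname augment
#' @export
default_augmentation <- function() {
  list(flip_prob = 0.5, rotation_range = 5, smooth_sigma_range = c(0, 0.8),
       noise_sd_range = c(0, 0.03))
}
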