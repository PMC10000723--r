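#' Structural similarity (SSIM) parameters
#'
#' Standard windowed SSIM constants: an 11x11 Gaussian window (sd 1.5) and
#' stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is the dynamic
#' range — 2 for images scaled to `[-1, 1]`.
#'
#' @param window Odd window size in pixels.
#' @param sigma Gaussian window standard deviation; `Inf` gives a uniform
#'   window.
#' @param L Dynamic range of the images.
#' @return A list of class `ssim_params`.
#' @export
ssim_params <- function(window = 11L, sigma = 1.5, L = 2) {
  stopifnot(window >= 3L, window %% 2L == 1L, L > 0)
  structure(list(window = as.integer(window), sigma = sigma, L = L,
                 C1 = (0.01 * L)^2, C2 = (0.03 * L)^2),
            class = "ssim_params")
}

ssim_window_weights <- function(params) {
  k <- params$window
  if (is.finite(params$sigma)) {
    g <- gaussian_kernel_1d(params$sigma, radius = (k - 1L) / 2L)
    w <- outer(g, g)
  } else {
    w <- matrix(1 / k^2, k, k)
  }
  array(w / sum(w), dim = c(k, k, 1L, 1L))
}

ssim_filter <- function(m, wts) {
  y <- .cpp_conv2d_fwd(array(m, dim = c(dim(m), 1L, 1L)), wts, 0, 1L, 0L)
  matrix(y, dim(y)[1], dim(y)[2])
}

ssim_filter_adjoint <- function(dmap, wts, in_dim) {
  x0 <- array(0, dim = c(in_dim, 1L, 1L))
  g <- .cpp_conv2d_bwd(x0, wts, array(dmap, dim = c(dim(dmap), 1L, 1L)), 1L, 0L)$dx
  matrix(g, in_dim[1], in_dim[2])
}

ssim_components <- function(a, b, params, wts) {
  mu_a <- ssim_filter(a, wts); mu_b <- ssim_filter(b, wts)
  m2a <- ssim_filter(a * a, wts); m2b <- ssim_filter(b * b, wts)
  mab <- ssim_filter(a * b, wts)
  va <- m2a - mu_a^2; vb <- m2b - mu_b^2; cab <- mab - mu_a * mu_b
  A1 <- 2 * mu_a * mu_b + params$C1
  A2 <- 2 * cab + params$C2
  B1 <- mu_a^2 + mu_b^2 + params$C1
  B2 <- va + vb + params$C2
  list(mu_a = mu_a, mu_b = mu_b, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       map = (A1 * A2) / (B1 * B2))
}

#' Structural similarity index between two images
#'
#' Mean local SSIM over sliding windows (valid positions only), the metric
#' the generator loss is built on. Symmetric in its arguments and equal to 1
#' iff the images agree on every window.
#'
#' @param a,b Numeric matrices of identical shape, at least as large as the
#'   window.
#' @param params An [ssim_params()] object.
#' @return A scalar in `[-1, 1]`.
#' @export
#' @examples
#' x <- matrix(rnorm(24 * 24), 24)
#' ssim(x, x) # exactly 1
ssim <- function(a, b, params = ssim_params()) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    abort("`a` and `b` must be matrices of identical shape")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    abort("SSIM inputs must be finite")
  if (any(dim(a) < params$window))
    abort("images smaller than the SSIM window")
  wts <- ssim_window_weights(params)
  mean(ssim_components(a, b, params, wts)$map)
}

# SSIM value plus its gradient with respect to `a` (the synthetic image).
# Chain rule through the three filtered moments of `a`; the adjoint of valid
# filtering scatters window-level gradients back to pixels.
ssim_with_grad <- function(a, b, params = ssim_params(), wts = NULL) {
  wts <- wts %||% ssim_window_weights(params)
  cm <- ssim_components(a, b, params, wts)
  P <- length(cm$map)
  S <- cm$map
  inv_BB <- 1 / (cm$B1 * cm$B2)
  # partials wrt mu_a, filt(a^2) and filt(ab)
  d_mu <- 2 * cm$mu_b * cm$A2 * inv_BB - 2 * cm$mu_b * cm$A1 * inv_BB -
    2 * cm$mu_a * S / cm$B1 + 2 * cm$mu_a * S / cm$B2
  d_m2 <- -S / cm$B2
  d_mab <- 2 * cm$A1 * inv_BB
  g <- ssim_filter_adjoint(d_mu, wts, dim(a)) +
    2 * a * ssim_filter_adjoint(d_m2, wts, dim(a)) +
    b * ssim_filter_adjoint(d_mab, wts, dim(a))
  list(value = mean(S), grad = g / P)
}
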