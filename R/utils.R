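#' Derive a stage seed from a global seed
#'
#' Every stochastic operation in the pipeline draws its seed from one global
#' seed through a stable integer hash of a stage tag, so stages are decoupled:
#' changing how many random numbers one stage consumes never perturbs another.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag (e.g. `"phantom"`, `"train"`).
#' @param index Optional integer sub-index (e.g. dataset number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "phantom", 3)
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, keeps results in R's integer range
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @keywords internal
gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a matrix, edge-replicated.
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  mr <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) mr <- mr + k[i] * mp[seq_len(nrow(m)) + i - 1L, , drop = FALSE]
  mp <- mr[, pad_idx(ncol(m)), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[, seq_len(ncol(m)) + i - 1L, drop = FALSE]
  out
}
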