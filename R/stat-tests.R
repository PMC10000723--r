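#' Wilcoxon signed-rank test on paired values
#'
#' The convention mirrors mainstream statistics packages: zero differences
#' are discarded, the remaining absolute differences are ranked with
#' mid-ranks for ties, and a two-sided p-value is taken from the normal
#' approximation `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie_correction)`
#' without continuity correction. An exact-enumeration variant (all `2^n`
#' sign assignments) is available for cross-checking; for small n the two
#' conventions can disagree materially, which is why the convention is part
#' of the contract.
#'
#' @param a,b Equal-length numeric vectors of paired values.
#' @param method `"asymptotic"` (default) or `"exact"` (enumeration,
#'   `n <= 20` after zero removal).
#' @return A list with `statistic` (W+, sum of ranks of positive
#'   differences), `z` (asymptotic method), `p_value`, `n_used`, `method`,
#'   and `undefined` (TRUE when every difference is zero).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(0.74, 0.43, 0.68, 0.77, 0.52, 0.73),
#'                      c(0.73, 0.35, 0.39, 0.77, 0.47, 0.67))$p_value
wilcoxon_signed_rank <- function(a, b, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, z = NA_real_, p_value = NA_real_,
                n_used = 0L, method = method, undefined = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (method == "exact") {
    if (n > 20L) abort("exact enumeration limited to n <= 20")
    # enumerate all sign assignments of the ranked magnitudes
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = W, z = NA_real_, p_value = min(1, p),
                n_used = n, method = method, undefined = FALSE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(list(statistic = W, z = NA_real_, p_value = NA_real_,
                n_used = n, method = method, undefined = TRUE))
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = W, z = z, p_value = min(1, 2 * pnorm(-abs(z))),
       n_used = n, method = method, undefined = FALSE)
}

#' McNemar's test for paired accuracy difference
#'
#' Counts discordant pairs `b` (method A correct, B wrong) and `c` (A wrong,
#' B correct). When `b + c < 25` the two-sided exact binomial p-value
#' `2 P(X <= min(b, c) | n = b + c, 1/2)` (capped at 1) is used; otherwise
#' the continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#'
#' @param correct_a,correct_b Equal-length logical vectors: per-item
#'   correctness of the two methods.
#' @return A list with `b`, `c`, `p_value`, `method` (`"exact"` or
#'   `"chi-square"`), and `undefined` (TRUE when `b + c = 0`, where `p = 1`
#'   by convention).
#' @export
#' @examples
#' mcnemar_test(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b))
    abort("correctness vectors must have equal length")
  stopifnot(is.logical(correct_a), is.logical(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  nd <- b + cc
  if (nd == 0L)
    return(list(b = b, c = cc, p_value = 1, method = "exact", undefined = TRUE))
  if (nd < 25L) {
    p <- min(1, 2 * pbinom(min(b, cc), nd, 0.5))
    list(b = b, c = cc, p_value = p, method = "exact", undefined = FALSE)
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    list(b = b, c = cc, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi-square", undefined = FALSE)
  }
}
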