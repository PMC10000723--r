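#' Cohen's kappa with a 95% confidence interval
#'
#' Unweighted chance-corrected agreement between two categorical grading
#' sequences: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o`
#' and chance agreement `p_e` from the raters' marginal distributions. The
#' confidence interval is `kappa +/- 1.96 * SE` with the large-sample
#' standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param g1,g2 Equal-length grade vectors (length >= 2) over a shared
#'   category set.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `kappa`, `se`, `conf_low`, `conf_high`, `p_o`, `p_e`,
#'   `n`, and `undefined` (TRUE when both raters are constant and identical,
#'   where chance agreement is 1 and kappa has no value).
#' @export
#' @examples
#' cohens_kappa(c(0, 0, 1, 1), c(0, 1, 1, 1))$kappa # 0.5
cohens_kappa <- function(g1, g2, conf_level = 0.95) {
  if (length(g1) != length(g2)) abort("grade sequences must have equal length")
  n <- length(g1)
  if (n < 2L) abort("need at least two paired gradings")
  cats <- sort(unique(c(g1, g2)))
  f1 <- factor(g1, levels = cats); f2 <- factor(g2, levels = cats)
  tab <- table(f1, f2) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) {
    return(list(kappa = NA_real_, se = NA_real_, conf_low = NA_real_,
                conf_high = NA_real_, p_o = p_o, p_e = p_e, n = n,
                undefined = TRUE))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se, conf_low = kappa - z * se,
       conf_high = kappa + z * se, p_o = p_o, p_e = p_e, n = n,
       undefined = FALSE)
}

#' Exact-match grading accuracy
#'
#' Fraction of gradings that equal the reference grade.
#'
#' @param g Grades under evaluation.
#' @param gt Reference (ground-truth) grades, same length.
#' @return A proportion in `[0, 1]`.
#' @export
grading_accuracy <- function(g, gt) {
  if (length(g) != length(gt)) abort("grade sequences must have equal length")
  if (length(g) == 0L) abort("empty grade sequences")
  mean(g == gt)
}
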