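#' Synthesize a fat-saturated volume from T1-w and non-fs T2-w inputs
#'
#' Runs every sagittal slice of the preprocessed input pair through the
#' trained generator (dropout off by default, so inference is deterministic)
#' and restacks the outputs. When a reference T2fs volume is supplied,
#' per-slice SSIM against it is attached.
#'
#' @param t1,t2 Preprocessed [contrast_volume()]s in `[-1, 1]`, identical
#'   shape, co-registered.
#' @param checkpoint A `gan_checkpoint` from [train()] or [load_checkpoint()].
#' @param reference Optional real T2fs [contrast_volume()] for evaluation.
#' @param stochastic Keep decoder dropout active at inference (off by
#'   default; on, outputs vary with `seed`).
#' @param seed Seed for stochastic inference.
#' @param normalization Optional `normalization_record` stored with the
#'   result so intensities can be mapped back to the display range.
#' @return A `synthesis_result`: list with `volume` (contrast `SYNTH_T2FS`),
#'   `per_slice_ssim` (or `NULL`), `mean_ssim`, `checkpoint_seed`,
#'   `normalization`.
#' @export
synthesize_volume <- function(t1, t2, checkpoint, reference = NULL,
                              stochastic = FALSE, seed = 0L,
                              normalization = NULL) {
  stopifnot(inherits(t1, "contrast_volume"), inherits(t2, "contrast_volume"))
  if (!inherits(checkpoint, "gan_checkpoint"))
    abort("`checkpoint` must be a gan_checkpoint (see train())")
  if (!all(dim(t1$data) == dim(t2$data)))
    abort("T1 and T2 volumes must have identical shape")
  if (!is.null(reference) && !all(dim(reference$data) == dim(t1$data)))
    abort("reference volume shape must match the inputs")

  gspec <- checkpoint$generator_spec
  mult <- 2L^gspec$depth
  ns <- n_slices(t1)
  out <- contrast_volume(array(0, dim = dim(t1$data)), t1$spacing,
                         "SYNTH_T2FS", t1$slice_axis)
  run <- function() {
    res <- out
    for (i in seq_len(ns)) {
      m1 <- pad_to_multiple(get_slice(t1, i), mult)
      m2 <- pad_to_multiple(get_slice(t2, i), mult)
      x <- array(0, dim = c(nrow(m1), ncol(m1), 2L, 1L))
      x[, , 1L, 1L] <- m1; x[, , 2L, 1L] <- m2
      y <- gen_forward(checkpoint$generator, gspec, x,
                       training = FALSE, use_dropout = stochastic)$y
      orig <- dim(get_slice(t1, i))
      res <- set_slice(res, i, matrix(y[seq_len(orig[1]), seq_len(orig[2]), 1L, 1L],
                                      orig[1], orig[2]))
    }
    res
  }
  out <- if (stochastic) with_seed_(derive_seed(seed, "synth-dropout"), run())
         else run()

  result <- structure(
    list(volume = out, per_slice_ssim = NULL, mean_ssim = NA_real_,
         checkpoint_seed = checkpoint$seed, normalization = normalization),
    class = "synthesis_result"
  )
  if (!is.null(reference)) {
    ev <- evaluate_synthesis(result, reference)
    result$per_slice_ssim <- ev$per_slice_ssim
    result$mean_ssim <- ev$mean_ssim
  }
  result
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis_result  %s voxels%s>\n",
              paste(dim(x$volume$data), collapse = "x"),
              if (is.na(x$mean_ssim)) ""
              else sprintf("  mean SSIM %.3f", x$mean_ssim)))
  invisible(x)
}

#' Per-slice and volume-mean SSIM of a synthesis result
#'
#' @param result A `synthesis_result`.
#' @param reference A real T2fs [contrast_volume()] of identical shape.
#' @param params SSIM parameters.
#' @return A list with `per_slice_ssim` (one value per sagittal slice) and
#'   `mean_ssim` (their arithmetic mean).
#' @export
evaluate_synthesis <- function(result, reference, params = ssim_params()) {
  stopifnot(inherits(result, "synthesis_result"),
            inherits(reference, "contrast_volume"))
  vol <- result$volume
  if (!all(dim(vol$data) == dim(reference$data)))
    abort("reference volume shape must match the synthetic volume")
  per <- vapply(seq_len(n_slices(vol)), function(i)
    ssim(get_slice(vol, i), get_slice(reference, i), params), numeric(1))
  list(per_slice_ssim = per, mean_ssim = mean(per))
}

#' @export
tidy.synthesis_result <- function(x, ...) {
  if (is.null(x$per_slice_ssim))
    return(tibble::tibble(slice = integer(), ssim = numeric()))
  tibble::tibble(slice = seq_along(x$per_slice_ssim), ssim = x$per_slice_ssim)
}

#' @export
glance.synthesis_result <- function(x, ...) {
  tibble::tibble(n_slices = n_slices(x$volume), mean_ssim = x$mean_ssim,
                 checkpoint_seed = x$checkpoint_seed)
}

#' Plot sagittal slices of a contrast volume
#'
#' @param vol A [contrast_volume()].
#' @param slices Slice indices to show (default: the middle slice).
#' @return A ggplot raster panel, one facet per slice.
#' @export
plot_slices <- function(vol, slices = NULL) {
  stopifnot(inherits(vol, "contrast_volume"))
  slices <- slices %||% ceiling(n_slices(vol) / 2)
  df <- dplyr::bind_rows(lapply(slices, function(i) {
    m <- get_slice(vol, i)
    tibble::tibble(slice = i,
                   row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   intensity = as.numeric(m))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~slice) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = vol$contrast, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
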