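#' In-plane 2-D rigid transform
#'
#' Rotation (degrees, about the in-plane image center) followed by a
#' translation in mm along the in-plane row and column directions.
#'
#' @param rotation_deg Rotation in degrees.
#' @param translation_mm Length-2 translation in mm.
#' @param fixed,moving Contrast labels of the fixed and moving images.
#' @return An object of class `rigid_transform_2d`.
#' @export
rigid_transform_2d <- function(rotation_deg = 0, translation_mm = c(0, 0),
                               fixed = NA_character_, moving = NA_character_) {
  stopifnot(is_scalar_number(rotation_deg), length(translation_mm) == 2L)
  structure(list(rotation = as.numeric(rotation_deg),
                 translation = as.numeric(translation_mm),
                 fixed = fixed, moving = moving),
            class = "rigid_transform_2d")
}

#' @export
print.rigid_transform_2d <- function(x, ...) {
  cat(sprintf("<rigid_transform_2d  rot %.3f deg  t (%.3f, %.3f) mm>\n",
              x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' @rdname rigid_transform_2d
#' @param tf A `rigid_transform_2d`.
#' @return `invert_rigid_2d()` returns the inverse transform: composing the
#'   two is the identity within interpolation tolerance.
#' @export
invert_rigid_2d <- function(tf) {
  th <- -tf$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform_2d(-tf$rotation, as.numeric(-R %*% tf$translation),
                     fixed = tf$moving, moving = tf$fixed)
}

# Warp one slice by a rigid transform (content rotated by theta about the
# center, then translated), bilinear resampling in mm coordinates.
apply_rigid_2d <- function(img, tf, spacing = c(1, 1), fill = 0) {
  th <- tf$rotation * pi / 180
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) # R(-theta)
  D <- diag(spacing); Dinv <- diag(1 / spacing)
  M <- Dinv %*% Rinv %*% D
  ctr <- (c(nrow(img), ncol(img)) - 1) / 2
  b <- as.numeric(-Dinv %*% Rinv %*% tf$translation + ctr - M %*% ctr)
  .cpp_affine_sample(img, M, b, nrow(img), ncol(img), fill)
}

#' Resample a volume to a target in-plane resolution
#'
#' Linear (bilinear) interpolation on a voxel-center grid: output voxel `i`
#' samples the input at world position `i * target_mm`, so an input of
#' in-plane extent `(n-1) * spacing` mm yields `floor((n-1) * spacing /
#' target_mm) + 1` voxels. Slice-axis spacing is unchanged.
#'
#' @param vol A [contrast_volume()].
#' @param target_mm Target in-plane spacing in mm (default 1).
#' @return A resampled [contrast_volume()].
#' @export
resample_inplane <- function(vol, target_mm = 1.0) {
  stopifnot(inherits(vol, "contrast_volume"), is_scalar_number(target_mm),
            target_mm > 0)
  if (!all(is.finite(vol$data))) abort("volume has non-finite intensities")
  ax <- inplane_axes(vol)
  sp <- vol$spacing[ax]
  n_in <- dim(vol$data)[ax]
  n_out <- floor((n_in - 1) * sp / target_mm) + 1L
  A <- diag(target_mm / sp)
  out <- array(0, dim = replace(dim(vol$data), ax, n_out))
  res <- contrast_volume(out, replace(vol$spacing, ax, c(target_mm, target_mm)),
                         vol$contrast, vol$slice_axis)
  for (i in seq_len(n_slices(vol)))
    res <- set_slice(res, i, .cpp_affine_sample(get_slice(vol, i), A, c(0, 0),
                                                n_out[1], n_out[2], 0))
  res
}

#' Estimate the rigid transform aligning a moving to a fixed volume
#'
#' In-plane rigid registration by minimizing the mean squared intensity
#' difference over a central window: a coarse rotation/translation grid
#' search on the slice-averaged image, refined by Nelder-Mead. Returns the
#' transform that maps the moving volume into the fixed space, and the
#' resampled moving volume.
#'
#' @param moving,fixed [contrast_volume()]s with overlapping fields of view
#'   and identical in-plane shape.
#' @param rotation_range,translation_range Search bounds (deg, mm).
#' @return List with `transform` (a [rigid_transform_2d()]) and `volume`
#'   (moving resampled into fixed space).
#' @export
rigid_register <- function(moving, fixed, rotation_range = 12,
                           translation_range = 18) {
  stopifnot(inherits(moving, "contrast_volume"), inherits(fixed, "contrast_volume"))
  if (!all(dim(moving$data) == dim(fixed$data)))
    abort("moving and fixed volumes must have equal shape")
  sp <- fixed$spacing[inplane_axes(fixed)]
  mov2 <- slice_mean(moving); fix2 <- slice_mean(fixed)
  if (sd(mov2) == 0 || sd(fix2) == 0)
    abort("registration undefined for constant images")
  # central window, away from resampling fill-in at the borders
  tr <- ceiling(0.15 * dim(fix2))
  win_r <- (tr[1] + 1):(nrow(fix2) - tr[1])
  win_c <- (tr[2] + 1):(ncol(fix2) - tr[2])
  obj <- function(p) {
    w <- apply_rigid_2d(mov2, rigid_transform_2d(p[1], p[2:3]), spacing = sp)
    mean((w[win_r, win_c] - fix2[win_r, win_c])^2)
  }
  grid <- expand.grid(
    r = seq(-rotation_range, rotation_range, by = 3),
    tr = seq(-translation_range, translation_range, by = 3),
    tc = seq(-translation_range, translation_range, by = 3)
  )
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  # two-stage local refinement
  fit <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-12))
  tf <- rigid_transform_2d(fit$par[1], fit$par[2:3],
                           fixed = fixed$contrast, moving = moving$contrast)
  out <- moving
  for (i in seq_len(n_slices(moving)))
    out <- set_slice(out, i, apply_rigid_2d(get_slice(moving, i), tf, spacing = sp))
  list(transform = tf, volume = out)
}

slice_mean <- function(vol) {
  acc <- get_slice(vol, 1)
  ns <- n_slices(vol)
  if (ns > 1) for (i in 2:ns) acc <- acc + get_slice(vol, i)
  acc / ns
}

#' Percentile capping and scaling to [-1, 1]
#'
#' Intensities are clipped to the 1st and 99th percentile of the volume
#' (linear-interpolation percentile convention, computed per volume) and
#' affinely mapped so the 1st percentile lands on -1 and the 99th on +1. The
#' returned record allows inversion to the original display range.
#'
#' @param vol A [contrast_volume()].
#' @return List with `volume` (intensities in `[-1, 1]`) and `record`
#'   (a `normalization_record` with `p_low`, `p_high`, `contrast`,
#'   `degenerate`). A constant input yields the all-zero volume and a
#'   degenerate-flagged record.
#' @export
#' @examples
#' v <- contrast_volume(array(0:100, c(101, 1, 1)))
#' cs <- cap_and_scale(v)
#' range(cs$volume$data)
cap_and_scale <- function(vol) {
  stopifnot(inherits(vol, "contrast_volume"))
  if (!all(is.finite(vol$data))) abort("volume has non-finite intensities")
  q <- quantile(vol$data, c(0.01, 0.99), type = 7, names = FALSE)
  degenerate <- q[1] == q[2]
  rec <- structure(list(p_low = q[1], p_high = q[2], contrast = vol$contrast,
                        degenerate = degenerate),
                   class = "normalization_record")
  out <- vol
  if (degenerate) {
    warning("degenerate intensity distribution (p1 == p99); output set to 0")
    out$data[] <- 0
  } else {
    x <- pmin(pmax(vol$data, q[1]), q[2])
    out$data <- (x - q[1]) / (q[2] - q[1]) * 2 - 1
  }
  list(volume = out, record = rec)
}

#' @rdname cap_and_scale
#' @param record A `normalization_record` from [cap_and_scale()].
#' @return `invert_cap_scale()` maps a `[-1, 1]` volume back onto the clipped
#'   intensity range `[p_low, p_high]`.
#' @export
invert_cap_scale <- function(vol, record) {
  stopifnot(inherits(vol, "contrast_volume"),
            inherits(record, "normalization_record"))
  out <- vol
  if (record$degenerate) {
    out$data[] <- record$p_low
  } else {
    out$data <- (vol$data + 1) / 2 * (record$p_high - record$p_low) + record$p_low
  }
  out
}

#' Build the paired sagittal slice dataset for training
#'
#' One record per sagittal index: a two-channel input (T1-w, non-fs T2-w) and
#' a one-channel target (T2-w fs), all expected in `[-1, 1]` after
#' [cap_and_scale()]. With `t2fs = NULL` the dataset carries empty targets
#' and can only be used for synthesis.
#'
#' @param t1,t2 Preprocessed [contrast_volume()]s of identical shape.
#' @param t2fs Optional preprocessed target volume, identical shape.
#' @param dataset_id Identifier stored with each record.
#' @return A tibble of class `paired_slice_dataset` with columns
#'   `dataset_id`, `slice_index`, and list-columns `t1`, `t2`, `t2fs`
#'   (matrices; `t2fs` entries are `NULL` when no target is supplied).
#' @export
extract_sagittal_slices <- function(t1, t2, t2fs = NULL, dataset_id = "d1") {
  stopifnot(inherits(t1, "contrast_volume"), inherits(t2, "contrast_volume"))
  if (!all(dim(t1$data) == dim(t2$data)))
    abort("T1 and T2 volumes must have identical shape")
  if (!is.null(t2fs) && !all(dim(t2fs$data) == dim(t1$data)))
    abort("T2fs volume shape must match the inputs")
  ns <- n_slices(t1)
  ds <- tibble::tibble(
    dataset_id = dataset_id,
    slice_index = seq_len(ns),
    t1 = lapply(seq_len(ns), function(i) get_slice(t1, i)),
    t2 = lapply(seq_len(ns), function(i) get_slice(t2, i)),
    t2fs = if (is.null(t2fs)) vector("list", ns)
           else lapply(seq_len(ns), function(i) get_slice(t2fs, i))
  )
  class(ds) <- c("paired_slice_dataset", class(ds))
  ds
}
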