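#' @title Spine phantom simulation
#' @description
#' The phantom emulates the statistical structure a fat-saturation synthesis
#' model must learn, not spine anatomy: a sagittal stack of vertebral bodies
#' and discs flanked by cord, CSF, paravertebral fat and muscle, each tissue a
#' three-compartment (fat / fluid / base) signal source. Fat is bright on
#' T1-w and non-fs T2-w but suppressed on T2-w fs; fluid (and pathological
#' edema) is bright on both T2-w contrasts and iso-to-dark on T1-w.
#' @name phantom
NULL

# Tissue label codes
PHANTOM_LABELS <- c(
  background = 0L, vertebra = 1L, disc = 2L, cord = 3L,
  csf = 4L, fat = 5L, muscle = 6L
)

# Per-tissue compartment fractions and base signal. Rows follow label order.
default_tissue_params <- function() {
  tibble::tribble(
    ~tissue,      ~label, ~fat_fraction, ~fluid_fraction, ~base_signal,
    "background",     0L,          0.00,            0.00,         0.00,
    "vertebra",       1L,          0.60,            0.15,         0.10,
    "disc",           2L,          0.05,            0.70,         0.15,
    "cord",           3L,          0.05,            0.35,         0.50,
    "csf",            4L,          0.00,            1.00,         0.00,
    "fat",            5L,          0.95,            0.02,         0.05,
    "muscle",         6L,          0.10,            0.30,         0.40
  )
}

# Per-contrast weights of the linear three-compartment signal model. The fat
# weight is zero for T2FS and the fluid/base weights equal those of T2, so
# fat suppression is exact by construction.
CONTRAST_WEIGHTS <- list(
  T1   = c(fat = 1.00, fluid = 0.20, base = 0.60),
  T2   = c(fat = 0.80, fluid = 1.00, base = 0.50),
  T2FS = c(fat = 0.00, fluid = 1.00, base = 0.50)
)

PATHOLOGY_KINDS <- c("bone_marrow_abnormality", "spondylodiscitis_expansion",
                     "modic_type1", "vertebral_fracture", "cord_lesion",
                     "paravertebral_abnormality")

# Legal grade range per pathology kind.
GRADE_RANGE <- list(
  bone_marrow_abnormality    = 0:4,
  spondylodiscitis_expansion = 0:3,
  modic_type1                = 0:1,
  vertebral_fracture         = 0:2,
  cord_lesion                = 0:1,
  paravertebral_abnormality  = 0:3
)

#' Legal grades for each spine pathology kind
#'
#' Bone-marrow abnormalities run 0 (absent) to 4 (whole body / pedicle
#' involvement), spondylodiscitis expansion 0-3, Modic type-1 changes and
#' cord lesions are present/absent, fractures are 0/1 (acute, edema) /
#' 2 (chronic), paravertebral abnormalities 0-3 (absent / inflammation /
#' hematoma / other).
#'
#' @return A tibble with columns `kind`, `min_grade`, `max_grade`.
#' @export
pathology_grade_ranges <- function() {
  tibble::tibble(
    kind = names(GRADE_RANGE),
    min_grade = 0L,
    max_grade = vapply(GRADE_RANGE, max, integer(1), USE.NAMES = FALSE)
  )
}

# Extent-to-grade mapping. Thirds define the upper classes; lesions under 10%
# of the body count as "focal".
grade_for_kind <- function(kind, extent = 0, severity = NULL, edema = FALSE) {
  switch(kind,
    bone_marrow_abnormality =
      if (extent <= 0.10) 1L else if (extent <= 1 / 3) 2L
      else if (extent <= 2 / 3) 3L else 4L,
    spondylodiscitis_expansion =
      if (extent <= 1 / 3) 1L else if (extent <= 2 / 3) 2L else 3L,
    modic_type1 = 1L,
    vertebral_fracture = if (isTRUE(edema)) 1L else 2L,
    cord_lesion = 1L,
    paravertebral_abnormality = as.integer(severity %||% 1L),
    abort(paste0("unknown pathology kind: ", kind))
  )
}

#' Generate a multi-contrast spine phantom scene
#'
#' Builds a 3-D tissue-label volume (vertebral bodies, intervertebral discs,
#' spinal cord, CSF, paravertebral fat, muscle) with optional graded
#' pathologies, plus the per-tissue signal parameters needed to render any
#' contrast. Geometry is jittered per scene, and structures taper towards the
#' lateral slices so sagittal slices differ. Deterministic given `seed`.
#'
#' @param seed Integer seed; identical seed and arguments reproduce the scene
#'   bit-exactly.
#' @param shape Integer length-3 voxel dimensions `(rows, cols, slices)`.
#' @param n_vertebrae Number of stacked vertebral bodies.
#' @param pathology_spec List of pathology requests, each a list with `kind`
#'   (see [pathology_grade_ranges()]) and `severity`. For extent-graded kinds
#'   (`bone_marrow_abnormality`, `spondylodiscitis_expansion`) severity is the
#'   target extent fraction of the affected vertebral body in `[0, 1]`; for
#'   `vertebral_fracture` it is 1 (acute, edema) or 2 (chronic); for
#'   `paravertebral_abnormality` the category 1-3; ignored for the
#'   present/absent kinds.
#' @param spacing Voxel spacing in mm.
#' @return A `phantom_scene`: list with `labels` (integer array),
#'   `tissue_params` (tibble), `pathologies` (list of annotations, each with
#'   `kind`, `mask` (logical array), `extent_fraction`, `edema`, `gt_grade`),
#'   `spacing`, `shape`, `seed`.
#' @export
#' @examples
#' sc <- make_phantom(seed = 1, shape = c(64, 64, 5), n_vertebrae = 4)
#' table(sc$labels)
make_phantom <- function(seed, shape = c(64, 64, 11), n_vertebrae = 4,
                         pathology_spec = list(), spacing = c(1, 1, 3)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape[1:2] >= 16L), shape[3] >= 1L,
            n_vertebrae >= 1L)
  H <- shape[1]; W <- shape[2]; S <- shape[3]
  # each body needs >= 4 rows plus a 2-row disc gap, inside a 90% margin
  body_h <- floor(0.92 * H / (n_vertebrae + 0.4 * (n_vertebrae - 1)))
  disc_h <- max(2L, floor(0.4 * body_h))
  if (body_h < 4L)
    abort(sprintf("cannot fit %d vertebrae in %d rows", n_vertebrae, H))

  with_seed_(derive_seed(seed, "phantom-geometry"), {
    jitter_w <- runif(1, -0.02, 0.02)   # per-scene column jitter
    body_jit <- runif(n_vertebrae, -0.015, 0.015)
    labels <- array(0L, dim = shape)
    rows <- seq_len(H); cols <- seq_len(W)
    total_h <- n_vertebrae * body_h + (n_vertebrae - 1L) * disc_h
    top <- max(1L, floor((H - total_h) / 2)) + 1L

    body_rows <- vector("list", n_vertebrae)
    for (v in seq_len(n_vertebrae)) {
      r0 <- top + (v - 1L) * (body_h + disc_h)
      body_rows[[v]] <- r0:(r0 + body_h - 1L)
    }

    for (s in seq_len(S)) {
      # mild lateral taper: structures narrow towards the outermost slices
      u <- if (S > 1) 2 * (s - 1) / (S - 1) - 1 else 0
      taper <- sqrt(pmax(1 - 0.35 * u^2, 0))
      cx <- function(f) pmax(1L, pmin(W, round(W * (f + jitter_w))))
      half <- function(a, b) round((b - a) / 2 * (1 - taper))
      band <- function(f1, f2) {
        a <- cx(f1); b <- cx(f2); sh <- half(a, b)
        seq.int(min(a + sh, b), max(b - sh, a))
      }
      sl <- matrix(0L, H, W)
      vert_cols <- band(0.28, 0.58)
      cord_cols <- band(0.64, 0.72)
      csf_cols  <- setdiff(band(0.60, 0.76), cord_cols)
      fat_cols  <- band(0.80, 0.94)
      mus_cols  <- band(0.06, 0.22)
      sl[, mus_cols] <- PHANTOM_LABELS[["muscle"]]
      sl[, fat_cols] <- PHANTOM_LABELS[["fat"]]
      spine_extent <- top:(top + total_h - 1L)
      sl[spine_extent, csf_cols] <- PHANTOM_LABELS[["csf"]]
      sl[spine_extent, cord_cols] <- PHANTOM_LABELS[["cord"]]
      for (v in seq_len(n_vertebrae)) {
        wj <- round(W * body_jit[v])
        vc <- pmax(1L, pmin(W, vert_cols + wj))
        sl[body_rows[[v]], vc] <- PHANTOM_LABELS[["vertebra"]]
        if (v < n_vertebrae) {
          dr <- (max(body_rows[[v]]) + 1L):(max(body_rows[[v]]) + disc_h)
          sl[dr, vc] <- PHANTOM_LABELS[["disc"]]
        }
      }
      labels[, , s] <- sl
    }
  })

  scene <- structure(
    list(labels = labels, tissue_params = default_tissue_params(),
         pathologies = list(), spacing = as.numeric(spacing),
         shape = shape, seed = as.integer(seed),
         body_rows = body_rows, n_vertebrae = as.integer(n_vertebrae)),
    class = "phantom_scene"
  )

  for (i in seq_along(pathology_spec)) {
    ps <- pathology_spec[[i]]
    scene <- add_pathology(scene, ps$kind, ps$severity %||% 0.5,
                           seed = derive_seed(seed, "pathology", i))
  }
  scene
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene %s voxels, %d vertebrae, %d pathologies, seed %d>\n",
              paste(x$shape, collapse = "x"), x$n_vertebrae,
              length(x$pathologies), x$seed))
  invisible(x)
}

# Ellipsoid mask clipped to a parent structure; axes scaled by bisection so
# the clipped volume fraction of the target structure matches `target_frac`.
ellipsoid_in <- function(labels, parent_mask, center, target_frac) {
  dm <- dim(labels)
  idx <- which(parent_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("pathology parent structure is empty")
  half <- pmax((apply(idx, 2, max) - apply(idx, 2, min)) / 2, 0.5)
  grid <- arrayInd(seq_along(labels), dm)
  dist2_of <- function(t) {
    ax <- pmax(half * t, 0.5)
    d <- sweep(grid, 2, center)
    d <- sweep(d, 2, ax, "/")
    rowSums(d^2)
  }
  frac_of <- function(t) {
    m <- array(dist2_of(t) <= 1, dm) & parent_mask
    sum(m) / sum(parent_mask)
  }
  lo <- 0.02; hi <- 4
  for (k in 1:28) {
    mid <- (lo + hi) / 2
    if (frac_of(mid) < target_frac) lo <- mid else hi <- mid
  }
  array(dist2_of(hi) <= 1, dm) & parent_mask
}

add_pathology <- function(scene, kind, severity, seed) {
  kind <- match.arg(kind, PATHOLOGY_KINDS)
  labels <- scene$labels
  with_seed_(seed, {
    v <- sample.int(scene$n_vertebrae, 1L)
    body_mask <- array(FALSE, dim = scene$shape)
    body_mask[scene$body_rows[[v]], , ] <- TRUE
    body_mask <- body_mask & (labels == PHANTOM_LABELS[["vertebra"]])
    center_of <- function(mask) {
      colMeans(which(mask, arr.ind = TRUE))
    }
    ann <- switch(kind,
      bone_marrow_abnormality = {
        if (!is_scalar_number(severity) || severity <= 0 || severity > 1)
          abort("bone_marrow severity must be an extent fraction in (0, 1]")
        m <- ellipsoid_in(labels, body_mask, center_of(body_mask), severity)
        ext <- sum(m) / sum(body_mask)
        list(mask = m, extent_fraction = ext, edema = TRUE,
             gt_grade = grade_for_kind(kind, extent = ext))
      },
      spondylodiscitis_expansion = {
        if (!is_scalar_number(severity) || severity <= 0 || severity > 1)
          abort("spondylodiscitis severity must be an extent fraction in (0, 1]")
        m <- ellipsoid_in(labels, body_mask, center_of(body_mask), severity)
        disc_mask <- labels == PHANTOM_LABELS[["disc"]]
        ext <- sum(m & body_mask) / sum(body_mask)
        list(mask = m | (disc_mask & ellipsoid_in(labels, disc_mask,
               center_of(disc_mask), 0.5)),
             extent_fraction = ext, edema = TRUE,
             gt_grade = grade_for_kind(kind, extent = ext))
      },
      modic_type1 = {
        # endplate band: top quarter of the body
        rr <- scene$body_rows[[v]]
        m <- body_mask
        keep <- rr[seq_len(max(1L, floor(length(rr) / 4)))]
        m[setdiff(seq_len(scene$shape[1]), keep), , ] <- FALSE
        list(mask = m, extent_fraction = sum(m) / sum(body_mask),
             edema = TRUE, gt_grade = grade_for_kind(kind))
      },
      vertebral_fracture = {
        sev <- as.integer(severity %||% 1L)
        if (!sev %in% 1:2) abort("fracture severity must be 1 (acute) or 2 (chronic)")
        rr <- scene$body_rows[[v]]
        m <- body_mask
        mid <- rr[seq(floor(length(rr) / 3) + 1L, ceiling(2 * length(rr) / 3))]
        m[setdiff(seq_len(scene$shape[1]), mid), , ] <- FALSE
        list(mask = m, extent_fraction = sum(m) / sum(body_mask),
             edema = sev == 1L, gt_grade = grade_for_kind(kind, edema = sev == 1L))
      },
      cord_lesion = {
        cm <- labels == PHANTOM_LABELS[["cord"]]
        m <- ellipsoid_in(labels, cm, center_of(cm) + c(runif(1, -5, 5), 0, 0), 0.15)
        list(mask = m, extent_fraction = sum(m) / sum(cm),
             edema = TRUE, gt_grade = grade_for_kind(kind))
      },
      paravertebral_abnormality = {
        sev <- as.integer(severity %||% 1L)
        if (!sev %in% 1:3) abort("paravertebral severity must be 1, 2 or 3")
        fm <- labels == PHANTOM_LABELS[["fat"]]
        m <- ellipsoid_in(labels, fm, center_of(fm), 0.25)
        list(mask = m, extent_fraction = sum(m) / sum(fm),
             edema = sev == 1L,
             gt_grade = grade_for_kind(kind, severity = sev))
      }
    )
  })
  ann$kind <- kind
  stopifnot(ann$gt_grade %in% GRADE_RANGE[[kind]])
  scene$pathologies <- c(scene$pathologies, list(ann))
  scene
}

#' Ground-truth grades of a phantom scene
#'
#' Maps each pathology annotation to its grade (extent thresholds at 10%,
#' one-third and two-thirds of the vertebral body for extent-graded kinds;
#' the edema flag decides acute vs chronic fractures) and reports grade 0 for
#' every kind with no annotation. With several annotations of one kind the
#' maximum grade is reported.
#'
#' @param scene A `phantom_scene`.
#' @return A tibble with columns `kind` (all six kinds) and `gt_grade`.
#' @export
grade_from_scene <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  g <- stats::setNames(integer(length(PATHOLOGY_KINDS)), PATHOLOGY_KINDS)
  for (ann in scene$pathologies)
    g[[ann$kind]] <- max(g[[ann$kind]], ann$gt_grade)
  tibble::tibble(kind = PATHOLOGY_KINDS, gt_grade = unname(g))
}

#' Render a contrast from a phantom scene
#'
#' Per-voxel signal is a linear mixture of the fat, fluid and base
#' compartments with contrast-specific weights; the fat weight is zero for
#' `T2FS`, which realizes exact fat suppression. Pathology masks with edema
#' swap fat for fluid (fraction 0.7 of the remaining non-fluid share), so
#' lesions are bright on both T2-w contrasts and iso-to-dark on T1-w.
#' Additive Gaussian noise with `noise_sd`; deterministic given `seed`.
#'
#' @param scene A `phantom_scene`.
#' @param contrast `"T1"`, `"T2"` or `"T2FS"`.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return A [contrast_volume()].
#' @export
#' @examples
#' sc <- make_phantom(seed = 1, shape = c(48, 48, 3), n_vertebrae = 3)
#' t2fs <- render_contrast(sc, "T2FS", noise_sd = 0, seed = 1)
render_contrast <- function(scene, contrast, noise_sd = 0.01, seed = 0L) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (!contrast %in% names(CONTRAST_WEIGHTS))
    abort(paste0("unknown contrast label: ", contrast))
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    abort("`noise_sd` must be a non-negative number")
  tp <- scene$tissue_params
  lut <- function(field) {
    v <- numeric(max(tp$label) + 1L)
    v[tp$label + 1L] <- tp[[field]]
    v[scene$labels + 1L]
  }
  fat <- array(lut("fat_fraction"), dim = scene$shape)
  fluid <- array(lut("fluid_fraction"), dim = scene$shape)
  base <- array(lut("base_signal"), dim = scene$shape)
  for (ann in scene$pathologies) {
    if (isTRUE(ann$edema)) {
      m <- ann$mask
      fluid[m] <- fluid[m] + 0.7 * (1 - fluid[m])
      fat[m] <- fat[m] * 0.3
    } else if (ann$kind == "vertebral_fracture") {
      m <- ann$mask # chronic: sclerotic, signal-poor
      fat[m] <- fat[m] * 0.5
      base[m] <- base[m] * 0.5
    } else if (ann$kind == "paravertebral_abnormality") {
      m <- ann$mask # hematoma / other: base-signal lesion without edema
      fat[m] <- fat[m] * 0.4
      base[m] <- base[m] + 0.4
    }
  }
  w <- CONTRAST_WEIGHTS[[contrast]]
  img <- w[["fat"]] * fat + w[["fluid"]] * fluid + w[["base"]] * base
  if (noise_sd > 0)
    img <- img + with_seed_(derive_seed(seed, paste0("noise-", contrast)),
                            array(rnorm(length(img), sd = noise_sd),
                                  dim = scene$shape))
  contrast_volume(img, spacing = scene$spacing, contrast = contrast)
}

#' Apply a known in-plane rigid misalignment to a volume
#'
#' Rotates (about the in-plane center) and translates every sagittal slice by
#' the same rigid transform, with bilinear resampling, and returns both the
#' resampled volume and the exact transform applied — ground truth for
#' registration parameter-recovery tests.
#'
#' @param vol A [contrast_volume()].
#' @param rotation_deg Rotation in degrees, `|rotation_deg| <= 15`.
#' @param translation_mm Length-2 translation in mm (row, column direction),
#'   each `|t| <= 20`.
#' @param seed Unused randomness hook kept for interface stability.
#' @return A list with `volume` (resampled [contrast_volume()]) and
#'   `transform` (a `rigid_transform_2d`).
#' @export
misalign <- function(vol, rotation_deg, translation_mm, seed = 0L) {
  stopifnot(inherits(vol, "contrast_volume"))
  if (abs(rotation_deg) > 15) abort("|rotation_deg| must be <= 15")
  if (length(translation_mm) != 2L || any(abs(translation_mm) > 20))
    abort("|translation| must be <= 20 mm in each direction")
  tf <- rigid_transform_2d(rotation_deg, translation_mm,
                           fixed = vol$contrast, moving = vol$contrast)
  out <- vol
  for (i in seq_len(n_slices(vol)))
    out <- set_slice(out, i, apply_rigid_2d(get_slice(vol, i), tf,
                                            spacing = vol$spacing[inplane_axes(vol)]))
  list(volume = out, transform = tf)
}
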