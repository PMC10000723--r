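test_that("phantom scenes are deterministic and respect the empty spec", {
  a <- tiny_scene(seed = 1)
  b <- tiny_scene(seed = 1)
  expect_identical(a$labels, b$labels)
  expect_length(a$pathologies, 0L)
  g <- grade_from_scene(a)
  expect_setequal(g$kind, spinefs:::PATHOLOGY_KINDS)
  expect_true(all(g$gt_grade == 0L))

  c1 <- tiny_scene(seed = 2)
  expect_false(identical(a$labels, c1$labels))
})

test_that("impossible geometry is rejected", {
  expect_error(make_phantom(seed = 1, shape = c(16, 32, 3), n_vertebrae = 10),
               "cannot fit")
})

test_that("extent-graded pathologies map to the documented thresholds", {
  # half-body lesion: above one-third, below two-thirds -> grade 3
  sc <- tiny_scene(seed = 2, shape = c(64, 64, 4), pathology_spec = list(
    list(kind = "bone_marrow_abnormality", severity = 0.5)))
  ann <- sc$pathologies[[1]]
  expect_gt(ann$extent_fraction, 1 / 3)
  expect_lte(ann$extent_fraction, 2 / 3)
  expect_identical(ann$gt_grade, 3L)
  expect_identical(grade_from_scene(sc)$gt_grade[
    grade_from_scene(sc)$kind == "bone_marrow_abnormality"], 3L)

  # whole-body involvement -> grade 4
  sc4 <- tiny_scene(seed = 3, shape = c(64, 64, 4), pathology_spec = list(
    list(kind = "bone_marrow_abnormality", severity = 1.0)))
  expect_identical(sc4$pathologies[[1]]$gt_grade, 4L)

  # focal lesion under 10% -> grade 1
  sc1 <- tiny_scene(seed = 4, shape = c(64, 64, 4), pathology_spec = list(
    list(kind = "bone_marrow_abnormality", severity = 0.05)))
  expect_identical(sc1$pathologies[[1]]$gt_grade, 1L)
})

test_that("grade mapping is monotone in extent and edema decides fracture acuity", {
  grades <- vapply(c(0.03, 0.2, 0.5, 0.9), function(e)
    spinefs:::grade_for_kind("bone_marrow_abnormality", extent = e), integer(1))
  expect_identical(grades, c(1L, 2L, 3L, 4L))
  expect_false(is.unsorted(grades))

  acute <- tiny_scene(seed = 5, pathology_spec = list(
    list(kind = "vertebral_fracture", severity = 1)))
  chronic <- tiny_scene(seed = 5, pathology_spec = list(
    list(kind = "vertebral_fracture", severity = 2)))
  expect_identical(acute$pathologies[[1]]$gt_grade, 1L)
  expect_true(acute$pathologies[[1]]$edema)
  expect_identical(chronic$pathologies[[1]]$gt_grade, 2L)
  expect_false(chronic$pathologies[[1]]$edema)
})

test_that("pathology masks stay inside the volume and annotations are valid", {
  spec <- list(list(kind = "spondylodiscitis_expansion", severity = 0.4),
               list(kind = "cord_lesion", severity = 0.5),
               list(kind = "paravertebral_abnormality", severity = 2))
  sc <- tiny_scene(seed = 6, shape = c(64, 64, 6), pathology_spec = spec)
  expect_length(sc$pathologies, 3L)
  for (ann in sc$pathologies) {
    expect_identical(dim(ann$mask), sc$shape)
    expect_gt(sum(ann$mask), 0)
    expect_true(ann$gt_grade %in% spinefs:::GRADE_RANGE[[ann$kind]])
  }
  expect_identical(sc$pathologies[[3]]$gt_grade, 2L) # hematoma category
})

test_that("rendered contrasts obey the fat-suppression contract", {
  sc <- tiny_scene(seed = 1, shape = c(64, 64, 4))
  tr <- rendered_triple(sc, noise_sd = 0)
  fat <- sc$labels == spinefs:::PHANTOM_LABELS[["fat"]]
  csf <- sc$labels == spinefs:::PHANTOM_LABELS[["csf"]]
  # fat-dominant voxels: T2FS well below a tenth of T2
  expect_lt(median(tr$t2fs$data[fat]), 0.1 * median(tr$t2$data[fat]))
  # fluid-dominant voxels: suppression changes nothing at zero noise
  expect_equal(tr$t2fs$data[csf], tr$t2$data[csf])
  # edema bright on T2/T2FS, darker on T1
  scp <- tiny_scene(seed = 2, shape = c(64, 64, 4), pathology_spec = list(
    list(kind = "bone_marrow_abnormality", severity = 0.4)))
  trp <- rendered_triple(scp, noise_sd = 0)
  m <- scp$pathologies[[1]]$mask
  vert <- scp$labels == 1L & !m
  expect_gt(mean(trp$t2fs$data[m]), mean(trp$t2fs$data[vert]))
  expect_lt(mean(trp$t1$data[m]), mean(trp$t1$data[vert]))
})

test_that("render_contrast is deterministic and validates arguments", {
  sc <- tiny_scene(seed = 1)
  a <- render_contrast(sc, "T2", noise_sd = 0.05, seed = 3)
  b <- render_contrast(sc, "T2", noise_sd = 0.05, seed = 3)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data,
                         render_contrast(sc, "T2", 0.05, seed = 4)$data))
  expect_error(render_contrast(sc, "FLAIR"), "unknown contrast")
  expect_error(render_contrast(sc, "T1", noise_sd = -1), "noise_sd")
})

test_that("misalign stores the exact transform and round-trips", {
  sc <- tiny_scene(seed = 1, shape = c(64, 64, 3))
  t2 <- rendered_triple(sc, noise_sd = 0)$t2
  # smooth the piecewise-constant phantom so the round-trip oracle probes
  # interpolation fidelity rather than edge blurring
  for (i in 1:3) t2$data[, , i] <- spinefs:::blur_matrix(t2$data[, , i], 1.5)
  # identity transform reproduces the input
  id <- misalign(t2, 0, c(0, 0))
  expect_equal(id$volume$data, t2$data, tolerance = 1e-10)
  # bookkeeping
  mis <- misalign(t2, 5, c(3, -2))
  expect_equal(mis$transform$rotation, 5)
  expect_equal(mis$transform$translation, c(3, -2))
  # inverse recovers the original within 2% of dynamic range (interior)
  inv <- spinefs:::apply_rigid_2d(spinefs:::get_slice(mis$volume, 2),
                                  invert_rigid_2d(mis$transform))
  orig <- spinefs:::get_slice(t2, 2)
  interior <- 10:54
  err <- mean(abs(inv[interior, interior] - orig[interior, interior]))
  expect_lt(err, 0.02 * diff(range(orig)))
  # out-of-bounds transforms rejected
  expect_error(misalign(t2, 20, c(0, 0)), "rotation")
  expect_error(misalign(t2, 5, c(25, 0)), "translation")
})

test_that("simulated readers follow the configured error model", {
  gt <- synthetic_gt_table(50)
  # zero error: gradings identical to ground truth, kappa 1 downstream
  rec0 <- simulate_readers(gt, "synthetic_protocol", error_model = 0,
                           n_readers = 2, seed = 1)
  expect_true(all(rec0$grade == rec0$gt_grade))
  expect_equal(cohens_kappa(rec0$grade, rec0$gt_grade)$kappa, 1)
  # certain error: always an adjacent wrong grade, accuracy 0
  rec1 <- simulate_readers(gt, "two_sequence",
                           error_model = 1, n_readers = 1, seed = 1)
  expect_true(all(rec1$grade != rec1$gt_grade))
  expect_true(all(abs(rec1$grade - rec1$gt_grade) == 1L))
  expect_equal(grading_accuracy(rec1$grade, rec1$gt_grade), 0)
  # determinism and validation
  expect_identical(simulate_readers(gt, "two_sequence", seed = 9),
                   simulate_readers(gt, "two_sequence", seed = 9))
  expect_error(simulate_readers(gt, "two_sequence", error_model = 1.2),
               "probabilities")
})

test_that("marginal reader error rate converges to the configured probability", {
  gt <- synthetic_gt_table(1700) # ~10^4 gradings over six kinds
  p <- 0.25
  rec <- simulate_readers(gt, "synthetic_protocol", error_model = p,
                          n_readers = 1, seed = 11)
  n <- nrow(rec)
  ci <- p + c(-1, 1) * 3 * sqrt(p * (1 - p) / n)
  expect_gt(mean(rec$grade != rec$gt_grade), ci[1])
  expect_lt(mean(rec$grade != rec$gt_grade), ci[2])
})
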