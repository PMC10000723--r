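# Shared fixtures: tiny phantoms and preprocessed contrast triples.

tiny_scene <- function(seed = 1, shape = c(48, 48, 4), n_vertebrae = 3,
                       pathology_spec = list()) {
  make_phantom(seed = seed, shape = shape, n_vertebrae = n_vertebrae,
               pathology_spec = pathology_spec)
}

rendered_triple <- function(scene, noise_sd = 0, seed = 1, scaled = FALSE) {
  vols <- lapply(c("T1", "T2", "T2FS"), function(ct) {
    v <- render_contrast(scene, ct, noise_sd = noise_sd, seed = seed)
    if (scaled) cap_and_scale(v)$volume else v
  })
  names(vols) <- c("t1", "t2", "t2fs")
  vols
}

# Ground-truth grade table for simulated reader studies: a mix of graded
# findings over many phantom datasets, built without rendering voxels.
synthetic_gt_table <- function(n_datasets = 100, seed = 7) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_datasets), function(i) {
      kinds <- spinefs:::PATHOLOGY_KINDS
      grades <- vapply(kinds, function(k) {
        rng <- spinefs:::GRADE_RANGE[[k]]
        sample(rng, 1, prob = c(0.5, rep(0.5 / (length(rng) - 1),
                                         length(rng) - 1)))
      }, integer(1))
      tibble::tibble(dataset_id = sprintf("d%03d", i), kind = kinds,
                     gt_grade = unname(grades))
    })
    dplyr::bind_rows(rows)
  })
}
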