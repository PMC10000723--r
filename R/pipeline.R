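#' Generate a phantom training corpus of paired slices
#'
#' Draws phantom scenes with a random pathology mix (0-3 pathologies per
#' scene), renders the three contrasts with mild acquisition noise, applies
#' [cap_and_scale()] per volume, and pools the sagittal slices of all scenes
#' into one `paired_slice_dataset`.
#'
#' @param n_slices Total number of slice pairs to return.
#' @param shape Voxel shape of each phantom volume.
#' @param n_vertebrae Vertebral bodies per phantom.
#' @param noise_sd Acquisition noise level passed to [render_contrast()].
#' @param seed Integer seed.
#' @return A `paired_slice_dataset` of `n_slices` rows, plus an attribute
#'   `scenes` holding the generating `phantom_scene`s.
#' @export
phantom_slice_dataset <- function(n_slices = 200L, shape = c(64, 64, 10),
                                  n_vertebrae = 4L, noise_sd = 0.02,
                                  seed = 1L) {
  per <- shape[3]
  n_scenes <- ceiling(n_slices / per)
  scenes <- vector("list", n_scenes)
  parts <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sseed <- derive_seed(seed, "scene", i)
    spec <- with_seed_(derive_seed(sseed, "mix"), random_pathology_mix())
    sc <- make_phantom(seed = sseed, shape = shape, n_vertebrae = n_vertebrae,
                       pathology_spec = spec)
    scenes[[i]] <- sc
    vols <- lapply(c("T1", "T2", "T2FS"), function(ct)
      cap_and_scale(render_contrast(sc, ct, noise_sd = noise_sd,
                                    seed = sseed))$volume)
    parts[[i]] <- extract_sagittal_slices(vols[[1]], vols[[2]], vols[[3]],
                                          dataset_id = sprintf("ds%03d", i))
  }
  ds <- dplyr::bind_rows(parts)[seq_len(n_slices), ]
  class(ds) <- c("paired_slice_dataset", class(tibble::tibble()))
  attr(ds, "scenes") <- scenes
  ds
}

# Random pathology mix: 0-3 pathologies of distinct kinds with plausible
# severities. Uses the current RNG stream.
random_pathology_mix <- function() {
  k <- sample(0:3, 1, prob = c(0.2, 0.35, 0.3, 0.15))
  if (k == 0L) return(list())
  kinds <- sample(PATHOLOGY_KINDS, k)
  lapply(kinds, function(kind) {
    sev <- switch(kind,
      bone_marrow_abnormality = runif(1, 0.05, 0.95),
      spondylodiscitis_expansion = runif(1, 0.1, 0.9),
      vertebral_fracture = sample(1:2, 1),
      paravertebral_abnormality = sample(1:3, 1),
      0.5)
    list(kind = kind, severity = sev)
  })
}

#' Pipeline configuration
#'
#' One global seed fans out to per-stage seeds via [derive_seed()], so no
#' stage's random stream depends on another's. Round-trips through YAML.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Global integer seed.
#' @param n_train_slices,n_test_datasets Corpus sizes.
#' @param shape Phantom voxel shape.
#' @param n_vertebrae Vertebral bodies per phantom.
#' @param noise_sd Acquisition noise.
#' @param epochs,batch_size,base_channels,depth,lambda_adv Training settings
#'   (see [train_config()]).
#' @param n_readers Simulated readers per protocol.
#' @param misalign_t1 Misalign the T1 volume and recover it by
#'   [rigid_register()] during preprocessing (exercises registration; off by
#'   default since phantom contrasts are generated co-registered).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_train_slices = 200L,
                            n_test_datasets = 20L, shape = c(64, 64, 10),
                            n_vertebrae = 4L, noise_sd = 0.02, epochs = 25L,
                            batch_size = 8L, base_channels = 16L, depth = 3L,
                            lambda_adv = 50, n_readers = 2L,
                            misalign_t1 = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_train_slices = as.integer(n_train_slices),
              n_test_datasets = as.integer(n_test_datasets),
              shape = as.integer(shape), n_vertebrae = as.integer(n_vertebrae),
              noise_sd = noise_sd, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              base_channels = as.integer(base_channels),
              depth = as.integer(depth), lambda_adv = lambda_adv,
              n_readers = as.integer(n_readers),
              misalign_t1 = isTRUE(misalign_t1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
save_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg)[sort(names(unclass(cfg)))])

stage_done <- function(dir, files, hash) {
  sidecar <- file.path(dir, ".stage_hash")
  all(file.exists(file.path(dir, files))) && file.exists(sidecar) &&
    identical(readLines(sidecar, warn = FALSE)[1], hash)
}

mark_stage <- function(dir, hash) writeLines(hash, file.path(dir, ".stage_hash"))

#' Run the phantom-to-report pipeline end to end
#'
#' simulate -> preprocess -> train -> synthesize -> simulate readers ->
#' evaluate, each stage writing its artifacts under `out_dir` tagged with the
#' config hash and skipped on rerun when its outputs already match the
#' current configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the `agreement_report`, the synthesis
#'   quality table, the training history and the path of the report JSON.
#' @export
run_end_to_end <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  h <- config_hash(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  dir_of <- function(sub) {
    d <- file.path(cfg$out_dir, sub)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(code), error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
    say("stage %-12s %6.1f s  (seed root %d)", name,
        proc.time()[["elapsed"]] - t0, cfg$seed)
    r
  }
  save_pipeline_config(cfg, file.path(dir_of(""), "config.yaml"))

  # -- simulate ---------------------------------------------------------------
  sim_dir <- dir_of("sim")
  sim_files <- c("train_slices.rds", "test_scenes.rds", "gradings_gt.csv")
  if (!stage_done(sim_dir, sim_files, h)) {
    t_stage("simulate", {
      train_ds <- phantom_slice_dataset(cfg$n_train_slices, cfg$shape,
                                        cfg$n_vertebrae, cfg$noise_sd,
                                        seed = derive_seed(cfg$seed, "train-data"))
      saveRDS(train_ds, file.path(sim_dir, "train_slices.rds"))
      test <- lapply(seq_len(cfg$n_test_datasets), function(i) {
        sseed <- derive_seed(cfg$seed, "test-scene", i)
        spec <- with_seed_(derive_seed(sseed, "mix"), random_pathology_mix())
        make_phantom(seed = sseed, shape = cfg$shape,
                     n_vertebrae = cfg$n_vertebrae, pathology_spec = spec)
      })
      saveRDS(test, file.path(sim_dir, "test_scenes.rds"))
      gt <- dplyr::bind_rows(lapply(seq_along(test), function(i)
        dplyr::mutate(grade_from_scene(test[[i]]),
                      dataset_id = sprintf("test%03d", i), .before = 1)))
      utils::write.csv(gt, file.path(sim_dir, "gradings_gt.csv"),
                       row.names = FALSE)
      mark_stage(sim_dir, h)
    })
  } else say("stage %-12s cached", "simulate")

  # -- preprocess -------------------------------------------------------------
  prep_dir <- dir_of("prep")
  if (!stage_done(prep_dir, "test_pairs.rds", h)) {
    t_stage("preprocess", {
      test <- readRDS(file.path(sim_dir, "test_scenes.rds"))
      pairs <- lapply(seq_along(test), function(i) {
        sc <- test[[i]]
        t1 <- render_contrast(sc, "T1", cfg$noise_sd, seed = sc$seed)
        t2 <- render_contrast(sc, "T2", cfg$noise_sd, seed = sc$seed)
        fs <- render_contrast(sc, "T2FS", cfg$noise_sd, seed = sc$seed)
        if (cfg$misalign_t1) {
          mis <- misalign(t1, rotation_deg = 4, translation_mm = c(2, -3))
          t1 <- rigid_register(mis$volume, t2)$volume
        }
        t1 <- resample_inplane(t1, 1); t2 <- resample_inplane(t2, 1)
        fs <- resample_inplane(fs, 1)
        cs1 <- cap_and_scale(t1); cs2 <- cap_and_scale(t2)
        csf <- cap_and_scale(fs)
        list(slices = extract_sagittal_slices(cs1$volume, cs2$volume,
                                              csf$volume,
                                              dataset_id = sprintf("test%03d", i)),
             t1 = cs1$volume, t2 = cs2$volume, t2fs = csf$volume,
             norm = csf$record)
      })
      saveRDS(pairs, file.path(prep_dir, "test_pairs.rds"))
      mark_stage(prep_dir, h)
    })
  } else say("stage %-12s cached", "preprocess")

  # -- train ------------------------------------------------------------------
  train_dir <- dir_of("train")
  if (!stage_done(train_dir, c("checkpoint.rds", "history.csv"), h)) {
    t_stage("train", {
      train_ds <- readRDS(file.path(sim_dir, "train_slices.rds"))
      tc <- train_config(
        lambda_adv = cfg$lambda_adv, epochs = cfg$epochs,
        batch_size = cfg$batch_size, seed = derive_seed(cfg$seed, "train"),
        generator = generator_spec(cfg$depth, cfg$base_channels),
        discriminator = discriminator_spec(base_channels = cfg$base_channels))
      fit <- train(train_ds, tc, verbose = verbose)
      save_checkpoint(fit$checkpoint, file.path(train_dir, "checkpoint.rds"))
      utils::write.csv(fit$history, file.path(train_dir, "history.csv"),
                       row.names = FALSE)
      mark_stage(train_dir, h)
    })
  } else say("stage %-12s cached", "train")

  # -- synthesize -------------------------------------------------------------
  synth_dir <- dir_of("synth")
  if (!stage_done(synth_dir, "quality.csv", h)) {
    t_stage("synthesize", {
      ck <- load_checkpoint(file.path(train_dir, "checkpoint.rds"))
      pairs <- readRDS(file.path(prep_dir, "test_pairs.rds"))
      qual <- dplyr::bind_rows(lapply(seq_along(pairs), function(i) {
        pr <- pairs[[i]]
        res <- synthesize_volume(pr$t1, pr$t2, ck, reference = pr$t2fs,
                                 normalization = pr$norm)
        write_contrast_volume(res$volume,
                              file.path(synth_dir,
                                        sprintf("test%03d_synth_t2fs.nii.gz", i)))
        tibble::tibble(dataset_id = sprintf("test%03d", i),
                       mean_ssim = res$mean_ssim)
      }))
      utils::write.csv(qual, file.path(synth_dir, "quality.csv"),
                       row.names = FALSE)
      mark_stage(synth_dir, h)
    })
  } else say("stage %-12s cached", "synthesize")

  # -- simulate readers -------------------------------------------------------
  read_dir <- dir_of("readers")
  if (!stage_done(read_dir, "gradings.csv", h)) {
    t_stage("readers", {
      gt <- tibble::as_tibble(utils::read.csv(file.path(sim_dir, "gradings_gt.csv")))
      rec <- dplyr::bind_rows(
        simulate_readers(gt, "two_sequence", n_readers = cfg$n_readers,
                         seed = derive_seed(cfg$seed, "readers")),
        simulate_readers(gt, "synthetic_protocol", n_readers = cfg$n_readers,
                         seed = derive_seed(cfg$seed, "readers")))
      utils::write.csv(rec, file.path(read_dir, "gradings.csv"),
                       row.names = FALSE)
      mark_stage(read_dir, h)
    })
  } else say("stage %-12s cached", "readers")

  # -- evaluate ---------------------------------------------------------------
  report_path <- file.path(cfg$out_dir, "report.json")
  report <- t_stage("evaluate", {
    rec <- tibble::as_tibble(utils::read.csv(file.path(read_dir, "gradings.csv")))
    rep <- summarize_study(rec)
    write_agreement_report(rep, json_path = report_path,
                           csv_path = file.path(cfg$out_dir, "report.csv"))
    rep
  })

  invisible(list(
    report = report,
    quality = tibble::as_tibble(utils::read.csv(file.path(synth_dir, "quality.csv"))),
    history = tibble::as_tibble(utils::read.csv(file.path(train_dir, "history.csv"))),
    report_path = report_path
  ))
}
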