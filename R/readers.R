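#' Default reader error models per protocol
#'
#' Misgrade probabilities per pathology kind. Under the two-sequence protocol
#' (T1-w + non-fs T2-w only) the fluid-sensitive findings — marrow edema,
#' spondylodiscitis, Modic type-1 changes, cord lesions, paravertebral
#' edema — are harder to call, so their error probability is higher; adding
#' the (synthetic) fat-saturated contrast restores fluid conspicuity and
#' drops all errors to a common low rate.
#'
#' @param protocol `"two_sequence"` or `"synthetic_protocol"`.
#' @return Named numeric vector of misgrade probabilities per kind.
#' @export
default_error_model <- function(protocol = c("two_sequence", "synthetic_protocol")) {
  protocol <- match.arg(protocol)
  fluid_sensitive <- c("bone_marrow_abnormality", "spondylodiscitis_expansion",
                       "modic_type1", "cord_lesion", "paravertebral_abnormality")
  p <- setNames(rep(0.10, length(PATHOLOGY_KINDS)), PATHOLOGY_KINDS)
  if (protocol == "two_sequence") {
    p[fluid_sensitive] <- 0.30
    p["vertebral_fracture"] <- 0.15
  }
  p
}

#' Simulate reader gradings under a protocol
#'
#' Each reader misgrades a finding with the kind-specific probability of the
#' error model; a misgrade moves the grade to an adjacent legal grade
#' (up/down with equal probability, forced inward at range boundaries), the
#' plausible clinical confusion. Deterministic given `seed`.
#'
#' @param gt Tibble of ground-truth grades with columns `dataset_id`, `kind`
#'   (see [pathology_grade_ranges()]) and `gt_grade`.
#' @param protocol `"two_sequence"` or `"synthetic_protocol"`.
#' @param error_model Named numeric vector of per-kind misgrade
#'   probabilities in `[0, 1]`, or a single probability for all kinds.
#'   Defaults to [default_error_model()] for the protocol.
#' @param n_readers Number of independent readers (default 2).
#' @param seed Integer seed.
#' @return A tibble of grading records: `dataset_id`, `reader_id`,
#'   `protocol`, `kind`, `grade`, `gt_grade`.
#' @export
simulate_readers <- function(gt, protocol = c("two_sequence", "synthetic_protocol"),
                             error_model = NULL, n_readers = 2L, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(is.data.frame(gt),
            all(c("dataset_id", "kind", "gt_grade") %in% names(gt)))
  if (is.null(error_model)) error_model <- default_error_model(protocol)
  if (length(error_model) == 1L && is.null(names(error_model)))
    error_model <- setNames(rep(error_model, length(PATHOLOGY_KINDS)),
                            PATHOLOGY_KINDS)
  if (any(error_model < 0 | error_model > 1))
    abort("misgrade probabilities must lie in [0, 1]")
  if (!all(gt$kind %in% PATHOLOGY_KINDS)) abort("unknown pathology kind in `gt`")

  with_seed_(derive_seed(seed, paste0("readers-", protocol)), {
    out <- lapply(seq_len(n_readers), function(r) {
      p_err <- error_model[gt$kind]
      miss <- runif(nrow(gt)) < p_err
      up <- runif(nrow(gt)) < 0.5
      grade <- gt$gt_grade
      hi <- vapply(gt$kind, function(k) max(GRADE_RANGE[[k]]), integer(1))
      step <- ifelse(up, 1L, -1L)
      cand <- grade + step
      cand <- ifelse(cand < 0L, grade + 1L, cand)
      cand <- ifelse(cand > hi, grade - 1L, cand)
      tibble::tibble(
        dataset_id = gt$dataset_id, reader_id = paste0("reader", r),
        protocol = protocol, kind = gt$kind,
        grade = ifelse(miss, cand, grade), gt_grade = gt$gt_grade
      )
    })
    dplyr::bind_rows(out)
  })
}
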