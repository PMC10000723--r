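#' Published reader-study agreement reference
#'
#' Per-pathology agreement statistics from a published two-reader spine MRI
#' grading study (101 multicenter test datasets, six pathologies): Cohen's
#' kappa against consensus ground truth under the two-sequence protocol
#' (T1-w + non-fs T2-w only) and under the synthetic protocol (with an
#' additional synthetic T2-w fs contrast), with 95% CI bounds, plus grading
#' accuracies in percent. These values serve as reference inputs for the
#' aggregation layer and for benchmarking simulated reader studies.
#'
#' @return A tibble with one row per pathology kind: `kind`, `n_gt`,
#'   `kappa_two_sequence` (+ `_low`/`_high` CI bounds), `kappa_synthetic`
#'   (+ CI bounds), `accuracy_two_sequence`, `accuracy_synthetic`.
#' @export
#' @examples
#' reader_study_reference()
reader_study_reference <- function() {
  path <- system.file("extdata", "reader_study_reference.csv",
                      package = "spinefs", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reader_study_reference
#' @return `reference_kappa_pairs()` returns the kappa columns reshaped for
#'   [aggregate_kappa_pairs()]: `kind`, `two_sequence`, `synthetic_protocol`.
#' @export
reference_kappa_pairs <- function() {
  ref <- reader_study_reference()
  tibble::tibble(kind = ref$kind, two_sequence = ref$kappa_two_sequence,
                 synthetic_protocol = ref$kappa_synthetic)
}
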