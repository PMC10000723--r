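#' Summarize a grading study into an agreement report
#'
#' For every pathology kind and protocol, both readers' gradings are pooled
#' as independent rows and compared against ground truth: Cohen's kappa with
#' 95% CI ([cohens_kappa()]) and exact-match accuracy. Protocols are then
#' compared by a Wilcoxon signed-rank test across the pathology-wise kappa
#' pairs ([wilcoxon_signed_rank()]) and, per pathology, by McNemar's test on
#' the paired correctness indicators ([mcnemar_test()]).
#'
#' @param records Tibble of grading records with columns `dataset_id`,
#'   `reader_id`, `protocol` (`"two_sequence"`, `"synthetic_protocol"`, and
#'   optionally `"ground_truth"` rows), `kind`, `grade`, and — unless
#'   ground-truth rows are supplied — `gt_grade`.
#' @return An `agreement_report`: list with `per_pathology` (tibble of kind,
#'   protocol, n, kappa, conf_low, conf_high, accuracy), `mean_kappa` (named
#'   vector over protocols), `wilcoxon` (z, p across kappa pairs), `mcnemar`
#'   (tibble of kind, b, c, p_value).
#' @export
summarize_study <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dataset_id", "reader_id", "protocol", "kind", "grade")
                %in% names(records)))
  protocols <- c("two_sequence", "synthetic_protocol")
  if (!"gt_grade" %in% names(records) || anyNA(records$gt_grade)) {
    gt <- dplyr::filter(records, .data$protocol == "ground_truth")
    if (nrow(gt) == 0L) abort("no ground truth: supply `gt_grade` or ground_truth rows")
    gt <- dplyr::distinct(dplyr::select(gt, "dataset_id", "kind",
                                        gt_grade = "grade"))
    records <- dplyr::left_join(
      dplyr::select(dplyr::filter(records, .data$protocol != "ground_truth"),
                    -dplyr::any_of("gt_grade")),
      gt, by = c("dataset_id", "kind"))
  }
  if (anyNA(records$gt_grade)) {
    bad <- unique(records$dataset_id[is.na(records$gt_grade)])
    abort(paste0("missing ground truth for datasets: ",
                 paste(bad, collapse = ", ")))
  }
  records <- dplyr::filter(records, .data$protocol %in% protocols)

  per <- records |>
    dplyr::group_by(.data$kind, .data$protocol) |>
    dplyr::group_modify(function(d, key) {
      kp <- cohens_kappa(d$grade, d$gt_grade)
      tibble::tibble(n = nrow(d), kappa = kp$kappa, conf_low = kp$conf_low,
                     conf_high = kp$conf_high,
                     accuracy = grading_accuracy(d$grade, d$gt_grade))
    }) |>
    dplyr::ungroup()

  pairs <- tidyr::pivot_wider(dplyr::select(per, "kind", "protocol", "kappa"),
                              names_from = "protocol", values_from = "kappa")
  agg <- aggregate_kappa_pairs(pairs)

  wide <- records |>
    dplyr::mutate(correct = .data$grade == .data$gt_grade) |>
    dplyr::select("dataset_id", "reader_id", "kind", "protocol", "correct") |>
    tidyr::pivot_wider(names_from = "protocol", values_from = "correct")
  mcn <- wide |>
    dplyr::group_by(.data$kind) |>
    dplyr::group_modify(function(d, key) {
      mt <- mcnemar_test(d$two_sequence, d$synthetic_protocol)
      tibble::tibble(b = mt$b, c = mt$c, p_value = mt$p_value,
                     method = mt$method)
    }) |>
    dplyr::ungroup()

  structure(list(per_pathology = per, mean_kappa = agg$mean_kappa,
                 wilcoxon = agg$wilcoxon, mcnemar = mcn),
            class = "agreement_report")
}

#' Aggregate pathology-wise kappa pairs across protocols
#'
#' The summary layer of [summarize_study()], usable directly on a table of
#' published or precomputed kappa coefficients: per-protocol mean kappa and
#' the Wilcoxon signed-rank comparison of the paired coefficients.
#'
#' @param pairs Tibble with columns `kind`, `two_sequence`,
#'   `synthetic_protocol` holding one kappa per pathology and protocol.
#' @return List with `mean_kappa` (named numeric) and `wilcoxon` (list with
#'   `statistic`, `z`, `p_value`, `n_used`, `undefined`).
#' @export
#' @examples
#' pairs <- tibble::tibble(kind = c("a", "b", "c"),
#'                         two_sequence = c(0.4, 0.5, 0.6),
#'                         synthetic_protocol = c(0.5, 0.7, 0.6))
#' aggregate_kappa_pairs(pairs)
aggregate_kappa_pairs <- function(pairs) {
  stopifnot(all(c("two_sequence", "synthetic_protocol") %in% names(pairs)))
  mean_kappa <- c(two_sequence = mean(pairs$two_sequence),
                  synthetic_protocol = mean(pairs$synthetic_protocol))
  wil <- wilcoxon_signed_rank(pairs$synthetic_protocol, pairs$two_sequence)
  list(mean_kappa = mean_kappa, wilcoxon = wil)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  mean kappa: two_sequence %.3f, synthetic_protocol %.3f\n",
              x$mean_kappa[["two_sequence"]],
              x$mean_kappa[["synthetic_protocol"]]))
  if (!isTRUE(x$wilcoxon$undefined))
    cat(sprintf("  Wilcoxon signed-rank: z = %.3f, p = %.3f\n",
                x$wilcoxon$z, x$wilcoxon$p_value))
  else cat("  Wilcoxon signed-rank: undefined (all kappa pairs equal)\n")
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::left_join(x$per_pathology,
                   dplyr::select(x$mcnemar, "kind", mcnemar_p = "p_value"),
                   by = "kind")
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    mean_kappa_two_sequence = x$mean_kappa[["two_sequence"]],
    mean_kappa_synthetic = x$mean_kappa[["synthetic_protocol"]],
    wilcoxon_z = x$wilcoxon$z, wilcoxon_p = x$wilcoxon$p_value,
    n_pathologies = nrow(x$mcnemar)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$per_pathology,
                  ggplot2::aes(x = .data$kappa, y = .data$kind,
                               colour = .data$protocol)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Cohen's kappa (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write an agreement report as JSON plus a summary CSV
#'
#' @param report An `agreement_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_agreement_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      per_pathology = report$per_pathology,
      mean_kappa = as.list(report$mean_kappa),
      wilcoxon = report$wilcoxon[c("statistic", "z", "p_value", "n_used")],
      mcnemar = report$mcnemar
    ), json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(csv_path)) utils::write.csv(tidy(report), csv_path, row.names = FALSE)
  invisible(report)
}
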