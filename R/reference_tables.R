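# Bundled summary tables from a published multicentre clinical evaluation
# of a commercial five-detector chest-radiograph ensemble: per-pathology
# image-level confusion counts (500 positive / 1000 negative images per
# pathology), the per-pathology metric panel with score-based AUCs, and the
# nine-reader aided-vs-unaided outcome statistics. They serve as worked-
# example inputs and as an exact arithmetic cross-check of the metric code.

ref_path <- function(file) {
  system.file("extdata", file, package = "cxreval", mustWork = TRUE)
}

#' Bundled reference study tables
#'
#' Summary tables from a published multicentre evaluation of a commercial
#' chest-radiograph detection ensemble, bundled as plain CSV:
#' \describe{
#'   \item{`reference_confusion_counts()`}{Image-level TP/FN/FP/TN per
#'     pathology, from an enriched design with 500 ground-truth-positive and
#'     1000 ground-truth-negative images per pathology.}
#'   \item{`reference_metric_table()`}{The published per-pathology
#'     sensitivity, specificity, NPV, PPV and score-based AUC with 95%
#'     bootstrap interval. The proportion metrics follow arithmetically from
#'     the confusion counts; the AUCs do not (they require per-image
#'     scores) and are carried as published.}
#'   \item{`reference_reader_outcomes()`}{Nine-reader aided-vs-unaided
#'     outcome statistics (reading time, AUC, sensitivity, specificity):
#'     mean, SD, variance and normal-theory 95% CI half-width per
#'     condition.}
#' }
#'
#' @return A data frame (see above).
#' @export
#' @examples
#' metric_panel(reference_confusion_counts())
reference_confusion_counts <- function() {
  out <- utils::read.csv(ref_path("reference_confusion_counts.csv"),
                         stringsAsFactors = FALSE)
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' @rdname reference_confusion_counts
#' @export
reference_metric_table <- function() {
  utils::read.csv(ref_path("reference_metric_table.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_confusion_counts
#' @export
reference_reader_outcomes <- function() {
  utils::read.csv(ref_path("reference_reader_outcomes.csv"),
                  stringsAsFactors = FALSE)
}
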