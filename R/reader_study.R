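# Multi-reader multi-case (MRMC) aided-vs-unaided comparison: per-reader
# metrics, Welch t-tests per outcome, percent-change reporting, and the
# Hanley-McNeil AUC sample-size calculation.

validate_reader_records <- function(records) {
  need <- c("reader_id", "condition", "image_id", "label", "call", "time_s")
  if (!all(need %in% names(records)))
    stop_input("reader records must have columns ",
               paste(need, collapse = ", "), " (confidence optional)")
  if (!all(records$condition %in% c("aided", "unaided")))
    stop_input("condition must be 'aided' or 'unaided'")
  if (!all(records$call %in% c(0, 1)))
    stop_input("call must be binary 0/1")
  if (any(records$time_s <= 0))
    stop_input("reading times must be positive")
  invisible(records)
}

#' Per-reader sensitivity and specificity against ground truth
#'
#' Computes, per pathology, the proportion of ground-truth-positive images
#' the reader flagged (sensitivity) and the proportion of ground-truth-
#' negative images the reader left clean (specificity), then macro-averages
#' across the pathologies into the reader's summary operating point. A
#' pathology with no positive (or no negative) image among those read is
#' excluded from the macro-average with a warning.
#'
#' @param records Data frame of one reader-condition's calls: columns
#'   `image_id`, `label`, `call` (0/1).
#' @param truth Data frame of positive image-label pairs: columns
#'   `image_id`, `label`. Every image the reader saw and is absent for a
#'   label is a ground-truth negative for it.
#' @param labels Pathology labels considered.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
reader_metrics <- function(records, truth, labels = pathology_labels()) {
  need <- c("image_id", "label", "call")
  if (!all(need %in% names(records)))
    stop_input("records must have columns ", paste(need, collapse = ", "))
  sens <- spec <- rep(NA_real_, length(labels))
  for (li in seq_along(labels)) {
    lab <- labels[li]
    r <- records[records$label == lab, , drop = FALSE]
    if (nrow(r) == 0L) next
    pos <- r$image_id %in% truth$image_id[truth$label == lab]
    if (any(pos)) sens[li] <- mean(r$call[pos] == 1)
    if (any(!pos)) spec[li] <- mean(r$call[!pos] == 0)
  }
  if (anyNA(sens) || anyNA(spec))
    warning("label(s) without both classes excluded from the macro-average: ",
            paste(labels[is.na(sens) | is.na(spec)], collapse = ", "),
            call. = FALSE)
  c(sensitivity = mean(sens, na.rm = TRUE),
    specificity = mean(spec, na.rm = TRUE))
}

# Per-reader-condition summaries of all four outcomes.
reader_condition_outcomes <- function(records, truth,
                                      labels = pathology_labels()) {
  validate_reader_records(records)
  key <- paste(records$reader_id, records$condition, sep = "\r")
  groups <- split_stable(records, key)
  rows <- lapply(groups, function(g) {
    m <- suppressWarnings(reader_metrics(g, truth, labels))
    # one reading time per image (rows are per image x label)
    t_img <- tapply(g$time_s, g$image_id, function(v) v[1L])
    auc <- NA_real_
    if ("confidence" %in% names(g) && !anyNA(g$confidence)) {
      per_lab <- vapply(labels, function(lab) {
        r <- g[g$label == lab, , drop = FALSE]
        if (nrow(r) == 0L) return(NA_real_)
        pos <- r$image_id %in% truth$image_id[truth$label == lab]
        if (!any(pos) || all(pos)) return(NA_real_)
        roc_auc(r$confidence, pos)
      }, numeric(1))
      auc <- mean(per_lab, na.rm = TRUE)
    }
    data.frame(reader_id = g$reader_id[1L], condition = g$condition[1L],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               auc = auc, time_s = mean(t_img))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare one outcome between unaided and aided reading
#'
#' Welch (unequal-variance) two-sample two-sided t-test on the per-reader
#' outcome values, with descriptive statistics per condition: mean, standard
#' deviation, variance, and the normal-theory 95% CI half-width
#' `qnorm(0.975) * sd / sqrt(n)`. The percent change is relative to the
#' unaided (baseline) mean.
#'
#' @param unaided,aided Numeric vectors of per-reader outcome values (at
#'   least two readers per condition).
#' @param level Confidence level for the half-widths.
#' @return A one-row data frame with the per-condition descriptives, the t
#'   statistic, p-value, and percent change.
#' @export
#' @examples
#' compare_conditions(c(22, 23, 24), c(14, 15, 16))
compare_conditions <- function(unaided, aided, level = 0.95) {
  if (length(unaided) < 2L || length(aided) < 2L)
    stop_input("need at least two readers per condition")
  # constant outcomes (e.g. every reader perfect) leave the t statistic
  # undefined; report NA rather than fail
  tt <- tryCatch(stats::t.test(aided, unaided, var.equal = FALSE),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    unaided_mean = mean(unaided), unaided_sd = stats::sd(unaided),
    unaided_var = stats::var(unaided),
    unaided_ci = z * stats::sd(unaided) / sqrt(length(unaided)),
    aided_mean = mean(aided), aided_sd = stats::sd(aided),
    aided_var = stats::var(aided),
    aided_ci = z * stats::sd(aided) / sqrt(length(aided)),
    t = unname(tt$statistic), p_value = tt$p.value,
    pct_change = percent_change(mean(unaided), mean(aided)))
}

#' MRMC summary of an aided-vs-unaided reader study
#'
#' Builds per-reader per-condition outcomes (reading time, AUC where
#' confidences are available, sensitivity, specificity) and compares the two
#' conditions outcome by outcome with [compare_conditions()].
#'
#' @param records Data frame of reader records: `reader_id`, `condition`
#'   (`"aided"`/`"unaided"`), `image_id`, `label`, `call` (0/1), optional
#'   `confidence` in `[0, 1]`, `time_s`.
#' @param truth Positive image-label pairs (see [reader_metrics()]).
#' @param labels Pathology labels.
#' @return An `mrmc_summary` data frame, one row per outcome, with the
#'   per-reader table attached as attribute `"readers"`.
#' @export
mrmc_summary <- function(records, truth, labels = pathology_labels()) {
  per <- reader_condition_outcomes(records, truth, labels)
  outcomes <- c("time_s", "auc", "sensitivity", "specificity")
  rows <- lapply(outcomes, function(oc) {
    u <- per[[oc]][per$condition == "unaided"]
    a <- per[[oc]][per$condition == "aided"]
    u <- u[!is.na(u)]; a <- a[!is.na(a)]
    if (length(u) < 2L || length(a) < 2L) return(NULL)
    cbind(outcome = oc, compare_conditions(u, a))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "readers") <- per
  class(out) <- c("mrmc_summary", "data.frame")
  out
}

#' @export
print.mrmc_summary <- function(x, digits = 3, ...) {
  cat("MRMC aided-vs-unaided comparison (Welch t-test per outcome)\n")
  show <- as.data.frame(x)
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, digits = digits)
  print.data.frame(show, row.names = FALSE, ...)
  invisible(x)
}

#' Percent change relative to a baseline
#'
#' `100 * (treated - baseline) / baseline`, reported to two decimals. Note
#' the asymmetry: `percent_change(a, b)` and `percent_change(b, a)` are
#' consistent with inverting the ratio, not sign-flips of each other.
#'
#' @param baseline Reference value (non-zero).
#' @param treated Comparison value.
#' @return Signed percentage, rounded to 2 decimals.
#' @export
#' @examples
#' percent_change(0.759, 0.88)   # +15.94
#' percent_change(22.9, 14.7)    # -35.81
percent_change <- function(baseline, treated) {
  if (any(baseline == 0)) stop_input("percent_change: baseline must be non-zero")
  round(100 * (treated - baseline) / baseline, 2)
}

# Hanley-McNeil variance of an empirical AUC with n_pos/n_neg cases.
hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
     (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Sample size for testing an AUC against a null value
#'
#' Smallest equal per-group size `n` such that the two-sided z-test of the
#' empirical AUC against `auc_null`, using the Hanley-McNeil variance
#' (`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`) evaluated under the null and the
#' alternative, attains power at least `1 - beta`:
#' \deqn{z_{1-\alpha/2}\sqrt{V_0(n)} + z_{1-\beta}\sqrt{V_1(n)} \le A_1 - A_0.}
#'
#' @param alpha Two-sided type I error (default 0.05).
#' @param beta Type II error (default 0.20, i.e. 80% power).
#' @param auc_alt Hypothesized (alternative) AUC, default 0.80.
#' @param auc_null Null AUC, default 0.50 (chance).
#' @return List with `n_positive`, `n_negative`, `n_total`, and the achieved
#'   `power` at that size.
#' @export
#' @examples
#' sample_size_auc()  # 14 positive + 14 negative cases
sample_size_auc <- function(alpha = 0.05, beta = 0.20, auc_alt = 0.80,
                            auc_null = 0.50) {
  if (!(alpha > 0 && alpha < 1 && beta > 0 && beta < 1))
    stop_input("alpha and beta must lie in (0, 1)")
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1))
    stop_input("need 0.5 <= auc_null < auc_alt < 1")
  za <- stats::qnorm(1 - alpha / 2)
  power_at <- function(n) {
    v0 <- hanley_mcneil_var(auc_null, n, n)
    v1 <- hanley_mcneil_var(auc_alt, n, n)
    stats::pnorm((auc_alt - auc_null - za * sqrt(v0)) / sqrt(v1))
  }
  n <- 2L
  while (power_at(n) < 1 - beta) {
    n <- n + 1L
    if (n > 1e6L) stop_input("sample size search did not converge")
  }
  list(n_positive = n, n_negative = n, n_total = 2L * n,
       power = power_at(n))
}
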