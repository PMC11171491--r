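# Standalone-performance evaluation: image-level confusion classification
# against the consensus reference, the derived metric panel, Wilson score
# intervals, rank-statistic ROC AUC with a stratified bootstrap CI, and
# macro-averaging across the six pathologies.

#' Classify one image's prediction/ground-truth status for a label
#'
#' Image-level rule: an image that is ground-truth positive for the label
#' (at least one consensus finding) is a true positive when any predicted
#' box of that label overlaps any finding, and a false negative otherwise —
#' including when non-overlapping predictions are present. A ground-truth
#' negative image is a false positive when any prediction of the label is
#' present, and a true negative otherwise. This precedence (positive images
#' are never FP) is the only reading consistent with exact per-label
#' row sums `tp + fn = positives`, `fp + tn = negatives`.
#'
#' @param predictions Data frame of predicted boxes for this image.
#' @param findings Data frame of consensus findings for this image.
#' @param label Pathology label evaluated; rows of other labels are ignored.
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
classify_image <- function(predictions, findings, label) {
  p <- predictions[predictions$label == label, , drop = FALSE]
  f <- findings[findings$label == label, , drop = FALSE]
  if (nrow(f) > 0L) {
    if (nrow(p) == 0L) return("FN")
    for (i in seq_len(nrow(p))) {
      hit <- isect_area_vec(p$x_min[i], p$y_min[i], p$x_max[i], p$y_max[i],
                            f$x_min, f$y_min, f$x_max, f$y_max)
      if (any(hit > 0)) return("TP")
    }
    return("FN")
  }
  if (nrow(p) > 0L) "FP" else "TN"
}

#' Tally per-pathology confusion counts over a study
#'
#' Applies [classify_image()] to every image and label and tallies TP/FN/
#' FP/TN per pathology. When the image table carries a `cohort` column the
#' tally for each label is restricted to that label's cohort (the enriched
#' per-pathology design: a fixed number of positive and negative images per
#' pathology); otherwise every image counts for every label.
#'
#' By construction `tp + fn` equals the number of ground-truth-positive
#' images and `fp + tn` the number of ground-truth-negative images for each
#' label.
#'
#' @param predictions Data frame of predicted boxes with `image_id`, `label`
#'   and box corners (typically the output of [ensemble_vote()]).
#' @param findings Data frame of consensus findings with `image_id`, `label`
#'   and box corners ([consensus_findings()]).
#' @param images Data frame with column `image_id` and optionally `cohort`
#'   (a pathology label), or a character vector of image ids. Defines the
#'   image universe, including images with neither predictions nor findings.
#' @param labels Pathology labels tallied.
#' @return A `confusion_counts` data frame: `label`, `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(predictions, findings, images,
                             labels = pathology_labels()) {
  if (is.character(images)) images <- data.frame(image_id = images)
  if (!"image_id" %in% names(images))
    stop_input("`images` must have an image_id column")
  if (anyDuplicated(images$image_id))
    stop_input("duplicate image_id in the image table")
  has_cohort <- "cohort" %in% names(images)
  out <- data.frame(label = labels, tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  for (li in seq_along(labels)) {
    lab <- labels[li]
    ids <- if (has_cohort) images$image_id[images$cohort == lab]
           else images$image_id
    if (length(ids) == 0L) next
    f <- findings[findings$label == lab & findings$image_id %in% ids, ,
                  drop = FALSE]
    p <- predictions[predictions$label == lab & predictions$image_id %in% ids, ,
                     drop = FALSE]
    pos_ids <- unique(f$image_id)
    pred_ids <- unique(p$image_id)
    n_pos <- length(pos_ids)
    n_neg <- length(ids) - n_pos
    # positives with at least one overlapping prediction
    tp <- 0L
    cand <- intersect(pos_ids, pred_ids)
    for (id in cand) {
      cls <- classify_image(p[p$image_id == id, , drop = FALSE],
                            f[f$image_id == id, , drop = FALSE], lab)
      if (cls == "TP") tp <- tp + 1L
    }
    fp <- length(setdiff(pred_ids, pos_ids))
    out$tp[li] <- tp
    out$fn[li] <- n_pos - tp
    out$fp[li] <- fp
    out$tn[li] <- n_neg - fp
  }
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Image-level confusion counts (per pathology)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Derived metric panel from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive value `tp/(tp+fp)` and `tn/(tn+fn)`, and the error
#' rates `fpr = fp/(fp+tn)`, `fnr = fn/(fn+tp)`, per pathology, with Wilson
#' score 95% intervals for the four proportions. A metric whose denominator
#' is zero is reported as `NA` (undefined, not coerced to 0 or 1) with a
#' warning. The identities `sensitivity + fnr = 1` and
#' `specificity + fpr = 1` hold exactly.
#'
#' @param counts A `confusion_counts` data frame (or any data frame with
#'   columns `label`, `tp`, `fn`, `fp`, `tn`).
#' @param level Confidence level for the Wilson intervals.
#' @param ci Logical: attach Wilson interval columns (`*_lo`, `*_hi`)?
#' @return A `metric_panel` data frame, one row per pathology.
#' @export
#' @examples
#' cc <- data.frame(label = "pleural_effusion", tp = 486, fn = 14,
#'                  fp = 130, tn = 870)
#' metric_panel(cc)  # sensitivity 0.972, specificity 0.87
metric_panel <- function(counts, level = 0.95, ci = TRUE) {
  need <- c("label", "tp", "fn", "fp", "tn")
  if (!all(need %in% names(counts)))
    stop_input("counts must have columns ", paste(need, collapse = ", "))
  if (any(counts[c("tp", "fn", "fp", "tn")] < 0))
    stop_input("confusion counts must be non-negative")
  safe_prop <- function(num, den, what) {
    p <- ifelse(den > 0, num / den, NA_real_)
    if (anyNA(p))
      warning(what, " undefined (zero denominator) for label(s): ",
              paste(counts$label[is.na(p)], collapse = ", "), call. = FALSE)
    p
  }
  out <- data.frame(
    label = counts$label,
    sensitivity = safe_prop(counts$tp, counts$tp + counts$fn, "sensitivity"),
    specificity = safe_prop(counts$tn, counts$tn + counts$fp, "specificity"),
    ppv = safe_prop(counts$tp, counts$tp + counts$fp, "PPV"),
    npv = safe_prop(counts$tn, counts$tn + counts$fn, "NPV"))
  out$fpr <- 1 - out$specificity
  out$fnr <- 1 - out$sensitivity
  if (ci) {
    add_ci <- function(num, den, prefix) {
      lo <- hi <- rep(NA_real_, nrow(out))
      ok <- den > 0
      if (any(ok)) {
        w <- rbind(wilson_ci(num[ok], den[ok], level = level))
        lo[ok] <- w[, 1L]; hi[ok] <- w[, 2L]
      }
      out[[paste0(prefix, "_lo")]] <<- lo
      out[[paste0(prefix, "_hi")]] <<- hi
    }
    add_ci(counts$tp, counts$tp + counts$fn, "sensitivity")
    add_ci(counts$tn, counts$tn + counts$fp, "specificity")
    add_ci(counts$tp, counts$tp + counts$fp, "ppv")
    add_ci(counts$tn, counts$tn + counts$fn, "npv")
  }
  class(out) <- c("metric_panel", "data.frame")
  out
}

#' @export
print.metric_panel <- function(x, digits = 4, ...) {
  cat("Per-pathology performance metrics\n")
  show <- x[c("label", "sensitivity", "specificity", "ppv", "npv",
              "fpr", "fnr")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], round, digits = digits)
  print.data.frame(show, row.names = FALSE, ...)
  if ("sensitivity_lo" %in% names(x))
    cat("(Wilson score intervals available in columns *_lo / *_hi)\n")
  invisible(x)
}

#' @export
summary.metric_panel <- function(object, ...) {
  num <- c("sensitivity", "specificity", "ppv", "npv", "fpr", "fnr")
  means <- vapply(num, function(m) {
    v <- stats::setNames(object[[m]], object$label)
    tryCatch(macro_average(v), error = function(e) NA_real_)
  }, numeric(1))
  structure(means, class = "summary.metric_panel")
}

#' @export
print.summary.metric_panel <- function(x, ...) {
  cat("Macro-averaged metrics across pathologies\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' Score-based confidence interval for a proportion, with better small-sample
#' and boundary behaviour than the Wald interval: the interval always lies in
#' `[0, 1]`, attains exactly 0 or 1 at the boundaries (`successes` 0 or `n`),
#' and contains the point estimate. Vectorised over `successes`/`n`.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level (default 0.95, z = 1.959964).
#' @return A two-column matrix `lo`, `hi` (a single row drops to a named
#'   vector of length 2).
#' @export
#' @examples
#' wilson_ci(486, 500)
wilson_ci <- function(successes, n, level = 0.95) {
  if (any(n < 1)) stop_input("wilson_ci: n must be >= 1")
  if (any(successes < 0 | successes > n))
    stop_input("wilson_ci: need 0 <= successes <= n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- cbind(lo = pmax(0, centre - hw), hi = pmin(1, centre + hw))
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Rank-statistic area under the ROC curve
#'
#' AUC as the probability that a randomly chosen positive case receives a
#' higher score than a randomly chosen negative case, with ties counted one
#' half (the Mann-Whitney statistic). Equals the trapezoidal area under the
#' empirical ROC curve, and is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores (higher = more suspicious).
#' @param labels Logical (or 0/1) case status; needs at least one positive
#'   and one negative.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop_input("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels))
    stop_input("scores/labels contain NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop_input("roc_auc needs at least one positive and one negative case")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval of `B` bootstrap replicates of [roc_auc()], resampling
#' cases with replacement within each class (stratified: every replicate
#' keeps the original number of positives and negatives, so no resample is
#' degenerate). Deterministic for a given `seed`; the caller's RNG state is
#' left untouched.
#'
#' @inheritParams roc_auc
#' @param B Number of bootstrap replicates (default 2000).
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return Named vector `c(lo, hi)` with the point estimate attached as
#'   attribute `"auc"`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000L, level = 0.95,
                             seed = NULL) {
  if (B < 1L) stop_input("B must be >= 1")
  labels <- as.logical(labels)
  point <- roc_auc(scores, labels)  # validates inputs
  pos <- which(labels); neg <- which(!labels)
  np <- length(pos); nn <- length(neg)
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- c(sample(pos, np, replace = TRUE), sample(neg, nn, replace = TRUE))
      roc_auc(scores[i], labels[i])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE)
  structure(c(lo = q[1L], hi = q[2L]), auc = point)
}

#' Unweighted macro-average across the pathology classes
#'
#' Aggregate per-pathology metrics into a study-level figure as the
#' unweighted arithmetic mean across all six classes; every label must be
#' present.
#'
#' @param per_label_values Named numeric vector keyed by pathology label.
#' @param labels The required label set.
#' @return The mean value.
#' @export
#' @examples
#' sens <- c(consolidation = 0.93, pleural_effusion = 0.972,
#'           pneumothorax = 0.976, acute_pulmonary_edema = 0.942,
#'           cardiomegaly = 0.978, pulmonary_nodule = 0.988)
#' macro_average(sens)  # 0.964...
macro_average <- function(per_label_values, labels = pathology_labels()) {
  miss <- setdiff(labels, names(per_label_values))
  if (length(miss))
    stop_input("macro_average: missing label(s): ", paste(miss, collapse = ", "))
  mean(per_label_values[labels])
}
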