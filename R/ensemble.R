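# Majority-vote ensembling of several object detectors.
#
# Each detector emits scored, labelled boxes. The ensemble keeps a finding
# only when boxes of the same pathology from enough distinct detectors form
# a connected overlap chain, and then reports the single highest-scoring box
# of that chain. A per-pathology score threshold is applied last.

# Validate a detections data.frame. Required columns:
# model_id, label, x_min, y_min, x_max, y_max, score (image_id optional).
validate_detections <- function(det, n_models = NULL, labels = NULL) {
  need <- c("model_id", "label", "score")
  if (!all(need %in% names(det)))
    stop_input("detections must have columns ", paste(need, collapse = ", "),
               " plus box corners")
  validate_box_df(det, "detections")
  if (anyNA(det$score) || any(det$score < 0 | det$score > 1))
    stop_input("detection scores must lie in [0, 1]")
  if (!is.null(n_models)) {
    bad <- !(det$model_id %in% seq_len(n_models))
    if (any(bad))
      stop_input("detection model_id outside 1..", n_models,
                 " (row ", which(bad)[1L], ")")
  }
  if (!is.null(labels)) {
    bad <- !(det$label %in% labels)
    if (any(bad))
      stop_input("unknown pathology label '", det$label[which(bad)[1L]], "'")
  }
  invisible(det)
}

#' Connected overlap components among same-label detections
#'
#' Groups detections of one pathology into connected components of the
#' pairwise box-overlap graph. Overlap is transitive through chains: if a
#' overlaps b and b overlaps c, all three belong to one component even when
#' a and c are disjoint. Voting support is counted per component.
#'
#' @param detections Data frame of detections (columns `model_id`, `label`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `score`), all rows carrying the same
#'   label.
#' @param label The expected pathology label; mixed labels are an error.
#' @return A list of data frames, one per component; every input row appears
#'   in exactly one component.
#' @export
support_components <- function(detections, label) {
  if (nrow(detections) == 0L) return(list())
  validate_detections(detections)
  if (!all(detections$label == label))
    stop_input("support_components: detections carry mixed labels")
  comp <- overlap_components(detections)
  lapply(seq_len(max(comp)), function(k) detections[comp == k, , drop = FALSE])
}

# Vote within one (image, label) group. Returns the retained rows (at most
# one per component), before threshold filtering.
vote_group <- function(det, min_support) {
  comp <- overlap_components(det)
  keep <- integer(0)
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(unique(det$model_id[idx])) < min_support) next
    sc <- det$score[idx]
    best <- idx[sc == max(sc)]
    if (length(best) > 1L) {
      # deterministic tie-break: lowest model id, then lexicographic corners
      o <- order(det$model_id[best], det$x_min[best], det$y_min[best],
                 det$x_max[best], det$y_max[best])
      best <- best[o]
    }
    keep <- c(keep, best[1L])
  }
  det[keep, , drop = FALSE]
}

#' Majority-vote ensembling of detector outputs
#'
#' Implements the consensus rule of a multi-detector ensemble: per image and
#' per pathology, detections from all models are grouped into connected
#' overlap components ([support_components()]); a component is retained when
#' its members come from at least `min_support` distinct models (so a box
#' must have non-null intersection, possibly through a chain, with boxes
#' from at least two other models when `min_support = 3`); each retained
#' component contributes exactly one output detection, its highest-scoring
#' member (ties: lowest model id, then lexicographic corners); finally any
#' emitted detection whose score falls below the pathology's threshold is
#' dropped. Sub-threshold boxes still vote — the score filter is the last
#' step, applied to emitted boxes only.
#'
#' Every output row is one of the input rows: the ensemble never synthesizes
#' or merges box geometry.
#'
#' @param detections Data frame of detections from all models, with columns
#'   `model_id`, `label`, `x_min`, `y_min`, `x_max`, `y_max`, `score` and
#'   optionally `image_id` (absent = a single image).
#' @param thresholds Named numeric vector mapping pathology label to the
#'   minimum retained score, or `NULL` for no score filtering. Every label
#'   present in `detections` must have an entry.
#' @param min_support Minimum number of distinct models per retained
#'   component (default 3, the 3-of-5 rule).
#' @param n_models Number of models in the ensemble (default 5).
#' @param labels Label enumeration used for output ordering.
#' @return Data frame of voted detections, ordered by image, then label
#'   enumeration order, then descending score.
#' @export
#' @examples
#' det <- data.frame(model_id = 1:3, label = "cardiomegaly",
#'                   x_min = c(10, 12, 11), y_min = c(10, 12, 9),
#'                   x_max = c(40, 42, 41), y_max = c(40, 42, 39),
#'                   score = c(0.6, 0.7, 0.8))
#' ensemble_vote(det)  # one box, the score-0.8 one
ensemble_vote <- function(detections, thresholds = NULL, min_support = 3L,
                          n_models = 5L, labels = pathology_labels()) {
  if (min_support > n_models)
    stop_input("min_support (", min_support, ") exceeds the number of models (",
               n_models, ")")
  if (min_support < 1L) stop_input("min_support must be >= 1")
  empty <- detections[integer(0), , drop = FALSE]
  if (nrow(detections) == 0L) return(empty)
  validate_detections(detections, n_models = n_models, labels = labels)
  if (!is.null(thresholds)) {
    if (anyNA(thresholds) || any(thresholds < 0 | thresholds > 1))
      stop_input("thresholds must lie in [0, 1]")
    miss <- setdiff(unique(detections$label), names(thresholds))
    if (length(miss))
      stop_input("no threshold for label(s): ", paste(miss, collapse = ", "))
  }
  has_img <- "image_id" %in% names(detections)
  key <- if (has_img) paste(detections$image_id, detections$label, sep = "\r")
         else detections$label
  groups <- split_stable(detections, key)
  out <- lapply(groups, function(g) vote_group(g, min_support))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  rownames(out) <- NULL
  if (!is.null(thresholds))
    out <- out[out$score >= thresholds[out$label], , drop = FALSE]
  o <- order(if (has_img) out$image_id else rep(1L, nrow(out)),
             match(out$label, labels), -out$score)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate per-pathology score thresholds on validation data
#'
#' Sweeps every candidate cut-point (the midpoints between adjacent distinct
#' sorted scores) for each pathology and returns the cut maximizing Youden's
#' J = sensitivity + specificity - 1, where a score at or above the cut is
#' called positive. Ties are broken toward the higher threshold (fewer
#' false positives at equal J). This realizes threshold selection "for the
#' higher performance" on a held-out validation set with a single explicit
#' objective.
#'
#' @param validation Data frame with columns `label`, `score` (in `[0, 1]`)
#'   and `is_true` (logical: the detection matches a real finding). Every
#'   pathology present must have at least one positive and one negative.
#' @return Named numeric vector of thresholds (one per label present), with
#'   the achieved J values attached as attribute `"youden"`.
#' @export
calibrate_thresholds <- function(validation) {
  need <- c("label", "score", "is_true")
  if (!all(need %in% names(validation)))
    stop_input("validation data must have columns ",
               paste(need, collapse = ", "))
  if (any(validation$score < 0 | validation$score > 1))
    stop_input("validation scores must lie in [0, 1]")
  labs <- unique(validation$label)
  thr <- numeric(length(labs)); names(thr) <- labs
  jj <- thr
  for (lab in labs) {
    v <- validation[validation$label == lab, ]
    pos <- v$score[v$is_true]
    neg <- v$score[!v$is_true]
    if (length(pos) == 0L || length(neg) == 0L)
      stop_input("pathology '", lab,
                 "' needs at least one positive and one negative score")
    s <- sort(unique(v$score))
    if (length(s) < 2L) {
      thr[lab] <- s[1L]
      jj[lab] <- mean(pos >= s[1L]) + mean(neg < s[1L]) - 1
      next
    }
    cuts <- (s[-length(s)] + s[-1L]) / 2
    j <- vapply(cuts, function(cc) mean(pos >= cc) + mean(neg < cc) - 1,
                numeric(1))
    best <- which(j >= max(j) - 1e-12)
    thr[lab] <- cuts[max(best)]
    jj[lab] <- max(j)
  }
  attr(thr, "youden") <- jj
  thr
}
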