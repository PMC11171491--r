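# Consensus ground truth from several annotators' boxes.

validate_annotations <- function(ann, n_annotators = NULL) {
  need <- c("annotator_id", "label")
  if (!all(need %in% names(ann)))
    stop_input("annotations must have columns ", paste(need, collapse = ", "),
               " plus box corners")
  validate_box_df(ann, "annotations")
  if (!is.null(n_annotators)) {
    bad <- !(ann$annotator_id %in% seq_len(n_annotators))
    if (any(bad))
      stop_input("annotator_id outside 1..", n_annotators,
                 " (row ", which(bad)[1L], ")")
  }
  invisible(ann)
}

# Consensus within one (image, label) group of annotations.
consensus_group <- function(ann, majority) {
  comp <- overlap_components(ann)
  res <- list()
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    members <- ann[idx, , drop = FALSE]
    annotators <- unique(members$annotator_id)
    if (length(annotators) < majority) next
    # one representative box per annotator: when an annotator contributed
    # several boxes to the component, keep the one with the largest summed
    # intersection with the other annotators' boxes (tie: lexicographic)
    reps <- lapply(annotators, function(a) {
      mine <- members[members$annotator_id == a, , drop = FALSE]
      if (nrow(mine) == 1L) return(mine)
      others <- members[members$annotator_id != a, , drop = FALSE]
      ov <- vapply(seq_len(nrow(mine)), function(i) {
        sum(isect_area_vec(mine$x_min[i], mine$y_min[i], mine$x_max[i],
                           mine$y_max[i], others$x_min, others$y_min,
                           others$x_max, others$y_max))
      }, numeric(1))
      best <- which(ov == max(ov))
      if (length(best) > 1L) {
        o <- order(mine$x_min[best], mine$y_min[best], mine$x_max[best],
                   mine$y_max[best])
        best <- best[o]
      }
      mine[best[1L], , drop = FALSE]
    })
    reps <- do.call(rbind, reps)
    avg <- average_boxes(reps)
    res[[length(res) + 1L]] <- data.frame(
      label = members$label[1L],
      x_min = avg[["x_min"]], y_min = avg[["y_min"]],
      x_max = avg[["x_max"]], y_max = avg[["y_max"]],
      support = length(annotators))
  }
  do.call(rbind, res)
}

#' Build consensus ground-truth findings from annotator boxes
#'
#' The reference standard for a radiological sign is the majority opinion of
#' the annotator panel: per image and pathology, annotations from all
#' annotators are grouped into connected components of the box-overlap graph
#' (agreement = at least one pixel of overlap, possibly through a chain); a
#' component supported by at least \eqn{\lceil (n+1)/2 \rceil} distinct
#' annotators (2 of 3 by default) yields one finding whose box is the
#' coordinate-wise average of the agreeing annotators' boxes and whose
#' `support` is the distinct-annotator count. Components below majority are
#' discarded; an image with no surviving finding of a label is a
#' ground-truth negative for that label.
#'
#' Only the agreeing annotators' boxes enter the average (a dissenting
#' disjoint box would drag the consensus off the finding). If one annotator
#' contributed several boxes to a component, their highest-overlap box
#' represents them.
#'
#' @param annotations Data frame with columns `annotator_id`, `label`,
#'   `x_min`, `y_min`, `x_max`, `y_max` and optionally `image_id`.
#' @param n_annotators Size of the annotator panel (default 3).
#' @return Data frame of findings: `image_id` (if present in the input),
#'   `label`, box corners, `support`.
#' @export
#' @examples
#' ann <- data.frame(annotator_id = c(1, 2, 3), label = "pneumothorax",
#'                   x_min = c(0, 2, 50), y_min = c(0, 2, 50),
#'                   x_max = c(10, 12, 60), y_max = c(10, 12, 60))
#' consensus_findings(ann)  # one finding (1,1,11,11), support 2
consensus_findings <- function(annotations, n_annotators = 3L) {
  if (n_annotators < 2L)
    stop_input("n_annotators must be at least 2 for a majority rule")
  majority <- ceiling((n_annotators + 1) / 2)
  has_img <- "image_id" %in% names(annotations)
  empty <- data.frame(label = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), support = integer(0))
  if (has_img) empty <- cbind(image_id = character(0), empty)
  if (nrow(annotations) == 0L) return(empty)
  validate_annotations(annotations, n_annotators)
  key <- if (has_img) paste(annotations$image_id, annotations$label, sep = "\r")
         else annotations$label
  groups <- split_stable(annotations, key)
  out <- lapply(groups, function(g) {
    f <- consensus_group(g, majority)
    if (!is.null(f) && has_img) f <- cbind(image_id = g$image_id[1L], f)
    f
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  rownames(out) <- NULL
  out
}

#' Image-level ground-truth status for a label
#'
#' @param findings Data frame of consensus findings (as returned by
#'   [consensus_findings()]), already restricted to one image.
#' @param label Pathology label queried.
#' @return TRUE iff at least one finding carries the label.
#' @export
image_positive <- function(findings, label) {
  nrow(findings) > 0L && any(findings$label == label)
}
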