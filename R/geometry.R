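#' Pathology label enumeration
#'
#' The six thoracic pathology classes the pipeline is parameterised over, in
#' canonical order: consolidation, pleural effusion, pneumothorax, acute
#' pulmonary edema, cardiomegaly, pulmonary nodule. Every box-bearing record
#' (detection, annotation, ground-truth finding) carries exactly one of these
#' labels, and voting/consensus never cross label boundaries.
#'
#' @return Character vector of the six label strings.
#' @export
#' @examples
#' pathology_labels()
pathology_labels <- function() {
  c("consolidation", "pleural_effusion", "pneumothorax",
    "acute_pulmonary_edema", "cardiomegaly", "pulmonary_nodule")
}

#' Construct an axis-aligned pixel bounding box
#'
#' Boxes live on an integer pixel grid with the origin at the top-left and a
#' half-open convention: the box covers the pixel set
#' \eqn{[x_{min}, x_{max}) \times [y_{min}, y_{max})}. Under this convention
#' two boxes that merely share an edge or a corner do \emph{not} overlap, so
#' "at least one pixel of overlap" is an exactly testable discrete predicate.
#'
#' @param x_min,y_min,x_max,y_max Integer pixel coordinates, `x_min < x_max`,
#'   `y_min < y_max`, all non-negative.
#' @return A named numeric vector of class `"pixel_box"`.
#' @export
#' @examples
#' b <- pixel_box(0, 0, 10, 10)
#' box_area(b)  # 100 pixels
pixel_box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_box(b)
  class(b) <- "pixel_box"
  b
}

#' @export
print.pixel_box <- function(x, ...) {
  cat(sprintf("<pixel_box [%d,%d) x [%d,%d), area %d px>\n",
              x[["x_min"]], x[["x_max"]], x[["y_min"]], x[["y_max"]],
              as.integer(box_area(x))))
  invisible(x)
}

# Coerce numeric(4) / list / one-row data.frame to the named corner form.
as_box <- function(b) {
  if (inherits(b, "pixel_box")) return(unclass(b))
  if (is.data.frame(b)) {
    if (nrow(b) != 1L) stop_input("expected a single box, got ", nrow(b), " rows")
    b <- c(x_min = b$x_min, y_min = b$y_min, x_max = b$x_max, y_max = b$y_max)
  }
  b <- unlist(b, use.names = TRUE)
  if (length(b) != 4L) stop_input("a box needs exactly 4 coordinates")
  if (is.null(names(b)) || !all(c("x_min", "y_min", "x_max", "y_max") %in% names(b)))
    names(b) <- c("x_min", "y_min", "x_max", "y_max")
  b <- b[c("x_min", "y_min", "x_max", "y_max")]
  validate_box(b)
  b
}

validate_box <- function(b) {
  if (anyNA(b)) stop_input("box coordinates contain NA")
  if (any(b < 0)) stop_input("box coordinates must be non-negative")
  if (any(b != floor(b))) stop_input("box coordinates must be integers")
  if (b[["x_min"]] >= b[["x_max"]] || b[["y_min"]] >= b[["y_max"]])
    stop_input("invalid box: need x_min < x_max and y_min < y_max")
  invisible(b)
}

# Validate the box columns of a data.frame in bulk.
validate_box_df <- function(df, what = "box") {
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(df)))
    stop_input(what, " table must have columns ", paste(need, collapse = ", "))
  m <- as.matrix(df[need])
  if (anyNA(m)) stop_input(what, ": coordinates contain NA")
  if (any(m < 0)) stop_input(what, ": coordinates must be non-negative")
  if (any(m != floor(m))) stop_input(what, ": coordinates must be integers")
  bad <- df$x_min >= df$x_max | df$y_min >= df$y_max
  if (any(bad))
    stop_input(what, ": invalid box (row ", which(bad)[1L],
               "): need x_min < x_max and y_min < y_max")
  invisible(df)
}

#' Box area in pixels
#' @param b A box (`pixel_box`, numeric(4), or one-row data frame).
#' @return Integer pixel count, always >= 1 for a valid box.
#' @export
box_area <- function(b) {
  b <- as_box(b)
  (b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]])
}

# Vectorised pairwise intersection area between parallel coordinate vectors.
isect_area_vec <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  iw <- pmin(ax2, bx2) - pmax(ax1, bx1)
  ih <- pmin(ay2, by2) - pmax(ay1, by1)
  pmax(iw, 0) * pmax(ih, 0)
}

#' Intersection area of two boxes
#'
#' Number of grid pixels contained in both boxes. Symmetric; zero when the
#' boxes are disjoint or merely edge-touching (half-open convention).
#'
#' @param a,b Boxes.
#' @return Non-negative integer pixel count.
#' @export
#' @examples
#' intersection_area(pixel_box(0, 0, 10, 10), pixel_box(5, 5, 15, 15))  # 25
intersection_area <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  isect_area_vec(a[["x_min"]], a[["y_min"]], a[["x_max"]], a[["y_max"]],
                 b[["x_min"]], b[["y_min"]], b[["x_max"]], b[["y_max"]])
}

#' Jaccard index (intersection over union) of two boxes
#'
#' Ratio of the pixel intersection to the pixel union: 1 iff the boxes are
#' identical, 0 iff they are disjoint. The Jaccard \emph{distance} is one
#' minus this value; annotator agreement requires a non-null index, i.e. at
#' least one shared pixel.
#'
#' @param a,b Boxes.
#' @return Ratio in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  inter <- intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Do two boxes overlap?
#'
#' TRUE iff the boxes share at least one grid pixel. Edge- or corner-touching
#' boxes do not overlap under the half-open convention.
#'
#' @param a,b Boxes.
#' @return Logical scalar.
#' @export
box_overlaps <- function(a, b) {
  intersection_area(a, b) >= 1
}

#' Coordinate-wise average of boxes
#'
#' The consensus localization of a finding is the arithmetic mean of the
#' agreeing annotators' boxes, taken corner by corner and rounded half-up
#' back onto the integer pixel grid. Averaging valid boxes always yields a
#' valid box (each side length is at least the mean of the input sides).
#'
#' @param boxes A list of boxes, or a data frame / matrix with columns
#'   `x_min, y_min, x_max, y_max` (one row per box).
#' @return A `pixel_box`.
#' @export
#' @examples
#' average_boxes(list(pixel_box(0, 0, 10, 10), pixel_box(2, 2, 12, 12)))
average_boxes <- function(boxes) {
  if (is.data.frame(boxes) || is.matrix(boxes)) {
    boxes <- as.data.frame(boxes)
    if (nrow(boxes) == 0L) stop_input("average_boxes: empty input")
    validate_box_df(boxes)
    m <- as.matrix(boxes[c("x_min", "y_min", "x_max", "y_max")])
  } else {
    if (length(boxes) == 0L) stop_input("average_boxes: empty input")
    m <- do.call(rbind, lapply(boxes, as_box))
  }
  mu <- round_half_up(colMeans(m))
  pixel_box(mu[[1L]], mu[[2L]], mu[[3L]], mu[[4L]])
}

# Connected components of the pairwise-overlap graph over n boxes.
# Returns an integer membership vector (component ids 1..k, in order of
# first appearance). Small-n union-find; groups in this pipeline rarely
# exceed a couple of dozen boxes.
overlap_components <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  x1 <- df$x_min; y1 <- df$y_min; x2 <- df$x_max; y2 <- df$y_max
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  iw <- outer(x2, x2, pmin) - outer(x1, x1, pmax)
  ih <- outer(y2, y2, pmin) - outer(y1, y1, pmax)
  adj <- iw > 0 & ih > 0
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx)) {
    for (k in seq_len(nrow(idx))) {
      ri <- find(idx[k, 1L]); rj <- find(idx[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
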