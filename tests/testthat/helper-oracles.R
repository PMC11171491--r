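# Independent oracles used to freeze expected values: brute-force pixel
# enumeration, transitive-closure components, a literal re-statement of the
# voting and consensus rules, an exhaustive threshold sweep, and the Welch
# closed form. Deliberately slow and structurally different from the
# implementations they check.

pixels_of <- function(b) {
  g <- expand.grid(x = b[["x_min"]]:(b[["x_max"]] - 1L),
                   y = b[["y_min"]]:(b[["y_max"]] - 1L))
  paste(g$x, g$y)
}

oracle_intersection <- function(a, b) {
  length(intersect(pixels_of(cxreval::pixel_box(a[1], a[2], a[3], a[4])),
                   pixels_of(cxreval::pixel_box(b[1], b[2], b[3], b[4]))))
}

oracle_jaccard <- function(a, b) {
  pa <- pixels_of(cxreval::pixel_box(a[1], a[2], a[3], a[4]))
  pb <- pixels_of(cxreval::pixel_box(b[1], b[2], b[3], b[4]))
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# transitive closure of the pairwise overlap matrix by repeated expansion
oracle_components <- function(df) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- oracle_intersection(
      c(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i]),
      c(df$x_min[j], df$y_min[j], df$x_max[j], df$y_max[j])) > 0
  }
  repeat {
    more <- adj | (adj %*% adj > 0)
    if (identical(more, adj)) break
    adj <- more
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[adj[i, ]] <- k
      comp[i] <- k
    }
  }
  comp
}

# literal evaluator of the retention rules, per label
oracle_vote <- function(det, thresholds = NULL, min_support = 3L) {
  out <- NULL
  for (lab in unique(det$label)) {
    d <- det[det$label == lab, , drop = FALSE]
    comp <- oracle_components(d)
    for (k in unique(comp)) {
      members <- d[comp == k, , drop = FALSE]
      if (length(unique(members$model_id)) < min_support) next
      members <- members[order(-members$score, members$model_id,
                               members$x_min, members$y_min,
                               members$x_max, members$y_max), ]
      winner <- members[1L, , drop = FALSE]
      if (!is.null(thresholds) && winner$score < thresholds[[lab]]) next
      out <- rbind(out, winner)
    }
  }
  out
}

# canonical form for comparing detection sets regardless of row order
canon_det <- function(d) {
  if (is.null(d) || nrow(d) == 0L)
    return(data.frame(model_id = integer(0), label = character(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      score = numeric(0)))
  d <- d[c("model_id", "label", "x_min", "y_min", "x_max", "y_max", "score")]
  d <- d[order(d$label, d$model_id, d$x_min, d$y_min, d$x_max, d$y_max,
               d$score), ]
  rownames(d) <- NULL
  d
}

# literal evaluator of the consensus rule for one image
oracle_consensus <- function(ann, n_annotators = 3L) {
  majority <- ceiling((n_annotators + 1) / 2)
  out <- NULL
  for (lab in unique(ann$label)) {
    d <- ann[ann$label == lab, , drop = FALSE]
    comp <- oracle_components(d)
    for (k in unique(comp)) {
      members <- d[comp == k, , drop = FALSE]
      annotators <- sort(unique(members$annotator_id))
      if (length(annotators) < majority) next
      reps <- NULL
      for (a in annotators) {
        mine <- members[members$annotator_id == a, , drop = FALSE]
        others <- members[members$annotator_id != a, , drop = FALSE]
        ov <- sapply(seq_len(nrow(mine)), function(i) {
          if (nrow(others) == 0L) return(0)
          sum(sapply(seq_len(nrow(others)), function(j) {
            oracle_intersection(
              c(mine$x_min[i], mine$y_min[i], mine$x_max[i], mine$y_max[i]),
              c(others$x_min[j], others$y_min[j], others$x_max[j],
                others$y_max[j]))
          }))
        })
        mine <- mine[order(-ov, mine$x_min, mine$y_min, mine$x_max,
                           mine$y_max), ]
        reps <- rbind(reps, mine[1L, ])
      }
      avg <- floor(colMeans(reps[c("x_min", "y_min", "x_max", "y_max")]) + 0.5)
      out <- rbind(out, data.frame(label = lab, x_min = avg[[1]],
                                   y_min = avg[[2]], x_max = avg[[3]],
                                   y_max = avg[[4]],
                                   support = length(annotators)))
    }
  }
  out
}

canon_findings <- function(f) {
  if (is.null(f) || nrow(f) == 0L)
    return(data.frame(label = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), support = integer(0)))
  f <- f[c("label", "x_min", "y_min", "x_max", "y_max", "support")]
  f <- f[order(f$label, f$x_min, f$y_min, f$x_max, f$y_max), ]
  rownames(f) <- NULL
  f
}

# exhaustive Youden sweep over midpoints of distinct sorted scores
oracle_youden <- function(pos, neg) {
  s <- sort(unique(c(pos, neg)))
  cuts <- (s[-length(s)] + s[-1]) / 2
  j <- sapply(cuts, function(cc) mean(pos >= cc) + mean(neg < cc) - 1)
  best <- cuts[j >= max(j) - 1e-12]
  list(threshold = max(best), j = max(j))
}

# closed-form Welch two-sample t-test
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random valid boxes on a small grid
random_box_df <- function(n, max_coord = 24L, max_side = 10L) {
  x <- sample.int(max_coord, n, replace = TRUE) - 1L
  y <- sample.int(max_coord, n, replace = TRUE) - 1L
  w <- sample.int(max_side, n, replace = TRUE)
  h <- sample.int(max_side, n, replace = TRUE)
  data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
}
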