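make_det <- function(model_id, label, x, y, x2, y2, score) {
  data.frame(model_id = model_id, label = label, x_min = x, y_min = y,
             x_max = x2, y_max = y2, score = score)
}

test_that("support components partition same-label detections by overlap chains", {
  expect_identical(support_components(make_det(integer(0), character(0),
                                               numeric(0), numeric(0),
                                               numeric(0), numeric(0),
                                               numeric(0)), "consolidation"),
                   list())
  two <- make_det(1:2, "consolidation", c(0, 50), c(0, 50), c(10, 60),
                  c(10, 60), c(0.5, 0.6))
  comps <- support_components(two, "consolidation")
  expect_length(comps, 2)
  expect_true(all(vapply(comps, nrow, integer(1)) == 1L))
  # chain: a-b overlap, b-c overlap, a-c disjoint -> one component
  chain <- make_det(1:3, "pneumothorax", c(0, 8, 16), c(0, 0, 0),
                    c(10, 18, 26), c(10, 10, 10), c(0.5, 0.6, 0.7))
  comps <- support_components(chain, "pneumothorax")
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]), 3)
  expect_equal(sort(unique(oracle_components(chain))), 1L)
  mixed <- chain; mixed$label[2] <- "cardiomegaly"
  expect_error(support_components(mixed, "pneumothorax"), "mixed")
})

test_that("the vote retains majority-supported components and their top score", {
  none <- make_det(integer(0), character(0), numeric(0), numeric(0),
                   numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(ensemble_vote(none)), 0)
  # a single model's box lacks support under the 3-of-5 rule
  lone <- make_det(1L, "cardiomegaly", 10, 10, 40, 40, 0.95)
  expect_equal(nrow(ensemble_vote(lone)), 0)
  # mutually overlapping boxes from models 1/2/3: highest score wins
  tri <- make_det(1:3, "cardiomegaly", c(10, 12, 11), c(10, 12, 9),
                  c(40, 42, 41), c(40, 42, 39), c(0.6, 0.7, 0.8))
  v <- ensemble_vote(tri, thresholds = c(cardiomegaly = 0.5))
  expect_equal(nrow(v), 1)
  expect_equal(v$score, 0.8)
  expect_equal(v$model_id, 3L)
  # same geometry, two labels: one output per label, no cross-label voting
  two_lab <- rbind(tri, transform(tri, label = "pneumothorax",
                                  score = c(0.5, 0.55, 0.55)))
  v2 <- ensemble_vote(two_lab)
  expect_equal(nrow(v2), 2)
  expect_setequal(v2$label, c("cardiomegaly", "pneumothorax"))
  oracle <- oracle_vote(two_lab)
  expect_equal(canon_det(v2), canon_det(oracle))
  # score ties break to the lowest model id
  tie <- make_det(c(2L, 1L, 3L), "cardiomegaly", c(10, 12, 11), c(10, 12, 9),
                  c(40, 42, 41), c(40, 42, 39), c(0.8, 0.8, 0.8))
  expect_equal(ensemble_vote(tie)$model_id, 1L)
})

test_that("vote configuration and inputs are validated", {
  d <- make_det(1L, "cardiomegaly", 0, 0, 5, 5, 0.9)
  expect_error(ensemble_vote(d, min_support = 6L, n_models = 5L),
               "min_support")
  expect_error(ensemble_vote(transform(d, model_id = 7L)), "model_id")
  expect_error(ensemble_vote(transform(d, score = 1.4)), "scores")
  expect_error(ensemble_vote(d, thresholds = c(pneumothorax = 0.2)),
               "no threshold")
})

test_that("min_support = 1 with one model reduces to threshold filtering", {
  set.seed(3)
  b <- random_box_df(12, max_coord = 200, max_side = 30)
  d <- cbind(data.frame(model_id = 1L, label = "consolidation"), b,
             data.frame(score = runif(12)))
  # separate the boxes so each is its own component: shift along x
  d$x_min <- d$x_min + (seq_len(12) - 1) * 300
  d$x_max <- d$x_max + (seq_len(12) - 1) * 300
  v <- ensemble_vote(d, thresholds = c(consolidation = 0.5),
                     min_support = 1L, n_models = 1L)
  expect_equal(canon_det(v), canon_det(d[d$score >= 0.5, ]))
})

test_that("voted output conserves inputs and responds monotonically to thresholds", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    det <- cbind(data.frame(model_id = sample(1:5, n, TRUE),
                            label = sample(c("cardiomegaly", "pneumothorax"),
                                           n, TRUE)),
                 random_box_df(n),
                 data.frame(score = round(runif(n), 2)))
    v0 <- ensemble_vote(det)
    if (nrow(v0)) {
      keys <- do.call(paste, det[c("model_id", "label", "x_min", "y_min",
                                   "x_max", "y_max", "score")])
      vkeys <- do.call(paste, v0[c("model_id", "label", "x_min", "y_min",
                                   "x_max", "y_max", "score")])
      expect_true(all(vkeys %in% keys))  # no synthesized boxes
    }
    t1 <- c(cardiomegaly = 0.3, pneumothorax = 0.3)
    t2 <- c(cardiomegaly = 0.7, pneumothorax = 0.3)
    n1 <- sum(ensemble_vote(det, t1)$label == "cardiomegaly")
    n2 <- sum(ensemble_vote(det, t2)$label == "cardiomegaly")
    expect_lte(n2, n1)
  }
})

test_that("vote agrees with a brute-force rule evaluator on small instances", {
  set.seed(99)
  for (i in 1:150) {
    n <- sample(0:8, 1)
    det <- cbind(data.frame(model_id = sample(1:5, n, TRUE),
                            label = sample(c("cardiomegaly", "pneumothorax"),
                                           n, TRUE)),
                 random_box_df(max(n, 1))[seq_len(n), , drop = FALSE],
                 data.frame(score = round(runif(n), 2)))
    thr <- c(cardiomegaly = round(runif(1), 2),
             pneumothorax = round(runif(1), 2))
    ms <- sample(1:4, 1)
    v <- ensemble_vote(det, thr, min_support = ms)
    o <- oracle_vote(det, thr, min_support = ms)
    expect_equal(canon_det(v), canon_det(o))
  }
})

test_that("3-of-5 voting suppresses spatially independent false positives", {
  # negatives only; independent clutter, no shared distractor
  cfg <- sim_config(n_positive_per_label = 0L, n_negative_per_label = 1000L,
                    labels = "consolidation", confuser_rate = 0,
                    model_fp_rate = rep(0.3, 5),
                    thresholds = c(consolidation = 0))
  gt <- simulate_ground_truth(cfg, seed = 5)
  det <- simulate_detections(gt, cfg, seed = 6)
  voted <- ensemble_vote(det, cfg$thresholds, labels = cfg$labels)
  fp_rate_voted <- length(unique(voted$image_id)) / 1000
  for (m in 1:5) {
    fp_rate_m <- length(unique(det$image_id[det$model_id == m])) / 1000
    expect_lt(fp_rate_voted, fp_rate_m)
  }
})

test_that("threshold calibration maximizes Youden's J over all cut-points", {
  # perfect separation: midpoint rule gives 0.5 with J = 1
  v <- data.frame(label = "consolidation",
                  score = c(rep(0.9, 5), rep(0.1, 5)),
                  is_true = rep(c(TRUE, FALSE), each = 5))
  thr <- calibrate_thresholds(v)
  expect_equal(unname(thr["consolidation"]), 0.5)
  expect_equal(unname(attr(thr, "youden")["consolidation"]), 1)
  # mixed case agrees with the exhaustive sweep oracle
  v2 <- data.frame(label = "pneumothorax", score = c(0.8, 0.6, 0.7, 0.2),
                   is_true = c(TRUE, TRUE, FALSE, FALSE))
  thr2 <- calibrate_thresholds(v2)
  o <- oracle_youden(c(0.8, 0.6), c(0.7, 0.2))
  expect_equal(unname(thr2["pneumothorax"]), o$threshold)
  expect_equal(unname(attr(thr2, "youden")["pneumothorax"]), o$j)
  # duplicating every observation leaves the cut unchanged
  thr3 <- calibrate_thresholds(rbind(v2, v2))
  expect_equal(unname(thr3["pneumothorax"]), unname(thr2["pneumothorax"]))
  # random cases against the oracle
  set.seed(12)
  for (i in 1:25) {
    pos <- round(runif(sample(2:8, 1)), 2)
    neg <- round(runif(sample(2:8, 1)), 2)
    vv <- data.frame(label = "cardiomegaly", score = c(pos, neg),
                     is_true = rep(c(TRUE, FALSE), c(length(pos), length(neg))))
    if (length(unique(vv$score)) < 2) next
    got <- calibrate_thresholds(vv)
    o <- oracle_youden(pos, neg)
    expect_equal(unname(got["cardiomegaly"]), o$threshold)
  }
  expect_error(
    calibrate_thresholds(data.frame(label = "cardiomegaly", score = 0.5,
                                    is_true = TRUE)),
    "cardiomegaly")
})
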