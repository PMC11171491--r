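pred_row <- function(image_id, label, x, y, x2, y2, score = 0.9) {
  data.frame(image_id = image_id, model_id = 1L, label = label, x_min = x,
             y_min = y, x_max = x2, y_max = y2, score = score)
}
find_row <- function(image_id, label, x, y, x2, y2) {
  data.frame(image_id = image_id, label = label, x_min = x, y_min = y,
             x_max = x2, y_max = y2, support = 2L)
}
no_pred <- pred_row("i", "consolidation", 0, 0, 1, 1)[0, ]
no_find <- find_row("i", "consolidation", 0, 0, 1, 1)[0, ]

test_that("image-level classification follows the overlap rule with FN precedence", {
  expect_equal(classify_image(no_pred, no_find, "consolidation"), "TN")
  f <- find_row("i", "consolidation", 10, 10, 40, 40)
  p_hit <- pred_row("i", "consolidation", 30, 30, 60, 60)
  p_miss <- pred_row("i", "consolidation", 100, 100, 130, 130)
  expect_equal(classify_image(p_hit, f, "consolidation"), "TP")
  expect_equal(classify_image(no_pred, f, "consolidation"), "FN")
  # positive image with only a non-overlapping prediction is FN, not FP
  expect_equal(classify_image(p_miss, f, "consolidation"), "FN")
  expect_equal(classify_image(p_miss, no_find, "consolidation"), "FP")
  # other-label rows are ignored
  expect_equal(classify_image(p_hit, transform(f, label = "pneumothorax"),
                              "consolidation"), "FP")
})

test_that("confusion tallies conserve the positive/negative image counts", {
  labs <- pathology_labels()
  expect_true(all(confusion_counts(no_pred, no_find,
                                   character(0))[c("tp", "fn", "fp", "tn")] == 0))
  ids <- sprintf("img%02d", 1:10)
  cc <- confusion_counts(no_pred, no_find, ids)
  expect_true(all(cc$tn == 10 & cc$tp == 0 & cc$fp == 0 & cc$fn == 0))
  # randomized small datasets: row sums always match the ground truth
  set.seed(55)
  for (i in 1:15) {
    n <- 20L
    ids <- sprintf("r%02d", seq_len(n))
    pos <- sample(ids, 8)
    f <- do.call(rbind, lapply(pos, function(id)
      find_row(id, "cardiomegaly", 10, 10, 40, 40)))
    with_pred <- sample(ids, 10)
    p <- do.call(rbind, lapply(with_pred, function(id)
      pred_row(id, "cardiomegaly",
               sample(c(15, 200), 1), 15, sample(c(45, 230), 1), 45)))
    p$x_max <- p$x_min + 30
    cc <- confusion_counts(p, f, ids)
    row <- cc[cc$label == "cardiomegaly", ]
    expect_equal(row$tp + row$fn, 8)
    expect_equal(row$fp + row$tn, 12)
  }
})

test_that("an exactly constructed study reproduces the published effusion row", {
  # 500 positives, 486 with an overlapping prediction; 1000 negatives, 130
  # with a spurious prediction
  pos_ids <- sprintf("pos%03d", 1:500)
  neg_ids <- sprintf("neg%04d", 1:1000)
  f <- do.call(rbind, lapply(pos_ids, function(id)
    find_row(id, "pleural_effusion", 100, 100, 200, 200)))
  p_hit <- do.call(rbind, lapply(pos_ids[1:486], function(id)
    pred_row(id, "pleural_effusion", 150, 150, 250, 250)))
  p_fp <- do.call(rbind, lapply(neg_ids[1:130], function(id)
    pred_row(id, "pleural_effusion", 100, 100, 200, 200)))
  cc <- confusion_counts(rbind(p_hit, p_fp), f, c(pos_ids, neg_ids),
                         labels = "pleural_effusion")
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(486, 14, 130, 870))
  ref <- reference_confusion_counts()
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")], use.names = FALSE),
               unlist(ref[ref$label == "pleural_effusion",
                          c("tp", "fn", "fp", "tn")], use.names = FALSE))
})

test_that("the metric panel derives the published proportions and identities", {
  mp <- metric_panel(data.frame(label = "pleural_effusion", tp = 486,
                                fn = 14, fp = 130, tn = 870))
  expect_equal(mp$sensitivity, 0.972)
  expect_equal(mp$specificity, 0.87)
  mp2 <- metric_panel(data.frame(label = "consolidation", tp = 465, fn = 35,
                                 fp = 114, tn = 886))
  expect_equal(mp2$ppv, 465 / 579)
  expect_equal(round(mp2$ppv, 3), 0.803)
  mp3 <- metric_panel(data.frame(label = "cardiomegaly", tp = 7, fn = 0,
                                 fp = 2, tn = 5))
  expect_equal(mp3$sensitivity, 1.0)
  expect_equal(mp3$fnr, 0.0)
  full <- metric_panel(reference_confusion_counts())
  expect_equal(full$sensitivity + full$fnr, rep(1, 6))
  expect_equal(full$specificity + full$fpr, rep(1, 6))
  expect_true(all(full$sensitivity_lo <= full$sensitivity &
                    full$sensitivity <= full$sensitivity_hi))
})

test_that("undefined metrics are reported as NA with a warning", {
  expect_warning(
    mp <- metric_panel(data.frame(label = "consolidation", tp = 0, fn = 0,
                                  fp = 3, tn = 7)),
    "sensitivity undefined")
  expect_true(is.na(mp$sensitivity))
  expect_false(is.na(mp$specificity))
})

test_that("Wilson intervals have exact boundary behaviour and match prop.test", {
  z <- qnorm(0.975)
  w <- wilson_ci(10, 10)
  expect_equal(unname(w["hi"]), 1.0)
  expect_equal(unname(w["lo"]), 1 / (1 + z^2 / 10))
  expect_equal(unname(wilson_ci(0, 10)["lo"]), 0.0)
  # agreement with the score interval of prop.test (no continuity correction)
  for (case in list(c(486, 500), c(130, 1000), c(7, 19))) {
    got <- wilson_ci(case[1], case[2])
    ref <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10)
  }
  # contains the point estimate and shrinks with n at fixed proportion
  w1 <- wilson_ci(30, 100); w2 <- wilson_ci(300, 1000)
  expect_true(w1["lo"] <= 0.3 && 0.3 <= w1["hi"])
  expect_lt(diff(w2), diff(w1))
  expect_error(wilson_ci(5, 0), "n must be")
  expect_error(wilson_ci(11, 10), "successes")
})

test_that("rank AUC equals pairwise counting and the trapezoidal ROC area", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               3 / 4)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "positive and one negative")
  set.seed(14)
  sc <- runif(60); lb <- runif(60) < 0.4
  if (any(lb) && any(!lb)) {
    a <- roc_auc(sc, lb)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(qlogis(sc / 1.0001 + 1e-5), lb), a)
    # agreement with an independent ROC implementation
    skip_if_not_installed("pROC")
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a, ref, tolerance = 1e-10)
  }
})

test_that("the stratified bootstrap interval is deterministic and degenerate-safe", {
  sc <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ci <- bootstrap_auc_ci(sc, lb, B = 200, seed = 9)
  expect_equal(as.numeric(ci), c(1, 1))
  set.seed(77)
  sc2 <- c(runif(30, 0.3, 1), runif(30, 0, 0.7))
  lb2 <- rep(c(TRUE, FALSE), each = 30)
  c1 <- bootstrap_auc_ci(sc2, lb2, B = 500, seed = 123)
  c2 <- bootstrap_auc_ci(sc2, lb2, B = 500, seed = 123)
  expect_identical(c1, c2)
  expect_true(c1["lo"] <= attr(c1, "auc") && attr(c1, "auc") <= c1["hi"])
  # the caller's RNG stream is untouched
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(bootstrap_auc_ci(sc2, lb2, B = 50, seed = 4))
  expect_identical(runif(3), before)
})

test_that("macro averaging is the unweighted mean over all six pathologies", {
  auc <- c(pleural_effusion = 0.9362, consolidation = 0.9161,
           cardiomegaly = 0.9464, pulmonary_nodule = 0.9582,
           pneumothorax = 0.9457, acute_pulmonary_edema = 0.9123)
  expect_equal(round(macro_average(auc), 4), 0.9358)
  same <- setNames(rep(0.7, 6), pathology_labels())
  expect_equal(macro_average(same), 0.7)
  expect_error(macro_average(auc[-1]), "missing label")
})
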