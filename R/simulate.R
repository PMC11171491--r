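# Seeded synthetic study generator: ground-truth lesions, annotator boxes,
# multi-detector outputs, reader behaviour and demographic metadata, with
# the statistical structure the evaluation pipeline assumes.

#' Configuration for a synthetic detection study
#'
#' Encodes the study composition (per-pathology counts of positive and
#' negative images), the lesion geometry, the detector, annotator and reader
#' behaviour models, and the demographic metadata mix. Defaults reproduce
#' the enriched per-pathology design of a standalone validation study (500
#' positive / 1000 negative images per pathology) and the aided/unaided
#' reader operating points and reading-time distributions of a nine-reader
#' clinical comparison.
#'
#' Detector false positives come from two mechanisms: independent uniform
#' clutter at a per-model Poisson rate (`model_fp_rate`), and a shared
#' per-image "confuser" structure (prevalence `confuser_rate`) that each
#' model flags independently with probability `confuser_hit_rate` — the
#' latter is what lets a false finding win a 3-of-5 vote at a realistic
#' image-level rate, since independent clutter almost never co-localizes
#' across three models.
#'
#' @param n_positive_per_label,n_negative_per_label Images per pathology
#'   cohort (defaults 500 / 1000).
#' @param labels Pathology enumeration.
#' @param image_width,image_height Image size in pixels.
#' @param lesion_side_range Bounds of the log-uniform lesion side-length
#'   distribution (pixels).
#' @param n_models Number of detector models in the ensemble.
#' @param model_sensitivity Per-model probability of detecting a true lesion.
#' @param model_fp_rate Per-model Poisson mean of independent false boxes
#'   per image.
#' @param model_jitter_sd Per-model localization jitter (pixels, Gaussian on
#'   each corner, clipped so the detected box keeps the lesion centre).
#' @param tp_score_shape,fp_score_shape Beta shape pairs for true-positive
#'   and false-positive confidence scores.
#' @param co_detection_rho Correlation of detection events across models via
#'   a shared per-lesion difficulty (Gaussian copula), 0 = independent.
#' @param confuser_rate,confuser_hit_rate Shared-distractor prevalence per
#'   image and per-model flag probability.
#' @param n_annotators,annotator_jitter_sd,annotator_miss_prob,annotator_spurious_prob
#'   Annotator panel size and behaviour (jitter clipped as for models; miss
#'   = probability of omitting a true lesion, scalar or one value per
#'   annotator; spurious = probability of one extra random box per image).
#' @param thresholds Named per-pathology score thresholds used by the
#'   ensemble step.
#' @param min_support Distinct-model majority required by the vote.
#' @param n_readers Readers per condition arm.
#' @param reader_n_images Images in the reader study (split into two equal
#'   sessions: unaided then aided).
#' @param reader_positive_counts Named per-pathology positive-image counts
#'   within the reader study.
#' @param reader_unaided,reader_aided Operating point and reading-time
#'   distribution per condition: list with `sensitivity`, `specificity`,
#'   `time_mean`, `time_sd` (seconds; across-reader spread of mean times).
#' @param reader_sens_sd,reader_spec_sd Across-reader spread of the
#'   operating points.
#' @param reader_time_cv Within-reader coefficient of variation of
#'   per-image reading times (log-normal).
#' @param age_mean,age_sd,female_prop,manufacturer_shares Demographic
#'   metadata mix.
#' @param multi_label Allow several pathologies on one positive image
#'   (off by default: one pathology per positive image).
#' @param seed Default seed threaded through the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    n_positive_per_label = 500L,
    n_negative_per_label = 1000L,
    labels = pathology_labels(),
    image_width = 1024L, image_height = 1024L,
    lesion_side_range = c(32, 256),
    n_models = 5L,
    model_sensitivity = rep(0.85, n_models),
    model_fp_rate = rep(0.15, n_models),
    model_jitter_sd = rep(8, n_models),
    tp_score_shape = c(8, 2),
    fp_score_shape = c(2, 5),
    co_detection_rho = 0,
    confuser_rate = 0.15,
    confuser_hit_rate = 0.8,
    n_annotators = 3L,
    annotator_jitter_sd = 4,
    annotator_miss_prob = 0,
    annotator_spurious_prob = 0.01,
    thresholds = stats::setNames(rep(0.1, length(labels)), labels),
    min_support = 3L,
    n_readers = 9L,
    reader_n_images = 900L,
    reader_positive_counts = c(consolidation = 77L, pleural_effusion = 60L,
                               pneumothorax = 32L, cardiomegaly = 16L,
                               acute_pulmonary_edema = 37L,
                               pulmonary_nodule = 43L),
    reader_unaided = list(sensitivity = 0.769, specificity = 0.946,
                          time_mean = 22.9, time_sd = 2.3),
    reader_aided = list(sensitivity = 0.857, specificity = 0.974,
                        time_mean = 14.7, time_sd = 1.3),
    reader_sens_sd = 0.02,
    reader_spec_sd = 0.01,
    reader_time_cv = 0.3,
    age_mean = 49.9, age_sd = 23, female_prop = 0.545,
    manufacturer_shares = c("GMM/Primax" = 0.17, Fujifilm = 0.11,
                            Shimadzu = 0.38, Canon = 0.28, Medecom = 0.06),
    multi_label = FALSE,
    seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$model_sensitivity, cfg$confuser_rate, cfg$confuser_hit_rate,
             cfg$annotator_miss_prob, cfg$annotator_spurious_prob,
             cfg$female_prop, cfg$co_detection_rho)
  if (any(probs < 0 | probs > 1))
    stop_input("probabilities in the configuration must lie in [0, 1]")
  if (cfg$n_positive_per_label < 0 || cfg$n_negative_per_label < 0)
    stop_input("image counts must be non-negative")
  if (length(cfg$model_sensitivity) != cfg$n_models ||
      length(cfg$model_fp_rate) != cfg$n_models ||
      length(cfg$model_jitter_sd) != cfg$n_models)
    stop_input("per-model parameter vectors must have length n_models")
  if (any(cfg$model_fp_rate < 0)) stop_input("FP rates must be non-negative")
  if (!length(cfg$annotator_miss_prob) %in% c(1L, cfg$n_annotators))
    stop_input("annotator_miss_prob must be scalar or one value per annotator")
  if (cfg$lesion_side_range[1L] < 2 ||
      cfg$lesion_side_range[2L] > min(cfg$image_width, cfg$image_height))
    stop_input("lesion side range incompatible with the image size")
  if (abs(sum(cfg$manufacturer_shares) - 1) > 1e-8)
    stop_input("manufacturer shares must sum to 1")
  if (sum(cfg$reader_positive_counts) > cfg$reader_n_images)
    stop_input("reader study positives exceed the image count")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  standalone: %d pathologies x (%d positive + %d negative) images\n",
              length(x$labels), x$n_positive_per_label, x$n_negative_per_label))
  cat(sprintf("  detectors: %d models, sens %s, vote %d-of-%d\n",
              x$n_models, paste(x$model_sensitivity, collapse = "/"),
              x$min_support, x$n_models))
  cat(sprintf("  annotators: %d (miss %.2f, spurious %.2f)\n",
              x$n_annotators, x$annotator_miss_prob, x$annotator_spurious_prob))
  cat(sprintf("  readers: %d per arm, %d images\n", x$n_readers,
              x$reader_n_images))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Random lesion-like boxes, vectorised. Returns a data.frame of n boxes.
random_boxes <- function(n, cfg) {
  lw <- log(cfg$lesion_side_range)
  w <- round(exp(stats::runif(n, lw[1L], lw[2L])))
  h <- round(exp(stats::runif(n, lw[1L], lw[2L])))
  x <- floor(stats::runif(n, 0, cfg$image_width - w + 1))
  y <- floor(stats::runif(n, 0, cfg$image_height - h + 1))
  data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
}

# Jitter box corners by N(0, sd), clipped to the image and so that the box
# still contains the original centre pixel (keeps jittered copies of one
# lesion mutually overlapping).
jitter_boxes <- function(boxes, sd, cfg) {
  n <- nrow(boxes)
  if (n == 0L || sd == 0) return(boxes)
  cx <- floor((boxes$x_min + boxes$x_max) / 2)
  cy <- floor((boxes$y_min + boxes$y_max) / 2)
  d <- matrix(round(stats::rnorm(4L * n, 0, sd)), ncol = 4L)
  data.frame(
    x_min = pmin(pmax(boxes$x_min + d[, 1L], 0), cx),
    y_min = pmin(pmax(boxes$y_min + d[, 2L], 0), cy),
    x_max = pmax(pmin(boxes$x_max + d[, 3L], cfg$image_width), cx + 1),
    y_max = pmax(pmin(boxes$y_max + d[, 4L], cfg$image_height), cy + 1))
}

#' Simulate the ground-truth composition of a standalone study
#'
#' Builds the enriched per-pathology design: for each pathology, exactly
#' `n_positive_per_label` cohort images carrying one true lesion of that
#' pathology and `n_negative_per_label` cohort images carrying none. Lesion
#' boxes have log-uniform side lengths and uniform positions within the
#' image. Deterministic for a given seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default from the config).
#' @return List with `images` (image_id, width, height, cohort, positive)
#'   and `truth` (image_id, label, box corners).
#' @export
simulate_ground_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    imgs <- list(); boxes <- list()
    for (lab in config$labels) {
      np <- config$n_positive_per_label; nn <- config$n_negative_per_label
      ids <- sprintf("%s_%05d", lab, seq_len(np + nn))
      imgs[[lab]] <- data.frame(
        image_id = ids, width = config$image_width,
        height = config$image_height, cohort = lab,
        positive = c(rep(TRUE, np), rep(FALSE, nn)))
      if (np > 0L) {
        b <- random_boxes(np, config)
        boxes[[lab]] <- cbind(data.frame(image_id = ids[seq_len(np)],
                                         label = lab), b)
      }
    }
    list(images = do.call(rbind, c(imgs, list(make.row.names = FALSE))),
         truth = if (length(boxes))
           do.call(rbind, c(boxes, list(make.row.names = FALSE)))
         else data.frame(image_id = character(0), label = character(0),
                         x_min = numeric(0), y_min = numeric(0),
                         x_max = numeric(0), y_max = numeric(0)))
  })
}

#' Simulate the annotator panel
#'
#' Each annotator independently reproduces each true lesion box with
#' Gaussian corner jitter (clipped so the drawn box keeps the lesion centre
#' pixel — annotators outline the sign they see), omits it with the
#' configured miss probability, and adds a spurious random box per image
#' with the configured probability. Deterministic per seed.
#'
#' @param truth Output of [simulate_ground_truth()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame of annotations: `image_id`, `annotator_id`, `label`,
#'   box corners.
#' @export
simulate_annotators <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  tb <- truth$truth
  with_seed(seed, {
    out <- list()
    miss <- rep(config$annotator_miss_prob, length.out = config$n_annotators)
    for (a in seq_len(config$n_annotators)) {
      keep <- stats::runif(nrow(tb)) >= miss[a]
      drawn <- tb[keep, , drop = FALSE]
      jit <- jitter_boxes(drawn[c("x_min", "y_min", "x_max", "y_max")],
                          config$annotator_jitter_sd, config)
      ann <- cbind(data.frame(image_id = drawn$image_id,
                              annotator_id = rep(a, nrow(drawn)),
                              label = drawn$label), jit)
      spur <- stats::runif(nrow(truth$images)) < config$annotator_spurious_prob
      if (any(spur)) {
        sb <- random_boxes(sum(spur), config)
        ann <- rbind(ann, cbind(
          data.frame(image_id = truth$images$image_id[spur],
                     annotator_id = a,
                     label = sample(config$labels, sum(spur), replace = TRUE)),
          sb))
      }
      out[[a]] <- ann
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the detector models
#'
#' Per model: each true lesion is detected with the model's sensitivity
#' (co-detection across models optionally correlated through a shared
#' per-lesion difficulty, Gaussian copula), localized with Gaussian jitter
#' and scored from the true-positive Beta distribution. False positives
#' arise from (a) a shared per-image confuser flagged independently by each
#' model and scored from the false-positive Beta distribution, and (b)
#' independent uniform clutter at the per-model Poisson rate. Deterministic
#' per seed.
#'
#' @param truth Output of [simulate_ground_truth()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame of detections: `image_id`, `model_id`, `label`, box
#'   corners, `score`.
#' @export
simulate_detections <- function(truth, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  tb <- truth$truth
  imgs <- truth$images
  with_seed(seed, {
    out <- list()
    nles <- nrow(tb)
    z_les <- stats::rnorm(nles)
    rho <- config$co_detection_rho
    # shared confuser structure per image
    conf <- stats::runif(nrow(imgs)) < config$confuser_rate
    conf_boxes <- random_boxes(sum(conf), config)
    conf_img <- imgs$image_id[conf]
    conf_lab <- imgs$cohort[conf]
    for (m in seq_len(config$n_models)) {
      # true-positive detections
      z <- sqrt(rho) * z_les + sqrt(1 - rho) * stats::rnorm(nles)
      hit <- stats::pnorm(z) < config$model_sensitivity[m]
      det <- tb[hit, , drop = FALSE]
      jit <- jitter_boxes(det[c("x_min", "y_min", "x_max", "y_max")],
                          config$model_jitter_sd[m], config)
      tp <- cbind(data.frame(image_id = det$image_id,
                             model_id = rep(m, nrow(det)),
                             label = det$label), jit,
                  data.frame(score = stats::rbeta(nrow(det),
                                                  config$tp_score_shape[1L],
                                                  config$tp_score_shape[2L])))
      # confuser false positives
      chit <- stats::runif(length(conf_img)) < config$confuser_hit_rate
      cjit <- jitter_boxes(conf_boxes[chit, , drop = FALSE],
                           config$model_jitter_sd[m], config)
      cf <- cbind(data.frame(image_id = conf_img[chit],
                             model_id = rep(m, sum(chit)),
                             label = conf_lab[chit]), cjit,
                  data.frame(score = stats::rbeta(sum(chit),
                                                  config$fp_score_shape[1L],
                                                  config$fp_score_shape[2L])))
      # independent clutter
      nfp <- stats::rpois(nrow(imgs), config$model_fp_rate[m])
      fb <- random_boxes(sum(nfp), config)
      fp <- cbind(data.frame(image_id = rep(imgs$image_id, nfp),
                             model_id = rep(m, sum(nfp)),
                             label = sample(config$labels, sum(nfp),
                                            replace = TRUE)), fb,
                  data.frame(score = stats::rbeta(sum(nfp),
                                                  config$fp_score_shape[1L],
                                                  config$fp_score_shape[2L])))
      out[[m]] <- rbind(tp, cf, fp)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the reader study
#'
#' Builds a two-session reader study: `reader_n_images` images with the
#' configured per-pathology positive counts, split into two equal halves
#' (session 1 read unaided, session 2 read aided by the algorithm). Each
#' reader receives a condition-specific operating point perturbed by
#' across-reader Gaussian spread, calls each image-label Bernoulli at that
#' operating point, reports a confidence consistent with the call, and
#' spends a log-normal per-image reading time around a reader-level mean
#' drawn from the condition's time distribution. Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `records` (reader_id, condition, image_id, label,
#'   call, confidence, time_s), `truth` (positive image-label pairs) and
#'   `images`.
#' @export
simulate_readers <- function(config, seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$reader_n_images
    ids <- sprintf("reader_img_%05d", seq_len(n))
    lab_of <- rep(NA_character_, n)
    k <- 1L
    for (lab in names(config$reader_positive_counts)) {
      cnt <- config$reader_positive_counts[[lab]]
      if (cnt > 0L) lab_of[k:(k + cnt - 1L)] <- lab
      k <- k + cnt
    }
    perm <- sample.int(n)          # shuffle before splitting into sessions
    ids <- ids; lab_of <- lab_of[perm]
    half <- n %/% 2L
    session <- rep(c("unaided", "aided"), c(half, n - half))
    truth <- data.frame(image_id = ids[!is.na(lab_of)],
                        label = lab_of[!is.na(lab_of)])
    images <- data.frame(image_id = ids, condition = session)
    conds <- list(unaided = config$reader_unaided,
                  aided = config$reader_aided)
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    recs <- list()
    for (cond in names(conds)) {
      cp <- conds[[cond]]
      sub <- ids[session == cond]
      sub_lab <- lab_of[session == cond]
      nl <- length(config$labels)
      for (r in seq_len(config$n_readers)) {
        sens_r <- clamp(stats::rnorm(1, cp$sensitivity, config$reader_sens_sd),
                        0.01, 0.999)
        spec_r <- clamp(stats::rnorm(1, cp$specificity, config$reader_spec_sd),
                        0.01, 0.999)
        tmean_r <- max(stats::rnorm(1, cp$time_mean, cp$time_sd), 1)
        cv <- config$reader_time_cv
        sdlog <- sqrt(log(1 + cv^2))
        mlog <- log(tmean_r) - sdlog^2 / 2
        t_img <- stats::rlnorm(length(sub), mlog, sdlog)
        g <- expand.grid(image_id = sub, label = config$labels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        pos <- g$label == rep(sub_lab, times = nl) & !is.na(rep(sub_lab, nl))
        p_call <- ifelse(pos, sens_r, 1 - spec_r)
        call <- as.integer(stats::runif(nrow(g)) < p_call)
        confidence <- ifelse(call == 1L,
                             stats::rbeta(nrow(g), 8, 2),
                             stats::rbeta(nrow(g), 2, 8))
        recs[[length(recs) + 1L]] <- data.frame(
          reader_id = r, condition = cond, image_id = g$image_id,
          label = g$label, call = call, confidence = confidence,
          time_s = rep(t_img, times = nl))
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    list(records = records, truth = truth, images = images)
  })
}

# Demographic metadata per standalone image.
simulate_metadata <- function(images, config, seed = config$seed + 4L) {
  with_seed(seed, {
    n <- nrow(images)
    data.frame(
      image_id = images$image_id,
      age = round(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 0), 1),
      sex = ifelse(stats::runif(n) < config$female_prop, "F", "M"),
      manufacturer = sample(names(config$manufacturer_shares), n,
                            replace = TRUE,
                            prob = config$manufacturer_shares))
  })
}

#' Simulate a complete study bundle
#'
#' Composes the four generators — ground truth, annotator panel, detector
#' models, reader study — plus demographic metadata into one bundle, each
#' stage on its own sub-stream derived from the master seed so the bundle
#' is fully deterministic per (config, seed).
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed (default from the config).
#' @return A `study_bundle` list with elements `images`, `truth`,
#'   `annotations`, `detections`, `reader` (records/truth/images),
#'   `metadata`, `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_positive_per_label = 5, n_negative_per_label = 10,
#'                   reader_n_images = 30,
#'                   reader_positive_counts = c(consolidation = 3,
#'                     pleural_effusion = 2, pneumothorax = 2,
#'                     cardiomegaly = 1, acute_pulmonary_edema = 2,
#'                     pulmonary_nodule = 2))
#' bundle <- simulate_study(cfg, seed = 7)
simulate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  gt <- simulate_ground_truth(config, seed)
  ann <- simulate_annotators(gt, config, seed + 1L)
  det <- simulate_detections(gt, config, seed + 2L)
  readers <- simulate_readers(config, seed + 3L)
  meta <- simulate_metadata(gt$images, config, seed + 4L)
  structure(list(images = gt$images, truth = gt$truth, annotations = ann,
                 detections = det, reader = readers, metadata = meta,
                 config = config, seed = seed),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic detection study bundle\n")
  cat(sprintf("  %d images (%d true lesions), %d detections from %d models\n",
              nrow(x$images), nrow(x$truth), nrow(x$detections),
              x$config$n_models))
  cat(sprintf("  %d annotations from %d annotators\n", nrow(x$annotations),
              x$config$n_annotators))
  cat(sprintf("  reader study: %d records, %d readers per arm\n",
              nrow(x$reader$records), x$config$n_readers))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Run the standalone-evaluation pipeline on a study bundle
#'
#' Convenience composition: majority-vote ensembling of the detector
#' outputs, consensus ground truthing of the annotator boxes, image-level
#' confusion counting and the derived metric panel.
#'
#' @param bundle A `study_bundle` from [simulate_study()] (or an equivalent
#'   list read back from disk).
#' @return List with `voted`, `findings`, `counts`, `panel`.
#' @export
evaluate_standalone <- function(bundle) {
  cfg <- bundle$config
  voted <- ensemble_vote(bundle$detections, thresholds = cfg$thresholds,
                         min_support = cfg$min_support,
                         n_models = cfg$n_models, labels = cfg$labels)
  findings <- consensus_findings(bundle$annotations,
                                 n_annotators = cfg$n_annotators)
  counts <- confusion_counts(voted, findings, bundle$images,
                             labels = cfg$labels)
  list(voted = voted, findings = findings, counts = counts,
       panel = metric_panel(counts))
}
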