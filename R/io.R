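# On-disk formats binding the pipeline together: a COCO-style JSON dialect
# for boxes (detections / annotations / ground truth), RFC-4180 CSV for
# reader results, JSON/YAML configuration, and the study-bundle layout.
#
# Boxes are serialized as bbox = [x, y, width, height] for COCO familiarity
# and converted to the internal corner form (x_min, y_min, x_max, y_max) at
# this boundary.

corners_to_bbox <- function(df) {
  cbind(df$x_min, df$y_min, df$x_max - df$x_min, df$y_max - df$y_min)
}

bbox_to_corners <- function(bbox) {
  data.frame(x_min = bbox[, 1L], y_min = bbox[, 2L],
             x_max = bbox[, 1L] + bbox[, 3L], y_max = bbox[, 2L] + bbox[, 4L])
}

images_out <- function(images) {
  img <- data.frame(id = images$image_id,
                    width = images$width %||% NA,
                    height = images$height %||% NA)
  if ("cohort" %in% names(images)) img$cohort <- images$cohort
  if ("positive" %in% names(images)) img$positive <- images$positive
  img
}

images_in <- function(img) {
  if (is.null(img) || length(img) == 0L)
    return(data.frame(image_id = character(0), width = numeric(0),
                      height = numeric(0)))
  out <- data.frame(image_id = img$id, width = img$width, height = img$height)
  if (!is.null(img$cohort)) out$cohort <- img$cohort
  if (!is.null(img$positive)) out$positive <- img$positive
  out
}

write_box_json <- function(df, images, path, extra_cols, record_name) {
  rec <- df[c("image_id", extra_cols)]
  rec$category <- df$label
  rec$bbox <- corners_to_bbox(df)
  obj <- list(images = images_out(images))
  obj[[record_name]] <- rec
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_box_json <- function(path, extra_cols, record_name, labels, strict) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  images <- images_in(obj$images)
  rec <- obj[[record_name]]
  tail0 <- intersect(c("score", "support"), extra_cols)
  empty <- data.frame(image_id = character(0))
  for (col in setdiff(extra_cols, tail0)) empty[[col]] <- numeric(0)
  empty$label <- character(0)
  for (col in c("x_min", "y_min", "x_max", "y_max")) empty[[col]] <- numeric(0)
  for (col in tail0) empty[[col]] <- numeric(0)
  if (is.null(rec) || length(rec) == 0L || NROW(rec) == 0L)
    return(list(images = images, records = empty))
  bbox <- rec$bbox
  if (is.list(bbox)) bbox <- do.call(rbind, bbox)
  bad <- rep(FALSE, nrow(rec))
  why <- character(nrow(rec))
  flag <- function(cond, msg) {
    new <- cond & !bad
    why[new] <<- msg
    bad <<- bad | cond
  }
  flag(is.na(bbox[, 3L]) | is.na(bbox[, 4L]) | bbox[, 3L] <= 0 | bbox[, 4L] <= 0,
       "malformed bbox (non-positive width/height)")
  flag(bbox[, 1L] < 0 | bbox[, 2L] < 0, "malformed bbox (negative origin)")
  flag(!(rec$category %in% labels), "unknown category")
  if ("score" %in% extra_cols)
    flag(is.na(rec$score) | rec$score < 0 | rec$score > 1,
         "score outside [0, 1]")
  if (any(bad)) {
    i <- which(bad)[1L]
    detail <- sprintf("%s: record %d (image_id '%s'): %s",
                      path, i, rec$image_id[i], why[i])
    if (strict) stop_input(detail)
    message(sprintf("skipping %d invalid record(s) in %s; first: %s",
                    sum(bad), path, detail))
    rec <- rec[!bad, , drop = FALSE]
    bbox <- bbox[!bad, , drop = FALSE]
  }
  if (nrow(rec) == 0L) return(list(images = images, records = empty))
  out <- cbind(data.frame(image_id = rec$image_id),
               rec[extra_cols],
               data.frame(label = rec$category),
               bbox_to_corners(bbox))
  # canonical internal column order (score/support last, as produced by the
  # pipeline)
  tail_cols <- intersect(c("score", "support"), extra_cols)
  out <- out[c("image_id", setdiff(extra_cols, tail_cols), "label",
               "x_min", "y_min", "x_max", "y_max", tail_cols)]
  rownames(out) <- NULL
  list(images = images, records = out)
}

#' Read and write detection files
#'
#' Detections travel in a COCO-style JSON dialect:
#' `{"images": [{"id", "width", "height"}],
#'   "detections": [{"image_id", "model_id", "category",
#'                   "bbox": [x, y, width, height], "score"}]}`.
#' Writing then reading any valid detection set is the identity. Malformed
#' records (unknown category, non-positive bbox width/height, score outside
#' `[0, 1]`) abort with record context in strict mode (the default) or are
#' skipped with a logged count in lenient mode — silent record-dropping
#' would corrupt confusion counts, so lenient mode is always explicit.
#'
#' @param detections Data frame of detections (`image_id`, `model_id`,
#'   `label`, corner columns, `score`).
#' @param images Image table (`image_id`, `width`, `height`, optional
#'   `cohort`/`positive`).
#' @param path File path.
#' @param labels Valid category strings.
#' @param strict Abort on the first invalid record (default) or skip them.
#' @return `read_detections()`: list with `images` and `detections`.
#' @export
write_detections <- function(detections, images, path) {
  validate_detections(detections)
  write_box_json(detections, images, path, c("model_id", "score"),
                 "detections")
}

#' @rdname write_detections
#' @export
read_detections <- function(path, labels = pathology_labels(),
                            strict = TRUE) {
  r <- read_box_json(path, c("model_id", "score"), "detections", labels,
                     strict)
  list(images = r$images, detections = r$records)
}

#' Read and write annotation and ground-truth files
#'
#' Annotations and consensus ground truth share the detection JSON dialect,
#' with `annotator_id` (annotations) or `support` (ground truth) in place of
#' `model_id`/`score`. Round-trip identity and strict/lenient validation as
#' in [read_detections()].
#'
#' @inheritParams write_detections
#' @param annotations Data frame of annotator boxes.
#' @param findings Data frame of consensus findings.
#' @return The read functions return a list with `images` and the record
#'   table (`annotations` / `findings`).
#' @export
write_annotations <- function(annotations, images, path) {
  validate_annotations(annotations)
  write_box_json(annotations, images, path, "annotator_id", "annotations")
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, labels = pathology_labels(),
                             strict = TRUE) {
  r <- read_box_json(path, "annotator_id", "annotations", labels, strict)
  list(images = r$images, annotations = r$records)
}

#' @rdname write_annotations
#' @export
write_ground_truth <- function(findings, images, path) {
  validate_box_df(findings, "ground truth")
  write_box_json(findings, images, path, "support", "findings")
}

#' @rdname write_annotations
#' @export
read_ground_truth <- function(path, labels = pathology_labels(),
                              strict = TRUE) {
  r <- read_box_json(path, "support", "findings", labels, strict)
  list(images = r$images, findings = r$records)
}

#' Read and write reader-study results
#'
#' Reader results travel as RFC-4180 CSV with header
#' `reader_id,condition,image_id,label,call,confidence,time_s`, one row per
#' reader x image x label. A missing `confidence` column is accepted (reader
#' AUC then unavailable, with a warning). Invalid `condition` values or
#' non-binary calls are rejected.
#'
#' @param records Data frame of reader records.
#' @param path File path.
#' @param strict Abort on invalid rows (default) or drop them.
#' @return `read_reader_results()`: the validated data frame.
#' @export
write_reader_results <- function(records, path) {
  validate_reader_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reader_results
#' @export
read_reader_results <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reader_id", "condition", "image_id", "label", "call", "time_s")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop_input(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!"confidence" %in% names(rec)) {
    warning("no confidence column in ", path,
            "; reader AUC will be unavailable", call. = FALSE)
    rec$confidence <- NA_real_
  }
  bad <- !(rec$condition %in% c("aided", "unaided")) |
    !(rec$call %in% c(0, 1)) | is.na(rec$time_s) | rec$time_s <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    detail <- sprintf("%s: row %d invalid (condition '%s', call '%s', time %s)",
                      path, i, rec$condition[i], rec$call[i], rec$time_s[i])
    if (strict) stop_input(detail)
    message(sprintf("skipping %d invalid row(s) in %s; first: %s",
                    sum(bad), path, detail))
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

# ---- configuration ---------------------------------------------------------

#' Write and read a simulation configuration
#'
#' Configurations serialize to a single JSON or YAML document (chosen by
#' file extension). Reading reconstructs a validated [sim_config()].
#'
#' @param config A [sim_config()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_sim_config()`: a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named atomic vectors must become objects, not bare arrays, in JSON
  named <- c("thresholds", "manufacturer_shares", "reader_positive_counts")
  for (f in intersect(named, names(x))) x[[f]] <- as.list(x[[f]])
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyVector = TRUE)
  named <- c("thresholds", "manufacturer_shares", "reader_positive_counts")
  for (f in intersect(named, names(x))) x[[f]] <- unlist(x[[f]])
  for (f in intersect(c("reader_unaided", "reader_aided"), names(x)))
    x[[f]] <- as.list(x[[f]])
  known <- names(formals(sim_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop_input("unknown configuration field(s): ",
               paste(unknown, collapse = ", "))
  do.call(sim_config, x)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# ---- study bundle ----------------------------------------------------------

#' Write and read a complete study bundle
#'
#' A bundle directory holds `manifest.json` (study id, image count, label
#' enumeration, generator config hash, and the image table with cohort
#' assignments), `detections.json`, `annotations.json`,
#' `ground_truth.json` (the generator's true lesions in the ground-truth
#' dialect), `reader_results.csv`, `reader_truth.json`, `metadata.csv` and
#' `config.json`. Every image id referenced in any file exists in the
#' manifest; write-then-read is the identity on all tables.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Bundle directory (created if needed).
#' @param study_id Identifier recorded in the manifest.
#' @return `read_study_bundle()`: a `study_bundle` list.
#' @export
write_study_bundle <- function(bundle, dir, study_id = "synthetic-study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  manifest <- list(study_id = study_id,
                   n_images = nrow(bundle$images),
                   labels = cfg$labels,
                   config_hash = config_hash(cfg),
                   seed = bundle$seed,
                   images = images_out(bundle$images))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_detections(bundle$detections, bundle$images,
                   file.path(dir, "detections.json"))
  write_annotations(bundle$annotations, bundle$images,
                    file.path(dir, "annotations.json"))
  gt <- bundle$truth
  gt$support <- cfg$n_annotators
  write_ground_truth(gt, bundle$images, file.path(dir, "ground_truth.json"))
  write_reader_results(bundle$reader$records,
                       file.path(dir, "reader_results.csv"))
  jsonlite::write_json(list(truth = bundle$reader$truth,
                            images = bundle$reader$images),
                       file.path(dir, "reader_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  write_sim_config(cfg, file.path(dir, "config.json"))
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir, strict = TRUE) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  images <- images_in(man$images)
  cfg <- read_sim_config(file.path(dir, "config.json"))
  det <- read_detections(file.path(dir, "detections.json"),
                         labels = cfg$labels, strict = strict)
  ann <- read_annotations(file.path(dir, "annotations.json"),
                          labels = cfg$labels, strict = strict)
  gt <- read_ground_truth(file.path(dir, "ground_truth.json"),
                          labels = cfg$labels, strict = strict)
  rr <- read_reader_results(file.path(dir, "reader_results.csv"),
                            strict = strict)
  rt <- jsonlite::fromJSON(file.path(dir, "reader_truth.json"),
                           simplifyVector = TRUE)
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  known <- images$image_id
  for (ids in list(det$detections$image_id, ann$annotations$image_id,
                   gt$findings$image_id, meta$image_id)) {
    stray <- setdiff(unique(ids), known)
    if (length(stray))
      stop_input("bundle ", dir, ": image id(s) missing from manifest: ",
                 paste(utils::head(stray, 3), collapse = ", "))
  }
  structure(list(images = images, truth = gt$findings,
                 annotations = ann$annotations, detections = det$detections,
                 reader = list(records = rr, truth = rt$truth,
                               images = rt$images),
                 metadata = meta, config = cfg,
                 seed = man$seed, study_id = man$study_id,
                 config_hash = man$config_hash),
            class = "study_bundle")
}

#' Write an evaluation report as CSV and JSON
#'
#' Emits `<prefix>_counts.csv` (per-pathology confusion counts),
#' `<prefix>_metrics.csv` and `<prefix>_metrics.json` (the metric panel with
#' Wilson intervals, plus the macro-averaged summary in the JSON).
#'
#' @param counts A `confusion_counts` table.
#' @param panel A `metric_panel` table.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_metrics_report <- function(counts, panel, prefix) {
  paths <- paste0(prefix, c("_counts.csv", "_metrics.csv", "_metrics.json"))
  utils::write.csv(as.data.frame(counts), paths[1L], row.names = FALSE)
  utils::write.csv(as.data.frame(panel), paths[2L], row.names = FALSE)
  macro <- summary(panel)
  jsonlite::write_json(list(per_label = as.data.frame(panel),
                            macro = as.list(unclass(macro))),
                       paths[3L], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write an MRMC report as CSV and JSON
#'
#' @param mrmc An `mrmc_summary`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_mrmc_report <- function(mrmc, prefix) {
  paths <- paste0(prefix, c("_mrmc.csv", "_mrmc.json"))
  utils::write.csv(as.data.frame(mrmc), paths[1L], row.names = FALSE)
  jsonlite::write_json(list(summary = as.data.frame(mrmc),
                            readers = attr(mrmc, "readers")),
                       paths[2L], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
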