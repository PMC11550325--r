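ann_key <- function(annotator_id, image_id, round)
  paste(annotator_id, image_id, round, sep = "\r")

#' Assemble a study dataset
#'
#' Container for one two-round annotation study: the image frames, the
#' annotators with their expertise groups, every participant annotation
#' (PRE = unassisted round, POST = AI-assisted round), and per image one
#' consensus ground-truth ring and one AI-prediction ring.
#'
#' Missing PRE/POST entries do not fail construction; they are recorded in
#' the `completeness` element (a data frame of annotator/image/round triples)
#' so downstream summaries can exclude incomplete pairs with a logged count.
#' Missing ground truth or AI prediction for a frame is an error.
#'
#' @param frames List of [image_frame()] (unique ids).
#' @param annotators List of [annotator()].
#' @param annotations List of participant [polygon_annotation()] with rounds
#'   `PRE`/`POST`.
#' @param ground_truth,ai_prediction Lists of [polygon_annotation()], one per
#'   frame, with rounds `GROUND_TRUTH` and `AI_PREDICTION`.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(frames, annotators, annotations, ground_truth,
                          ai_prediction) {
  frame_ids <- vapply(frames, `[[`, "", "image_id")
  if (anyDuplicated(frame_ids)) stop("duplicate image_id among frames")
  names(frames) <- frame_ids
  ann_ids <- vapply(annotators, `[[`, "", "annotator_id")
  if (anyDuplicated(ann_ids)) stop("duplicate annotator_id")
  names(annotators) <- ann_ids

  gt <- stats::setNames(ground_truth, vapply(ground_truth, `[[`, "", "image_id"))
  ai <- stats::setNames(ai_prediction, vapply(ai_prediction, `[[`, "", "image_id"))
  miss_gt <- setdiff(frame_ids, names(gt))
  miss_ai <- setdiff(frame_ids, names(ai))
  if (length(miss_gt))
    stop("missing ground truth for frame(s): ", paste(miss_gt, collapse = ", "))
  if (length(miss_ai))
    stop("missing AI prediction for frame(s): ", paste(miss_ai, collapse = ", "))

  for (a in annotations) {
    if (!a$round %in% c("PRE", "POST"))
      stop("participant annotations must have round PRE or POST")
    if (!a$image_id %in% frame_ids)
      stop("annotation references unknown image: ", a$image_id)
    if (!a$annotator_id %in% ann_ids)
      stop("annotation references unknown annotator: ", a$annotator_id)
  }
  keys <- vapply(annotations, function(a) ann_key(a$annotator_id, a$image_id, a$round), "")
  if (anyDuplicated(keys)) stop("duplicate (annotator, image, round) annotation")
  names(annotations) <- keys

  expected <- expand.grid(annotator_id = ann_ids, image_id = frame_ids,
                          round = c("PRE", "POST"),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  have <- with(expected, ann_key(annotator_id, image_id, round)) %in% keys
  completeness <- expected[!have, , drop = FALSE]
  rownames(completeness) <- NULL

  structure(list(frames = frames, annotators = annotators,
                 annotations = annotations, ground_truth = gt,
                 ai_prediction = ai, completeness = completeness),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset: %d frames, %d annotators, ",
                     "%d participant annotations, %d missing pairs>\n"),
              length(x$frames), length(x$annotators),
              length(x$annotations), nrow(x$completeness)))
  invisible(x)
}

#' Retrieve one annotation from a dataset
#'
#' @param dataset A [study_dataset()].
#' @param annotator_id,image_id,round Key of the annotation; `round` may also
#'   be `"GROUND_TRUTH"` or `"AI_PREDICTION"` (then `annotator_id` is ignored).
#' @return A [polygon_annotation()] or `NULL` if absent.
#' @export
get_annotation <- function(dataset, annotator_id, image_id, round) {
  if (round == "GROUND_TRUTH") return(dataset$ground_truth[[image_id]])
  if (round == "AI_PREDICTION") return(dataset$ai_prediction[[image_id]])
  dataset$annotations[[ann_key(annotator_id, image_id, round)]]
}

feature_of <- function(ann, group = NULL) {
  props <- list(annotator_id = ann$annotator_id, image_id = ann$image_id,
                round = ann$round)
  if (!is.null(group)) props$group <- group
  ring <- unname(rbind(ann$vertices, ann$vertices[1L, ]))  # GeoJSON closed ring
  list(type = "Feature",
       geometry = list(type = "Polygon",
                       coordinates = list(ring)),
       properties = props)
}

#' Write a study dataset to the annotation GeoJSON dialect
#'
#' The file is a GeoJSON `FeatureCollection`: each feature is a `Polygon`
#' with a single exterior ring and properties `annotator_id`, `image_id`,
#' `round` (`PRE`/`POST`/`GROUND_TRUTH`/`AI_PREDICTION`) and, for participant
#' features, `group`; a top-level foreign member `frames` lists
#' `{image_id, width, height, display_order}`.
#'
#' @param dataset A [study_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  feats <- c(
    unname(lapply(dataset$annotations, function(a)
      feature_of(a, group = dataset$annotators[[a$annotator_id]]$group))),
    unname(lapply(dataset$ground_truth, feature_of)),
    unname(lapply(dataset$ai_prediction, feature_of)))
  frames <- lapply(unname(dataset$frames), function(f)
    f[c("image_id", "width", "height", "display_order")])
  doc <- list(type = "FeatureCollection", frames = frames, features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a study dataset from the annotation GeoJSON dialect
#'
#' Parses and validates the file written by [write_dataset()] (or produced by
#' any conforming exporter): all ring invariants are checked, out-of-frame
#' vertices are clipped with one warning per modified ring, and missing
#' PRE/POST pairs are reported in the returned dataset's `completeness`
#' element rather than failing the load. A missing ground truth or AI
#' prediction, an unknown `group` or `round` label, or a ring with fewer than
#' 3 distinct vertices is a schema error naming the offending feature.
#'
#' @param path Path to the annotation file.
#' @return A validated [study_dataset()].
#' @export
load_dataset <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection") || is.null(doc$frames))
    stop("schema error: expected a FeatureCollection with a 'frames' member")
  frames <- lapply(doc$frames, function(f)
    image_frame(f$image_id, f$width, f$height, f$display_order))

  annotators <- list()
  participant <- list()
  gts <- list()
  ais <- list()
  for (ft in doc$features) {
    p <- ft$properties
    if (is.null(p$round) || !p$round %in% ROUNDS)
      stop("schema error: unknown round label for feature ",
           paste(p$annotator_id, p$image_id, sep = "/"))
    if (!identical(ft$geometry$type, "Polygon") ||
        length(ft$geometry$coordinates) != 1L)
      stop("schema error: each feature must be a Polygon with one exterior ring (",
           paste(p$annotator_id, p$image_id, p$round, sep = "/"), ")")
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1L]], unlist))
    if (is.null(ring) || nrow(ring) < 3L)
      stop("schema error: ring with fewer than 3 vertices in feature ",
           paste(p$annotator_id, p$image_id, p$round, sep = "/"))
    ann <- polygon_annotation(p$annotator_id %||% "", p$image_id, p$round, ring)
    if (p$round %in% c("PRE", "POST")) {
      if (is.null(p$group) || !p$group %in% GROUPS)
        stop("schema error: unknown group label for annotator ", p$annotator_id)
      annotators[[p$annotator_id]] <- annotator(p$annotator_id, p$group)
      participant[[length(participant) + 1L]] <- ann
    } else if (p$round == "GROUND_TRUTH") {
      gts[[length(gts) + 1L]] <- ann
    } else {
      ais[[length(ais) + 1L]] <- ann
    }
  }
  ds <- study_dataset(frames, unname(annotators), participant, gts, ais)
  # clip once at load so downstream rasterization never warns repeatedly
  frame_of <- function(a) ds$frames[[a$image_id]]
  ds$annotations <- lapply(ds$annotations, function(a) clip_to_frame(a, frame_of(a)))
  ds$ground_truth <- lapply(ds$ground_truth, function(a) clip_to_frame(a, frame_of(a)))
  ds$ai_prediction <- lapply(ds$ai_prediction, function(a) clip_to_frame(a, frame_of(a)))
  if (nrow(ds$completeness))
    message(sprintf("load_dataset: %d missing round entr%s (see $completeness)",
                    nrow(ds$completeness),
                    if (nrow(ds$completeness) == 1L) "y" else "ies"))
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
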