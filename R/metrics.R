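#' Pixel overlap counts between ground truth and a predicted mask
#'
#' Exact set-algebra pixel counts: `tp = |GT intersect P|`, `fp = |P \ GT|`,
#' `fn = |GT \ P|`. These satisfy `tp + fp = |P|`, `tp + fn = |GT|` and
#' `tp + fp + fn = |GT union P|`.
#'
#' @param gt,p [binary_mask()]s of equal dimensions (ground truth, prediction).
#' @return A list of class `overlap_counts` with integer fields `tp`, `fp`,
#'   `fn`.
#' @export
overlap_counts <- function(gt, p) {
  if (!all(dim(gt) == dim(p)))
    stop(sprintf("mask dimension mismatch: %dx%d vs %dx%d",
                 nrow(gt), ncol(gt), nrow(p), ncol(p)))
  k <- overlap_counts_cpp(gt, p)
  structure(list(tp = k[[1L]], fp = k[[2L]], fn = k[[3L]]),
            class = "overlap_counts")
}

#' DICE similarity coefficient from overlap counts
#'
#' `2 tp / (2 tp + fp + fn)`, i.e. `2|A intersect B| / (|A| + |B|)`. When both
#' masks are empty the score is 1.0 by convention (perfect agreement on
#' absence); when exactly one is empty it is 0.
#'
#' @param counts An [overlap_counts()].
#' @return DICE score in `[0, 1]`.
#' @export
dice <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1.0)
  2 * counts$tp / denom
}

#' Union-normalized false-positive and false-negative area fractions
#'
#' The false-positive fraction is the area labelled by the annotator that
#' falls outside ground truth, and the false-negative fraction the
#' ground-truth area the annotator missed, each divided by the area of the
#' union of the two labels. With this denominator the DICE score is recovered
#' exactly as `2 (1 - fp - fn) / (2 - fp - fn)`.
#'
#' @param counts An [overlap_counts()] with non-empty union.
#' @return Named numeric vector `c(fp_frac =, fn_frac =)`.
#' @export
error_fractions <- function(counts) {
  union <- counts$tp + counts$fp + counts$fn
  if (union == 0)
    stop("error fractions undefined: both masks are empty")
  c(fp_frac = counts$fp / union, fn_frac = counts$fn / union)
}

#' Area centroid of a binary mask
#'
#' Arithmetic mean of the centres `(r + 0.5, c + 0.5)` of the true pixels,
#' in (row, col) order with 0-based pixel indices. The centroid of a
#' non-convex mask (e.g. an annulus) may fall outside the true-pixel set.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Numeric `c(row =, col =)` in continuous pixel coordinates.
#' @export
mask_centroid <- function(mask) {
  ctr <- mask_centroid_cpp(mask)
  if (anyNA(ctr)) stop("centroid undefined: mask is empty")
  c(row = ctr[[1L]], col = ctr[[2L]])
}

#' Does an annotation cover the ground-truth centroid?
#'
#' The centroid of the ground-truth mask is an approximation of the middle of
#' the sella; the test asks whether the pixel containing that point (floor of
#' each coordinate) is labelled in the participant mask.
#'
#' @param gt Non-empty ground-truth [binary_mask()].
#' @param p Participant [binary_mask()] of the same dimensions.
#' @return Logical scalar.
#' @export
centroid_contained <- function(gt, p) {
  if (!all(dim(gt) == dim(p))) stop("mask dimension mismatch")
  ctr <- mask_centroid(gt)
  p[floor(ctr[["row"]]) + 1L, floor(ctr[["col"]]) + 1L]
}

#' Score one annotation against ground truth
#'
#' Combines [dice()], [error_fractions()] and [centroid_contained()] into one
#' per-annotation record. An empty participant mask scores
#' `dice = 0, fp_frac = 0, fn_frac = 1, centroid_hit = FALSE`.
#'
#' @param gt Non-empty ground-truth [binary_mask()].
#' @param p Participant [binary_mask()] of the same dimensions.
#' @param annotator_id,image_id,round Identifiers copied into the record.
#' @return One-row data frame with columns `annotator_id`, `image_id`,
#'   `round`, `dice`, `fp_frac`, `fn_frac`, `centroid_hit`.
#' @export
evaluate_annotation <- function(gt, p, annotator_id = NA_character_,
                                image_id = NA_character_,
                                round = NA_character_) {
  counts <- overlap_counts(gt, p)
  if (counts$tp + counts$fn == 0L) stop("ground truth mask is empty")
  fr <- error_fractions(counts)
  data.frame(annotator_id = annotator_id, image_id = image_id, round = round,
             dice = dice(counts), fp_frac = unname(fr["fp_frac"]),
             fn_frac = unname(fr["fn_frac"]),
             centroid_hit = centroid_contained(gt, p),
             stringsAsFactors = FALSE)
}

#' Classify the change between the unassisted and AI-assisted annotation
#'
#' An annotation counts as changed if any pixel differs between the two
#' rasterized masks (exact equality; the most conservative reading). The
#' DICE outcome compares the two scores with tolerance `tol`: an unchanged
#' annotation is always `UNCHANGED`, and a changed one whose DICE moved by
#' less than `tol` is also `UNCHANGED`.
#'
#' @param pre_mask,post_mask [binary_mask()]s of the two rounds.
#' @param pre_record,post_record Records from [evaluate_annotation()] for the
#'   same annotator/image.
#' @param tol DICE comparison tolerance (default `1e-9`, effectively exact).
#' @return One-row data frame with `annotator_id`, `image_id`,
#'   `annotation_changed`, `dice_outcome` (`IMPROVED`/`WORSENED`/`UNCHANGED`).
#' @export
classify_change <- function(pre_mask, post_mask, pre_record, post_record,
                            tol = 1e-9) {
  if (!identical(pre_record$annotator_id, post_record$annotator_id) ||
      !identical(pre_record$image_id, post_record$image_id))
    stop("classify_change: pre/post records refer to different annotator or image")
  if (!all(dim(pre_mask) == dim(post_mask))) stop("mask dimension mismatch")
  changed <- !identical(unclass(pre_mask), unclass(post_mask))
  d <- post_record$dice - pre_record$dice
  outcome <- if (!changed || abs(d) < tol) "UNCHANGED"
             else if (d > 0) "IMPROVED" else "WORSENED"
  data.frame(annotator_id = pre_record$annotator_id,
             image_id = pre_record$image_id,
             annotation_changed = changed, dice_outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Score every complete annotation pair in a study dataset
#'
#' Rasterizes ground truth once per frame, scores every participant
#' annotation against it, and classifies pre-to-post changes for every
#' complete PRE/POST pair. Incomplete pairs (listed in the dataset's
#' `completeness` element) are excluded from the change records.
#'
#' @param dataset A [study_dataset()].
#' @return List with `metrics` (one row per annotation: `annotator_id`,
#'   `group`, `image_id`, `round`, `dice`, `fp_frac`, `fn_frac`,
#'   `centroid_hit`) and `changes` (one row per complete pair, from
#'   [classify_change()]), plus `ai_metrics` (the AI prediction scored
#'   against ground truth per frame).
#' @export
evaluate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  gt_masks <- lapply(dataset$ground_truth, function(g)
    rasterize(g, dataset$frames[[g$image_id]]))
  groups <- vapply(dataset$annotators, `[[`, "", "group")

  # stream one annotator-image pair at a time so only two participant masks
  # are ever held in memory
  rows <- list()
  change_rows <- list()
  for (aid in names(dataset$annotators)) {
    for (img in names(dataset$frames)) {
      frame <- dataset$frames[[img]]
      pre_ann <- get_annotation(dataset, aid, img, "PRE")
      post_ann <- get_annotation(dataset, aid, img, "POST")
      pre_rec <- post_rec <- NULL
      pre_mask <- post_mask <- NULL
      if (!is.null(pre_ann)) {
        pre_mask <- rasterize(pre_ann, frame)
        pre_rec <- evaluate_annotation(gt_masks[[img]], pre_mask, aid, img, "PRE")
        pre_rec$group <- groups[[aid]]
        rows[[length(rows) + 1L]] <- pre_rec
      }
      if (!is.null(post_ann)) {
        post_mask <- rasterize(post_ann, frame)
        post_rec <- evaluate_annotation(gt_masks[[img]], post_mask, aid, img, "POST")
        post_rec$group <- groups[[aid]]
        rows[[length(rows) + 1L]] <- post_rec
      }
      if (!is.null(pre_rec) && !is.null(post_rec)) {
        ch <- classify_change(pre_mask, post_mask, pre_rec, post_rec)
        ch$group <- groups[[aid]]
        change_rows[[length(change_rows) + 1L]] <- ch
      }
    }
  }
  metrics <- do.call(rbind, rows)
  metrics <- metrics[, c("annotator_id", "group", "image_id", "round",
                         "dice", "fp_frac", "fn_frac", "centroid_hit")]
  metrics <- metrics[order(metrics$annotator_id, metrics$image_id,
                           metrics$round), , drop = FALSE]
  rownames(metrics) <- NULL

  changes <- do.call(rbind, change_rows)
  if (!is.null(changes)) {
    changes <- changes[order(changes$annotator_id, changes$image_id), ]
    rownames(changes) <- NULL
  }

  ai_rows <- lapply(dataset$ai_prediction, function(a)
    evaluate_annotation(gt_masks[[a$image_id]],
                        rasterize(a, dataset$frames[[a$image_id]]),
                        "AI", a$image_id, "AI_PREDICTION"))
  ai_metrics <- do.call(rbind, ai_rows)
  rownames(ai_metrics) <- NULL
  list(metrics = metrics, changes = changes, ai_metrics = ai_metrics)
}
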