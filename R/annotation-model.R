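#' @useDynLib sellabench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ROUNDS <- c("PRE", "POST", "GROUND_TRUTH", "AI_PREDICTION")
GROUPS <- c("STUDENT", "JUNIOR", "INTERMEDIATE", "EXPERT")

#' Create an image frame
#'
#' An `image_frame` records the pixel grid a set of annotations lives on:
#' its identifier, width and height in pixels, and the order in which the
#' image was presented to participants.
#'
#' @param image_id Character scalar, unique within a dataset.
#' @param width,height Positive integer pixel dimensions.
#' @param display_order Integer >= 1, the presentation position.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(image_id, width, height, display_order = 1L) {
  stopifnot(is.character(image_id), length(image_id) == 1L, nzchar(image_id))
  width <- as.integer(width); height <- as.integer(height)
  display_order <- as.integer(display_order)
  if (is.na(width) || width <= 0L || is.na(height) || height <= 0L)
    stop("frame dimensions must be positive integers")
  if (is.na(display_order) || display_order < 1L)
    stop("display_order must be an integer >= 1")
  structure(list(image_id = image_id, width = width, height = height,
                 display_order = display_order),
            class = "image_frame")
}

#' Create an annotator
#'
#' @param annotator_id Character scalar.
#' @param group One of `"STUDENT"`, `"JUNIOR"`, `"INTERMEDIATE"`, `"EXPERT"`.
#'   Group membership is fixed across both annotation rounds.
#' @return An object of class `annotator`.
#' @export
annotator <- function(annotator_id, group) {
  stopifnot(is.character(annotator_id), length(annotator_id) == 1L)
  group <- match.arg(group, GROUPS)
  structure(list(annotator_id = annotator_id, group = group),
            class = "annotator")
}

#' Create a polygon annotation
#'
#' One closed-ring sella outline drawn by one annotator on one image in one
#' round, in continuous pixel coordinates (origin top-left, x rightward,
#' y downward). The ring is implicitly closed: the last vertex connects back
#' to the first. On construction the ring is cleaned: a repeated closing
#' vertex and consecutive duplicate vertices are dropped, and a
#' self-intersecting ring is rejected rather than silently repaired.
#'
#' @param annotator_id,image_id Character identifiers.
#' @param round One of `"PRE"`, `"POST"`, `"GROUND_TRUTH"`, `"AI_PREDICTION"`.
#' @param vertices Two-column numeric matrix (x, y) with >= 3 distinct rows
#'   after cleaning.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(annotator_id, image_id, round, vertices) {
  round <- match.arg(round, ROUNDS)
  vertices <- clean_ring(vertices,
                         label = sprintf("%s/%s/%s", annotator_id, image_id, round))
  structure(list(annotator_id = annotator_id, image_id = image_id,
                 round = round, vertices = vertices),
            class = "polygon_annotation")
}

# Ring cleaning rule: coerce to an n x 2 double matrix; drop an explicit
# closing vertex equal to the first; drop consecutive duplicates; require
# >= 3 vertices; reject self-intersection (no silent repair - repair would
# change areas invisibly).
clean_ring <- function(vertices, label = "ring") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || !is.numeric(vertices) || anyNA(vertices))
    stop(sprintf("%s: vertices must be a numeric n x 2 matrix without NAs", label))
  storage.mode(vertices) <- "double"
  n <- nrow(vertices)
  if (n > 1L && all(vertices[n, ] == vertices[1L, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(vertices))) == 0)
    vertices <- vertices[!dup, , drop = FALSE]
  }
  if (nrow(vertices) < 3L)
    stop(sprintf("%s: a ring needs at least 3 distinct vertices", label))
  if (!ring_is_simple_cpp(vertices[, 1L], vertices[, 2L]))
    stop(sprintf("%s: self-intersecting ring rejected", label))
  dimnames(vertices) <- list(NULL, c("x", "y"))
  vertices
}

# Clip out-of-frame vertices to [0, width] x [0, height] with a warning;
# annotation tools permit slight overshoot.
clip_to_frame <- function(ann, frame) {
  v <- ann$vertices
  cx <- pmin(pmax(v[, 1L], 0), frame$width)
  cy <- pmin(pmax(v[, 2L], 0), frame$height)
  if (any(cx != v[, 1L]) || any(cy != v[, 2L])) {
    warning(sprintf("clipped out-of-frame vertices in %s/%s/%s",
                    ann$annotator_id, ann$image_id, ann$round),
            call. = FALSE)
    ann$vertices <- clean_ring(cbind(cx, cy),
                               label = sprintf("%s/%s/%s (clipped)",
                                               ann$annotator_id, ann$image_id,
                                               ann$round))
  }
  ann
}

#' Create a binary mask
#'
#' @param grid Logical matrix (rows = image rows, columns = image columns).
#' @return An object of class `binary_mask`: the logical matrix with the
#'   class attribute set.
#' @export
binary_mask <- function(grid) {
  if (!is.matrix(grid) || !is.logical(grid) || anyNA(grid))
    stop("grid must be a logical matrix without NAs")
  class(grid) <- c("binary_mask", "matrix", "array")
  grid
}

#' Rasterize a polygon annotation to a binary mask
#'
#' Scanline even-odd fill on the frame's pixel grid: pixel (r, c) is set iff
#' its centre (c + 0.5, r + 0.5) lies inside the ring. Rasterization of an
#' axis-aligned rectangle with integer corners is exact, and the operation is
#' deterministic.
#'
#' @param polygon A [polygon_annotation()].
#' @param frame An [image_frame()]. Vertices outside the frame are clipped
#'   with a warning.
#' @return A [binary_mask()] of the frame's dimensions.
#' @export
rasterize <- function(polygon, frame) {
  stopifnot(inherits(polygon, "polygon_annotation"), inherits(frame, "image_frame"))
  polygon <- clip_to_frame(polygon, frame)
  v <- polygon$vertices
  grid <- rasterize_ring_cpp(v[, 1L], v[, 2L], frame$width, frame$height)
  if (!any(grid))
    stop(sprintf("degenerate annotation (zero rasterized area): %s/%s/%s",
                 polygon$annotator_id, polygon$image_id, polygon$round))
  binary_mask(grid)
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %s: %dx%d px, shown #%d>\n",
              x$image_id, x$width, x$height, x$display_order))
  invisible(x)
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation %s/%s/%s: %d vertices>\n",
              x$annotator_id, x$image_id, x$round, nrow(x$vertices)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d: area %d px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
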