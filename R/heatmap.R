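#' Per-pixel multi-rater agreement map
#'
#' Counts, at every pixel, how many of the supplied annotator masks label it.
#' Summed over pixels the counts equal the summed member-mask areas, and the
#' map is invariant to the order of the masks.
#'
#' @param masks Non-empty list of [binary_mask()]s of equal dimensions (the
#'   annotations of one subgroup on one image in one round).
#' @param image_id,round,group Key recorded on the map.
#' @return An object of class `agreement_map`: list with the integer `counts`
#'   raster, `n_annotators`, and the key fields.
#' @export
agreement_map <- function(masks, image_id = NA_character_,
                          round = NA_character_, group = NA_character_) {
  if (!length(masks)) stop("agreement_map: empty mask list")
  d <- dim(masks[[1L]])
  counts <- matrix(0L, d[1L], d[2L])
  for (m in masks) {
    if (!all(dim(m) == d)) stop("agreement_map: mask dimension mismatch")
    counts <- counts + unclass(m)
  }
  structure(list(counts = counts, n_annotators = length(masks),
                 image_id = image_id, round = round, group = group),
            class = "agreement_map")
}

#' @export
print.agreement_map <- function(x, ...) {
  cat(sprintf("<agreement_map %s/%s/%s: %dx%d, n=%d, max count %d>\n",
              x$group, x$image_id, x$round, nrow(x$counts), ncol(x$counts),
              x$n_annotators, max(x$counts)))
  invisible(x)
}

# Stamp a polygon outline onto an RGB integer array by dense sampling of the
# ring's edges (step 0.25 px), setting the pixel under each sample.
draw_ring <- function(rgb, ring, colour) {
  v <- rbind(ring$vertices, ring$vertices[1L, ])
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  for (i in seq_len(nrow(v) - 1L)) {
    len <- sqrt(sum((v[i + 1L, ] - v[i, ])^2))
    nstep <- max(2L, ceiling(len / 0.25))
    t <- seq(0, 1, length.out = nstep)
    cx <- floor(v[i, 1L] + t * (v[i + 1L, 1L] - v[i, 1L])) + 1L
    cy <- floor(v[i, 2L] + t * (v[i + 1L, 2L] - v[i, 2L])) + 1L
    keep <- cx >= 1L & cx <= w & cy >= 1L & cy <= h
    for (ch in 1:3) rgb[cbind(cy[keep], cx[keep], ch)] <- colour[ch]
  }
  rgb
}

#' Render an agreement map to a PNG heat map
#'
#' Counts are normalized by the subgroup size `n_annotators` (so pre- and
#' post-assistance maps of one subgroup share a scale) and mapped through a
#' pinned sequential colormap; the ground-truth ring is overlaid in white and
#' the AI-prediction ring in black. Rendering is deterministic: identical
#' inputs produce byte-identical files.
#'
#' @param map An [agreement_map()].
#' @param gt_ring,ai_ring [polygon_annotation()]s to overlay (either may be
#'   `NULL` to omit).
#' @param path Output PNG path.
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, gt_ring, ai_ring, path, colormap = "viridis") {
  stopifnot(inherits(map, "agreement_map"))
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256L, colormap))
  v <- pmin(map$counts / map$n_annotators, 1)
  idx <- pmin(255L, as.integer(floor(v * 256))) + 1L
  h <- nrow(map$counts); w <- ncol(map$counts)
  rgb <- array(0L, c(h, w, 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[ch, idx], h, w)
  if (!is.null(gt_ring)) rgb <- draw_ring(rgb, gt_ring, c(255L, 255L, 255L))
  if (!is.null(ai_ring)) rgb <- draw_ring(rgb, ai_ring, c(0L, 0L, 0L))
  png_write_rgb(rgb, path)
}
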