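# Ring samples per generated polygon: sub-pixel angular resolution at the
# default 720x576 frame.
RING_SAMPLES <- 360L

#' Shape parameters for a synthetic sella-like ground truth
#'
#' The ground-truth outline is a star-convex radial shape
#' `r(theta) = r_ellipse(theta) * (1 + sum_k a_k cos(k theta + phi_k))`:
#' an ellipse whose radius is modulated by a few low-order harmonics, which
#' gives smooth organ-like outlines without self-intersection.
#'
#' @param center Numeric `(x, y)` centre in pixels.
#' @param semi_axes Numeric `(a, b)` ellipse semi-axes in pixels, both > 0.
#' @param n_harmonics Number of radial harmonics (default 4).
#' @param harmonic_amp_max Total harmonic amplitude bound as a fraction of
#'   the radius; must be < 1 so the radius stays positive and the ring
#'   star-convex about the centre (default 0.12).
#' @return A list of class `shape_params`.
#' @export
shape_params <- function(center, semi_axes, n_harmonics = 4L,
                         harmonic_amp_max = 0.12) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes > 0), n_harmonics >= 0L,
            harmonic_amp_max >= 0, harmonic_amp_max < 1)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_amp_max = harmonic_amp_max),
            class = "shape_params")
}

#' Behavioural profile of a simulated annotator
#'
#' @param group Expertise group label (see [annotator()]).
#' @param boundary_noise_sd Standard deviation of the smooth relative radial
#'   error, as a fraction of the local radius.
#' @param center_offset_sd Standard deviation (pixels) of the Gaussian
#'   placement offset of the whole annotation.
#' @param adoption_prob Probability that the annotator revises their
#'   annotation when shown the AI prediction.
#' @param blend_weight When revising, the weight given to the AI radial
#'   profile (1 = replace with the AI outline, 0 = keep own outline).
#' @return A list of class `annotator_profile`.
#' @export
annotator_profile <- function(group, boundary_noise_sd, center_offset_sd,
                              adoption_prob, blend_weight) {
  group <- match.arg(group, GROUPS)
  stopifnot(boundary_noise_sd >= 0, center_offset_sd >= 0,
            adoption_prob >= 0, adoption_prob <= 1,
            blend_weight >= 0, blend_weight <= 1)
  structure(list(group = group, boundary_noise_sd = boundary_noise_sd,
                 center_offset_sd = center_offset_sd,
                 adoption_prob = adoption_prob, blend_weight = blend_weight),
            class = "annotator_profile")
}

#' Default expertise-group profiles
#'
#' Noise decreases and AI scepticism increases with expertise: students have
#' the largest boundary noise and placement error and adopt the AI suggestion
#' most often and most fully (adoption 0.9), while experts have the least
#' noise and adopt least (adoption 0.3). These defaults are chosen to
#' reproduce the qualitative structure of a human-vs-AI annotation study -
#' monotone expertise ordering of unassisted accuracy and of AI uptake - not
#' any particular numeric result.
#'
#' @return Named list of [annotator_profile()]s, one per group.
#' @export
default_profiles <- function() {
  list(
    STUDENT      = annotator_profile("STUDENT",      0.40, 22, 0.90, 0.85),
    JUNIOR       = annotator_profile("JUNIOR",       0.32, 16, 0.75, 0.75),
    INTERMEDIATE = annotator_profile("INTERMEDIATE", 0.30, 14, 0.50, 0.65),
    EXPERT       = annotator_profile("EXPERT",       0.26, 10, 0.30, 0.50)
  )
}

#' Configuration of a synthetic annotation study
#'
#' Defaults mirror the evaluated study design: 6 images on a 720x576 (PAL
#' video geometry) frame, 4 expertise groups of 6 annotators each, two
#' rounds, and an AI prediction of DICE 0.85 +/- 0.02 against ground truth.
#'
#' @param n_images Number of image frames.
#' @param frame_width,frame_height Frame size in pixels.
#' @param groups Named list `group -> list(n, profile)`; defaults to 6
#'   annotators per group with [default_profiles()].
#' @param ai_target_dice Target DICE of the simulated AI prediction.
#' @param ai_tolerance Acceptable deviation from the target.
#' @param seed Mandatory integer seed; every generated dataset is a pure
#'   function of this configuration.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_images = 6L, frame_width = 720L, frame_height = 576L,
                         groups = NULL, ai_target_dice = 0.85,
                         ai_tolerance = 0.02, seed) {
  if (missing(seed) || is.null(seed)) stop("study_config: seed is mandatory")
  if (is.null(groups))
    groups <- lapply(default_profiles(), function(p) list(n = 6L, profile = p))
  stopifnot(n_images >= 1L, frame_width > 0L, frame_height > 0L,
            ai_target_dice > 0, ai_target_dice <= 1, ai_tolerance >= 0)
  for (g in groups) stopifnot(g$n >= 1L, inherits(g$profile, "annotator_profile"))
  structure(list(n_images = as.integer(n_images),
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 groups = groups, ai_target_dice = ai_target_dice,
                 ai_tolerance = ai_tolerance, seed = as.integer(seed)),
            class = "study_config")
}

ring_angles <- function(k = RING_SAMPLES) (seq_len(k) - 1L) * 2 * pi / k

# Smooth zero-mean noise profile over the sample angles: a mixture of the
# first m harmonics with Gaussian coefficients scaled so the pointwise
# standard deviation equals sd.
smooth_noise <- function(theta, sd, m = 4L) {
  if (sd == 0) return(numeric(length(theta)))
  amp <- sd / sqrt(m)
  g <- numeric(length(theta))
  for (k in seq_len(m))
    g <- g + stats::rnorm(1, 0, amp) * cos(k * theta) +
             stats::rnorm(1, 0, amp) * sin(k * theta)
  g
}

ring_from_radial <- function(center, theta, r, annotator_id, image_id, round) {
  polygon_annotation(annotator_id, image_id, round,
                     cbind(center[1L] + r * cos(theta),
                           center[2L] + r * sin(theta)))
}

# Radial profile of a ring about an arbitrary interior point, by casting a
# ray at each angle and taking the farthest edge crossing. Exact for
# star-convex rings; well-defined for any simple ring.
radial_resample <- function(ring, center, theta) {
  v <- ring$vertices
  n <- nrow(v)
  px <- v[, 1L] - center[1L]; py <- v[, 2L] - center[2L]
  qx <- c(px[-1L], px[1L]);   qy <- c(py[-1L], py[1L])
  ex <- qx - px; ey <- qy - py
  r <- numeric(length(theta))
  for (i in seq_along(theta)) {
    dx <- cos(theta[i]); dy <- sin(theta[i])
    # solve p + s*e = t*d for each edge
    det <- ex * dy - ey * dx
    s <- -(px * dy - py * dx) / det
    t <- (px * ey - py * ex) / -det
    ok <- is.finite(s) & s >= 0 & s < 1 & t > 0
    if (!any(ok))
      stop("radial_resample: centre is not interior to the ring")
    r[i] <- max(t[ok])
  }
  r
}

# Largest radius along each angle that keeps the vertex at least margin px
# inside the frame.
max_radius_in_frame <- function(center, theta, frame, margin = 1) {
  dx <- cos(theta); dy <- sin(theta)
  lim <- function(dist, dirc) ifelse(abs(dirc) < 1e-12, Inf, dist / abs(dirc))
  pmin(lim(ifelse(dx > 0, frame$width - margin - center[1L], center[1L] - margin), dx),
       lim(ifelse(dy > 0, frame$height - margin - center[2L], center[2L] - margin), dy))
}

#' Generate a synthetic ground-truth sella outline
#'
#' Samples the radial shape of [shape_params()] at `RING_SAMPLES` equal
#' angles. Harmonic amplitudes are drawn uniformly and rescaled so their
#' total stays below `harmonic_amp_max`, keeping the ring star-convex about
#' its centre (hence the centroid pixel lies inside the shape). Uses the
#' current R random number stream; call [set.seed()] (or use
#' [generate_study()]) for reproducibility.
#'
#' @param frame Target [image_frame()]; the shape must fit inside it.
#' @param params A [shape_params()].
#' @param image_id Identifier stamped on the annotation.
#' @return A `GROUND_TRUTH` [polygon_annotation()].
#' @export
generate_gt_shape <- function(frame, params, image_id = "img") {
  stopifnot(inherits(params, "shape_params"))
  theta <- ring_angles()
  a <- params$semi_axes[1L]; b <- params$semi_axes[2L]
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  mod <- numeric(length(theta))
  if (params$n_harmonics > 0L && params$harmonic_amp_max > 0) {
    raw <- stats::runif(params$n_harmonics, 0, 1) / seq_len(params$n_harmonics)
    amps <- raw / sum(raw) * stats::runif(1, 0.5, 1) * params$harmonic_amp_max
    phis <- stats::runif(params$n_harmonics, 0, 2 * pi)
    for (k in seq_len(params$n_harmonics))
      mod <- mod + amps[k] * cos(k * theta + phis[k])
  }
  r <- r_ell * (1 + mod)
  if (any(r > max_radius_in_frame(params$center, theta, frame)))
    stop("generate_gt_shape: shape exceeds the frame")
  ring_from_radial(params$center, theta, r, "GT", image_id, "GROUND_TRUTH")
}

#' Generate an AI prediction of controlled quality
#'
#' Perturbs the ground-truth radial profile with a fixed smooth noise shape
#' whose amplitude is found by bisection until the rasterized DICE against
#' ground truth lands in `[target - tol, target + tol]`. A target of 1
#' returns an exact copy.
#'
#' @param gt Ground-truth [polygon_annotation()].
#' @param frame The owning [image_frame()].
#' @param target_dice Target DICE in (0, 1].
#' @param tol Acceptance half-width (> 0 unless `target_dice == 1`).
#' @param max_iter Bisection iteration cap before a convergence error.
#' @return An `AI_PREDICTION` [polygon_annotation()].
#' @export
generate_ai_prediction <- function(gt, frame, target_dice = 0.85, tol = 0.02,
                                   max_iter = 60L) {
  stopifnot(target_dice > 0, target_dice <= 1)
  if (target_dice == 1)
    return(polygon_annotation("AI", gt$image_id, "AI_PREDICTION", gt$vertices))
  theta <- ring_angles()
  center <- colMeans(gt$vertices)
  center <- c(center[[1L]], center[[2L]])
  r0 <- radial_resample(gt, center, theta)
  shape <- smooth_noise(theta, 1, m = 4L)  # unit-sd noise shape, scaled below
  rmax <- max_radius_in_frame(center, theta, frame)
  gt_mask <- rasterize(gt, frame)
  ring_at <- function(s)
    ring_from_radial(center, theta, pmin(pmax(r0 * (1 + s * shape), 1), rmax),
                     "AI", gt$image_id, "AI_PREDICTION")
  dice_at <- function(s) dice(overlap_counts(gt_mask, rasterize(ring_at(s), frame)))
  lo <- 0; hi <- 0.05
  it <- 0L
  while (dice_at(hi) > target_dice) {
    lo <- hi; hi <- hi * 2
    it <- it + 1L
    if (it > 20L) stop("generate_ai_prediction: target DICE unattainable")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    d <- dice_at(mid)
    if (abs(d - target_dice) <= tol) return(ring_at(mid))
    if (d > target_dice) lo <- mid else hi <- mid
  }
  stop("generate_ai_prediction: bisection did not converge to target DICE")
}

#' Simulate one unassisted (round 1) annotation
#'
#' The ground-truth radial profile about its centroid is multiplied by
#' `1 + g(theta)` with `g` a smooth noise profile of pointwise sd
#' `boundary_noise_sd`, and the whole outline is shifted by a Gaussian
#' placement offset of sd `center_offset_sd` per coordinate. Radii are
#' clamped so the ring stays at least 1 px inside the frame. With both noise
#' parameters zero the ground-truth ring is returned verbatim.
#'
#' @param gt Ground-truth [polygon_annotation()].
#' @param frame The owning [image_frame()].
#' @param profile An [annotator_profile()].
#' @param annotator_id Identifier stamped on the annotation.
#' @return A `PRE` [polygon_annotation()].
#' @export
simulate_annotation_pre <- function(gt, frame, profile, annotator_id = "A") {
  stopifnot(inherits(profile, "annotator_profile"))
  if (profile$boundary_noise_sd == 0 && profile$center_offset_sd == 0)
    return(polygon_annotation(annotator_id, gt$image_id, "PRE", gt$vertices))
  theta <- ring_angles()
  center <- colMeans(gt$vertices)
  center <- c(center[[1L]], center[[2L]])
  r0 <- radial_resample(gt, center, theta)
  g <- smooth_noise(theta, profile$boundary_noise_sd)
  offset <- stats::rnorm(2L, 0, profile$center_offset_sd)
  new_center <- c(
    min(max(center[1L] + offset[1L], 2), frame$width - 2),
    min(max(center[2L] + offset[2L], 2), frame$height - 2))
  r <- pmin(pmax(r0 * (1 + g), 1), max_radius_in_frame(new_center, theta, frame))
  ring_from_radial(new_center, theta, r, annotator_id, gt$image_id, "PRE")
}

# even-odd membership test of a point in a closed ring
point_in_ring <- function(pt, vertices) {
  x <- vertices[, 1L]; y <- vertices[, 2L]
  xj <- c(x[-1L], x[1L]); yj <- c(y[-1L], y[1L])
  crossing <- ((y <= pt[2L]) != (yj <= pt[2L]))
  if (!any(crossing)) return(FALSE)
  xint <- x[crossing] + (pt[2L] - y[crossing]) / (yj[crossing] - y[crossing]) *
    (xj[crossing] - x[crossing])
  sum(pt[1L] < xint) %% 2L == 1L
}

# A point interior to both rings: the pre centroid when possible, otherwise
# a pixel centre of the rasterized intersection (whose membership rule is
# exactly "centre inside both rings"). NULL if the rings are disjoint.
blend_center <- function(pre, ai, frame) {
  ctr <- colMeans(pre$vertices)
  ctr <- c(ctr[[1L]], ctr[[2L]])
  if (point_in_ring(ctr, pre$vertices) && point_in_ring(ctr, ai$vertices))
    return(ctr)
  inter <- unclass(rasterize(pre, frame)) & unclass(rasterize(ai, frame))
  if (!any(inter)) return(NULL)
  idx <- which(inter, arr.ind = TRUE)
  ctrs <- cbind(idx[, 2L] - 0.5, idx[, 1L] - 0.5)  # (x, y) pixel centres
  mid <- colMeans(ctrs)
  ctrs[which.min((ctrs[, 1L] - mid[1L])^2 + (ctrs[, 2L] - mid[2L])^2), ]
}

#' Simulate one AI-assisted (round 2) annotation
#'
#' With probability `adoption_prob` the annotator revises: the result's
#' radial profile about the pre-annotation's centroid is
#' `blend_weight * AI + (1 - blend_weight) * pre`, both profiles resampled at
#' matching angles. Otherwise the pre annotation is returned unmodified
#' (exact vertex equality). When the pre centroid is not interior to both
#' rings (a heavily displaced annotation), the blend is taken about a point
#' of their intersection instead; if the two rings are disjoint the
#' annotator either keeps their annotation (`blend_weight < 0.5`) or takes
#' the AI outline verbatim.
#'
#' @param pre The annotator's round-1 [polygon_annotation()].
#' @param ai The `AI_PREDICTION` [polygon_annotation()] for the same image.
#' @param frame The owning [image_frame()].
#' @param profile An [annotator_profile()].
#' @return A `POST` [polygon_annotation()].
#' @export
simulate_annotation_post <- function(pre, ai, frame, profile) {
  stopifnot(inherits(profile, "annotator_profile"))
  adopt <- stats::runif(1) < profile$adoption_prob
  if (!adopt)
    return(polygon_annotation(pre$annotator_id, pre$image_id, "POST",
                              pre$vertices))
  theta <- ring_angles()
  center <- blend_center(pre, ai, frame)
  if (is.null(center)) {
    keep <- profile$blend_weight < 0.5
    src <- if (keep) pre else ai
    return(polygon_annotation(pre$annotator_id, pre$image_id, "POST",
                              src$vertices))
  }
  r_pre <- radial_resample(pre, center, theta)
  r_ai <- radial_resample(ai, center, theta)
  w <- profile$blend_weight
  r <- pmin(pmax(w * r_ai + (1 - w) * r_pre, 1),
            max_radius_in_frame(center, theta, frame))
  ring_from_radial(center, theta, r, pre$annotator_id, pre$image_id, "POST")
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  code
}

#' Generate a complete synthetic study
#'
#' Produces, deterministically from the configuration's seed, `n_images`
#' frames with one sella-like ground truth and one AI prediction each, and a
#' PRE and POST annotation for every annotator-image pair (288 participant
#' annotations at the default 24 x 6 x 2 design). The caller's random number
#' stream is left untouched.
#'
#' @param config A [study_config()].
#' @return A [study_dataset()].
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_preserved_rng({
    set.seed(config$seed)
    w <- config$frame_width; h <- config$frame_height
    order <- sample.int(config$n_images)
    frames <- lapply(seq_len(config$n_images), function(i)
      image_frame(sprintf("img%02d", i), w, h, order[i]))

    gts <- list(); ais <- list()
    for (i in seq_len(config$n_images)) {
      f <- frames[[i]]
      center <- c(w / 2 + stats::runif(1, -0.06, 0.06) * w,
                  h / 2 + stats::runif(1, -0.06, 0.06) * h)
      axes <- c(stats::runif(1, 0.13, 0.18) * w, stats::runif(1, 0.15, 0.21) * h)
      gts[[i]] <- generate_gt_shape(f, shape_params(center, axes), f$image_id)
      ais[[i]] <- generate_ai_prediction(gts[[i]], f, config$ai_target_dice,
                                         config$ai_tolerance)
    }

    annotators <- list(); annotations <- list()
    for (gname in names(config$groups)) {
      spec <- config$groups[[gname]]
      for (j in seq_len(spec$n)) {
        aid <- sprintf("%s%02d", tolower(gname), j)
        annotators[[length(annotators) + 1L]] <- annotator(aid, spec$profile$group)
        for (i in seq_len(config$n_images)) {
          pre <- simulate_annotation_pre(gts[[i]], frames[[i]], spec$profile, aid)
          post <- simulate_annotation_post(pre, ais[[i]], frames[[i]], spec$profile)
          annotations[[length(annotations) + 1L]] <- pre
          annotations[[length(annotations) + 1L]] <- post
        }
      }
    }
    study_dataset(frames, annotators, annotations, gts, ais)
  })
}
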