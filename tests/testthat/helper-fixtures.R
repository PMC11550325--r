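# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

square_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

mask_from <- function(m) binary_mask(matrix(as.logical(m), nrow(m), ncol(m)))

# Mask with TRUE on the given (row, col) 1-based cells of an h x w grid.
mask_at <- function(h, w, cells) {
  g <- matrix(FALSE, h, w)
  g[cells] <- TRUE
  binary_mask(g)
}

# Independent rasterization oracle: even-odd crossing test evaluated at
# every pixel centre, one point at a time.
rasterize_oracle <- function(vertices, width, height) {
  n <- nrow(vertices)
  inside <- function(px, py) {
    cross <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- vertices[i, 2]; y2 <- vertices[j, 2]
      if ((y1 <= py) != (y2 <= py)) {
        xint <- vertices[i, 1] +
          (py - y1) / (y2 - y1) * (vertices[j, 1] - vertices[i, 1])
        if (px < xint) cross <- cross + 1L
      }
    }
    cross %% 2L == 1L
  }
  out <- matrix(FALSE, height, width)
  for (r in seq_len(height))
    for (c in seq_len(width))
      out[r, c] <- inside(c - 0.5, r - 0.5)
  out
}

# Independent Wilcoxon signed-rank oracle: enumerate every sign assignment.
wilcoxon_oracle <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# A small 4-group study configuration for structural tests.
small_study_config <- function(seed, n_images = 2L) {
  groups <- lapply(default_profiles(), function(p) list(n = 2L, profile = p))
  study_config(n_images = n_images, frame_width = 200L, frame_height = 160L,
               groups = groups, seed = seed)
}

# Two-group miniature config for CLI / pipeline tests.
tiny_groups_json <- function() {
  list(
    n_images = 2L, frame_width = 160L, frame_height = 120L,
    ai_target_dice = 0.85, ai_tolerance = 0.03,
    groups = list(
      STUDENT = list(n = 2L, profile = list(
        group = "STUDENT", boundary_noise_sd = 0.3, center_offset_sd = 10,
        adoption_prob = 0.9, blend_weight = 0.8)),
      EXPERT = list(n = 2L, profile = list(
        group = "EXPERT", boundary_noise_sd = 0.15, center_offset_sd = 4,
        adoption_prob = 0.3, blend_weight = 0.5))))
}

frame_200 <- function(id = "img") image_frame(id, 200L, 160L)
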