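# Deterministic procedural generator of fundus-like images: recursive
# branching vessel trees rasterized with soft (anti-aliased) edges on a
# low-contrast background with a smooth illumination gradient, sensor
# noise, bright/dark lesion distractors, and an elliptical field of view.

#' Parameters of the synthetic fundus generator
#'
#' Defaults emulate the regime of real fundus photographs: a handful of
#' primary vessels branching dichotomously outward from near the disc,
#' calibers tapering by a fixed decay per generation, vessels darker than
#' the background by a modest contrast gap, a smooth illumination gradient,
#' Gaussian sensor noise, and a few exudate-like (bright) and
#' hemorrhage-like (dark) disc distractors. Default geometry keeps the
#' vessel fraction within the FOV in the 2-20% class-imbalance band of
#' real data.
#'
#' @param seed Integer seed; identical parameters give bit-identical samples.
#' @param size `(H, W)` in pixels, at least 64 each.
#' @param n_trees Number of primary vessel trees.
#' @param branch_depth Branching generations per tree.
#' @param root_width Root caliber in pixels (must be at least 0.5).
#' @param width_decay Child/parent caliber ratio in `(0, 1)`.
#' @param branch_angle_deg Mean full angle between sibling branches.
#' @param contrast Vessel-background intensity gap in `(0, 1]`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param illum_gradient Peak-to-trough amplitude of the illumination plane.
#' @param n_lesions Number of lesion distractors.
#' @param lesion_radius Mean lesion radius in pixels.
#' @param fov_margin Elliptical FOV inset as a fraction of each half-axis.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(seed = 1L, size = c(256L, 256L), n_trees = 5L,
                         branch_depth = 4L, root_width = 5,
                         width_decay = 0.85, branch_angle_deg = 35,
                         contrast = 0.35, noise_sd = 0.03,
                         illum_gradient = 0.25, n_lesions = 4L,
                         lesion_radius = 8, fov_margin = 0.04) {
  if (length(size) == 1L) size <- c(size, size)
  stopifnot(all(size >= 64L), n_trees >= 0L, branch_depth >= 0L,
            width_decay > 0, width_decay < 1, contrast > 0, contrast <= 1,
            noise_sd >= 0, n_lesions >= 0L, lesion_radius >= 0,
            fov_margin >= 0, fov_margin < 0.5)
  if (root_width < 0.5) stop("root_width below 0.5 px is degenerate")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 root_width = root_width, width_decay = width_decay,
                 branch_angle_deg = branch_angle_deg, contrast = contrast,
                 noise_sd = noise_sd, illum_gradient = illum_gradient,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = lesion_radius, fov_margin = fov_margin),
            class = "synth_params")
}

# Soft-rasterize a thick segment onto the canvas (max composition).
raster_segment <- function(canvas, x0, y0, x1, y1, w) {
  d <- dim(canvas)
  m <- w / 2 + 1.5
  rlo <- max(1L, floor(min(y0, y1) - m)); rhi <- min(d[1], ceiling(max(y0, y1) + m))
  clo <- max(1L, floor(min(x0, x1) - m)); chi <- min(d[2], ceiling(max(x0, x1) + m))
  if (rlo > rhi || clo > chi) return(canvas)
  rows <- rlo:rhi; cols <- clo:chi
  py <- matrix(rows, length(rows), length(cols))
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  tt <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  dx <- px - (x0 + tt * vx); dy <- py - (y0 + tt * vy)
  dist <- sqrt(dx * dx + dy * dy)
  cov <- pmin(1, pmax(0, w / 2 + 0.5 - dist))
  canvas[rows, cols] <- pmax(canvas[rows, cols], cov)
  canvas
}

gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
}

#' Generate one synthetic fundus sample
#'
#' Grows `n_trees` recursive branching polylines from points near the FOV
#' center outward (two children per branch point, jittered angles, child
#' caliber = parent caliber x `width_decay`), soft-rasterizes them, blurs
#' by 0.5 px and binarizes at 0.5 for the vessel mask, and composes the
#' image as background + illumination gradient - contrast x blurred vessels
#' + lesions + noise, clipped to `[0, 1]`. The FOV is a centered ellipse;
#' the boundary mask is the morphological gradient of the vessel mask.
#'
#' @param params A [synth_params()].
#' @param keep_prenoise Attach the pre-noise, pre-FOV canvas as attribute
#'   `"prenoise"` (used by contrast diagnostics).
#' @return A `fundus_sample` with `source = "synthetic"`.
#' @export
synth_fundus <- function(params = synth_params(), keep_prenoise = FALSE) {
  stopifnot(inherits(params, "synth_params"))
  H <- params$size[1]; W <- params$size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry <- (H / 2) * (1 - params$fov_margin)
  rx <- (W / 2) * (1 - params$fov_margin)
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  fov <- (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1) * 1

  res <- with_seed(params$seed, {
    canvas <- matrix(0, H, W)
    scale <- min(H, W)
    # vessel trees
    if (params$n_trees > 0) {
      segs <- list()
      grow <- function(x, y, angle, width, len, depth) {
        if (depth < 0 || width < 0.5) return(invisible())
        nsub <- 3L
        for (s in seq_len(nsub)) {
          angle <- angle + stats::rnorm(1, 0, 8 * pi / 180)
          x1 <- x + cos(angle) * len / nsub
          y1 <- y + sin(angle) * len / nsub
          segs[[length(segs) + 1L]] <<- c(x, y, x1, y1, width)
          x <- x1; y <- y1
        }
        if (((y - cy) / ry)^2 + ((x - cx) / rx)^2 > 1.15) return(invisible())
        half <- params$branch_angle_deg / 2 * pi / 180
        for (sgn in c(-1, 1)) {
          a <- angle + sgn * half * stats::runif(1, 0.7, 1.3)
          grow(x, y, a, width * params$width_decay, len * 0.78, depth - 1L)
        }
      }
      r0 <- 0.12 * scale
      base_angle <- stats::runif(1, 0, 2 * pi)
      for (k in seq_len(params$n_trees)) {
        a <- base_angle + 2 * pi * (k - 1) / params$n_trees +
          stats::rnorm(1, 0, 0.2)
        grow(cx + cos(a) * r0, cy + sin(a) * r0, a, params$root_width,
             0.22 * scale, params$branch_depth)
      }
      for (sg in segs)
        canvas <- raster_segment(canvas, sg[1], sg[2], sg[3], sg[4], sg[5])
    }
    soft <- gblur_mat(canvas, 0.5)
    vessel <- (soft >= 0.5) * 1

    # background with smooth illumination gradient
    dir <- stats::runif(1, 0, 2 * pi)
    plane <- (cos(dir) * (xx / W - 0.5) + sin(dir) * (yy / H - 0.5))
    bg <- 0.55 + params$illum_gradient * plane
    shade <- gblur_mat(canvas, 0.8)
    prenoise <- bg - params$contrast * shade

    # lesion distractors outside vessels: half bright, half dark
    if (params$n_lesions > 0) {
      for (k in seq_len(params$n_lesions)) {
        for (try in 1:20) {
          ly <- stats::runif(1, cy - 0.8 * ry, cy + 0.8 * ry)
          lx <- stats::runif(1, cx - 0.8 * rx, cx + 0.8 * rx)
          if (canvas[round(ly), round(lx)] < 0.1) break
        }
        r <- params$lesion_radius * stats::runif(1, 0.5, 1.5)
        amp <- if (k %% 2 == 0) 0.2 else -0.15
        d2 <- ((yy - ly)^2 + (xx - lx)^2) / r^2
        bump <- amp * pmax(0, 1 - d2)
        prenoise <- prenoise + bump * (1 - soft)
      }
    }
    img <- prenoise + stats::rnorm(H * W, 0, params$noise_sd)
    list(img = img, vessel = vessel, prenoise = prenoise)
  })

  img <- res$img
  img[fov == 0] <- 0.03
  img <- pmin(pmax(img, 0), 1)
  s <- fundus_sample(img, res$vessel, fov,
                     sample_id = paste0("synthetic_", params$seed),
                     source = "synthetic")
  if (keep_prenoise) attr(s, "prenoise") <- res$prenoise
  s
}

#' Generate disjoint train/test sample lists
#'
#' Per-sample seeds are derived deterministically from the master seed with
#' distinct stream indices for the training and test lists, so the two
#' lists are disjoint by construction and the whole split is reproducible.
#'
#' @param params Template [synth_params()]; the `seed` field is replaced
#'   per sample.
#' @param n_train,n_test Sample counts.
#' @param seed Master seed.
#' @return List with elements `train` and `test`.
#' @export
synth_split <- function(params = synth_params(), n_train = 20L, n_test = 5L,
                        seed = 1L) {
  stopifnot(n_train >= 1L, n_test >= 1L)
  derive <- function(i) as.integer((as.numeric(seed) * 10007 + i * 97) %%
                                     2147483587)
  gen <- function(i, tag) {
    p <- params
    p$seed <- derive(i)
    s <- synth_fundus(p)
    s$sample_id <- sprintf("syn_%s_%03d", tag, i)
    s
  }
  list(train = lapply(seq_len(n_train), function(i) gen(i, "train")),
       test = lapply(n_train + seq_len(n_test), function(i) gen(i, "test")))
}
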