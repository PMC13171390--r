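# Whole-image <-> patch conversion: random training crops, the regular
# inference grid, and overlap-averaged stitching.
#
# Coordinates are 0-based (row, col) top-left offsets, row-major. Padding
# is symmetric reflection applied to the bottom/right edges only, so no
# black borders create phantom vessel edges.

reflect_pad_br <- function(m, h_pad, w_pad) {
  d <- dim(m)
  if (h_pad < d[1] || w_pad < d[2]) stop("padded size smaller than input")
  if (h_pad - d[1] > d[1] || w_pad - d[2] > d[2])
    stop("reflect padding larger than the image itself (image ",
         d[1], "x", d[2], ", target ", h_pad, "x", w_pad, ")")
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(h_pad)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(w_pad)]
  m[ri, ci, drop = FALSE]
}

new_patch_set <- function(patches, coords, patch_size, stride, source_shape,
                          padded_shape, extra = list()) {
  structure(c(list(patches = patches, coords = coords,
                   patch_size = patch_size, stride = stride,
                   source_shape = source_shape, padded_shape = padded_shape),
              extra),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set:", dim(x$patches)[3], "patches of",
      x$patch_size, "x", x$patch_size, "from a",
      paste(x$source_shape, collapse = "x"), "image (stride ",
      x$stride, ")\n")
  invisible(x)
}

#' Regular patch grid for tiled inference
#'
#' Reflect-pads the image on the bottom/right to the smallest size for
#' which `(dim_pad - size)` is divisible by `stride`, then enumerates all
#' `size x size` windows row-major. Patch counts per axis are
#' `(dim_pad - size) / stride + 1`.
#'
#' @param image Numeric matrix.
#' @param size Patch side length in pixels.
#' @param stride Step between window origins; `1 <= stride <= size`.
#' @return A `patch_set` with fields `patches` (`size x size x n` array),
#'   `coords` (0-based `(row, col)` offsets into the padded canvas),
#'   `patch_size`, `stride`, `source_shape`, `padded_shape`.
#' @export
grid_patches <- function(image, size = 96L, stride = 32L) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (stride <= 0L) stop("stride must be positive")
  if (size < stride) stop("size must be >= stride")
  d <- dim(image)
  pad_to <- function(x) {
    if (x <= size) size
    else size + stride * as.integer(ceiling((x - size) / stride))
  }
  hp <- pad_to(d[1]); wp <- pad_to(d[2])
  canvas <- reflect_pad_br(image, hp, wp)
  nr <- (hp - size) %/% stride + 1L
  nc <- (wp - size) %/% stride + 1L
  n <- nr * nc
  patches <- array(0, c(size, size, n))
  coords <- matrix(0L, n, 2L, dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      k <- k + 1L
      r0 <- (r - 1L) * stride
      c0 <- (cc - 1L) * stride
      patches[, , k] <- canvas[r0 + seq_len(size), c0 + seq_len(size)]
      coords[k, ] <- c(r0, c0)
    }
  }
  new_patch_set(patches, coords, size, stride, d, c(hp, wp))
}

#' Overlap-averaged stitching
#'
#' Inverse of [grid_patches()] for per-patch predictions: every padded
#' canvas pixel receives the mean of all patch values covering it, and the
#' canvas is cropped back to the original shape. Errors if any pixel is
#' uncovered.
#'
#' @param patch_set A `patch_set` whose `patches` hold (real-valued)
#'   predictions.
#' @param full_shape Target `(H, W)`; defaults to the recorded source shape.
#' @return Numeric `H x W` matrix.
#' @export
stitch_patches <- function(patch_set, full_shape = patch_set$source_shape) {
  s <- patch_set$patch_size
  hp <- patch_set$padded_shape[1]; wp <- patch_set$padded_shape[2]
  acc <- matrix(0, hp, wp)
  cnt <- matrix(0, hp, wp)
  for (k in seq_len(dim(patch_set$patches)[3])) {
    r0 <- patch_set$coords[k, 1]; c0 <- patch_set$coords[k, 2]
    ri <- r0 + seq_len(s); ci <- c0 + seq_len(s)
    acc[ri, ci] <- acc[ri, ci] + patch_set$patches[, , k]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0))
    stop("internal inconsistency: ", sum(cnt == 0), " canvas pixels uncovered")
  (acc / cnt)[seq_len(full_shape[1]), seq_len(full_shape[2])]
}

#' Random training patches
#'
#' Draws `n` patch centers uniformly from FOV-interior pixels (so crops
#' show retina, not pure background) and cuts aligned windows from the
#' preprocessed image, the vessel mask, and the boundary mask. Windows are
#' shifted to stay inside the image; when the image is smaller than the
#' patch, it is reflect-padded on the bottom/right first. A fixed seed
#' makes the draw a pure function of `(sample, n, size, seed)`.
#'
#' @param sample A `fundus_sample` (image must be single-channel).
#' @param n Number of patches.
#' @param size Patch side length.
#' @param seed Integer seed.
#' @return A `patch_set` with extra fields `vessel` and `boundary`
#'   (`size x size x n` arrays aligned with `patches`).
#' @export
sample_train_patches <- function(sample, n, size = 64L, seed = 1L) {
  stopifnot(inherits(sample, "fundus_sample"))
  n <- as.integer(n); size <- as.integer(size)
  if (n <= 0L) stop("n must be positive")
  if (size <= 0L) stop("size must be positive")
  img <- sample$image
  if (length(dim(img)) == 3L) stop("preprocess the sample first (RGB image)")
  ves <- sample$vessel_mask
  bnd <- sample$boundary_mask
  fov <- sample$fov_mask
  d <- dim(img)
  hp <- max(d[1], size); wp <- max(d[2], size)
  if (hp > d[1] || wp > d[2]) {
    img <- reflect_pad_br(img, hp, wp)
    ves <- reflect_pad_br(ves, hp, wp)
    bnd <- reflect_pad_br(bnd, hp, wp)
  }
  inside <- which(fov == 1)
  if (length(inside) == 0L) stop("FOV mask has no interior pixels")
  idx <- with_seed(seed, sample(inside, n, replace = TRUE))
  cr <- (idx - 1L) %% d[1]          # 0-based center row
  cc <- (idx - 1L) %/% d[1]
  half <- size %/% 2L
  r0 <- pmin(pmax(cr - half, 0L), hp - size)
  c0 <- pmin(pmax(cc - half, 0L), wp - size)
  x <- array(0, c(size, size, n))
  yv <- array(0, c(size, size, n))
  yb <- array(0, c(size, size, n))
  for (k in seq_len(n)) {
    ri <- r0[k] + seq_len(size); ci <- c0[k] + seq_len(size)
    x[, , k] <- img[ri, ci]
    yv[, , k] <- ves[ri, ci]
    yb[, , k] <- bnd[ri, ci]
  }
  new_patch_set(x, cbind(row = r0, col = c0), size, "random", d, c(hp, wp),
                extra = list(vessel = yv, boundary = yb, seed = seed))
}
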