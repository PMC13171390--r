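# Fundus image / mask I/O, the preprocessing chain, and boundary targets.
# Images are stored as H x W (or H x W x 3) numeric arrays in [0, 1]; note
# EBImage uses (x = width, y = height) order, so everything read or written
# through it is transposed at the boundary.

ebi_to_arr <- function(img) {
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) t(a)
  else aperm(a, c(2L, 1L, 3L))
}

arr_to_ebi <- function(a) {
  if (length(dim(a)) == 2L) EBImage::Image(t(a))
  else EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
}

read_raster <- function(path) {
  if (grepl("\\.gif$", path, ignore.case = TRUE))
    stop("cannot read '", path, "': GIF is not supported by the available ",
         "decoders; convert to PNG or TIFF first")
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read '", path, "': ",
                                           conditionMessage(e)))
  a <- ebi_to_arr(img)
  d <- dim(a)
  if (length(d) == 3L && d[3] > 3L) a <- a[, , 1:3]  # drop alpha
  pmin(pmax(a, 0), 1)
}

binarize_mask <- function(a, what) {
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  u <- unique(as.vector(round(a, 6)))
  if (length(u) > 2L)
    warning(what, " has more than two levels; binarizing at the midpoint")
  (a >= 0.5) * 1
}

#' Assemble and validate a fundus sample
#'
#' Container for one image with its vessel mask, optional field-of-view
#' (FOV) mask, and the derived boundary mask. All grids must share the same
#' height and width; masks must be binary; the boundary mask is the
#' morphological gradient of the vessel mask (computed when not supplied).
#'
#' @param image `H x W` or `H x W x 3` intensity array in `[0, 1]`.
#' @param vessel_mask Binary `H x W` matrix.
#' @param fov_mask Binary `H x W` matrix, or `NULL` for all ones.
#' @param boundary_mask Binary `H x W` matrix, or `NULL` to derive it.
#' @param sample_id Identifier string.
#' @param source One of `"drive"`, `"stare"`, `"chasedb1"`, `"synthetic"`,
#'   `"other"`.
#' @return A list of class `fundus_sample`.
#' @export
fundus_sample <- function(image, vessel_mask, fov_mask = NULL,
                          boundary_mask = NULL, sample_id = "sample",
                          source = c("other", "drive", "stare", "chasedb1",
                                     "synthetic")) {
  source <- match.arg(source)
  d <- dim(image)[1:2]
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  if (!identical(dim(vessel_mask), d))
    stop("vessel mask shape ", paste(dim(vessel_mask), collapse = "x"),
         " does not match image ", paste(d, collapse = "x"))
  if (any(vessel_mask != 0 & vessel_mask != 1)) stop("vessel_mask must be binary")
  if (is.null(fov_mask)) fov_mask <- matrix(1, d[1], d[2])
  if (!identical(dim(fov_mask), d)) stop("fov mask shape mismatch")
  if (any(fov_mask != 0 & fov_mask != 1)) stop("fov_mask must be binary")
  if (is.null(boundary_mask)) boundary_mask <- derive_boundary(vessel_mask)
  if (!identical(dim(boundary_mask), d)) stop("boundary mask shape mismatch")
  structure(list(image = image, vessel_mask = vessel_mask,
                 fov_mask = fov_mask, boundary_mask = boundary_mask,
                 sample_id = sample_id, source = source),
            class = "fundus_sample")
}

#' Load an image/mask pair from disk
#'
#' Reads PNG/TIFF/JPEG rasters, scales intensities to `[0, 1]`, binarizes
#' masks at the midpoint, and derives the boundary mask. When no FOV file
#' is given the FOV is all ones.
#'
#' @param image_path,mask_path,fov_path File paths (`fov_path` optional).
#' @param sample_id Identifier (defaults to the image file name).
#' @param source Dataset tag, see [fundus_sample()].
#' @return A `fundus_sample`.
#' @export
load_sample <- function(image_path, mask_path, fov_path = NULL,
                        sample_id = NULL, source = "other") {
  img <- read_raster(image_path)
  msk <- binarize_mask(read_raster(mask_path), "vessel mask")
  if (!identical(dim(img)[1:2], dim(msk)))
    stop("image ", paste(dim(img)[1:2], collapse = "x"), " and mask ",
         paste(dim(msk), collapse = "x"), " shapes differ for '",
         image_path, "'")
  fov <- if (is.null(fov_path) || is.na(fov_path) || !nzchar(fov_path)) NULL
         else binarize_mask(read_raster(fov_path), "FOV mask")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(image_path))
  fundus_sample(img, msk, fov, sample_id = sample_id, source = source)
}

#' Boundary mask from a vessel mask
#'
#' Morphological gradient: dilation minus erosion of the binary mask with a
#' `(2*thickness + 1)^2` box structuring element. Pixels outside the grid
#' count as background, so a mask touching the border produces boundary
#' pixels along that border.
#'
#' @param vessel_mask Binary matrix.
#' @param thickness Half-width of the box element in pixels.
#' @return Binary matrix of the same shape.
#' @export
derive_boundary <- function(vessel_mask, thickness = 1L) {
  if (any(vessel_mask != 0 & vessel_mask != 1))
    stop("vessel_mask must be binary")
  t <- as.integer(thickness)
  stopifnot(t >= 1L)
  d <- dim(vessel_mask)
  # explicit zero padding pins down the border convention
  padded <- matrix(0, d[1] + 2L * t, d[2] + 2L * t)
  padded[t + seq_len(d[1]), t + seq_len(d[2])] <- vessel_mask
  kern <- EBImage::makeBrush(2L * t + 1L, shape = "box")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(padded), kern))
  ero <- EBImage::imageData(EBImage::erode(EBImage::Image(padded), kern))
  g <- (dil - ero)[t + seq_len(d[1]), t + seq_len(d[2])]
  (g > 0) * 1
}

#' Preprocessing configuration
#'
#' The standard fundus chain: grayscale conversion, histogram equalization
#' (CLAHE by default, the de-facto fundus standard; a `global` variant and
#' `none` are also exposed), then gamma correction for illumination.
#'
#' @param use_grayscale Convert RGB input to single-channel luminance.
#' @param hist_eq `"clahe"`, `"global"`, or `"none"`.
#' @param gamma Positive illumination-correction exponent (`v^gamma`).
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tile CLAHE tile grid count per axis.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(use_grayscale = TRUE,
                              hist_eq = c("clahe", "global", "none"),
                              gamma = 1.2, clahe_clip = 2, clahe_tile = 8L) {
  hist_eq <- match.arg(hist_eq)
  if (gamma <= 0) stop("gamma must be positive")
  stopifnot(clahe_clip > 0, clahe_tile >= 1)
  structure(list(use_grayscale = use_grayscale, hist_eq = hist_eq,
                 gamma = gamma, clahe_clip = clahe_clip,
                 clahe_tile = as.integer(clahe_tile)),
            class = "preprocess_config")
}

to_gray <- function(image) {
  if (length(dim(image)) == 3L)
    0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  else image
}

#' Apply the preprocessing chain
#'
#' Grayscale, then histogram equalization, then gamma correction, in that
#' order; masks are untouched and the output stays in `[0, 1]`.
#'
#' @param sample A `fundus_sample`.
#' @param cfg A [preprocess_config()].
#' @return The sample with a single-channel preprocessed image.
#' @export
preprocess <- function(sample, cfg = preprocess_config()) {
  stopifnot(inherits(sample, "fundus_sample"))
  img <- sample$image
  if (cfg$use_grayscale) img <- to_gray(img)
  if (length(dim(img)) == 3L) img <- to_gray(img)
  img <- pmin(pmax(img, 0), 1)
  if (diff(range(img)) == 0) {
    # a constant image is a single histogram bin: equalization is a no-op
  } else if (cfg$hist_eq == "global") {
    img <- ebi_to_arr(EBImage::equalize(arr_to_ebi(img), range = c(0, 1),
                                        levels = 256))
  } else if (cfg$hist_eq == "clahe") {
    img <- ebi_to_arr(EBImage::clahe(arr_to_ebi(img), nx = cfg$clahe_tile,
                                     ny = cfg$clahe_tile,
                                     limit = cfg$clahe_clip))
  }
  img <- pmin(pmax(img, 0), 1)^cfg$gamma
  sample$image <- pmin(pmax(img, 0), 1)
  sample
}

#' Write a sample to a directory as PNG files
#'
#' Writes `<id>_image.png`, `<id>_vessel.png`, and `<id>_fov.png` under
#' `dir` and returns the three paths. The layout matches the manifest
#' convention of [write_manifest()], so synthetic and real data are
#' interchangeable downstream.
#'
#' @param sample A `fundus_sample`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sample$sample_id
  paths <- c(image = file.path(dir, paste0(id, "_image.png")),
             mask = file.path(dir, paste0(id, "_vessel.png")),
             fov = file.path(dir, paste0(id, "_fov.png")))
  EBImage::writeImage(arr_to_ebi(sample$image), paths["image"])
  EBImage::writeImage(arr_to_ebi(sample$vessel_mask), paths["mask"])
  EBImage::writeImage(arr_to_ebi(sample$fov_mask), paths["fov"])
  paths
}

#' Write / read a manifest of image-mask-FOV triples
#'
#' The manifest is a tab-separated file with one `image`, `mask`, `fov`
#' triple per line (empty `fov` means all-ones) and is the neutral layout
#' for arbitrary datasets; [read_dataset()] also understands the
#' conventional DRIVE/STARE/CHASE_DB1 directory structures.
#'
#' @param samples List of `fundus_sample` objects.
#' @param dir Directory receiving the PNGs and `manifest.tsv`.
#' @return Path to the manifest file.
#' @export
write_manifest <- function(samples, dir) {
  rows <- vapply(samples, function(s) {
    p <- write_sample(s, dir)
    paste(basename(p), collapse = "\t")
  }, character(1))
  mf <- file.path(dir, "manifest.tsv")
  writeLines(c("image\tmask\tfov", rows), mf)
  mf
}

#' @rdname write_manifest
#' @param manifest Path to a `manifest.tsv`.
#' @param source Dataset tag applied to all loaded samples.
#' @return `read_manifest` returns a list of `fundus_sample` objects.
#' @export
read_manifest <- function(manifest, source = "other") {
  if (!file.exists(manifest)) stop("manifest '", manifest, "' does not exist")
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("manifest '", manifest, "' lists no samples")
  base <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    fov <- if ("fov" %in% names(tab) && nzchar(tab$fov[i]))
      file.path(base, tab$fov[i]) else NULL
    load_sample(file.path(base, tab$image[i]), file.path(base, tab$mask[i]),
                fov, source = source)
  })
}

#' Read a dataset directory in a conventional layout
#'
#' Supports the common on-disk layouts: DRIVE
#' (`images/`, `1st_manual/`, `mask/`), STARE and CHASE_DB1 (images and
#' `*_1stHO`/`.ah` style manual annotations side by side), or any directory
#' containing a `manifest.tsv`. Files are paired by sorted order within
#' matching subdirectories.
#'
#' @param dir Dataset directory.
#' @param layout `"auto"`, `"manifest"`, `"drive"`, or `"paired"` (two
#'   subdirectories `images/` and `labels/`).
#' @return A list of `fundus_sample` objects.
#' @export
read_dataset <- function(dir, layout = c("auto", "manifest", "drive", "paired")) {
  layout <- match.arg(layout)
  if (layout == "auto") {
    layout <- if (file.exists(file.path(dir, "manifest.tsv"))) "manifest"
    else if (dir.exists(file.path(dir, "images")) &&
             dir.exists(file.path(dir, "1st_manual"))) "drive"
    else if (dir.exists(file.path(dir, "images")) &&
             dir.exists(file.path(dir, "labels"))) "paired"
    else stop("cannot recognise dataset layout under '", dir, "'")
  }
  if (layout == "manifest")
    return(read_manifest(file.path(dir, "manifest.tsv")))
  imgdir <- file.path(dir, "images")
  mskdir <- if (layout == "drive") file.path(dir, "1st_manual")
            else file.path(dir, "labels")
  fovdir <- file.path(dir, "mask")
  imgs <- sort(list.files(imgdir, full.names = TRUE))
  msks <- sort(list.files(mskdir, full.names = TRUE))
  if (length(imgs) == 0) stop("no images under '", imgdir, "'")
  if (length(imgs) != length(msks))
    stop("image/mask counts differ (", length(imgs), " vs ", length(msks), ")")
  fovs <- if (dir.exists(fovdir)) sort(list.files(fovdir, full.names = TRUE))
          else rep(NA_character_, length(imgs))
  lapply(seq_along(imgs), function(i)
    load_sample(imgs[i], msks[i], fovs[i],
                source = if (layout == "drive") "drive" else "other"))
}
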