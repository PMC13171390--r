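# File-level pipeline operations behind the command-line entry points:
# synth -> train -> predict -> evaluate, each reading/writing the manifest
# layout so synthetic and real data are interchangeable.

#' Generate a synthetic dataset on disk
#'
#' Writes `n_train` + `n_test` synthetic samples as PNGs with
#' `manifest.tsv` files under `out_dir/train` and `out_dir/test`.
#'
#' @param out_dir Output directory.
#' @param params A [synth_params()] template.
#' @param n_train,n_test Sample counts.
#' @param seed Master seed.
#' @return Named paths of the two manifests.
#' @export
pipeline_synth <- function(out_dir, params = synth_params(), n_train = 20L,
                           n_test = 5L, seed = 1L) {
  sp <- synth_split(params, n_train, n_test, seed)
  c(train = write_manifest(sp$train, file.path(out_dir, "train")),
    test = write_manifest(sp$test, file.path(out_dir, "test")))
}

#' Predict and write probability/mask files for every manifest entry
#'
#' For each sample: preprocess, tile into overlapping patches, average
#' overlapping predictions, and write `<id>_prob.png` (float map scaled to
#' 16-bit) and `<id>_mask.png` (binarized) under `out_dir`.
#'
#' @param fit An `sgbnet` fit (or path to a checkpoint).
#' @param manifest Path to a `manifest.tsv`.
#' @param out_dir Output directory.
#' @param patch_size,stride,threshold See [predict.sgbnet()].
#' @return Invisibly, a data.frame of written paths.
#' @export
pipeline_predict <- function(fit, manifest, out_dir, patch_size = 96L,
                             stride = 32L, threshold = 0.5) {
  if (is.character(fit)) fit <- load_sgbnet(fit)
  samples <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    pr <- predict(fit, s, patch_size, stride, threshold, type = "both")
    pp <- file.path(out_dir, paste0(s$sample_id, "_prob.png"))
    mp <- file.path(out_dir, paste0(s$sample_id, "_mask.png"))
    EBImage::writeImage(arr_to_ebi(pr$prob), pp, bits.per.sample = 16L)
    EBImage::writeImage(arr_to_ebi(pr$mask), mp)
    data.frame(sample_id = s$sample_id, prob = pp, mask = mp)
  })
  invisible(do.call(rbind, rows))
}

#' Evaluate written predictions against a manifest
#'
#' Matches `<id>_prob.png` files in `pred_dir` to the manifest's ground
#' truth, computes per-image metrics (FOV-restricted by default) and the
#' dataset mean, and writes `metrics.json` plus a key-value
#' `metrics.txt` under `pred_dir`. Entries without a prediction are listed
#' in `missing` and skipped.
#'
#' @param pred_dir Directory holding `<id>_prob.png` files.
#' @param manifest Ground-truth manifest path.
#' @param fov_mode `"fov"` restricts evaluation to the FOV interior;
#'   `"full"` uses every pixel.
#' @param threshold Binarization threshold.
#' @return List with `per_image`, `aggregate`, and `missing`.
#' @export
pipeline_evaluate <- function(pred_dir, manifest, fov_mode = c("fov", "full"),
                              threshold = 0.5) {
  fov_mode <- match.arg(fov_mode)
  samples <- read_manifest(manifest)
  missing <- character()
  per <- list()
  for (s in samples) {
    pp <- file.path(pred_dir, paste0(s$sample_id, "_prob.png"))
    if (!file.exists(pp)) { missing <- c(missing, s$sample_id); next }
    prob <- read_raster(pp)
    if (length(dim(prob)) == 3L) prob <- prob[, , 1L]
    mask <- if (fov_mode == "fov") s$fov_mask else NULL
    per[[s$sample_id]] <- vessel_metrics(prob, s$vessel_mask, mask, threshold)
  }
  fields <- c("sensitivity", "specificity", "accuracy", "precision",
              "dice", "iou", "auc_roc")
  agg <- if (length(per))
    vapply(fields, function(f)
      mean(vapply(per, function(r) r[[f]], numeric(1)), na.rm = TRUE),
      numeric(1))
  else stats::setNames(rep(NaN, length(fields)), fields)
  res <- list(per_image = per, aggregate = as.list(agg), missing = missing,
              fov_mode = fov_mode, threshold = threshold)
  # machine-readable + human-readable reports
  json <- list(aggregate = res$aggregate,
               per_image = lapply(per, function(r)
                 r[c("tp", "fp", "tn", "fn", fields)]),
               fov_mode = fov_mode, threshold = threshold,
               missing = missing)
  jsonlite::write_json(json, file.path(pred_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  txt <- c(sprintf("fov_mode\t%s", fov_mode),
           sprintf("threshold\t%g", threshold),
           vapply(fields, function(f)
             sprintf("%s\t%.6f", f, agg[[f]]), character(1)))
  writeLines(txt, file.path(pred_dir, "metrics.txt"))
  res
}
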