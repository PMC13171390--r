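# Training: Adam on the compound loss over random patch batches.

#' Seed every random source used by the package
#'
#' One call makes model initialization, patch sampling, synthetic data
#' generation, and batch shuffling reproducible on a single device.
#'
#' @param seed Integer seed.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  invisible(seed)
}

#' Low-level training on a fixed patch pool
#'
#' Runs `steps` Adam updates of the compound loss on batches drawn (in a
#' seeded shuffled cycle) from a training `patch_set` that carries aligned
#' `vessel` and `boundary` targets. Used by [sgbnet()] per epoch; also
#' convenient for overfitting diagnostics on a single patch set.
#'
#' @param net A network from [sgbnet_network()].
#' @param patches A `patch_set` from [sample_train_patches()].
#' @param steps Number of optimizer updates.
#' @param batch_size Patches per update.
#' @param lr Adam learning rate.
#' @param loss A [loss_config()].
#' @param seed Seed for batch shuffling.
#' @param log_file Optional path; one line per step with the loss breakdown.
#' @param epoch Epoch label used in logs/history.
#' @param verbose Print a line every 20 steps.
#' @return `data.frame` with columns `epoch`, `step`, `total`, `term0`,
#'   `term1`, `term2`.
#' @export
train_network <- function(net, patches, steps, batch_size = 8L, lr = 1e-4,
                          loss = loss_config(), seed = 1L, log_file = NULL,
                          epoch = 1L, verbose = FALSE) {
  n <- dim(patches$patches)[3]
  s <- patches$patch_size
  ord <- with_seed(seed, sample.int(n))
  hist <- matrix(NA_real_, steps, 4L)
  pos <- 0L
  con <- if (!is.null(log_file)) file(log_file, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con))
  for (step in seq_len(steps)) {
    take <- integer(0)
    while (length(take) < batch_size) {
      if (pos >= n) { pos <- 0L }
      k <- min(batch_size - length(take), n - pos)
      take <- c(take, ord[pos + seq_len(k)])
      pos <- pos + k
    }
    nb <- length(take)
    xb <- array(patches$patches[, , take], c(s, s, 1L, nb))
    vb <- array(patches$vessel[, , take], c(s, s, 1L, nb))
    bb <- array(patches$boundary[, , take], c(s, s, 1L, nb))
    tape_reset()
    out <- net_forward(net, nn_tensor(xb), training = TRUE)
    lo <- compound_loss_t(out, vb, bb, loss)
    total <- as.numeric(lo$loss$v)
    if (!is.finite(total))
      stop("training aborted: non-finite loss at epoch ", epoch,
           " step ", step, " (terms: ",
           paste(sprintf("%.4g", lo$terms), collapse = ", "), ")")
    nn_backward(lo$loss)
    adam_step(net, lr)
    tape_reset()
    hist[step, ] <- c(total, lo$terms)
    if (!is.null(con))
      writeLines(sprintf("%s epoch %d step %d total %.6f term0 %.6f term1 %.6f term2 %.6f",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), epoch, step,
                         total, lo$terms[1], lo$terms[2], lo$terms[3]), con)
    if (verbose && step %% 20L == 0L)
      message(sprintf("epoch %d step %d/%d loss %.4f", epoch, step, steps, total))
  }
  data.frame(epoch = epoch, step = seq_len(steps), total = hist[, 1],
             term0 = hist[, 2], term1 = hist[, 3], term2 = hist[, 4])
}

draw_epoch_pool <- function(samples, n_patches, size, seed) {
  ns <- length(samples)
  counts <- rep(n_patches %/% ns, ns)
  extra <- n_patches - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  parts <- lapply(seq_len(ns), function(i) {
    if (counts[i] == 0L) return(NULL)
    sample_train_patches(samples[[i]], counts[i], size,
                         seed = (seed * 1009L + i * 131L) %% 2147483587)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  s <- size
  ntot <- sum(vapply(parts, function(p) dim(p$patches)[3], numeric(1)))
  x <- array(0, c(s, s, ntot)); v <- array(0, c(s, s, ntot)); b <- array(0, c(s, s, ntot))
  at <- 0L
  for (p in parts) {
    k <- dim(p$patches)[3]
    x[, , at + seq_len(k)] <- p$patches
    v[, , at + seq_len(k)] <- p$vessel
    b[, , at + seq_len(k)] <- p$boundary
    at <- at + k
  }
  new_patch_set(x, matrix(0L, ntot, 2), s, "random", dim(samples[[1]]$image),
                dim(samples[[1]]$image), extra = list(vessel = v, boundary = b))
}

#' Fit the vessel segmentation network
#'
#' The main entry point: preprocesses the training samples, builds the
#' requested architecture variant, and optimizes the compound loss with
#' Adam over randomly sampled patches. Defaults follow the reference
#' training protocol (10,000 random 64x64 patches per epoch, batch size 8,
#' learning rate 1e-4, 50 epochs); scale `epochs` / `patches_per_epoch`
#' down for desk-scale experiments. `epochs = 0` returns the untrained
#' (seed-initialized) model, useful as a baseline.
#'
#' @param x Training data: a list of `fundus_sample` objects, a single
#'   sample, or the path to a `manifest.tsv`.
#' @param variant Architecture variant, see [sgbnet_network()].
#' @param epochs Training epochs.
#' @param patches_per_epoch Random patches drawn per epoch across samples.
#' @param patch_size Training patch side length in pixels.
#' @param batch_size Patches per Adam update.
#' @param lr Adam learning rate.
#' @param loss A [loss_config()].
#' @param preprocess_cfg A [preprocess_config()] applied to all samples
#'   (and remembered for prediction).
#' @param base_width,depths,use_bn,pretrained Passed to [sgbnet_network()].
#' @param seed Master seed for initialization, patch draws, and shuffling.
#' @param validation Optional list of `fundus_sample` for per-epoch Dice
#'   tracking; the best-epoch parameters are kept and used by default at
#'   prediction time.
#' @param val_split If `validation` is `NULL` and this is positive, hold
#'   out this fraction of `x` (seeded) as validation.
#' @param log_file Optional training log path (one step per line).
#' @param verbose Print progress.
#' @return An object of class `sgbnet` with the trained network, the
#'   resolved configuration, and the step-level loss history.
#' @examples
#' \donttest{
#' sp <- synth_split(synth_params(size = c(128, 128)), n_train = 2,
#'                   n_test = 1, seed = 7)
#' fit <- sgbnet(sp$train, epochs = 1, patches_per_epoch = 16,
#'               batch_size = 4, base_width = 4, seed = 7, verbose = FALSE)
#' pr <- predict(fit, sp$test[[1]])
#' }
#' @export
sgbnet <- function(x, variant = "sgbnet", epochs = 50L,
                   patches_per_epoch = 10000L, patch_size = 64L,
                   batch_size = 8L, lr = 1e-4, loss = loss_config(),
                   preprocess_cfg = preprocess_config(),
                   base_width = 16L, depths = c(2L, 2L, 2L, 2L),
                   use_bn = TRUE, pretrained = FALSE, seed = 1L,
                   validation = NULL, val_split = 0, log_file = NULL,
                   verbose = TRUE) {
  stopifnot(epochs >= 0L, batch_size >= 1L, lr > 0)
  if (is.character(x)) x <- read_manifest(x)
  if (inherits(x, "fundus_sample")) x <- list(x)
  if (length(x) == 0L) stop("no training samples")
  x <- lapply(x, preprocess, cfg = preprocess_cfg)
  if (!is.null(validation))
    validation <- lapply(validation, preprocess, cfg = preprocess_cfg)
  else if (val_split > 0 && length(x) >= 2L) {
    nval <- max(1L, floor(val_split * length(x)))
    idx <- with_seed(seed + 1L, sample.int(length(x), nval))
    validation <- x[idx]
    x <- x[-idx]
  }
  net <- sgbnet_network(variant, base_width = base_width, depths = depths,
                        use_bn = use_bn, seed = seed, pretrained = pretrained)
  history <- NULL
  val_dice <- rep(NA_real_, max(epochs, 0L))
  best <- list(dice = -Inf, state = NULL, epoch = NA_integer_)
  for (ep in seq_len(epochs)) {
    pool <- draw_epoch_pool(x, patches_per_epoch, patch_size,
                            seed = seed + ep * 7919L)
    steps <- ceiling(dim(pool$patches)[3] / batch_size)
    h <- train_network(net, pool, steps, batch_size, lr, loss,
                       seed = seed + ep, log_file = log_file, epoch = ep,
                       verbose = verbose)
    history <- rbind(history, h)
    if (!is.null(validation)) {
      dices <- vapply(validation, function(s) {
        pm <- predict_map(net, s$image)
        vessel_metrics(pm, s$vessel_mask, s$fov_mask)$dice
      }, numeric(1))
      val_dice[ep] <- mean(dices)
      if (val_dice[ep] > best$dice)
        best <- list(dice = val_dice[ep], state = network_state(net),
                     epoch = ep)
      if (verbose)
        message(sprintf("epoch %d validation dice %.4f", ep, val_dice[ep]))
    }
  }
  structure(list(net = net, variant = variant,
                 config = list(epochs = epochs,
                               patches_per_epoch = patches_per_epoch,
                               patch_size = patch_size,
                               batch_size = batch_size, lr = lr,
                               loss = loss, preprocess = preprocess_cfg,
                               base_width = base_width, depths = depths,
                               use_bn = use_bn, seed = seed),
                 history = history, val_dice = val_dice[seq_len(epochs)],
                 best = if (is.null(best$state)) NULL else best,
                 n_train = length(x)),
            class = "sgbnet")
}

# Tiled inference with overlap averaging on a preprocessed image matrix.
predict_map <- function(net, image, patch_size = 96L, stride = 32L,
                        infer_batch = 8L) {
  ps <- grid_patches(image, patch_size, stride)
  n <- dim(ps$patches)[3]
  preds <- array(0, dim(ps$patches))
  for (at in seq(1L, n, by = infer_batch)) {
    take <- at:min(n, at + infer_batch - 1L)
    xb <- array(ps$patches[, , take], c(patch_size, patch_size, 1L, length(take)))
    out <- no_grad(net_forward(net, nn_tensor(xb), training = FALSE))
    preds[, , take] <- out$t0$v[, , 1L, ]
  }
  ps$patches <- preds
  stitch_patches(ps)
}

#' Predict a vessel probability map
#'
#' Applies the remembered preprocessing, tiles the image into overlapping
#' patches (96 px windows, stride 32 by default), runs the fused head on
#' each patch, and averages predictions where tiles overlap. When the fit
#' tracked validation Dice, the best-epoch parameters are used.
#'
#' @param object An `sgbnet` fit.
#' @param newdata A `fundus_sample`, or a numeric `H x W` matrix already
#'   preprocessed to `[0, 1]`.
#' @param patch_size,stride Inference tiling (patch_size must be divisible
#'   by 16).
#' @param threshold Binarization threshold for the mask.
#' @param type `"prob"` (matrix), `"mask"`, or `"both"` (list).
#' @param use_best Use best-validation parameters when available.
#' @param ... Unused.
#' @return Probability matrix, binary matrix, or both.
#' @export
predict.sgbnet <- function(object, newdata, patch_size = 96L, stride = 32L,
                           threshold = 0.5, type = c("prob", "mask", "both"),
                           use_best = TRUE, ...) {
  type <- match.arg(type)
  img <- if (inherits(newdata, "fundus_sample"))
    preprocess(newdata, object$config$preprocess)$image
  else as.matrix(newdata)
  net <- object$net
  if (use_best && !is.null(object$best)) {
    net <- network_from_state(object$best$state)
  }
  prob <- predict_map(net, img, patch_size, stride)
  switch(type,
         prob = prob,
         mask = (prob >= threshold) * 1,
         both = list(prob = prob, mask = (prob >= threshold) * 1))
}

#' Save / load a fit as a checkpoint
#'
#' The checkpoint holds a versioned schema id, the variant and width
#' configuration, every parameter and batch-norm buffer, the seed, and the
#' training history; [load_sgbnet()] validates the schema and rebuilds the
#' network.
#'
#' @param fit An `sgbnet` object.
#' @param path Destination file.
#' @export
save_sgbnet <- function(fit, path) {
  obj <- list(schema = 1L, state = network_state(fit$net),
              best_state = if (!is.null(fit$best)) fit$best$state,
              variant = fit$variant, config = fit$config,
              history = fit$history, val_dice = fit$val_dice,
              n_train = fit$n_train)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_sgbnet
#' @export
load_sgbnet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, 1L)) stop("unknown checkpoint schema")
  net <- network_from_state(obj$state)
  structure(list(net = net, variant = obj$variant, config = obj$config,
                 history = obj$history, val_dice = obj$val_dice,
                 best = if (!is.null(obj$best_state))
                   list(state = obj$best_state) else NULL,
                 n_train = obj$n_train),
            class = "sgbnet")
}
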