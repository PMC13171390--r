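# S3 methods for the fitted model object.

#' @export
print.sgbnet <- function(x, ...) {
  cat("Saliency-guided boundary-refinement segmentation fit\n")
  cat("  variant:      ", x$variant, "\n")
  cat("  parameters:   ", format(network_n_params(x$net), big.mark = ","), "\n")
  cat("  trained:      ", x$config$epochs, "epoch(s) x",
      x$config$patches_per_epoch, "patches on", x$n_train, "sample(s)\n")
  if (!is.null(x$history) && nrow(x$history) > 0)
    cat("  final loss:   ", sprintf("%.4f", utils::tail(x$history$total, 1)), "\n")
  if (!is.null(x$best) && !is.null(x$best$epoch))
    cat("  best val dice:", sprintf("%.4f (epoch %d)", x$best$dice, x$best$epoch), "\n")
  invisible(x)
}

#' @export
summary.sgbnet <- function(object, ...) {
  h <- object$history
  out <- list(variant = object$variant,
              n_params = network_n_params(object$net),
              config = object$config,
              n_steps = if (is.null(h)) 0L else nrow(h),
              loss_first = if (!is.null(h) && nrow(h)) h$total[1] else NA_real_,
              loss_last = if (!is.null(h) && nrow(h)) utils::tail(h$total, 1) else NA_real_,
              terms_last = if (!is.null(h) && nrow(h))
                unlist(utils::tail(h[, c("term0", "term1", "term2")], 1)) else NULL,
              val_dice = object$val_dice)
  class(out) <- "summary.sgbnet"
  out
}

#' @export
print.summary.sgbnet <- function(x, ...) {
  cat("Variant:", x$variant, " (", format(x$n_params, big.mark = ","),
      "parameters )\n")
  cat("Loss config: lambda_t", x$config$loss$lambda_t,
      " gamma_f", x$config$loss$gamma_f,
      " eta_w", x$config$loss$eta_w, " psi_w", x$config$loss$psi_w,
      " seg:", x$config$loss$seg_loss, "\n")
  cat("Optimizer: adam, lr", x$config$lr, ", batch", x$config$batch_size, "\n")
  if (x$n_steps > 0) {
    cat(sprintf("Training: %d steps, loss %.4f -> %.4f\n",
                x$n_steps, x$loss_first, x$loss_last))
    if (!is.null(x$terms_last))
      cat(sprintf("Last-step terms: vessel %.4f boundary %s auxiliary %s\n",
                  x$terms_last[1],
                  ifelse(is.na(x$terms_last[2]), "-", sprintf("%.4f", x$terms_last[2])),
                  ifelse(is.na(x$terms_last[3]), "-", sprintf("%.4f", x$terms_last[3]))))
  } else cat("Untrained (seed-initialized) model\n")
  if (length(x$val_dice) && any(!is.na(x$val_dice)))
    cat("Validation dice by epoch:",
        paste(sprintf("%.3f", x$val_dice), collapse = " "), "\n")
  invisible(x)
}

#' Model parameters as named arrays
#' @param object An `sgbnet` fit.
#' @param ... Unused.
#' @return Named list of parameter arrays (dotted-path names).
#' @export
coef.sgbnet <- function(object, ...) {
  lapply(object$net$params, function(p) p$v)
}

#' Plot training progress or a segmentation overlay
#'
#' Without `sample`, plots the step-wise training loss (and a running
#' mean). With a `fundus_sample`, shows the preprocessed image, the ground
#' truth, and the predicted probability map side by side.
#'
#' @param x An `sgbnet` fit.
#' @param sample Optional `fundus_sample` to segment and display.
#' @param ... Passed to [graphics::plot()] for the loss curve.
#' @export
plot.sgbnet <- function(x, sample = NULL, ...) {
  if (is.null(sample)) {
    h <- x$history
    if (is.null(h) || nrow(h) == 0) stop("no training history to plot")
    graphics::plot(seq_len(nrow(h)), h$total, type = "l", col = "grey60",
                   xlab = "step", ylab = "total loss", ...)
    k <- min(50L, nrow(h))
    rm_ <- stats::filter(h$total, rep(1 / k, k), sides = 1)
    graphics::lines(seq_len(nrow(h)), rm_, col = "red3", lwd = 2)
    graphics::legend("topright", c("step loss", "running mean"),
                     col = c("grey60", "red3"), lwd = c(1, 2), bty = "n")
  } else {
    pr <- predict(x, sample, type = "prob")
    img <- preprocess(sample, x$config$preprocess)$image
    op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op))
    show <- function(m, main) {
      graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256),
                      axes = FALSE, main = main, useRaster = TRUE)
    }
    show(img, "input")
    show(sample$vessel_mask, "ground truth")
    show(pr, "prediction")
  }
  invisible(x)
}
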