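# Compound training objective: focal loss on the boundary head, overlap
# (Dice) / cross-entropy losses on the vessel heads.

#' Loss configuration
#'
#' Bundles the loss weights: `lambda_t` and `gamma_f` parameterize the focal
#' loss on the boundary head (class weight and modulation exponent; the
#' modulation exponent is restricted to `[0, 5]`), `eta_w` weights the
#' boundary term and `psi_w` the auxiliary feature-guided vessel term in the
#' compound loss. Defaults are the reference operating point
#' (`lambda_t = 0.25`, `gamma_f = 2`, `eta_w = 0.7`, `psi_w = 0.3`).
#'
#' @param lambda_t Non-negative focal class weight on positives.
#' @param gamma_f Focal modulation exponent in `[0, 5]`; `0` reduces the
#'   focal loss to (class-weighted) cross-entropy.
#' @param eta_w Non-negative weight of the boundary focal term.
#' @param psi_w Non-negative weight of the auxiliary vessel term.
#' @param seg_loss Segmentation loss for the vessel heads: `"dice"`,
#'   `"bce"`, or `"dice_bce"`.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(lambda_t = 0.25, gamma_f = 2, eta_w = 0.7,
                        psi_w = 0.3, seg_loss = c("dice", "bce", "dice_bce")) {
  seg_loss <- match.arg(seg_loss)
  stopifnot(lambda_t >= 0, eta_w >= 0, psi_w >= 0)
  if (gamma_f < 0 || gamma_f > 5)
    stop("gamma_f must lie in [0, 5]")
  structure(list(lambda_t = lambda_t, gamma_f = gamma_f, eta_w = eta_w,
                 psi_w = psi_w, seg_loss = seg_loss),
            class = "loss_config")
}

check_pred_target <- function(pred, target) {
  if (!identical(dim(as_array4(pred)), dim(as_array4(target))) &&
      !identical(length(pred), length(target)))
    stop("prediction and target shapes differ")
  if (any(pred < 0 | pred > 1)) stop("predictions must lie in [0, 1]")
  if (any(target != 0 & target != 1)) stop("target must be binary {0, 1}")
}

#' Focal loss
#'
#' Mean over pixels of \eqn{-\alpha_t (1 - p_t)^{\gamma} \log p_t}, where
#' \eqn{p_t} is the predicted probability of the true class and
#' \eqn{\alpha_t} equals `lambda_t` on positives and `1 - lambda_t` on
#' negatives. Down-weights easy pixels, concentrating the gradient on hard
#' boundary pixels under heavy class imbalance. Predictions are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm. With `gamma_f = 0` and
#' `lambda_t = 0.5` this is half the binary cross-entropy.
#'
#' @param pred Probability grid in `[0, 1]`.
#' @param target Binary grid of the same shape.
#' @param lambda_t Class weight on positives.
#' @param gamma_f Modulation exponent.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(pred, target, lambda_t = 0.25, gamma_f = 2) {
  check_pred_target(pred, target)
  no_grad(as.numeric(op_focal(nn_tensor(as_array4(pred)),
                              as_array4(target), lambda_t, gamma_f)$v))
}

#' Segmentation loss for the vessel heads
#'
#' `"dice"` is the soft Dice loss `1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)`
#' with smoothing `s = 1`; `"bce"` is mean binary cross-entropy;
#' `"dice_bce"` is their sum.
#'
#' @inheritParams focal_loss
#' @param kind One of `"dice"`, `"bce"`, `"dice_bce"`.
#' @return Non-negative scalar.
#' @export
seg_loss <- function(pred, target, kind = c("dice", "bce", "dice_bce")) {
  kind <- match.arg(kind)
  check_pred_target(pred, target)
  p <- nn_tensor(as_array4(pred))
  t <- as_array4(target)
  no_grad(switch(kind,
                 dice = as.numeric(op_dice_loss(p, t)$v),
                 bce = as.numeric(op_bce(p, t)$v),
                 dice_bce = as.numeric(op_dice_loss(p, t)$v) +
                   as.numeric(op_bce(p, t)$v)))
}

# Tensor-level compound loss used inside the training loop. `outputs` are
# tensors from net_forward; targets are arrays. Heads absent from a variant
# (copies of t0) contribute no extra term.
compound_loss_t <- function(outputs, vessel_target, boundary_target, cfg) {
  native <- outputs$native
  seg_t <- function(pred, target) {
    switch(cfg$seg_loss,
           dice = op_dice_loss(pred, target),
           bce = op_bce(pred, target),
           dice_bce = op_wsum(list(op_dice_loss(pred, target),
                                   op_bce(pred, target)), c(1, 1)))
  }
  terms <- list(seg_t(outputs$t0, vessel_target))
  weights <- 1
  vals <- c(term0 = as.numeric(terms[[1]]$v), term1 = NA_real_, term2 = NA_real_)
  if ("t1" %in% native) {
    t1 <- op_focal(outputs$t1, boundary_target, cfg$lambda_t, cfg$gamma_f)
    terms <- c(terms, list(t1)); weights <- c(weights, cfg$eta_w)
    vals["term1"] <- as.numeric(t1$v)
  }
  if ("t2" %in% native) {
    t2 <- seg_t(outputs$t2, vessel_target)
    terms <- c(terms, list(t2)); weights <- c(weights, cfg$psi_w)
    vals["term2"] <- as.numeric(t2$v)
  }
  list(loss = op_wsum(terms, weights), terms = vals)
}

#' Compound training loss
#'
#' Total loss `seg(t0) + eta_w * focal(t1) + psi_w * seg(t2)`: the fused
#' vessel head is scored with the segmentation loss, the boundary head with
#' the focal loss, and the feature-guided vessel head with a weighted
#' auxiliary segmentation term. For ablation variants whose `t1`/`t2` heads
#' are copies of `t0`, the corresponding terms are dropped rather than
#' double-counted.
#'
#' @param outputs List with probability grids `t0`, `t1`, `t2` (e.g. from
#'   [network_forward()]); an optional `native` field restricts terms to the
#'   heads the variant computes.
#' @param vessel_target,boundary_target Binary grids matching the heads.
#' @param cfg A [loss_config()].
#' @return List with `total` and the unweighted `terms`
#'   (`term0`, `term1`, `term2`; `NA` for absent heads).
#' @export
total_loss <- function(outputs, vessel_target, boundary_target,
                       cfg = loss_config()) {
  native <- outputs$native
  if (is.null(native)) native <- c("t0", "t1", "t2")
  vt <- as_array4(vessel_target)
  bt <- as_array4(boundary_target)
  ot <- list(t0 = nn_tensor(as_array4(outputs$t0)),
             t1 = nn_tensor(as_array4(outputs$t1)),
             t2 = nn_tensor(as_array4(outputs$t2)),
             native = native)
  r <- no_grad(compound_loss_t(ot, vt, bt, cfg))
  list(total = as.numeric(r$loss$v), terms = r$terms)
}
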