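# Independent brute-force oracles and small fixtures used across tests.

# Morphological gradient by explicit per-pixel neighbourhood loops
# (outside-the-grid counts as background).
oracle_morph_gradient <- function(mask, thickness = 1L) {
  d <- dim(mask)
  out <- matrix(0, d[1], d[2])
  t <- thickness
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      ri <- max(1, i - t):min(d[1], i + t)
      ci <- max(1, j - t):min(d[2], j + t)
      nb <- mask[ri, ci]
      dil <- as.numeric(any(nb == 1))
      full_window <- length(nb) == (2 * t + 1)^2
      ero <- as.numeric(full_window && all(nb == 1))
      out[i, j] <- dil - ero
    }
  }
  out
}

# Confusion rates by an explicit pixel loop.
oracle_confusion <- function(pred, gt, mask, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (mask[i] == 0) next
    pb <- pred[i] >= threshold
    if (pb && gt[i] == 1) tp <- tp + 1
    else if (pb && gt[i] == 0) fp <- fp + 1
    else if (!pb && gt[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
       accuracy = if (tp + fp + tn + fn > 0) (tp + tn) / (tp + fp + tn + fn) else NaN,
       dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NaN,
       iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NaN)
}

# AUC by enumeration of every positive-negative pair (ties count 1/2).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NaN)
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# Central finite differences of a scalar function.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small deterministic synthetic sample, preprocessed, for training tests.
tiny_sample <- function(seed = 5, size = 128) {
  preprocess(synth_fundus(synth_params(seed = seed, size = c(size, size))))
}

dice_at_half <- function(prob, truth) {
  tp <- sum((prob >= 0.5) * truth)
  2 * tp / (2 * tp + sum((prob >= 0.5) * (1 - truth)) + sum((prob < 0.5) * truth))
}
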