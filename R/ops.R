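# Differentiable operations. All act on nn_tensors with values [H, W, C, N].

op_conv <- function(x, w, b, stride = 1L) {
  y <- cpp_conv2d_fwd(x$v, dim(x$v), w$v, dim(w$v), b$v, as.integer(stride))
  record(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(x$v, dim(x$v), w$v, dim(w$v), g,
                        as.integer(stride), isTRUE(x$rg))
    list(if (isTRUE(x$rg)) r$gx else NULL, r$gw, r$gb)
  })
}

op_relu <- function(x) {
  mask <- x$v > 0
  record(x$v * mask, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  # keep strictly inside (0,1): saturated doubles would otherwise round to 0/1
  y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  dim(y) <- dim(x$v)
  record(y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(a, b) {
  record(a$v + b$v, list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  record(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

op_scale <- function(x, s) {
  record(x$v * s, list(x), function(g) list(g * s))
}

# Broadcast a [1,1,C,N] channel descriptor over the spatial grid of x and add.
op_add_cbcast <- function(x, d) {
  dm <- dim(x$v)
  hw <- dm[1L] * dm[2L]
  y <- x$v + rep(as.vector(d$v), each = hw)
  dim(y) <- dm
  record(y, list(x, d), function(g) {
    gm <- g
    dim(gm) <- c(hw, dm[3L] * dm[4L])
    gd <- .colSums(gm, hw, dm[3L] * dm[4L])
    dim(gd) <- c(1L, 1L, dm[3L], dm[4L])
    list(g, gd)
  })
}

# Multiply x by a [1,1,C,N] per-channel gate (broadcast over space).
op_mul_cbcast <- function(d, x) {
  dm <- dim(x$v)
  hw <- dm[1L] * dm[2L]
  dv <- rep(as.vector(d$v), each = hw)
  y <- x$v * dv
  dim(y) <- dm
  record(y, list(d, x), function(g) {
    gm <- g * x$v
    dim(gm) <- c(hw, dm[3L] * dm[4L])
    gd <- .colSums(gm, hw, dm[3L] * dm[4L])
    dim(gd) <- c(1L, 1L, dm[3L], dm[4L])
    gx <- g * dv
    dim(gx) <- dm
    list(gd, gx)
  })
}

op_concat_c <- function(tensors) {
  dims <- lapply(tensors, function(t) dim(t$v))
  d1 <- dims[[1L]]
  chans <- vapply(dims, function(d) d[3L], integer(1))
  total <- sum(chans)
  y <- array(0, c(d1[1L], d1[2L], total, d1[4L]))
  at <- 0L
  for (i in seq_along(tensors)) {
    y[, , at + seq_len(chans[i]), ] <- tensors[[i]]$v
    at <- at + chans[i]
  }
  record(y, tensors, function(g) {
    out <- vector("list", length(tensors))
    at <- 0L
    for (i in seq_along(tensors)) {
      gi <- g[, , at + seq_len(chans[i]), , drop = FALSE]
      dim(gi) <- dims[[i]]
      out[[i]] <- gi
      at <- at + chans[i]
    }
    out
  })
}

op_maxpool2 <- function(x) {
  r <- cpp_maxpool2_fwd(x$v, dim(x$v))
  xdim <- dim(x$v)
  record(r$y, list(x), function(g) list(cpp_maxpool2_bwd(g, r$idx, xdim)))
}

op_resize <- function(x, oh, ow) {
  d <- dim(x$v)
  if (d[1L] == oh && d[2L] == ow) return(x)
  y <- cpp_resize_bilinear_fwd(x$v, d, as.integer(oh), as.integer(ow))
  record(y, list(x), function(g)
    list(cpp_resize_bilinear_bwd(g, dim(g), d[1L], d[2L])))
}

op_upsample2 <- function(x) {
  d <- dim(x$v)
  op_resize(x, 2L * d[1L], 2L * d[2L])
}

# Global average pool over space -> [1,1,C,N].
op_gap <- function(x) {
  d <- dim(x$v)
  hw <- d[1L] * d[2L]
  xm <- x$v
  dim(xm) <- c(hw, d[3L] * d[4L])
  y <- .colSums(xm, hw, d[3L] * d[4L]) / hw
  dim(y) <- c(1L, 1L, d[3L], d[4L])
  record(y, list(x), function(g) {
    gx <- rep(as.vector(g) / hw, each = hw)
    dim(gx) <- d
    list(gx)
  })
}

# Global max pool over space -> [1,1,C,N].
op_gmp <- function(x) {
  d <- dim(x$v)
  hw <- d[1L] * d[2L]
  xm <- x$v
  dim(xm) <- c(hw, d[3L] * d[4L])
  idx <- integer(ncol(xm))
  vals <- numeric(ncol(xm))
  for (j in seq_len(ncol(xm))) {
    idx[j] <- which.max(xm[, j])
    vals[j] <- xm[idx[j], j]
  }
  y <- vals
  dim(y) <- c(1L, 1L, d[3L], d[4L])
  record(y, list(x), function(g) {
    gx <- matrix(0, hw, d[3L] * d[4L])
    gx[cbind(idx, seq_along(idx))] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# Batch normalization over (H, W, N) per channel. `st` is the buffer
# environment holding running_mean / running_var; updated in training mode.
op_bn <- function(x, gamma, beta, st, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x$v)
  hw <- d[1L] * d[2L]
  C <- d[3L]; N <- d[4L]
  m <- hw * N
  a <- x$v
  dim(a) <- c(hw, C, N)
  if (training && m > 1) {
    cs <- colSums(a)                       # C x N sums over space
    mu <- .rowSums(cs, C, N) / m
    sq <- colSums(a * a)
    va <- .rowSums(sq, C, N) / m - mu^2
    va[va < 0] <- 0
    st$running_mean <- (1 - momentum) * st$running_mean + momentum * mu
    st$running_var <- (1 - momentum) * st$running_var + momentum * va * m / max(1, m - 1)
  } else {
    mu <- st$running_mean
    va <- st$running_var
  }
  inv <- 1 / sqrt(va + eps)
  mu_e <- rep(mu, each = hw)          # length hw*C, recycles over N below
  inv_e <- rep(inv, each = hw)
  xm <- x$v
  dim(xm) <- c(hw * C, N)
  xhat <- (xm - mu_e) * inv_e
  ge <- rep(gamma$v, each = hw)
  be <- rep(beta$v, each = hw)
  y <- xhat * ge + be
  dim(y) <- d
  batch_stats <- training && m > 1
  record(y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(hw * C, N)
    # per-channel reductions
    red <- function(z) { dim(z) <- c(hw, C * N); r <- .colSums(z, hw, C * N)
                         dim(r) <- c(C, N); .rowSums(r, C, N) }
    dgamma <- red(gm * xhat)
    dbeta <- red(gm)
    dxhat <- gm * ge
    if (batch_stats) {
      t1 <- red(dxhat) / m
      t2 <- gamma$v * dgamma / m   # == mean(dxhat * xhat) per channel
      gx <- (dxhat - rep(t1, each = hw) - xhat * rep(t2, each = hw)) * inv_e
    } else {
      gx <- dxhat * inv_e
    }
    dim(gx) <- d
    list(gx, dgamma, dbeta)
  })
}

# ---- scalar loss ops (closed-form gradients) --------------------------------

clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

op_focal <- function(pred, target, lambda_t, gamma_f, eps = 1e-7) {
  p <- pred$v
  inside <- p > eps & p < 1 - eps
  pc <- clamp01(p, eps)
  y <- target
  pt <- ifelse(y > 0.5, pc, 1 - pc)
  at <- ifelse(y > 0.5, lambda_t, 1 - lambda_t)
  n <- length(p)
  val <- sum(-at * (1 - pt)^gamma_f * log(pt)) / n
  record(array(val, c(1, 1, 1, 1)), list(pred), function(g) {
    # d/dpt of -(1-pt)^gamma log(pt); dpt/dp = +1 on positives, -1 on negatives
    dpt <- -at * (-gamma_f * (1 - pt)^(pmax(gamma_f - 1, 0)) * log(pt) +
                    (1 - pt)^gamma_f / pt)
    if (gamma_f == 0) dpt <- -at / pt
    gp <- dpt * ifelse(y > 0.5, 1, -1) * inside / n
    gp <- as.numeric(g) * gp
    dim(gp) <- dim(pred$v)
    list(gp)
  })
}

op_dice_loss <- function(pred, target, smooth = 1) {
  p <- pred$v
  t <- target
  sp <- sum(p); st_ <- sum(t); spt <- sum(p * t)
  denom <- sp + st_ + smooth
  val <- 1 - (2 * spt + smooth) / denom
  record(array(val, c(1, 1, 1, 1)), list(pred), function(g) {
    gp <- -(2 * t * denom - (2 * spt + smooth)) / denom^2
    gp <- as.numeric(g) * gp
    dim(gp) <- dim(pred$v)
    list(gp)
  })
}

op_bce <- function(pred, target, eps = 1e-7) {
  p <- pred$v
  inside <- p > eps & p < 1 - eps
  pc <- clamp01(p, eps)
  n <- length(p)
  val <- -sum(target * log(pc) + (1 - target) * log(1 - pc)) / n
  record(array(val, c(1, 1, 1, 1)), list(pred), function(g) {
    gp <- (-target / pc + (1 - target) / (1 - pc)) * inside / n
    gp <- as.numeric(g) * gp
    dim(gp) <- dim(pred$v)
    list(gp)
  })
}

# Weighted sum of scalar loss tensors.
op_wsum <- function(tensors, weights) {
  val <- 0
  for (i in seq_along(tensors)) val <- val + weights[i] * as.numeric(tensors[[i]]$v)
  record(array(val, c(1, 1, 1, 1)), tensors, function(g) {
    lapply(seq_along(tensors), function(i)
      array(as.numeric(g) * weights[i], c(1, 1, 1, 1)))
  })
}

op_addc <- function(x, const) {
  record(x$v + const, list(x), function(g) list(g))
}
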