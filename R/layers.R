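# Layer constructors. A "network" is an environment holding a flat, named
# parameter registry (`params`), batch-norm buffer environments (`bn`), and
# closures wired into the architecture. Parameter names are dotted paths
# ("stage2.block1.c1.w") so checkpoints and coef() are self-describing.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

new_network_env <- function() {
  M <- new.env(parent = emptyenv())
  M$params <- list()
  M$bn <- list()
  M
}

add_param <- function(M, name, value) {
  t <- nn_tensor(value, requires_grad = TRUE)
  M$params[[name]] <- t
  t
}

# Convolution unit: conv -> optional BN -> activation. He-normal init.
make_conv <- function(M, name, cin, cout, k, stride = 1L, bn = TRUE,
                      act = c("relu", "sigmoid", "none")) {
  act <- match.arg(act)
  sd <- sqrt(2 / (k * k * cin))
  w <- add_param(M, paste0(name, ".w"),
                 array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)))
  b <- add_param(M, paste0(name, ".b"), rep(0, cout))
  gamma <- beta <- st <- NULL
  if (bn) {
    gamma <- add_param(M, paste0(name, ".bn.gamma"), rep(1, cout))
    beta <- add_param(M, paste0(name, ".bn.beta"), rep(0, cout))
    st <- new.env(parent = emptyenv())
    st$running_mean <- rep(0, cout)
    st$running_var <- rep(1, cout)
    M$bn[[paste0(name, ".bn")]] <- st
  }
  function(x, training = FALSE) {
    y <- op_conv(x, w, b, stride)
    if (bn) y <- op_bn(y, gamma, beta, st, training)
    switch(act, relu = op_relu(y), sigmoid = op_sigmoid(y), none = y)
  }
}

# Basic residual block (two 3x3 convs + identity/projection skip).
make_resblock <- function(M, name, cin, cout, stride, use_bn) {
  c1 <- make_conv(M, paste0(name, ".c1"), cin, cout, 3L, stride, use_bn, "relu")
  c2 <- make_conv(M, paste0(name, ".c2"), cout, cout, 3L, 1L, use_bn, "none")
  proj <- if (stride != 1L || cin != cout)
    make_conv(M, paste0(name, ".proj"), cin, cout, 1L, stride, use_bn, "none")
  else NULL
  function(x, training = FALSE) {
    y <- c2(c1(x, training), training)
    s <- if (is.null(proj)) x else proj(x, training)
    op_relu(op_add(y, s))
  }
}

# Residual backbone with side outputs at strides {2, 4, 8, 16}. The stem has
# no max pool and there is no classification head.
build_backbone_mod <- function(M, in_ch, base, depths, use_bn,
                               keep_stages = 4L) {
  # keep_stages < 4 drops unused deep stages (the boundary-only variant
  # never consumes the deepest side output, so it is not built)
  stem <- make_conv(M, "stem", in_ch, base, 7L, 2L, use_bn, "relu")
  stages <- vector("list", keep_stages)
  cin <- base
  for (s in seq_len(keep_stages)) {
    cout <- base * 2L^(s - 1L)
    blocks <- vector("list", depths[s])
    for (bi in seq_len(depths[s])) {
      stride <- if (bi == 1L && s > 1L) 2L else 1L
      blocks[[bi]] <- make_resblock(M, sprintf("stage%d.block%d", s, bi),
                                    cin, cout, stride, use_bn)
      cin <- cout
    }
    stages[[s]] <- blocks
  }
  function(x, training = FALSE) {
    h <- stem(x, training)
    outs <- vector("list", keep_stages)
    for (s in seq_len(keep_stages)) {
      for (blk in stages[[s]]) h <- blk(h, training)
      outs[[s]] <- h
    }
    names(outs) <- c("beta1", "beta2", "beta3", "alpha4")[seq_len(keep_stages)]
    outs
  }
}

# Scale-adaptive aggregation applied to the deepest backbone features.
build_sa_mod <- function(M, c4, ws, use_bn) {
  conv_b5 <- make_conv(M, "sa.b5", c4, ws, 5L, 1L, use_bn, "relu")
  conv_g3a <- make_conv(M, "sa.g3a", ws, ws, 3L, 1L, use_bn, "relu")
  conv_g3b <- make_conv(M, "sa.g3b", ws, ws, 3L, 1L, use_bn, "relu")
  conv_g1a <- make_conv(M, "sa.g1a", ws, ws, 1L, 1L, use_bn, "relu")
  conv_g1b <- make_conv(M, "sa.g1b", ws, ws, 1L, 1L, use_bn, "relu")
  conv_g5 <- make_conv(M, "sa.g5", ws, ws, 5L, 1L, use_bn, "relu")
  conv_mu <- make_conv(M, "sa.mu", c4, ws, 1L, 1L, use_bn, "none")
  conv_rho <- make_conv(M, "sa.rho", c4, 4L * ws, 1L, 1L, FALSE, "none")
  function(alpha4, training = FALSE, want_trace = FALSE) {
    hw <- dim(alpha4$v)[1:2]
    b5 <- conv_b5(alpha4, training)
    d3 <- op_maxpool2(b5)
    g3 <- conv_g3b(conv_g3a(d3, training), training)
    d1 <- op_maxpool2(g3)
    g1 <- conv_g1b(conv_g1a(d1, training), training)
    g5 <- conv_g5(b5, training)
    g1u <- op_resize(g1, hw[1], hw[2])
    g3u <- op_resize(g3, hw[1], hw[2])
    eta <- op_add(op_add(g1u, g3u), g5)
    mu <- op_mul(conv_mu(alpha4, training), eta)
    kap <- op_concat_c(list(g1u, g3u, g5, mu))
    rho_g <- op_gap(alpha4)
    rho <- conv_rho(rho_g, training)
    alpha_sa <- op_add_cbcast(kap, rho)
    out <- list(alpha_sa = alpha_sa)
    if (want_trace) {
      out$trace <- list(
        beta5 = b5$v, delta3 = d3$v, delta1 = d1$v,
        gamma1 = g1u$v, gamma3 = g3u$v, gamma5 = g5$v,
        eta = eta$v, mu = mu$v, kappa = kap$v,
        rho_g = rho_g$v,
        rho = {
          r <- array(rep(as.vector(rho$v), each = hw[1] * hw[2]),
                     c(hw[1], hw[2], dim(rho$v)[3], dim(rho$v)[4]))
          r
        },
        alpha_sa = alpha_sa$v)
    }
    out
  }
}

# One attention-enhancement decoder block. `high_attn` drives the channel
# gate (global max pool path); `high_eta` is the fused-feature recursion
# input. `gate_shift` is a test hook added to the gate's pre-activation.
build_ae_block_mod <- function(M, name, c_low, c_high_attn, c_high_eta, wi, use_bn) {
  low_desc <- make_conv(M, paste0(name, ".low_desc"), c_low, wi, 1L, 1L, FALSE, "relu")
  high_desc <- make_conv(M, paste0(name, ".high_desc"), c_high_attn, wi, 1L, 1L, FALSE, "relu")
  gate_conv <- make_conv(M, paste0(name, ".gate"), wi, wi, 1L, 1L, FALSE, "none")
  feat_conv <- make_conv(M, paste0(name, ".feat"), c_low, wi, 3L, 1L, use_bn, "relu")
  high_proj <- make_conv(M, paste0(name, ".high_proj"), c_high_eta, wi, 1L, 1L, use_bn, "none")
  function(beta_low, high_attn, high_eta, training = FALSE,
           gate_shift = 0, want_trace = FALSE) {
    hw <- dim(beta_low$v)[1:2]
    a_low <- low_desc(op_gap(beta_low), training)
    a_high <- high_desc(op_gmp(high_attn), training)
    pre <- gate_conv(op_add(a_low, a_high), training)
    if (gate_shift != 0) pre <- op_addc(pre, gate_shift)
    gate <- op_sigmoid(pre)
    feat <- feat_conv(beta_low, training)
    gamma_out <- op_mul_cbcast(gate, feat)
    hp <- op_resize(high_proj(high_eta, training), hw[1], hw[2])
    eta_ae <- op_upsample2(op_add(gamma_out, hp))
    out <- list(gamma_out = gamma_out, eta_ae = eta_ae)
    if (want_trace) {
      out$trace <- list(a_low = a_low$v, a_high = a_high$v, gate = gate$v,
                        gamma_out = gamma_out$v, eta_ae = eta_ae$v)
    }
    out
  }
}

# Boundary refinement operator R(.): 1x1 channel alignment, sigmoid attention
# map over a BN'd 3x3 conv, and a residual 3x3 refinement. The refinement
# conv has no BN and no activation, so zeroing its weights and bias leaves
# r_out identical to a_proj.
build_br_refine_mod <- function(M, name, cin, wb, use_bn) {
  a_conv <- make_conv(M, paste0(name, ".a"), cin, wb, 1L, 1L, FALSE, "none")
  tau_conv <- make_conv(M, paste0(name, ".tau"), wb, wb, 3L, 1L, TRUE, "sigmoid")
  r_conv <- make_conv(M, paste0(name, ".r"), wb, wb, 3L, 1L, FALSE, "none")
  function(x, training = FALSE) {
    a <- a_conv(x, training)
    tau <- tau_conv(a, training)
    r <- op_add(r_conv(tau, training), a)
    list(a_proj = a, tau = tau, r_out = r)
  }
}

# One stage of the cascaded boundary network: fuse a shallow and an adjacent
# deeper refined map, cross-weight them, and refine the concatenation.
build_boundary_stage_mod <- function(M, name, wb, use_bn) {
  refine <- build_br_refine_mod(M, paste0(name, ".refine"), 2L * wb, wb, use_bn)
  function(r_shallow, r_deep, training = FALSE, want_trace = FALSE) {
    hs <- dim(r_shallow$v)[1:2]
    hd <- dim(r_deep$v)[1:2]
    if (!all(pmax(1L, hs %/% 2L) == hd))
      stop("boundary stage requires adjacent resolutions: deep ",
           paste(hd, collapse = "x"), " is not half of shallow ",
           paste(hs, collapse = "x"))
    gsum <- op_add(op_resize(r_deep, hs[1], hs[2]), r_shallow)
    gy1 <- op_mul(r_shallow, gsum)
    gy2 <- op_mul(r_deep, op_maxpool2(gsum))
    cat_in <- op_concat_c(list(gy1, op_resize(gy2, hs[1], hs[2])))
    ref <- refine(cat_in, training)
    out <- list(eta_out = ref$r_out)
    if (want_trace) {
      out$trace <- list(gamma_sum = gsum$v, gamma_y1 = gy1$v, gamma_y2 = gy2$v,
                        a_proj = ref$a_proj$v, tau = ref$tau$v,
                        eta_out = ref$r_out$v)
    }
    out
  }
}

adam_init <- function(net) {
  net$adam <- list(t = 0L,
                   m = lapply(net$params, function(p) p$v * 0),
                   v = lapply(net$params, function(p) p$v * 0))
  invisible(net)
}

adam_step <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(net$adam)) adam_init(net)
  st <- net$adam
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    g <- p$g
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    p$g <- NULL
  }
  net$adam <- st
  invisible(net)
}

zero_grads <- function(net) {
  for (p in net$params) p$g <- NULL
  invisible(net)
}
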