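#' Construct the segmentation network
#'
#' Builds the saliency-guided boundary-refinement network (or one of its
#' ablation variants) with seeded, deterministic initialization. The
#' architecture has three branches sharing one residual backbone: a
#' feature-guided branch (scale-adaptive aggregation of the deepest features
#' followed by attention-enhanced decoding), a boundary branch (cascaded
#' residual boundary refinement of the three shallow side outputs), and a
#' fusion stage producing three per-pixel probability heads:
#' \describe{
#'   \item{t0}{the fused vessel-probability map,}
#'   \item{t1}{the boundary-probability map (boundary branch),}
#'   \item{t2}{the vessel-probability map of the feature-guided branch.}
#' }
#' The deepest side output feeds only the scale-adaptive module; the
#' decoder and boundary branches consume the three shallower side outputs.
#'
#' Variants wire subsets of the branches:
#' `"resnet"` backbone + plain upsampling head; `"bnet"` backbone + boundary
#' branch; `"resnet_wsa"` / `"resnet_wae"` backbone + one feature-guided
#' module; `"fsnet"` both feature-guided modules; `"sgbnet"` the full model
#' with three-head fusion.
#'
#' @param variant One of `"resnet"`, `"bnet"`, `"resnet_wsa"`,
#'   `"resnet_wae"`, `"fsnet"`, `"sgbnet"`.
#' @param base_width Stem channel count; stage widths are
#'   `base_width * c(1, 2, 4, 8)` and all decoder widths scale with it.
#'   `base_width = 64` with `depths = c(3, 4, 6, 3)` reproduces the
#'   ResNet34-scale reference configuration; the default (16, with two
#'   blocks per stage) is a compact CPU-scale model.
#' @param depths Residual blocks per backbone stage (length 4).
#' @param in_ch Input channels (1 after the standard preprocessing chain).
#' @param use_bn Batch-normalize after convolutions in the backbone and
#'   branch feature paths. The boundary attention map keeps its BN
#'   regardless (it is part of its definition). Disable for exactness tests.
#' @param seed Integer seed for weight initialization.
#' @param pretrained If `TRUE`, attempt to load externally pretrained
#'   backbone weights. No weight archive ships with the package, so this
#'   falls back to seeded random initialization with a warning; the flag
#'   exists so a user-supplied checkpoint workflow can honour it.
#' @return An object of class `sgbnet_network`: an environment with the
#'   named parameter registry, batch-norm buffers, and forward closures.
#' @seealso [network_forward()], [sgbnet()] for training.
#' @export
sgbnet_network <- function(variant = c("sgbnet", "resnet", "bnet", "resnet_wsa",
                                       "resnet_wae", "fsnet"),
                           base_width = 16L, depths = c(2L, 2L, 2L, 2L),
                           in_ch = 1L, use_bn = TRUE, seed = 1L,
                           pretrained = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(depths) == 4L, all(depths >= 1L), base_width >= 1L)
  if (pretrained)
    warning("no pretrained backbone weights are available; ",
            "using seeded random initialization")
  M <- new_network_env()
  cb <- base_width * c(1L, 2L, 4L, 8L)    # side-output channels
  ws <- base_width                        # scale-adaptive branch width
  wae <- base_width * c(4L, 2L, 1L)       # decoder widths, deep to shallow
  wb <- base_width                        # boundary projection width
  wf <- base_width                        # fusion width

  has_sa <- variant %in% c("resnet_wsa", "fsnet", "sgbnet")
  has_ae <- variant %in% c("resnet_wae", "fsnet", "sgbnet")
  has_br <- variant %in% c("bnet", "sgbnet")

  with_seed(seed, {
    M$backbone <- build_backbone_mod(M, in_ch, base_width, depths, use_bn,
                                     keep_stages = if (variant == "bnet") 3L
                                                   else 4L)
    if (has_sa) M$sa <- build_sa_mod(M, cb[4], ws, use_bn)
    if (has_ae) {
      c_high1 <- if (has_sa) 4L * ws else cb[4]
      M$ae <- list(
        build_ae_block_mod(M, "ae1", cb[3], c_high1, c_high1, wae[1], use_bn),
        build_ae_block_mod(M, "ae2", cb[2], wae[1], wae[1], wae[2], use_bn),
        build_ae_block_mod(M, "ae3", cb[1], wae[2], wae[2], wae[3], use_bn))
    }
    if (has_br) {
      M$br <- list(
        build_br_refine_mod(M, "br1", cb[1], wb, use_bn),
        build_br_refine_mod(M, "br2", cb[2], wb, use_bn),
        build_br_refine_mod(M, "br3", cb[3], wb, use_bn))
      M$bstage <- list(
        build_boundary_stage_mod(M, "bstage1", wb, use_bn),
        build_boundary_stage_mod(M, "bstage2", wb, use_bn),
        build_boundary_stage_mod(M, "bstage3", wb, use_bn))
    }
    # heads
    if (variant == "resnet") {
      M$dec <- make_conv(M, "dec", cb[4], wf, 3L, 1L, use_bn, "relu")
      M$head_t0 <- make_conv(M, "head.t0", wf, 1L, 1L, 1L, FALSE, "sigmoid")
    } else if (variant == "resnet_wsa") {
      M$head_t0 <- make_conv(M, "head.t0", 4L * ws, 1L, 1L, 1L, FALSE, "sigmoid")
    } else if (variant %in% c("resnet_wae", "fsnet")) {
      M$head_t0 <- make_conv(M, "head.t0", wae[3], 1L, 1L, 1L, FALSE, "sigmoid")
    } else if (variant == "bnet") {
      M$head_t0 <- make_conv(M, "head.t0", wb, 1L, 1L, 1L, FALSE, "sigmoid")
      M$head_t1 <- make_conv(M, "head.t1", wb, 1L, 1L, 1L, FALSE, "sigmoid")
    } else { # sgbnet
      M$fuse_gout <- make_conv(M, "fuse.gout", wae[3], wf, 1L, 1L, use_bn, "none")
      M$fuse_eta <- make_conv(M, "fuse.eta", wae[3], wf, 1L, 1L, use_bn, "none")
      M$fuse_bout <- make_conv(M, "fuse.bout", wb, wf, 1L, 1L, use_bn, "none")
      M$head_t0 <- make_conv(M, "head.t0", wf, 1L, 1L, 1L, FALSE, "sigmoid")
      M$head_t1 <- make_conv(M, "head.t1", wb, 1L, 1L, 1L, FALSE, "sigmoid")
      M$head_t2 <- make_conv(M, "head.t2", wae[3], 1L, 1L, 1L, FALSE, "sigmoid")
    }
    # class-prior initialization of the head biases: starting the sigmoid
    # heads near the foreground prior (~10% vessel pixels) instead of 0.5
    # removes the early training phase spent unlearning the uninformative
    # initial output (the standard dense-detection recipe).
    for (nm in intersect(c("head.t0.b", "head.t1.b", "head.t2.b"),
                         names(M$params)))
      M$params[[nm]]$v <- rep(stats::qlogis(0.1), length(M$params[[nm]]$v))
  })
  M$cfg <- list(variant = variant, base_width = base_width, depths = depths,
                in_ch = in_ch, use_bn = use_bn, seed = seed,
                channels = cb, sa_width = ws, ae_widths = wae,
                br_width = wb, fuse_width = wf)
  M$native_heads <- switch(variant,
                           sgbnet = c("t0", "t1", "t2"),
                           bnet = c("t0", "t1"),
                           c("t0"))
  class(M) <- c("sgbnet_network", class(M))
  M
}

check_input_size <- function(h, w) {
  if (h %% 16L != 0L || w %% 16L != 0L)
    stop("input height and width must be divisible by 16 (got ",
         h, "x", w, "); pad upstream")
}

# Internal forward over tensors; used by both training and the exported
# array-level interface. `image` is a [H,W,C,N] tensor.
net_forward <- function(net, image, training = FALSE, want_traces = FALSE,
                        ae_gate_shift = 0) {
  d <- dim(image$v)
  check_input_size(d[1], d[2])
  H <- d[1]; W <- d[2]
  variant <- net$cfg$variant
  py <- net$backbone(image, training)
  traces <- if (want_traces) list() else NULL
  t0 <- t1 <- t2 <- NULL

  alpha_top <- py$alpha4
  if (!is.null(net$sa)) {
    sa <- net$sa(py$alpha4, training, want_trace = want_traces)
    alpha_top <- sa$alpha_sa
    if (want_traces) traces$sa <- sa$trace
  }

  gout_last <- eta_ae_last <- NULL
  if (!is.null(net$ae)) {
    lows <- list(py$beta3, py$beta2, py$beta1)
    high_attn <- alpha_top
    high_eta <- alpha_top
    ae_traces <- list()
    for (i in 1:3) {
      blk <- net$ae[[i]](lows[[i]], high_attn, high_eta, training,
                         gate_shift = ae_gate_shift, want_trace = want_traces)
      if (want_traces) ae_traces[[i]] <- blk$trace
      high_attn <- blk$gamma_out
      high_eta <- blk$eta_ae
      gout_last <- blk$gamma_out
      eta_ae_last <- blk$eta_ae
    }
    if (want_traces) traces$ae <- ae_traces
  }

  eta_out_last <- NULL
  if (!is.null(net$br)) {
    r1 <- net$br[[1]](py$beta1, training)
    r2 <- net$br[[2]](py$beta2, training)
    r3 <- net$br[[3]](py$beta3, training)
    s1 <- net$bstage[[1]](r1$r_out, r2$r_out, training, want_trace = want_traces)
    s2 <- net$bstage[[2]](r2$r_out, r3$r_out, training, want_trace = want_traces)
    s3 <- net$bstage[[3]](s1$eta_out, s2$eta_out, training, want_trace = want_traces)
    eta_out_last <- s3$eta_out
    if (want_traces) {
      traces$br <- list(r1 = list(a_proj = r1$a_proj$v, tau = r1$tau$v, r_out = r1$r_out$v),
                        r2 = list(a_proj = r2$a_proj$v, tau = r2$tau$v, r_out = r2$r_out$v),
                        r3 = list(a_proj = r3$a_proj$v, tau = r3$tau$v, r_out = r3$r_out$v),
                        stages = list(s1$trace, s2$trace, s3$trace))
    }
  }

  if (variant == "resnet") {
    t0 <- op_resize(net$head_t0(net$dec(py$alpha4, training), training), H, W)
  } else if (variant == "resnet_wsa") {
    t0 <- op_resize(net$head_t0(alpha_top, training), H, W)
  } else if (variant %in% c("resnet_wae", "fsnet")) {
    t0 <- op_resize(net$head_t0(eta_ae_last, training), H, W)
  } else if (variant == "bnet") {
    t0 <- op_resize(net$head_t0(eta_out_last, training), H, W)
    t1 <- op_resize(net$head_t1(eta_out_last, training), H, W)
  } else { # sgbnet
    a <- op_resize(net$fuse_gout(gout_last, training), H, W)
    b <- op_resize(net$fuse_eta(eta_ae_last, training), H, W)
    cc <- op_resize(net$fuse_bout(eta_out_last, training), H, W)
    eq <- op_add(op_add(a, b), cc)
    t0 <- net$head_t0(eq, training)
    t1 <- op_resize(net$head_t1(eta_out_last, training), H, W)
    t2 <- op_resize(net$head_t2(eta_ae_last, training), H, W)
  }
  if (is.null(t1)) t1 <- t0
  if (is.null(t2)) t2 <- t0
  list(t0 = t0, t1 = t1, t2 = t2, traces = traces,
       native = net$native_heads)
}

#' Run the network on an image
#'
#' Full forward pass in inference mode (batch-norm running statistics, no
#' gradient recording), returning the three probability heads at input
#' resolution and, optionally, per-block intermediate traces.
#'
#' @param net A network from [sgbnet_network()].
#' @param image Numeric matrix `H x W` (values in `[0,1]`) or array
#'   `H x W x 1 x N`; height and width must be divisible by 16.
#' @param return_traces Return intermediate per-block arrays (slower).
#' @return A list with `t0`, `t1`, `t2` (arrays shaped like the input
#'   batch), `native` (which heads the variant actually computes; the others
#'   are copies of `t0`), and `traces` when requested.
#' @export
network_forward <- function(net, image, return_traces = FALSE) {
  x <- as_tensor4(image)
  out <- no_grad(net_forward(net, x, training = FALSE,
                             want_traces = return_traces))
  list(t0 = out$t0$v, t1 = out$t1$v, t2 = out$t2$v,
       native = out$native, traces = out$traces)
}

#' Backbone feature pyramid
#'
#' Runs only the residual backbone and returns the four side outputs with
#' their stride/channel contract: strides {2, 4, 8, 16} relative to the
#' input, channels `base_width * c(1, 2, 4, 8)`.
#'
#' @inheritParams network_forward
#' @return List with arrays `beta1`, `beta2`, `beta3`, `alpha4`, plus
#'   `strides` and `channels`.
#' @export
backbone_forward <- function(net, image) {
  x <- as_tensor4(image)
  check_input_size(dim(x$v)[1], dim(x$v)[2])
  py <- no_grad(net$backbone(x, training = FALSE))
  out <- lapply(py, function(t) t$v)
  out$strides <- c(beta1 = 2L, beta2 = 4L, beta3 = 8L, alpha4 = 16L)[names(py)]
  out$channels <- net$cfg$channels[seq_along(py)]
  out
}

#' Scale-adaptive module forward
#'
#' Applies the multi-kernel aggregation with global-context fusion to a
#' deepest-stage feature map and returns all intermediates: the coarse 5x5
#' features, the pooled intermediates, the three branch outputs (aligned to
#' the input resolution), their sum `eta`, the reweighted projection `mu`,
#' the concatenation `kappa`, the pooled global descriptor `rho_g`, its
#' broadcast projection `rho`, and the output `alpha_sa`.
#'
#' @param net A network built with a variant that includes the module.
#' @param alpha4 Feature array `[h, w, C4, N]` from [backbone_forward()].
#' @return Named list of arrays (see description).
#' @export
sa_forward <- function(net, alpha4) {
  if (is.null(net$sa))
    stop("variant '", net$cfg$variant, "' has no scale-adaptive module")
  r <- no_grad(net$sa(as_tensor4(alpha4), training = FALSE, want_trace = TRUE))
  r$trace
}

#' Attention-enhancement decoder block forward
#'
#' Runs one decoder block: channel descriptors from global average pooling
#' of the low-level features and global max pooling of the high-level input,
#' a sigmoid channel gate, gating of the 3x3-convolved low-level features,
#' and the doubled-resolution fused output.
#'
#' @param net A network whose variant includes the decoder.
#' @param index Block index 1-3 (block 1 consumes the deepest decoder input).
#' @param beta_low Low-level side-output array; spatial size must be twice
#'   that of `high`.
#' @param high High-level input array (the scale-adaptive output for block
#'   1, the previous block's gated features thereafter).
#' @param gate_shift Test hook added to the gate pre-activation
#'   (e.g. `-1e9` forces the gate to 0).
#' @return List of arrays `a_low`, `a_high`, `gate`, `gamma_out`, `eta_ae`.
#' @export
ae_forward <- function(net, index, beta_low, high, gate_shift = 0) {
  if (is.null(net$ae))
    stop("variant '", net$cfg$variant, "' has no attention-enhancement decoder")
  bl <- as_tensor4(beta_low)
  hi <- as_tensor4(high)
  if (!all(dim(bl$v)[1:2] == 2L * dim(hi$v)[1:2]))
    stop("beta_low spatial size must be exactly twice that of high")
  r <- no_grad(net$ae[[index]](bl, hi, hi, training = FALSE,
                               gate_shift = gate_shift, want_trace = TRUE))
  r$trace
}

#' Boundary refinement operator
#'
#' Channel-aligns a side output with a 1x1 convolution, forms a sigmoid
#' attention map over a batch-normalized 3x3 convolution, and adds a
#' residual 3x3 refinement of the attention map.
#'
#' @param net A network whose variant includes the boundary branch.
#' @param level Side-output level 1-3.
#' @param beta_i Feature array for that level.
#' @return List of arrays `a_proj`, `tau`, `r_out`.
#' @export
br_refine <- function(net, level, beta_i) {
  if (is.null(net$br))
    stop("variant '", net$cfg$variant, "' has no boundary branch")
  r <- no_grad(net$br[[level]](as_tensor4(beta_i), training = FALSE))
  list(a_proj = r$a_proj$v, tau = r$tau$v, r_out = r$r_out$v)
}

#' Cascaded boundary-stage fusion
#'
#' Fuses refined boundary features from two adjacent resolutions: the deep
#' map is bilinearly up-sampled and added to the shallow map
#' (`gamma_sum`), both inputs are cross-weighted by it (`gamma_y1`,
#' `gamma_y2`, the deep side against the max-pooled sum), and the refined
#' concatenation is returned at the shallow resolution.
#'
#' @param net A network whose variant includes the boundary branch.
#' @param stage Stage index 1-3.
#' @param r_shallow,r_deep Refined feature arrays; `r_deep` must be at half
#'   the spatial size of `r_shallow`.
#' @return List of arrays `gamma_sum`, `gamma_y1`, `gamma_y2`, `eta_out`.
#' @export
boundary_stage <- function(net, stage, r_shallow, r_deep) {
  if (is.null(net$bstage))
    stop("variant '", net$cfg$variant, "' has no boundary branch")
  r <- no_grad(net$bstage[[stage]](as_tensor4(r_shallow), as_tensor4(r_deep),
                                   training = FALSE, want_trace = TRUE))
  r$trace
}

#' Three-head fusion
#'
#' Projects the last decoder gate features, the last fused decoder output,
#' and the last boundary-stage output to a common width, bilinearly aligns
#' them to the target shape, and produces the three sigmoid heads.
#'
#' @param net A full (`"sgbnet"`) network.
#' @param gamma_out_last,eta_ae_last,eta_out_last Feature arrays from the
#'   decoder and boundary branches.
#' @param target_shape Integer `(H, W)` output size.
#' @return List of arrays `t0`, `t1`, `t2` of size `target_shape`.
#' @export
fuse_heads <- function(net, gamma_out_last, eta_ae_last, eta_out_last,
                       target_shape) {
  if (net$cfg$variant != "sgbnet")
    stop("head fusion exists only in the full 'sgbnet' variant")
  H <- target_shape[1]; W <- target_shape[2]
  no_grad({
    g <- as_tensor4(gamma_out_last)
    e <- as_tensor4(eta_ae_last)
    bo <- as_tensor4(eta_out_last)
    a <- op_resize(net$fuse_gout(g, FALSE), H, W)
    b <- op_resize(net$fuse_eta(e, FALSE), H, W)
    cc <- op_resize(net$fuse_bout(bo, FALSE), H, W)
    eq <- op_add(op_add(a, b), cc)
    list(t0 = net$head_t0(eq, FALSE)$v,
         t1 = op_resize(net$head_t1(bo, FALSE), H, W)$v,
         t2 = op_resize(net$head_t2(e, FALSE), H, W)$v)
  })
}

#' Number of trainable parameters
#' @param net A network.
#' @return Integer count of scalar parameters.
#' @export
network_n_params <- function(net) {
  sum(vapply(net$params, function(p) length(p$v), numeric(1)))
}

#' Get or set a named parameter
#'
#' Parameters are addressed by dotted path (see `names(coef(fit))`).
#' Setting is mainly useful for identity tests (e.g. zeroing a refinement
#' convolution).
#'
#' @param net A network.
#' @param name Parameter name.
#' @param value Replacement array/vector of identical shape.
#' @return `network_param` returns the parameter array.
#' @export
network_param <- function(net, name) {
  p <- net$params[[name]]
  if (is.null(p)) stop("no parameter named '", name, "'")
  p$v
}

#' @rdname network_param
#' @export
set_network_param <- function(net, name, value) {
  p <- net$params[[name]]
  if (is.null(p)) stop("no parameter named '", name, "'")
  stopifnot(length(value) == length(p$v))
  if (!is.null(dim(p$v))) dim(value) <- dim(p$v)
  p$v <- value
  invisible(net)
}

# Serializable state: parameter values plus BN buffers. Versioned so
# checkpoints can be validated on load.
network_state <- function(net) {
  list(schema = 1L,
       variant = net$cfg$variant,
       cfg = net$cfg,
       params = lapply(net$params, function(p) p$v),
       bn = lapply(net$bn, function(st)
         list(running_mean = st$running_mean, running_var = st$running_var)))
}

restore_network_state <- function(net, state) {
  stopifnot(identical(state$schema, 1L))
  for (nm in names(state$params)) {
    p <- net$params[[nm]]
    if (is.null(p)) stop("checkpoint parameter '", nm, "' not in network")
    p$v <- state$params[[nm]]
  }
  for (nm in names(state$bn)) {
    st <- net$bn[[nm]]
    if (is.null(st)) stop("checkpoint buffer '", nm, "' not in network")
    st$running_mean <- state$bn[[nm]]$running_mean
    st$running_var <- state$bn[[nm]]$running_var
  }
  invisible(net)
}

network_from_state <- function(state) {
  cfg <- state$cfg
  net <- sgbnet_network(variant = cfg$variant, base_width = cfg$base_width,
                        depths = cfg$depths, in_ch = cfg$in_ch,
                        use_bn = cfg$use_bn, seed = cfg$seed)
  restore_network_state(net, state)
}
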