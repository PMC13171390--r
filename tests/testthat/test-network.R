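# Architecture contracts: backbone strides, module traces, identities.

small_net <- function(variant = "sgbnet", seed = 3, bw = 8)
  sgbnet_network(variant, base_width = bw, seed = seed)

test_that("backbone side outputs follow the stride/channel table", {
  net <- small_net()
  x <- matrix(runif(64 * 64), 64, 64)
  py <- backbone_forward(net, x)
  expect_equal(dim(py$beta1)[1:2], c(32, 32))
  expect_equal(dim(py$beta2)[1:2], c(16, 16))
  expect_equal(dim(py$beta3)[1:2], c(8, 8))
  expect_equal(dim(py$alpha4)[1:2], c(4, 4))
  expect_equal(unname(py$channels), 8L * c(1L, 2L, 4L, 8L))
  expect_equal(dim(py$beta1)[3], py$channels[[1]])
  py96 <- backbone_forward(net, matrix(runif(96 * 96), 96, 96))
  expect_equal(dim(py96$alpha4)[1:2], c(6, 6))
  expect_error(backbone_forward(net, matrix(0, 60, 60)), "divisible by 16")
})

test_that("identical seeds give identical parameters; different seeds differ", {
  a <- sgbnet_network("resnet", base_width = 4, seed = 11)
  b <- sgbnet_network("resnet", base_width = 4, seed = 11)
  cc <- sgbnet_network("resnet", base_width = 4, seed = 12)
  expect_identical(lapply(a$params, function(p) p$v),
                   lapply(b$params, function(p) p$v))
  expect_false(identical(network_param(a, "stem.w"), network_param(cc, "stem.w")))
  expect_warning(sgbnet_network("resnet", base_width = 4, pretrained = TRUE),
                 "pretrained")
})

test_that("scale-adaptive trace obeys the aggregation algebra", {
  net <- small_net()
  a4 <- backbone_forward(net, matrix(runif(64 * 64), 64, 64))$alpha4
  tr <- sa_forward(net, a4)
  expect_equal(dim(tr$alpha_sa)[1:2], dim(a4)[1:2])        # resolution kept
  expect_equal(tr$eta, tr$gamma1 + tr$gamma3 + tr$gamma5)  # element-wise sum
  # concatenation arithmetic: 3 branch widths + mu width
  ws <- net$cfg$sa_width
  expect_equal(dim(tr$kappa)[3], 3L * ws + ws)
  expect_equal(dim(tr$alpha_sa), dim(tr$kappa))
  # zeroing all branch convolutions forces eta = 0 and hence mu = 0
  net0 <- small_net(seed = 5)
  for (nm in grep("^sa\\.(b5|g1a|g1b|g3a|g3b|g5)\\.(w|b|bn\\.gamma|bn\\.beta)$",
                  names(net0$params), value = TRUE))
    set_network_param(net0, nm, rep(0, length(network_param(net0, nm))))
  tr0 <- sa_forward(net0, a4)
  expect_equal(max(abs(tr0$eta)), 0)
  expect_equal(max(abs(tr0$mu)), 0)
})

test_that("attention-enhancement block gates and doubles resolution", {
  net <- small_net()
  beta3 <- array(runif(8 * 8 * net$cfg$channels[3]),
                 c(8, 8, net$cfg$channels[3], 1))
  high <- array(runif(4 * 4 * 4 * net$cfg$sa_width),
                c(4, 4, 4 * net$cfg$sa_width, 1))
  tr <- ae_forward(net, 1, beta3, high)
  expect_true(all(tr$gate > 0 & tr$gate < 1))
  expect_equal(dim(tr$eta_ae)[1:2], c(16, 16))  # two doublings from high
  expect_equal(dim(tr$gamma_out)[1:2], c(8, 8))
  # forcing the gate to zero nulls the gated features
  tr0 <- ae_forward(net, 1, beta3, high, gate_shift = -1e9)
  expect_equal(max(abs(tr0$gamma_out)), 0)
  expect_error(ae_forward(net, 1, beta3, beta3), "twice")
})

test_that("boundary refinement is a strict residual around the projection", {
  net <- small_net(seed = 9)
  beta1 <- array(runif(16 * 16 * net$cfg$channels[1]),
                 c(16, 16, net$cfg$channels[1], 1))
  tr <- br_refine(net, 1, beta1)
  expect_true(all(tr$tau > 0 & tr$tau < 1))
  expect_equal(dim(tr$r_out)[1:2], dim(beta1)[1:2])
  # zero refinement conv (weights and bias) -> r_out == a_proj bit-exactly
  set_network_param(net, "br1.r.w", rep(0, length(network_param(net, "br1.r.w"))))
  set_network_param(net, "br1.r.b", rep(0, length(network_param(net, "br1.r.b"))))
  tr0 <- br_refine(net, 1, beta1)
  expect_identical(tr0$r_out, tr0$a_proj)
})

test_that("boundary stages cross-weight adjacent resolutions", {
  net <- small_net(seed = 13)
  wb <- net$cfg$br_width
  r_sh <- array(runif(8 * 8 * wb), c(8, 8, wb, 1))
  r_dp <- array(runif(4 * 4 * wb), c(4, 4, wb, 1))
  tr <- boundary_stage(net, 1, r_sh, r_dp)
  expect_equal(dim(tr$eta_out)[1:2], c(8, 8))    # shallow resolution
  # gamma_y1 equals the element-wise product oracle
  up <- sgbnet:::cpp_resize_bilinear_fwd(r_dp, dim(r_dp), 8L, 8L)
  expect_equal(tr$gamma_y1, (up + r_sh) * r_sh, tolerance = 1e-12)
  expect_error(boundary_stage(net, 1, r_sh, r_sh), "adjacent")
  # zero inputs with zero-initialised biases stay zero through the stage
  z_sh <- array(0, dim(r_sh)); z_dp <- array(0, dim(r_dp))
  netz <- small_net(seed = 14)
  for (nm in grep("^bstage1\\.", names(netz$params), value = TRUE))
    set_network_param(netz, nm,
                      rep(0, length(network_param(netz, nm))))
  trz <- boundary_stage(netz, 1, z_sh, z_dp)
  expect_equal(max(abs(trz$eta_out)), 0)
})

test_that("three-head fusion projects, aligns, and squashes", {
  net <- small_net(seed = 21)
  w3 <- net$cfg$ae_widths[3]; wb <- net$cfg$br_width
  g <- array(0, c(32, 32, w3, 1))
  e <- array(0, c(64, 64, w3, 1))
  bo <- array(0, c(32, 32, wb, 1))
  # zero inputs and zero classifier bias -> heads identically 0.5
  for (nm in c("head.t0.b", "head.t1.b", "head.t2.b"))
    set_network_param(net, nm, 0)
  # fusion projections carry BN in eval mode: zero input stays zero
  hd <- fuse_heads(net, g, e, bo, c(64, 64))
  expect_equal(dim(hd$t0), c(64, 64, 1, 1))
  expect_true(all(abs(hd$t0 - 0.5) < 1e-12))
  expect_true(all(abs(hd$t1 - 0.5) < 1e-12))
  expect_true(all(abs(hd$t2 - 0.5) < 1e-12))
})

test_that("every variant returns full-resolution probability heads", {
  for (v in c("resnet", "bnet", "resnet_wsa", "resnet_wae", "fsnet", "sgbnet")) {
    net <- sgbnet_network(v, base_width = 4, seed = 2)
    x <- matrix(runif(64 * 64), 64, 64)
    out <- network_forward(net, x)
    expect_equal(dim(out$t0)[1:2], c(64, 64), info = v)
    expect_true(all(out$t0 > 0 & out$t0 < 1), info = v)
    out2 <- network_forward(net, x)
    expect_identical(out$t0, out2$t0)   # deterministic forward
  }
  expect_error(sgbnet_network("nope"), "arg")
})

test_that("parameter census grows from backbone to full model", {
  n_res <- network_n_params(sgbnet_network("resnet", base_width = 8, seed = 1))
  n_fs <- network_n_params(sgbnet_network("fsnet", base_width = 8, seed = 1))
  n_full <- network_n_params(sgbnet_network("sgbnet", base_width = 8, seed = 1))
  expect_lt(n_res, n_fs)
  expect_lt(n_fs, n_full)
})

test_that("traces are exposed behind the return_traces flag", {
  net <- small_net(seed = 30)
  out <- network_forward(net, matrix(runif(64 * 64), 64, 64),
                         return_traces = TRUE)
  expect_named(out$traces, c("sa", "ae", "br"))
  expect_equal(out$traces$sa$eta,
               out$traces$sa$gamma1 + out$traces$sa$gamma3 + out$traces$sa$gamma5)
  expect_true(all(out$traces$ae[[2]]$gate > 0 & out$traces$ae[[2]]$gate < 1))
  expect_true(all(out$traces$br$r1$tau > 0 & out$traces$br$r1$tau < 1))
  out_no <- network_forward(net, matrix(runif(64 * 64), 64, 64))
  expect_null(out_no$traces)
})

test_that("checkpoint state round-trips through save and restore", {
  net <- small_net(seed = 41)
  st <- sgbnet:::network_state(net)
  expect_identical(st$schema, 1L)
  net2 <- sgbnet:::network_from_state(st)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(network_forward(net, x)$t0, network_forward(net2, x)$t0)
})
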