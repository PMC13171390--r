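# Shared desk-scale training protocol used by the learning-signal and
# ablation acceptance checks: 20 synthetic 256x256 training images, 5
# held-out test images, 2 epochs x 200 random 64x64 patches, batch 8,
# Adam lr 1e-3 with the dice+cross-entropy segmentation term (the
# short-schedule operating point; see the methods vignette). Computed once
# and cached so both checks score the same run.

.protocol_cache <- new.env(parent = emptyenv())

protocol_results <- function() {
  if (!is.null(.protocol_cache$res)) return(.protocol_cache$res)
  seed <- 42L
  set_global_seed(seed)
  sp <- synth_split(synth_params(), n_train = 20, n_test = 5, seed = seed)
  lc <- loss_config(seg_loss = "dice_bce")
  test_dice <- function(fit) {
    mean(vapply(sp$test, function(s) {
      pr <- predict(fit, s)
      vessel_metrics(pr, s$vessel_mask, s$fov_mask)$dice
    }, numeric(1)))
  }
  fits <- list()
  dices <- c()
  for (v in c("sgbnet", "resnet", "fsnet")) {
    fits[[v]] <- sgbnet(sp$train, variant = v, epochs = 2,
                        patches_per_epoch = 200, batch_size = 8, lr = 1e-3,
                        loss = lc, base_width = 16, seed = seed,
                        verbose = FALSE)
    dices[v] <- test_dice(fits[[v]])
  }
  untrained <- sgbnet(sp$train, variant = "sgbnet", epochs = 0,
                      base_width = 16, seed = seed, verbose = FALSE)
  dices["untrained"] <- test_dice(untrained)
  .protocol_cache$res <- list(dices = dices, seed = seed)
  .protocol_cache$res
}
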