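# sgbnet

Retinal vessel segmentation with a saliency-guided boundary-refinement
network, implemented entirely in R (compiled CPU kernels + a small
reverse-mode tape; no external deep-learning framework).

Fundus photographs pose three coupled difficulties for vessel segmentation:
vessels span calibers from wide arcades to near-pixel capillaries, their
boundaries sit in low-contrast, unevenly illuminated surroundings, and
lesions imitate vessel intensity. The model here attacks each with a
dedicated branch over one shared residual backbone:

* a **feature-guided network**: a scale-adaptive module aggregating the
  deepest features at three receptive-field scales with global-context
  fusion, followed by attention-enhanced decoder blocks that gate low-level
  side features with channel attention from pooled low/high descriptors;
* a **boundary network**: residual boundary refinement
  `R(β) = conv(σ(BN(conv(A(β))))) + A(β)` on each shallow side output,
  cascaded bottom-up across resolutions;
* a **fusion stage** emitting three sigmoid heads: the fused vessel map
  `t0`, the boundary map `t1`, and the feature-guided vessel map `t2`.

Training minimizes the compound objective

```
ℓ = ℓ_seg(t0) + η·ℓ_fl(t1) + ψ·ℓ_seg(t2),     η = 0.7, ψ = 0.3
```

with the focal loss `ℓ_fl = −α_t (1 − p_t)^γ log p_t` (λ_t = 0.25, γ = 2)
on the boundary head and a soft-Dice (optionally cross-entropy) term on the
vessel heads. The reference protocol is 10,000 random 64×64 patches per
epoch, Adam at 1e-4, batch 8, 50 epochs; inference tiles images into 96×96
patches at stride 32 and averages overlapping predictions.

The package also provides the standard fundus preprocessing chain
(grayscale → histogram equalization → gamma correction), dataset/manifest
readers, FOV-restricted evaluation (sensitivity, specificity, accuracy,
Dice/F1, IoU, rank-based AUC, PR curves), and a deterministic synthetic
fundus generator with paired vessel, boundary, and FOV masks, so the whole
pipeline is testable end-to-end without external data.

## Worked example

```r
library(sgbnet)
set_global_seed(7)

# synthetic train/test data (use read_dataset()/read_manifest() for real data)
sp <- synth_split(synth_params(), n_train = 20, n_test = 5, seed = 7)

# desk-scale training run of the full model
fit <- sgbnet(sp$train, variant = "sgbnet", epochs = 2,
              patches_per_epoch = 200, batch_size = 8, lr = 1e-3,
              loss = loss_config(seg_loss = "dice_bce"),
              base_width = 16, seed = 7, verbose = FALSE)
fit
#> Saliency-guided boundary-refinement segmentation fit
#>   variant:       sgbnet
#>   parameters:    880,963
#>   trained:       2 epoch(s) x 200 patches on 20 sample(s)
#>   final loss:    0.9300

pr <- predict(fit, sp$test[[1]])                      # probability map
vessel_metrics(pr, sp$test[[1]]$vessel_mask, sp$test[[1]]$fov_mask)
#> Segmentation metrics (47460 evaluated pixels, threshold 0.5)
#>   TP 2665  FP 391  TN 44029  FN 375
#>   sensitivity  0.8766
#>   specificity  0.9912
#>   accuracy     0.9839
#>   precision    0.8721
#>   dice         0.8743
#>   iou          0.7767
#>   auc_roc      0.9875
```

Interpretation: at threshold 0.5 inside the camera field of view, ~88% of
true vessel pixels are recovered (sensitivity) at 99% background
specificity; the Dice/F1 of 0.87 and AUC of 0.99 are what two epochs on
twenty small synthetic images buy — the numbers move with the training
budget and the generator's difficulty settings, not magic.

A command-line wrapper over the same functions lives at
`inst/cli/sgbnet.R` (`synth`, `train`, `predict`, `evaluate` subcommands).

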