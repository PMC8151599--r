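# squseg

Four-class brain-MRI tissue segmentation — background, cerebrospinal fluid
(CSF), gray matter (GM), white matter (WM) — with a **multi-scale squeeze
U-SegNet with global attention**, implemented end to end in R (the network
arithmetic runs through RcppArmadillo).  The package is aimed at
neuroimaging methods work: it provides the complete workflow — slice/patch
preprocessing, model building for four ablation variants with exact
parameter counting, CPU training, patch-wise prediction with lossless
reassembly, per-tissue evaluation metrics, and a seeded synthetic
brain-phantom generator — so the whole system is buildable and testable
without any clinical dataset.

## The model

An encoder–decoder network over 128×128 patches of T1-weighted slices:

- **Fire modules** replace every convolution block: squeeze
  `conv1×1 → F/4` channels with ReLU, then parallel expand
  `conv1×1` and `conv3×3` of `F/2` channels each, concatenated
  (`F_out = F_in`).  The squeeze keeps the filter count below the expand
  width, cutting parameters roughly six-fold versus a plain 3×3 block.
- **Multi-scale input fusion** `ms_l = concat[f(maxpool(x_{l−1}) * w^{1×1}),
  f(maxpool(x_{l−1}) * w^{3×3})]` carries neighbour-scale context at every
  encoder level.
- **Global attention (GAM)**: with gating map `g` and low-level map `x`,
  `α = ReLU(GAP(g) * W_g + b) ⊙ (x * W_x + b)` and the output is the
  residual `x_out = x + α`.  Each level has two GAMs — one fusing `ms_l`
  into the encoder trunk, one gating the decoder skip connection.
- **Pooling-index unpooling**: 2×2 max-pool argmax positions stored at each
  encoder level are reused by the decoder
  (`decoder(l) = Concat[GAM(x_l, x_{l−1}), Unpool(x_{l−1}, Poolidx)]`),
  so up-sampling is parameter-free.
- **Head**: 1×1 convolution to 4 logits, per-pixel softmax, mean-pixel
  cross-entropy loss `−Σ y_i log y′_i`; SGD with learning rate 0.001 and
  momentum 0.99.

Four variants are buildable from one config — `squeeze_usegnet` (neither
branch), `multiscale`, `multiattention`, and `full` — for the ablation
study of the parameter-efficiency claim.

## Worked example

```r
library(squseg)

# a seeded synthetic phantom in the 208 x 176 x 176 axial geometry
ph <- generate_phantom(phantom_spec(seed = 7))
ph$labels
#> <squseg_labels 208 x 176 x 176>
#> background        csf         gm         wm
#>    5399536     491160     370048     182264

# slice selection (48 from the 10th, stride 3), zero-pad to 256x256,
# split into four 128x128 patches: 192 training samples per scan
pp <- preprocess_volume(ph$volume, ph$labels)
length(pp$samples)   #> 192
pp$pad_spec          #> top 24, bottom 24, left 40, right 40

# the ablation/parameter report (the package's validation report)
ablation_report()
#>           variant parameters reference residual
#> 1 squeeze_usegnet     736564    768788   -32224
#> 2      multiscale     901012    860180    40832
#> 3  multiattention     931732    942164   -10432
#> 4            full    1098388   1030420    67968
```

The `parameters` column is counted from the actually-built models (every
convolution's `k²·C_in·C_out + C_out`, itemised by `model_summary()`); the
`reference` column lists the published counts for the four variants.  The
published depth and widths are given only graphically, and no coherent
width assignment we searched reproduces all four totals at once; the
default configuration (3 levels of widths 96/96/192, three fire modules
per level) is the closest assignment, with residuals shown and the
published ordering preserved.  See the methods vignette
(`vignettes/squseg-methods.Rmd`) for the search and the design decisions.

Training and evaluating on phantoms (this is the package's functional
smoke test, ~8 minutes on one CPU):

```r
cohort <- generate_cohort(4, phantom_spec(noise_sd = 2, bias_amplitude = 0.02,
                                          seed = 1),
                          jitter = list(geometry = 0.04, intensity = 0.03))
rc <- run_config(model = model_config("full"), epochs = 6, batch_size = 2,
                 steps_per_epoch = 30, seed = 11)
fit <- train(rc, cohort[1:3])
#> epoch 1/6  mean loss 0.88903  (30 steps)
#> ...
#> epoch 6/6  mean loss 0.02928  (30 steps)

pred <- predict_volume(fit$model, cohort[[4]]$volume)
truth <- label_stack(cohort[[4]]$labels, pred$slice_indices)
evaluate_segmentation(pred$labels, truth, hd = FALSE)
#>   class       dsc   jaccard
#> 1   csf 0.9791390 0.9591306
#> 2    gm 0.9710752 0.9437767
#> 3    wm 0.9805199 0.9617843
```

A Dice of 0.98 here means the network recovers 98% overlap with the true
tissue masks of a held-out phantom — evidence the mechanics work, not a
claim about clinical MRI.

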