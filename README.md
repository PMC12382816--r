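# morphoreg

Image-based estimation of fish biometrics — total length (cm) and body
weight (g) — with a lightweight convolutional regression network built and
trained natively in R. The package is aimed at quantitative
fisheries/aquaculture researchers who need non-contact growth monitoring
and at methods researchers studying **imbalanced regression**: cohorts are
dominated by mid-sized fish, and plain pointwise losses collapse
predictions toward the label mode, mis-sizing exactly the rare small and
large animals that matter most.

## The method

Three components address that failure mode:

**1. Adaptive contrastive regularization for imbalanced regression (AMCR).**
Each image yields two augmented views; on a batch of 2N views with
L2-normalized embeddings `z`, standardized labels `y` and predictions `ŷ`,
pairs are selected by Manhattan label distance against a threshold ω:
label-similar pairs are positives, and pairs with *dissimilar labels but
erroneously similar predictions* ("prediction collapse") are negatives.
Samples with a negative become anchors and contribute

    L_j = −log [ (1/N⁺_j) Σ_{i∈K⁺} exp(z_j·z_i/τ)
                 / ( Σ_{p∈K⁺} exp(z_j·z_p/τ) + Σ_{q∈K⁻} S_jq exp(z_j·z_q/τ) ) ]

with repulsion weights `S_jq = η_j · Dist(y_j,y_q)/ω`, where
`η_j = η₀ · d_j` and `d_j` is an inverse label-density weight from a 2-D
histogram of the training labels — minority-label anchors repel their
collapsed negatives hardest. The training objective is the hybrid
`L = L_R + β·L_AMCR`, `L_R` being the mean summed absolute error over both
targets.

**2. Efficient channel attention (ECA) regression head.** The
MobileNetV3-Small feature extractor (width 1.0, trained from scratch)
pools to a 576-d embedding, recalibrated by a sigmoid-gated 1-D
convolution across channels with the adaptive kernel
`k = |(log₂C + b)/γ|_odd` (γ=2, b=1 → k=5 at C=576), then mapped by a
single affine layer to the two targets. This head replaces the stock
1024-unit classifier: the whole model has **0.93 M** trainable parameters
and **0.12 GFLOPs** at 224×224 (1 MAC = 2 FLOPs), both reproduced exactly
by `model_summary()`.

**3. Dependency-graph structured pruning.** Layers are decomposed into
input/output nodes; inter-layer edges link producers to consumers and
intra-layer edges join channel-preserving ops (batch-norm, activations,
residual adds, depthwise convolutions, gating). Connected components are
indivisible dependency groups pruned as units. A short retraining with the
adaptive group-sparsity penalty `R = λ Σ_g Σ_k γ_k ·Σ_{w∈g}‖w_k‖²`,
`γ_k = 2^{α(I_max−I_k)/(I_max−I_min)}`, drives low-importance channels to
zero; one-shot global pruning then removes the lowest-importance indices
(head and embedding protected) and a small-learning-rate fine-tune
recovers accuracy. Pruning is **bit-exact**: the eval-mode forward
accumulates in channel order, and the tests assert `identical()` outputs
after removing zeroed groups.

Because comparable fish-image datasets are not openly deposited, the
package ships a seeded synthetic generator emulating the statistical
structure of such data: truncated-lognormal lengths on 17.5–34 cm
(mean 24.6, SD 2.6), allometric weights `w = a·l^b·e^ε` calibrated to
mean 419 g / SD 121 g (weight CV ≈ 2.8× length CV), three capture
scenarios (clear lateral, turbid lateral, top-down), and schematic fish
whose pixel geometry encodes length and condition factor monotonically.

## Worked example

```r
library(morphoreg)

# static accounting of the full architecture
s <- model_summary(build_model(architecture_spec("mnv3s-feat"), seed = 1))
glance(s)[, c("params_m", "gflops")]
#> # A tibble: 1 × 2
#>   params_m gflops
#>      <dbl>  <dbl>
#> 1     0.93   0.12

# synthetic benchmark -> train the tiny backbone with the hybrid loss
cfg <- synth_config(n_samples = 200, seed = 7)
man <- generate_dataset(cfg, "demo-data")
sp  <- stratified_split(man, seed = 1)
fit <- train_model(build_model(architecture_spec("tiny-cnn"), seed = 1),
                   man, sp,
                   train_config(epochs = 10, batch_size = 32,
                                loss = "l1+amcr", seed = 1),
                   amcr_config())
tail(tidy(fit)[, c("epoch", "loss_l1", "loss_amcr", "val_l1_std",
                   "collapse_rate")], 3)
#> # A tibble: 3 × 5
#>   epoch loss_l1 loss_amcr val_l1_std collapse_rate
#>   <int>   <dbl>     <dbl>      <dbl>         <dbl>
#> 1     8    1.52      4.54       1.76             1
#> 2     9    1.52      4.53       1.76             1
#> 3    10    1.51      4.50       1.76             1

idx <- sp$idx[sp$split == "test"]
compute_metrics(man[idx, c("length_cm", "weight_g")],
                predict(fit, man[idx, ]))
#> # A tibble: 2 × 7
#>   target unit    rmse    mae mape_percent      r2     n
#>   <chr>  <chr>  <dbl>  <dbl>        <dbl>   <dbl> <int>
#> 1 length cm    2.04   1.66           6.93 -0.0313    19
#> 2 weight kg    0.0891 0.0746        21.3  -0.0770    19
```

The loss columns show the two components of the hybrid objective; the
collapse rate is the fraction of dissimilar-label pairs whose predictions
are still within ω of each other. At this deliberately miniature scale
(200 images, 10 epochs) the model is still inside the collapse regime —
the rate sits at 1.0 and the test R² hovers around zero. The package's
own benchmark configuration at n = 600 and 30 epochs (the scale the
acceptance suite trains at) behaves very differently: one such run drove
the collapse rate from 1.00 to 0.36 and reached a test R² of 0.37 for
length and 0.44 for weight with the same tiny backbone.
`compute_metrics()` reports per-target RMSE/MAE/MAPE/R² in physical units
(weight in kg) after inverting the train-fitted label standardizer.

Pruning the trained model:

```r
pc     <- prune_config(global_ratio = 0.45, sparsity_epochs = 5,
                       finetune_epochs = 10)
sparse <- sparsify_train(fit$net, man, sp, pc, fit$train_config)
pruned <- execute_prune(sparse$net, find_groups(sparse$net), pc)
ft     <- finetune(pruned$net, man, sp, pc, fit$train_config)
model_summary(fit$net)$n_params     # 24597
model_summary(pruned$net)$n_params  # 12816 (-48%)
```

A thin CLI over the same functions lives at `inst/cli/morphoreg`
(subcommands `synth`, `split`, `train`, `eval`, `prune`, `finetune`,
`demo`).

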