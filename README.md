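# kidneyct

Contrast-adaptive classification of kidney CT slices in R: a learnable
dual-window intensity transform (ADWE), a multi-scale texture-prior branch
(MTPF), and a compact ConvNeXtV2-style backbone, trained end-to-end with
histogram-matching and maximum-mean-discrepancy constraints — plus a seeded
synthetic phantom generator, a full evaluation kit (accuracy / precision /
recall / F1 / AUC, noise-robustness sweeps, cluster indices, Grad-CAM), and
a YAML-configured command workflow.

## Who this is for

Researchers in medical image analysis who want a transparent, fully tested
reference implementation of adaptive windowing and texture-prior fusion:
every operator is a documented R function with an explicit backward pass,
and every numerical claim in the package is asserted against an
independent oracle in the test suite. No GPU, no Python, no external data:
the synthetic phantom generator reproduces the class-conditional intensity
and texture structure (hyperdense stone foci, homogeneous hypodense cysts,
heterogeneous irregular tumors) that the method is designed to exploit.

## The model

Windowing is a smooth, learnable mapping of normalized CT intensity
`x ∈ [0, 1]`:

    f(x; WL, WW) = ½ [ tanh( α (x − WL) / WW ) + 1 ]

Two windows run in parallel — `(WL₁, WW₁)` for parenchyma, `(WL₂, WW₂)`
for high-density structures — and a per-pixel sigmoid gate `Z` blends the
views: `X* = Z ⊙ X₁ + (1 − Z) ⊙ X₂`. Window parameters are clipped into
`[a, b] × [c, d]` after every optimiser step. Multi-scale convolutions
(`Σ_k W_k * X*`, k ∈ {3, 5, 7}) feed the backbone; a soft-histogram
constraint `‖H(X*) − λ₁H(X₁) − λ₂H(X₂)‖²` keeps the fused image
statistically faithful to both windows.

The texture branch stacks the Laplacian edge map (kernel centre 4,
four-neighbours −1), LBP codes (`Σ_k s(I_k − I_p) 2^k`, ties count as 1),
and eight even-symmetric Gabor responses; a 3×3 convolution + GELU
compresses the stack, channel attention fuses it with backbone stage-3
features (`F* = α ⊙ F + β ⊙ T'`), pyramid pooling (grids 1, 2, 4)
aggregates scales, and a squared RBF-MMD between prior statistics and `X*`
regularises the branch. Metrics follow the standard definitions; for K > 2
classes, macro averaging and one-vs-rest AUC; robustness tables report
`decline(σ) = AUC(σ) − AUC(0)`.

## A worked example

The converged desk-scale run below takes about 25 minutes on one CPU
core (a from-scratch model of this family needs a few hundred optimiser
steps before the phantom task's learning onset; see the methods
vignette). `smoke_train_config()` gives a five-epoch recipe for quick
pipeline checks.

```r
library(kidneyct)

# 300 seeded binary phantoms (normal vs stone), 64x64, split 7:1.5:1.5
ds <- generate_dataset(300, seed = 5, task = "binary")
table(ds$labels, ds$split)
#>          train val test
#>   normal   105  23   22
#>   stone    105  23   22

# the tiny test preset: depths [1,1,2,1], dim 24
model <- build_classifier(model_config(num_classes = 2, preset = "tiny"),
                          seed = 1)
model
#> <kct_model> 2 classes, depths [1,1,2,1], dim 24, input 64x64 (ADWE: on, MTPF: on)
#>   trainable parameters: 629,418

fit <- train_classifier(model, ds,
                        train_config(epochs = 25, batch_size = 8, lr = 1e-3,
                                     warmup_epochs = 1, seed = 11))
fit
#> <kct_fit> 25 epochs; best val accuracy 0.8913 at epoch 17

idx <- which(ds$split == "test")
report <- evaluate_model(model, ds$images[, , idx], ds$labels[idx])
report
#> <metrics_report> n=44 (binary averaging)
#>   ACC 0.8409  P 0.8571  R 0.8182  F1 0.8372  AUC 0.9029
tidy(report)     # per-class precision / recall / F1
autoplot(report) # confusion-matrix heatmap

# noise robustness with the decline statistic
sweep <- robustness_sweep(model, ds$images[, , idx], ds$labels[idx],
                          sigma_list = c(0, 0.01, 0.05, 0.1), seed = 1)
sweep
#>   sigma accuracy precision recall    f1   auc decline
#>   0       0.841     0.857  0.818 0.837 0.903  0
#>   0.01    0.818     0.85   0.773 0.810 0.893 -0.0103
#>   0.05    0.705     0.68   0.773 0.723 0.826 -0.0764
#>   0.1     0.727     0.75   0.682 0.714 0.742 -0.161

# the learned windows drift from their initialization
model_window_params(model)
#> <window_params> wl1=0.141 ww1=0.170 | wl2=0.615 ww2=0.320 | alpha=2.280

# where does the model look?
img <- ds$images[, , idx[1]]
plot_image(img, grad_cam(model, img))
```

`report` prints the five metrics of the evaluation kit: accuracy falls
and the AUC decline grows as noise corrupts the constructed contrast,
while the two learned windows settle over the soft-tissue and
high-density intensity ranges.

A YAML-driven command workflow (generate / train / evaluate) is available
through `cmd_generate()`, `cmd_train()` and `cmd_evaluate()`, or from a
shell via the thin wrapper installed at
`system.file("cli", "kidneyct.R", package = "kidneyct")`.

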