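# cxrreason

Anatomy-guided, interpretable multi-label classification of chest
radiographs at desk scale — with every stage, including the neural network
and its gradients, implemented in plain R so the whole pipeline is
inspectable, testable and reproducible on a single CPU.

## The problem

Deep models for chest X-ray reading are accurate but opaque: a probability
per finding, with no account of *where* the evidence sits or *why* the
finding was called. `cxrreason` implements an anatomy-guided pipeline that
couples a dual-path classifier to explicit anatomical knowledge:

1. **Synthetic phantoms with known truth.** A generator renders
   radiograph-like studies from elliptical thorax/lung/heart geometry,
   injects one additive intensity signature per pathology (14 classes, the
   standard thoracic-finding set from *Atelectasis* to *Pneumothorax*),
   and emits pixel-exact lung/heart/thorax masks and binary label vectors
   `y ∈ {0,1}^14`. Every downstream stage is testable without any external
   data.
2. **Preprocessing.** Contrast-limited adaptive histogram equalization
   (CLAHE: per-tile histograms clipped at β·μ, excess redistributed,
   CDF mapping `y = F(x)·(L−1)`, bilinear tile blending), then resize and
   ImageNet-style 3-channel standardization.
3. **Hybrid classifier.** A convolutional backbone of fused-MBConv and
   MBConv+SE stages (squeeze-and-excitation gates
   `s = σ(W₂ δ(W₁ GAP(X)))`) in parallel with a patch-token vision
   transformer (`Z₀ = [x_cls; x₁E; …; x_N E] + E_pos`, multi-head
   scaled-dot-product attention `softmax(QKᵀ/√d)V`). The class token and
   the globally pooled convolutional descriptor are concatenated
   (`F_fused = [F_cnn; F_vit]`) and passed through a three-layer MLP to 14
   sigmoid outputs `p_c = σ(z_c)`. An auxiliary decoder predicts lung and
   heart masks; training minimizes
   `L_total = L_classification + λ·L_segmentation` with a class-balanced
   focal loss (`FL(p_t) = −α_t (1−p_t)^γ log p_t`) or plain BCE, a soft
   Dice segmentation loss, and AdamW. Per-class decision thresholds τ_c
   are fitted on a validation split (`ŷ_c = 1 iff p_c ≥ τ_c`).
4. **Saliency.** Grad-CAM from the last backbone stage
   (`α_k = mean ∂y_c/∂A_k`, heatmap `ReLU(Σ_k α_k A_k)`), constrained to
   anatomy by elementwise mask multiplication, normalized to [0, 1], and
   summarized as per-region mean activation energies.
5. **Neuro-symbolic reporting.** Continuous cues — the cardiothoracic
   area ratio, basal activation, apical gradient strength, per-class
   region energies — become fuzzy memberships
   `μ(p_c) = 1/(1+e^{−β(Conf_c−τ_c)})`, are aggregated with reliability
   weights (`μ_final = Σ w_k μ_k / Σ w_k`), pass through Horn-clause rules
   (`IF S_i > τ_i AND A_region > η_i THEN D_j`), and the fired hypotheses
   are ranked by a sharpened softmax `P(D_i) = e^{αS_i}/Σ_j e^{αS_j}` into
   a templated JSON report whose every sentence is traceable to a rule and
   a region.

All gradients come from a small reverse-mode autodiff tape written in R;
finite differences are used only as independent test oracles.

Two model presets ship: `"paper"` (384 px input, the published geometry:
576 patches, 768-dim embedding, 16 heads of width 48, 1280-dim fusion)
used for architectural checks, and `"desk"` (128 px, 64-dim branches) that
trains in about two minutes on one CPU.

## Worked example

```r
library(cxrreason)

# 200 phantoms at the desk conditions, train 5 epochs, evaluate on 100
spec   <- phantom_spec(image_size = 128, prevalence = 0.15, seed = 11)
cohort <- generate_cohort(spec, 200)
fit    <- train_model(cohort, hybrid_config("desk"),
                      epochs = 5, batch_size = 4, lr = 5e-3, loss = "bce",
                      seed = 1)
glance(fit)
#>   preset n_params epochs best_epoch best_val_micro_auroc
#> 1 desk     168080      5          4                0.735

test <- generate_cohort(phantom_spec(128, prevalence = 0.15, seed = 777), 100)
ev   <- cxr_evaluate(fit, test)
dplyr::filter(ev$metrics, class %in% c("Cardiomegaly", "Effusion",
                                       "Pneumothorax", "macro"))
#>          class auroc accuracy    f1
#> 1 Cardiomegaly 1.000    0.980 0.929
#> 2     Effusion 0.795    0.760 0.429
#> 3 Pneumothorax 0.974    0.960 0.857
#> 4        macro 0.784    0.886 0.290

# calibrate the fuzzy layer on the validation split, then explain a study
rb <- calibrate_rulebase(cxr_rulebase(), fit, cohort[fit$val_idx])
st <- generate_phantom(phantom_spec(128, seed = 4242),
                       labels = as.integer(cxr_classes() == "Cardiomegaly"),
                       index = 2)
explain_study(fit, st, rb)$report
#> Diagnostic report (2 findings)
#>   Cardiomegaly         p = 0.649  [heart]
#>     Generalised increased activity through the cardiac silhouette with a
#>     raised cardiothoracic ratio (likely), compatible with cardiomegaly.
#>   Pneumonia            p = 0.351  [mid_lung]
#>     likely patchy parenchymal activity in the mid lung, compatible with
#>     pneumonia.
```

The per-class AUROC table reads as expected for a two-minute CPU run:
classes with fixed anatomical signatures (cardiomegaly, pneumothorax,
pleural thickening) are close to perfect; small random-location lesions
(nodule, mass) are hard at this training budget, which holds the macro
average near 0.8. The methods vignette
(`vignettes/anatomy-guided-reasoning.Rmd`) discusses this ceiling in
detail.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/exec/cxrreason generate --out cohort --n 200 --seed 1
Rscript inst/exec/cxrreason train    --data cohort --out run --epochs 5
Rscript inst/exec/cxrreason explain  --checkpoint run/checkpoint.rds --data cohort --study 1 --out run/expl
Rscript inst/exec/cxrreason evaluate --checkpoint run/checkpoint.rds --data cohort --out run/eval
```

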