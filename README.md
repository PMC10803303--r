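# mlnet3d

A fully automated, two-stage deep-learning pipeline for baseline rectal-cancer
MRI, implemented in R and exercised end-to-end on synthetic multi-centre
phantoms:

1. **Segmentation.** A miniature deep-supervised 3D U-Net delineates the
   tumour on the diffusion-weighted (DWI) channel (optionally DWI + T2W) and
   exposes its four decoder feature maps — stage 1 finest to stage 4
   coarsest — as a feature pyramid.
2. **Classification.** *MLNet*, a 3D ResNet10-style classifier whose identity
   shortcuts are removed, takes the original MRI as input and injects the
   segmentation feature pyramid by concatenation at the matching residual
   block. It classifies extramural vascular invasion (EMVI) status and
   predicts complete response (CR) to chemoradiotherapy. The plain ResNet10
   and single-stage (Stage *N*) variants form the ablation family, alongside
   a clinical logistic-regression baseline (age, sex, cT, cN).

Training uses class-weighted binary cross-entropy, Adam (batch 4, learning
rate 1e-4 at protocol scale) wrapped in sharpness-aware minimisation (SAM),
early stopping with patience 10, and best-internal-validation-loss
checkpointing. Evaluation follows the standard external-validation playbook:

- Dice = 2TP / (2TP + FP + FN) for segmentation;
- rank-based AUC, sensitivity, specificity, PPV, NPV and
  F1 = TP / (TP + (FP + FN)/2) for classification;
- the operating threshold maximises the Youden index J = sens + spec − 1 on
  the *internal* validation cohort and is transferred unchanged to the
  external cohort;
- 95% CIs by percentile bootstrap (10,000 case-level replications at
  protocol scale);
- Kruskal–Wallis tests for cohort characteristics, Mann–Whitney U tests for
  method comparisons;
- Grad-CAM++ attention maps for explainability.

Because the real multi-centre cohort (509 patients, 9 centres) is private,
the package ships a controllable phantom generator: two-channel 3D volumes
containing an ellipsoidal tumour whose EMVI-like label adds thin tubular
protrusions (a fine boundary feature) and whose CR-like label alters coarse
attributes (size and internal texture), with per-centre gain/bias/noise
shifts, NIfTI I/O, and Table-1-style cohort summaries.

## Worked example

```r
library(mlnet3d)

centres <- default_centre_profiles(9)
cohort  <- generate_cohort(60, centres, p_emvi = 0.60, p_cr = 0.28, seed = 11)
splits  <- centre_split(cohort, split_plan(paste0("C", 1:4),
                                           paste0("C", 5:6),
                                           paste0("C", 7:9)))

cfg <- unet_config(input_channels = 1)          # DWI arm, base 8 channels
fit <- train_segmenter(splits$train, cfg, epochs = 10,
                       val_cases = splits$internal, lr = 1e-3)
tail(fit$log$epochs, 3)
#    epoch train_loss  val_dice
# 8      8   1.123895 0.7918323
# 9      9   1.091002 0.7750851
# 10    10   1.058327 0.8207706
```

The deep-supervision loss falls steadily and internal-validation Dice climbs
past 0.8 within ten epochs on 28 training phantoms (the acceptance run, with
40 cases and 14 epochs, reaches ~0.97). Feature pyramids then feed the
classifiers:

```r
pyr <- setNames(lapply(cohort, function(cs) extract_features(fit$model, cs$image)),
                vapply(cohort, function(cs) cs$patient_id, ""))
abl <- run_ablation(splits, pyr,
                    classifier_config(input_channels = 1, learning_rate = 1e-3),
                    target = "emvi",
                    variants = c("plain_resnet10", "mlnet", "stage1", "stage4"))
op  <- youden_threshold(abl$mlnet$internal)
metric_report(abl$mlnet$external, op$threshold, n_boot = 1000, seed = 1)
```

On the 200-case acceptance cohort this prints an external AUC near chance for
the plain skip-less ResNet10 and a clear margin for MLNet, with Stage-1
injection ahead of Stage-4 — the fine-boundary EMVI signal is recovered from
the injected finest-stage features, not from the downsampled raw image.
Exact numbers for the shipped seeds are asserted in
`tests/testthat/test-acceptance.R`.

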