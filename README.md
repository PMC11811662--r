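# painpipe

Objective assessment of postoperative pain from wearable biosignals.
`painpipe` implements a complete multimodal pain-recognition pipeline:
electrocardiography (ECG) and five-channel facial electromyography (EMG)
from a 500 Hz biopotential device, plus electrodermal activity (EDA, 4 Hz)
and photoplethysmography (PPG, 64 Hz) from a wristband, are filtered,
windowed, and turned into handcrafted and autoencoder-learned features;
sparse self-reported pain scores (numerical rating scale, NRS 0–10) become
strong labels by time-threshold matching, optionally augmented by a
three-classifier weak-supervision label model and SMOTE minority
oversampling; binary classifiers with early or late modality fusion are
then evaluated subject-wise.

It is written for researchers in physiological computing and clinical
machine learning who need a tested, fully reproducible reference
implementation of this recognition stack — including a synthetic multimodal
cohort generator with known ground truth, because the motivating clinical
dataset is not public.

## The method in brief

* **Pain classes.** NRS is downsampled to baseline `BL` and three
  intensities: `PL1` (1–3), `PL2` (4–6), `PL3` (7–10). Binary tasks contrast
  `BL` against each `PLk`.
* **Handcrafted features per window (5.5 s or 10 s):** 19 time-domain heart
  rate variability features from detected R-peaks (RMSSD, SDSD, pNN20/50,
  NN statistics, HR statistics, NN slope); 14 amplitude/variability
  features per EMG channel (70 total); 12 EDA features on a cvxEDA-style
  decomposition — a sparse nonnegative sudomotor driver convolved with a
  Bateman impulse response, solved as a nonnegative lasso; 10 respiration
  features from the PPG via empirical mode decomposition of the
  beat-amplitude envelope.
* **Learned features:** convolutional and LSTM autoencoders (32 latents for
  ECG/EDA/RR, 6 per EMG channel; 126 across modalities), trained with Adam
  at batch size 10 for 100 epochs to minimize reconstruction MSE.
* **Evaluation:** random-forest Gini importance selects the top 25
  features; SVM, random forest, AdaBoost and k-NN classifiers are scored by
  leave-one-subject-out balanced accuracy, `(TPR + TNR) / 2`. All
  fitting — including weak labels, SMOTE and autoencoder training — happens
  strictly inside training folds.

See `vignettes/pain-recognition-methods.Rmd` for the full model
description, parameter defaults and design rationale.

## Worked example

Simulate a small cohort, extract respiration features, and evaluate
baseline versus severe pain with an SVM under leave-one-subject-out
cross-validation:

```r
library(painpipe)

sp <- cohort_spec(n_subjects = 6, duration_s = 300, activity_len_s = 50,
                  modalities = "ppg")
cohort <- generate_cohort(sp, seed = 42)
feats  <- cohort_features(cohort, window_len = 10)
ev <- loso_evaluate(feats$rr, task_spec("PL3", classifier = "svm"),
                    seed = 42)
ev
#> <pp_eval BL vs PL3 | svm | fusion=none>
#>   6 evaluable fold(s); balanced accuracy 0.843 (SD 0.191)
ev$per_fold[, c("subject_id", "TP", "FP", "TN", "FN", "balanced_accuracy")]
#>     subject_id TP FP TN FN balanced_accuracy
#> s01        s01  2  0 16  2         0.7500000
#> s02        s02  3  0 15  1         0.8750000
#> s03        s03  4  1 12  0         0.9615385
#> s04        s04  0  0 15  4         0.5000000
#> s05        s05  4  0 13  0         1.0000000
#> s06        s06  4  1 15  0         0.9687500
```

Each fold holds out one subject entirely; the confusion counts are over
that subject's strong-labeled windows (`PL3` positive), and the headline
number is the cross-fold mean balanced accuracy. Subject s04's 0.5 shows
what an uninformative fold looks like — every one of its pain windows was
missed — which is exactly the kind of inter-subject variability
leave-one-subject-out evaluation is meant to expose.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/painpipe.R simulate --out cohort/ --subjects 6 --seed 42
Rscript inst/cli/painpipe.R extract  --in cohort/ --out features/ --seed 42
Rscript inst/cli/painpipe.R evaluate --features features/ --task BL_vs_PL3 \
    --modality rr --report report.json --seed 42
```

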