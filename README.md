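# emglearn

Classification of lower-limb surface electromyography (sEMG) recordings
from healthy and knee-abnormal subjects, for researchers working on
gait-based screening of knee pathology. The package implements the full
processing chain — hybrid wavelet/EEMD denoising, windowed time-domain
features, SMOTE minority oversampling, and a leakage-safe stratified
cross-validation harness — plus a synthetic sEMG generator so the whole
pipeline is testable without external data.

## The method

Walking sEMG (4 muscle channels — RF, BF, VM, ST — at 1000 Hz,
hardware-bandpassed 20–460 Hz) is contaminated by broadband sensor noise,
50 Hz power-line interference and sub-5 Hz baseline wander, and the two
classes are imbalanced (~4.5 : 1 at the window level) because
knee-abnormal subjects walk slower, producing longer recordings.

1. **WD stage.** Level-4 `db7` wavelet decomposition; the D2 detail band
   is shrunk with the non-negative garrote
   (`ĉ = c − λ²/c` for `|c| > λ`, else 0) under the universal threshold
   `λ = σ√(2 ln N)`, σ estimated as MAD/0.6745 from the D2 band itself;
   reconstruction restores the signal length exactly.
2. **EEMD stage.** Ensemble empirical mode decomposition
   (`IMF_q = (1/T) Σ_n h_{q,n}` over T noise-perturbed sifting runs) of
   the WD output; the sum **IMF1 + IMF2 + IMF3** is the denoised signal
   (low-frequency contaminants stay in the discarded modes).
3. **Features.** A 256 ms sliding window (25% overlap) and nine
   time-domain statistics per window and channel — MAV, RMS, ZC, SSC,
   VAR, DASDV, AAC, skewness, kurtosis — giving a windows × 36 matrix
   (44 with the optional 11-feature bank).
4. **SMOTE.** Minority rows are interpolated toward their k = 5 nearest
   minority neighbours (`x + u·(nbr − x)`, one `u ~ U(0,1)` per synthetic
   row) until the classes balance.
5. **Evaluation.** Stratified 10-fold CV; SMOTE is applied to training
   rows only, *after* the split, so synthetic rows never reach a test
   fold. Reports carry per-fold and pooled metrics under both
   positive-class conventions, confusion matrices and ROC curves, for
   eight standard classifiers (entropy/Gini trees, bagging, gradient
   boosting, random forest, RBF SVM, MLP, extremely randomised trees).

## Worked example

```r
library(emglearn)

# synthetic study data: 2 subjects/class, abnormal recordings 4.48x longer
cfg  <- synth_config(duration_s = 3, duration_ratio = 4.48, n_subjects = 2, seed = 42)
recs <- gen_dataset(cfg)
recs[[1]]
#> <emg_recording> subject H01 (healthy): 3000 samples x 4 channels @ 1000 Hz (3.00 s)

# WD-EEMD denoising + windowed features (imbalanced: 138 vs 30 windows)
fm <- build_feature_matrix(recs, arm = "wd-eemd",
                           eemd_cfg = eemd_config(ensemble_size = 10, max_imfs = 5, seed = 7))
fm
#> <emg_features> 168 windows x 36 columns (abnormal: 138, healthy: 30)

run_experiment(fm, c("svm", "et"), cv_config(n_folds = 10, seed = 9))
#> <emg_eval_report> 168 rows (abnormal: 138, healthy: 30), 10-fold CV, SMOTE off, positive = healthy
#>   svm      acc  88.6  recall  46.7  precision  78.3  F  56.3  AUROC 0.902
#>   et       acc  91.1  recall  50.0  precision  90.0  F  62.0  AUROC 0.987

run_experiment(fm, c("svm", "et"),
               cv_config(n_folds = 10, seed = 9, apply_smote = TRUE,
                         smote_cfg = smote_config(seed = 10)))
#> <emg_eval_report> 168 rows (abnormal: 138, healthy: 30), 10-fold CV, SMOTE on, positive = healthy
#>   svm      acc  88.1  recall  60.0  precision  76.7  F  63.2  AUROC 0.909
#>   et       acc  96.4  recall  83.3  precision  97.5  F  88.6  AUROC 0.994
```

The pattern to read: without oversampling, accuracy looks strong because
the majority class dominates, but minority (healthy) recall is ~50% —
half the healthy windows are missed. With SMOTE confined to the training
folds, minority recall and F-score rise sharply (ET: F 62.0 → 88.6)
while overall accuracy does not degrade.

A thin command-line wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/emglearn", package = "emglearn"))')
Rscript $CLI synth --config cfg.yaml --out data/
Rscript $CLI run --data data/ --out report/ --arm wd-eemd --smote on --classifiers et
```

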