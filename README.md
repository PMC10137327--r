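# selectmri

Confidence-aware selective evaluation of MRI-based radiogenomic
classifiers, built around the question of whether multi-parametric brain
MRI carries usable information about MGMT promoter methylation in
glioblastoma.

## The problem

MGMT promoter methylation predicts the benefit of alkylating chemotherapy
and is measured invasively (pyrosequencing of biopsy tissue, a percentage
in [0, 100] binarised at 10%). Published attempts to predict the binary
status from MRI report wildly contradictory performance. Raw AUC on a whole
test set cannot settle the question: if the model were reliable on *some*
patients — say those far from the 10% decision frontier — a per-prediction
confidence score `c(x)` should isolate them. Writing `C_t = {x : c(x) > t}`
for the subset whose confidence strictly exceeds a threshold `t`, the curve

```
M : t ↦ m_t   (accuracy / AUC / average precision on C_t)
```

should be monotonically increasing for any trustworthy confidence metric.
If no metric produces an increasing curve, the apparent signal is noise.

`selectmri` implements this evaluation as a reusable, fully tested pipeline
that runs on synthetic cohorts with a *tunable* radiogenomic signal, so
both regimes are reproducible on a laptop:

* **synthetic cohorts** — multimodal 3D tumour phantoms (nested ellipsoid
  shells with BraTS mask labels 1/2/4, ring-enhancement contrast, Rician-like
  noise) whose appearance encodes the label with strength
  `signal_strength ∈ [0, 1]`; percentage structure calibrated to a
  98-patient private-style cohort (40 patients at exactly 0%, 58 drawn from
  a truncated-normal law on [8.4, 85.4] moment-matched to mean 41.3 /
  sd 21.04) and a 574-patient challenge-style cohort (300/274 binary
  labels);
* **preprocessing** — non-zero-voxel standardization
  `x ← (x − mean*) / sd*`, volumetric CLAHE, tumour-ROI extraction from the
  union of mask labels, mask sanity filtering, seeded augmentation;
* **models** — a small trainable 3D residual convolutional classifier
  (exact analytic gradients, CPU-friendly) with early, intermediate
  (multi-head attention + probabilistic modality docking) and late fusion;
* **confidence scores** — maximum softmax probability; ODIN-style
  temperature scaling with a signed-gradient input perturbation
  `x̃ = x − ε·sign(−∇x log S_ŷ(x;T))`; a jointly trained confidence branch
  (`p′ = c·p + (1−c)·y`, loss `−Σ y log p′ − λ log c`); an
  attribution-resilience score (integrated gradients → per-patch switch
  probabilities → prediction stability over S perturbed inputs); and the
  percentage surrogate metric

  ```
  c(κ; x) = x − κ              if x > κ
          = (κ − x)·exp(x/α)   otherwise        (κ = 10, α = 5.5)
  ```

* **selective evaluation** — percentile thresholds (0/25/50/70) on the
  confidence distribution, strict-exceedance subsets, rank AUC / average
  precision / accuracy per subset, ROC & PR curves, and report tables in
  which splits that ties make empty are shown as `"-"`.

## Worked example

Train the tiny classifier on a fully separable synthetic cohort (60
patients, FLAIR + T1wCE, early fusion) and evaluate selectively:

```r
library(selectmri)

cfg <- experiment_config(
  cohort = cohort_config(n_unmethylated_zero = 30, n_methylated = 30,
                         signal_strength = 1, volume_shape = c(24, 24, 12),
                         modalities = c("FLAIR", "T1wCE"), seed = 7),
  preprocess = preprocess_spec("roi", target_shape = c(16, 16, 8)),
  model = model_config("tiny", in_channels = 2, fusion = "early", seed = 7),
  train = list(epochs = 6, batch_size = 8, lr = 1e-3),
  metrics = c("msp", "oracle"),
  seed = 7)
res <- run_experiment(cfg)

round(c(val_auc = res$summary$val_auc, val_accuracy = res$summary$val_accuracy), 3)
#>      val_auc val_accuracy
#>            1            1

res$curves$msp[, c("percentile", "fraction_considered", "auc", "accuracy", "available")]
#>    percentile fraction_considered auc accuracy available
#> 0           0           100.00000   1        1      TRUE
#> 25         25            72.22222   1        1      TRUE
#> 50         50            50.00000  NA        1      TRUE
#> 70         70            33.33333  NA        1      TRUE
```

With full signal the model separates the validation set (AUC 1) and
accuracy never degrades as low-confidence samples are dropped; the `NA`
AUC rows are subsets that retain a single class (AUC is reported as
unavailable, accuracy is still defined). Setting `signal_strength = 0`
reproduces the opposite regime: chance-level AUC and flat curves for every
confidence metric — the package's mechanical account of why selective
evaluation cannot rescue a signal that is not there.

The surrogate metric maps percentages to distance-from-frontier
confidence:

```r
round(surrogate_confidence(c(0, 4.5, 10, 60)), 3)
#> [1] 10.000 12.465  0.000 50.000
```

A completely unmethylated patient (0%) scores 10, the decision frontier
scores 0, and the sub-threshold branch peaks at `κ − α = 4.5`. Because 40
of the 98 private-like patients share the identical percentage 0, their
confidence values tie, and strict exceedance makes some percentile
subgroups empty or irregular — the package surfaces this in the subgroup
composition report rather than hiding it.

A thin command-line wrapper is installed at `inst/cli/selectmri.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/selectmri.R", package="selectmri"))')" \
    run --preset private_like --signal-strength 1 --epochs 6 --seed 1 --out run1
```

## Package layout

| Module | Files |
| --- | --- |
| synthetic cohorts | `R/cohort.R` |
| preprocessing | `R/preprocess.R` |
| model & fusion | `R/net.R`, `R/fusion.R`, `R/train.R` |
| confidence metrics | `R/confidence.R` |
| selective evaluation | `R/selective.R` |
| orchestration / CLI | `R/experiment.R`, `inst/cli/selectmri.R` |

The methods vignette (`vignettes/selective-confidence.Rmd`) documents the
model assumptions, parameter defaults, numerical choices and the limits of
what synthetic phantoms can show about real MRI data.
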