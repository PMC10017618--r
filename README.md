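# cranioseg

Automatic segmentation of craniopharyngioma on coronal contrast-enhanced T1
(T1CE) MRI, in R.

Craniopharyngiomas are benign sellar/suprasellar tumors with highly variable
appearance: predominantly cystic, solid, or mixed. On T1CE the cyst wall
enhances brightly while the cyst fluid is darker than brain, and the internal
carotid arteries sit directly against the tumor as bright distractors that do
not belong in the outline. A classic U-Net segments the solid component and
the enhancing rim but misses the dark cyst interior — a false-negative-heavy
failure mode. `cranioseg` implements the two modifications that target it:

* a **U-Net with one non-local self-attention block at the bottleneck**
  (embedded Gaussian: for position *i*,
  `y_i = Σ_j softmax_j(θ(x_i)ᵀφ(x_j)) g(x_j)`, added residually through a
  zero-initialized projection), letting rim context label the enclosed dark
  interior across long ranges; and
* a **compound objective** `L = 0.5·L_Tversky + 0.5·L_CE` with Tversky
  weights `α = 0.1` (false positives) and `β = 0.9` (false negatives), i.e.
  `TI = (Σpg + s) / (Σpg + α·Σp(1−g) + β·Σ(1−p)g + s)` and
  `L_Tversky = 1 − TI`.

The package is a complete, tested pipeline: NIfTI/DICOM input and a CSV case
manifest; preprocessing (resize to 256×256, isotropic 1×1×1 mm resampling,
[0,1] normalization, slice-wise CLAHE) and per-epoch flip/±10° rotation
augmentation; training with Adam, case-level 8:2 splitting and a tuning set
for per-epoch checkpoint selection; per-case evaluation (DSC, Jaccard, TPR,
FPR, 95th-percentile Hausdorff distance in mm, volume in mL, processing
time); subgroup one-way ANOVA across radiological features, ICC(2,1) volume
agreement and Bland–Altman analysis; and a synthetic sellar-tumor phantom
generator (enhancing rim, dark cyst, bright solid, lobulated outlines,
vessel distractors) so everything runs without patient data. The network,
its backward pass, Adam, and the attention block are implemented in the
package itself (RcppArmadillo kernels + R orchestration) and verified
against finite-difference gradient checks and brute-force oracles.

## Worked example

Desk-scale end-to-end run on a 30-case synthetic cohort (a few minutes on
one CPU):

```r
library(cranioseg)

coh   <- generate_cohort(30, seed = 101, size = c(64, 64, 12),
                         lobe_radius_mm = c(3, 8))
cases <- preprocess_cases(coh$cases, preprocess_config(out_size = c(64, 64)))
sp    <- split_cases(coh$manifest$case_id, ratio = 0.8, tuning_n = 4, seed = 101)
pick  <- function(ids) cases[match(ids, coh$manifest$case_id)]

res <- train_unet(pick(sp$train), pick(sp$tuning),
                  desk_profile(epochs = 30, seed = 101), verbose = TRUE)
#> epoch   9  loss 0.3103 (tversky 0.6042, ce 0.0164)  tuning DSC 0.8904
#> ...
#> epoch  30  loss 0.0350 (tversky 0.0635, ce 0.0065)  tuning DSC 0.8599

ev <- evaluate_dataset(res$net, pick(sp$test))
ev$summary
#>            metric        mean        ci_lo       ci_hi n
#> 1             dsc 0.872940691 0.7846454356 0.961235945 6
#> 2         jaccard 0.782151635 0.6534253348 0.910877936 6
#> 3             tpr 0.970962360 0.9402076660 1.001717054 6
#> 4             fpr 0.001160043 0.0005679978 0.001752089 6
#> 5         hd95_mm 1.360379610 0.4339943306 2.286764889 6
```

Reading: on the six held-out phantom cases the trained non-local U-Net
overlaps the ground truth at mean DSC 0.87 (a DSC of 1 is a perfect match),
finds 97% of tumor voxels (TPR), almost never labels background as tumor
(FPR ≈ 1e−3 of all non-tumor voxels), and its surfaces stay within
1.4 mm at the 95th percentile (95HD). Per-case rows, including predicted
and reference volumes in mL and per-case prediction time, are in
`ev$records`; subgroup statistics come from `subgroup_grid(ev$records,
coh$manifest)` and volume agreement from
`icc_agreement(ev$records$gt_volume_ml, ev$records$pred_volume_ml)`.

A thin CLI wraps the same functions
(`exec/cranioseg synth | preprocess | train | predict | evaluate | stats |
compare`, each `--help`-free but documented in the script header), reading
YAML/JSON configs whose sections mirror `preprocess_config()`,
`augment_config()`, `loss_config()`, `network_config()`, `train_config()`.

## Layout

* `R/`, `src/` — package code; `src/kernels.cpp` holds the conv/pool/
  up-conv/instance-norm forward+backward and surface-distance kernels.
* `tests/testthat/` — unit, property and end-to-end tests.
* `vignettes/cranioseg-methods.Rmd` — the methods notes: model, loss,
  phantom design, metric conventions, numerical choices, limitations.
* `exec/cranioseg` — command-line interface.
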