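# mtsanet

Joint gross-tumor-volume (GTV) segmentation and EGFR genotype
classification for brain-metastasis MRI slices, as one multi-task network
in native R.

## The problem

Lung adenocarcinoma frequently metastasizes to the brain. Two questions
drive treatment planning from a contrast-enhanced MR exam: *where is the
tumor* (the GTV contour used in stereotactic radiosurgery planning) and
*what is the EGFR mutation status* (which decides whether targeted therapy
is an option when a biopsy is impractical). These are usually attacked with
separate single-task models; `mtsanet` implements a multi-task network in
which both heads share one encoder, so the segmentation objective steers
the classifier's attention toward the lesion — the region that actually
carries the genotype signal.

## The model

- **Shared encoder** — five resolution levels of multi-scale attention
  (MSA) blocks. An MSA layer builds an attention map from a local 3×3
  convolution plus three strip-convolution branches (k×1 followed by 1×k
  depth-wise kernels, k = 5, 7, 11) applied to a shared depth-wise
  convolution, mixes them with a 1×1 convolution, and reweights its input:

  ```
  Att = Conv1x1( Conv3x3(F) + Σ_i Branch_i(DWConv(F)) ),   Out = Att ⊗ F
  ```

- **Classifier head** — the deepest feature map (side input/16) is split
  into `patch_grid²` patches, each flattened into a token sequence and run
  through a shared transformer block (multi-head scaled dot-product
  attention, `softmax(QKᵀ/√d)V`, plus a feed-forward MLP); the processed
  map is average-pooled, flattened and mapped to softmax probabilities
  (wild, mutant).

- **Decoder head** — four up-blocks (stride-2 transposed convolution, skip
  concatenation, 3×3 conv + batch-norm + ReLU) back to full resolution,
  then a 1×1 convolution and sigmoid giving a foreground probability map.

- **Multi-task loss** — segmentation uses Dice plus a pixel-summed focal
  loss scaled by β = 1/25 000 (α = 0.8, γ = 2); classification uses
  cross-entropy; the two are combined with homoscedastic uncertainty
  weighting,

  ```
  L = L_GTV/(2σ²_GTV) + L_EGFR/(2σ²_EGFR) + log(σ_GTV σ_EGFR)
  ```

  with both σ learned jointly with the weights (initialized at 1), or with
  fixed 0.5/0.5 weights as an ablation.

- **Patient-level call** — per-slice mutation probabilities are aggregated
  by ranking slices on predicted lesion area, averaging the top half, and
  calling mutant when the mean strictly exceeds 0.5.

All forward passes, the hand-derived backpropagation, and the Adam
optimizer (lr 3e-4, patience-20 early stopping on validation loss) are
implemented in R with compiled convolution kernels under `src/`.

Because clinical MRI cohorts are private, the package ships a seeded
phantom generator (`phantom_params()`, `generate_cohort()`): elliptical
"brain" slices with bright disk lesions and exact masks, in which mutant
lesions differ only *inside* the lesion (a bright rim with darker core by
default). This reproduces the premise the method is built on — the
genotype signal lives in the segmented region — and makes the whole
pipeline runnable and testable offline.

## Worked example

```r
library(mtsanet)

cohort <- generate_cohort(100, phantom_params(), seed = 0)
test_set <- cohort[81:100]
sp <- split_cohort(cohort[1:80], n_val = 20, seed = 0)

cfg <- mtsa_config(input_size = 96L,
                   stage_channels = c(8L, 16L, 32L, 64L, 64L),
                   patch_grid = 2L, pool_kernel = 3L, mlp_hidden = 32L,
                   batch_size = 16L, seed = 0L)
model <- mtsa_fit(sp$train, sp$val, cfg, epochs = 14, verbose = TRUE)
evaluate_cohort(model, test_set)
```

On this phantom study (desk scale: 96×96 slices, ~330 training slices,
14 epochs, one CPU, about 8 minutes) the run above prints:

```
Segmentation (slice level):
  Dice 0.9027   HD95 3.64 mm   precision 0.8884   recall 0.9349
EGFR genotyping (patient level):
  accuracy 1.0000   precision 1.0000   recall 1.0000   F1 1.0000
  20 patients
```

i.e. the network recovers the lesion mask (Dice ≈ 0.90; the mean
95th-percentile Hausdorff distance between predicted and true boundaries
is a few mm) and the genotype of every held-out patient. `coef(model)`
returns the learned task uncertainties; `plot(model)` draws the loss and
σ trajectories; `predict(model, patient)` gives per-slice probability maps
plus the aggregated patient call.

A command-line wrapper with `simulate`, `train`, `predict` and `evaluate`
subcommands is installed at `inst/cli/mtsanet.R`:

```sh
Rscript inst/cli/mtsanet.R simulate --n 20 --seed 0 --out data/
Rscript inst/cli/mtsanet.R train --manifest data/manifest.yaml --out run/ --seed 0
```

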