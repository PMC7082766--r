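# multidelin

Voxel-wise multimodal MRI delineation of brain tumors, evaluated against
histology-derived gold standards.

Independent observers delineating a brain metastasis on single-modality
post-gadolinium T1-weighted MRI systematically under-draw it: metastases
carry an invasive rim that does not enhance, and the missed rim is a
plausible driver of local relapse after therapy. This package implements a
simple, automated alternative — classify every voxel against a
contralateral normal reference across six MRI parameter maps and call it
tumor when two or more parameters are abnormal — together with the full
apparatus needed to evaluate such a rule: histology-derived gold-standard
tumor maps, vessel morphometry, voxel-wise metrics, and
modality-importance analyses. It is aimed at preclinical imaging groups
who want a tested reference implementation of the analysis pipeline, with
synthetic phantoms standing in for the (undeposited) study data.

## The rule

For each modality $m$, compute mean $\mu_m$ and sample SD $\sigma_m$ over
one pooled contralateral region (brain beyond the midline on the
tumor-free side, ventricles excluded). A voxel is **abnormal** on a
channel when it is strictly beyond $\mu_m \pm k\sigma_m$ ($k = 1$) in the
channel's direction:

| channel | direction |
|---|---|
| post-Gd T1w intensity | above |
| baseline T1 time | above |
| baseline T2 time | below |
| cerebral blood volume | below |
| cerebral blood flow | below |
| ADC | above **or** below (two exclusive channels) |

A voxel is **tumor** when ≥ 2 of the 7 channels are abnormal. For a fixed
pair of independent channels the chance a normal Gaussian voxel co-fires
is $\Phi(-1)^2 \approx 0.025$, keeping the pairwise false-positive rate
under 0.05. Delineations are scored against a histological gold standard
(voxel tumor iff > 0.001 % EpCAM or > 1 % pimonidazole staining) by
sensitivity, specificity, accuracy, Jaccard index, and Youden index
$Y = \text{sens} + \text{spec} − 1$; channel importance comes from
systematic ablation and from accuracy gains across channel addition
orders.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
phantom (seed 17): `01` simulates it, `02` computes reference statistics,
`03` delineates with every method, `04` builds the histology gold
standard, `05` evaluates, `06` runs the importance and occult-rim
analyses, `07` summarizes rim histology and vessels. Tables land in
`results/`. For example:

```sh
Rscript analysis/05_evaluate.R
```

prints

```
Evaluable voxels: 2986 (746 uL)
     method sensitivity specificity accuracy jaccard youden volume_ul
 multimodal       0.878       0.777    0.817   0.654  0.655       359
        sd2       0.465       0.973    0.773   0.447  0.439       149
    refined       0.849       0.946    0.908   0.784  0.795       274
  consensus       0.494       1.000    0.800   0.494  0.494       146
 gold_volume_ul
            294
```

Reading: the observer consensus and the plain 2-SD threshold are highly
specific but find only half of the histologically confirmed tumor
(146–149 uL of 294 uL — the enhancing core without the invasive rim).
The multimodal rule recovers 88 % of the tumor including the rim at a
modest specificity cost, the best Youden index of the automated
whole-extent methods, and a volume (359 uL in-grid) tracking the gold
standard. In equivalent R:

```r
library(multidelin)
spec <- phantom_spec(seed = 17)
ph <- generate_phantom(spec)
contra <- build_contralateral_mask(ph$masks$brain, spec$midline, "left",
                                   ph$masks$ventricle)
stats <- compute_reference_stats(ph$volumes, contra)
mm <- multimodal_combine(build_channel_set(ph$volumes, stats, k = 1), 2)
gold <- gold_standard_map(stack_to_volume(ph$stacks$epcam),
                          stack_to_volume(ph$stacks$pimonidazole))
valid <- binary_mask(gold$valid$values & ph$masks$brain$values, ph$geometry)
report(confusion(mm, gold, valid), ph$geometry)
```

## Package layout

- `R/` — implementation: geometry/volumes/IO, contralateral reference,
  abnormality channels and delineation methods, histology fraction
  volumes and gold standard, vessel morphometry, evaluation and
  importance analyses, phantom generator.
- `analysis/` — the numbered study scripts (thin drivers over the package).
- `vignettes/multimodal-delineation.Rmd` — model, phantom design, and the
  reasoning behind every open design choice.
- `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles.
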