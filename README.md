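# idseg

Segmentation of the bilateral hippocampus and amygdala in infant
T2-weighted brain MRI, with multi-rater consensus, transfer learning, and a
brain–behavior morphometry stage — implemented as a complete, desk-scale R
framework for methods researchers who want to study, extend, or validate
the pipeline without GPUs or restricted clinical data.

## What it implements

**Multi-view segmentation model.** Three identical 2D fully-convolutional
networks (dense blocks of two 5×5 convolutions with concatenated inputs and
a 1×1 compression; batch norm and a shared PReLU slope per block; four
index-preserving 2×2 pool stages; an unpooling decoder with skip
concatenation) are trained on axial, coronal and sagittal slices. Per-voxel
probabilities are fused by a weighted argmax

    L(x) = argmax_c [ λ₁ p_axial(x,c) + λ₂ p_coronal(x,c) + λ₃ p_sagittal(x,c) ],

with λ = (0.4, 0.4, 0.2). At the default configuration (64 base channels,
88 output classes) each view network has exactly 3,520,871 trainable
parameters, 10,562,613 for the three-view model. Inputs must have
dimensions divisible by 16; `conform_size()` crops empty borders
symmetrically or pads, with an invertible record.

**Transfer learning.** `pretrain()` (seeded 80/20 subject split, best
validation checkpoint) then `finetune()`: 5 epochs with only the classifier
and final decoder block unfrozen, then 15 epochs of the whole network at
learning rate 5·10⁻⁴, batch size 8. `loocv()` runs leave-one-out
cross-validation with a no-pretraining ablation arm. The forward/backward
pass is implemented in the package (compiled im2col kernels + BLAS) and
checked against finite differences.

**STAPLE consensus.** `staple_binary()` is the expectation–maximization
estimator of a consensus mask and per-rater sensitivity/specificity;
`consensus_multilabel()` applies it per structure; `interrater_qc()`
enforces a minimum mean pairwise Dice (default 0.6) per structure.

**Evaluation.** Dice overlap, ICC(3,1) on voxel pairs in a region of
interest, and symmetric average surface distance in mm, plus per-structure
one-way ANOVA comparison of methods with Benjamini–Hochberg adjustment.

**Brain–behavior stage.** Total-brain-volume-adjusted structure volumes,
Spearman rank partial correlation with covariate adjustment
(postmenstrual age, maternal education, EPDS), and a structure × outcome
correlation matrix with significance flags.

**Phantom world.** `generate_phantom()` builds brain-shaped volumes with
curved, banana-like hippocampi (torus segments) and adjacent low-contrast
amygdalae; `simulate_raters()` emulates human tracers with calibrated
boundary noise; `generate_cohort()` draws behavior cohorts from a Gaussian
copula with a known embedded volume–behavior partial correlation. Every
downstream stage is testable against these generators' ground truth.

## Worked example

```r
library(idseg)

ph <- generate_phantom(phantom_spec(seed = 1))
raters <- simulate_raters(ph$labels, k = 3, rater_noise_spec(seed = 101))
interrater_qc(raters, threshold = 0.6)
#>           structure code mean_pairwise_dsc n_pairs pass
#> 1  left_hippocampus    1         0.7712213       3 TRUE
#> 2 right_hippocampus    2         0.7607401       3 TRUE
#> 3     left_amygdala    3         0.7610591       3 TRUE
#> 4    right_amygdala    4         0.7821322       3 TRUE

consensus <- consensus_multilabel(raters)
evaluate_pair(consensus, ph$labels)
#>           structure code       dsc       icc    asd_mm note
#> 1  left_hippocampus    1 0.9440000 0.9419797 0.1147240
#> 2 right_hippocampus    2 0.9215686 0.9189905 0.1632861
#> 3     left_amygdala    3 0.9542857 0.9526502 0.1208762
#> 4    right_amygdala    4 0.9257143 0.9231829 0.1965878
```

The three simulated raters agree with each other at a mean pairwise Dice of
about 0.76 per structure (the calibrated human-level default), yet the
STAPLE consensus recovers the true labels at Dice 0.92–0.95 with sub-voxel
surface error — the point of multi-rater fusion.

```r
co <- generate_cohort(n = 200, seed = 7)   # embeds a right-amygdala signal
bb <- brain_behavior_matrix(co$table)
subset(bb, measure == "adj_right_amygdala",
       select = c(measure, outcome, rho, df, p, significant))
#>               measure            outcome        rho  df            p significant
#> 4  adj_right_amygdala         cbcl_total -0.5288561 195 1.366925e-15        TRUE
#> 8  adj_right_amygdala cbcl_internalizing -0.3901205 195 1.453963e-08        TRUE
#> 12 adj_right_amygdala cbcl_externalizing -0.5952317 195 2.855611e-20        TRUE
```

Each row is a Spearman rank partial correlation between an adjusted
structure volume and an outcome T score, given the three covariates; the
generator embedded negative right-amygdala associations and the pipeline
recovers them.

A thin command-line wrapper ships in `inst/cli/idseg`
(`phantom`, `conform`, `staple`, `segment`, `evaluate`, `correlate`).

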