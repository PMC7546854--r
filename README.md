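# ablamark

Quantitative assessment of the **ablative margin (AM)** after image-guided
thermal ablation of liver tumours, built on unsupervised deformable image
registration.

After microwave or radiofrequency ablation, the shortest distance from the
tumour boundary to the ablation-zone boundary — the minimal AM — is the main
predictor of local tumour progression (LTP); ≥ 5 mm is the conventional
safety target. Measuring it requires aligning the pre-ablation image (tumour
visible) with the post-ablation image (ablation zone visible) despite
breathing motion and heat-induced tissue deformation. `ablamark` is aimed at
imaging-methods researchers who want a fully reproducible, synthetic-data
testbed for this pipeline.

## What is inside

**Registration.** A Siamese spatial transformer: a control-lattice
displacement field (cubic Keys interpolation), the differentiable
tent-kernel sampler

```
V_i = Σ_n Σ_m U_nm · max(0, 1 − |x_i − m|) · max(0, 1 − |y_i − n|)
```

(border-zero, 2D slice-wise or trilinear 3D), and a block-wise similarity
loss on deep multiscale features

```
LOSS = − Σ_{i=1..N}  ⟨F_w,i , F_a,i⟩ / sqrt(⟨F_w,i,F_w,i⟩·⟨F_a,i,F_a,i⟩)
```

where each image is partitioned into N regions and each region is encoded by
a fixed, seeded random convolution/ReLU/max-pool stack (global mean per
level, concatenated). The loss plus a bending-energy penalty is
backpropagated through features, sampler and lattice; descent with momentum
(preceded by a global NCC translation fit) yields the field.

**Margin.** The tumour mask is warped into the post-ablation frame; signed
surface distances (exact spacing-aware Euclidean distance transform,
positive inside the ablation zone) give the minimal AM, floored at 0, with
group A (≤ 5 mm) / group B (> 5 mm) classification and theoretical 5-mm
contours by ball dilation.

**Synthetic ground truth.** `makePhantomPair()` generates pre/post pairs
(liver-like ellipsoid, vessel-like tubes, tumour, ablation zone) deformed by
a known breathing + heating field with vessel landmarks; `makeCohort()`
generates survival cohorts from an exponential proportional-hazards model
with known hazard ratios.

**Statistics.** Kaplan–Meier / log-rank / forward-stepwise Cox (via
`survival`, Efron ties), DeLong comparison of correlated ROC AUCs,
Mann–Whitney / χ² / Fisher utilities, and cross-tabulation summaries for
comparing two margin-assessment methods.

## Worked example

```r
library(ablamark)

ph  <- makePhantomPair(phantomSpec(seed = 7))   # 64×128×128 @ 5×1×1 mm
cfg <- registrationConfig(maxIters = 8L, tolerance = 1e-6, seed = 7)
rr  <- registerPair(ph$moving, ph$fixed, cfg)
rr
#> RegistrationResult: 8 iterations, budget exhausted
#>   loss -31.98204 (identity -31.96891)

landmarkError(resultField(rr), ph$landmarks, voxelSpacing(ph$moving))$meanMM
#> 0.31   # mm, down from 5.28 mm before registration

res <- marginSufficiency(ph$tumor, ph$ablation, resultField(rr))
res$margin
#> MarginResult: min margin 5.00 mm, group A (threshold 5 mm), tumour covered
res$achieved
#> FALSE
```

The phantom's 6-mm breathing field misaligns the pair by 5.28 mm at the
vessel landmarks; registration brings this to 0.31 mm while the similarity
loss drops below its identity-field value. The warped tumour is fully inside
the ablation zone with a minimal margin of 5.00 mm — at the inclusive
group-A boundary, so the 5-mm *safe* margin is not achieved.

A thin CLI over the same functions lives at `inst/cli/ablamark.R`
(subcommands `register`, `margin`, `run`, `simulate-pair`,
`simulate-cohort`, `cohort-stats`).

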