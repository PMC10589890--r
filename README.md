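# mcmrf — multi-component MR fingerprinting analysis

`mcmrf` quantifies diffuse white-matter change from transient-state
MRF-EPI brain data by multi-component relaxometry. It is aimed at
quantitative-MRI methodologists and neuroimaging researchers who want a
tested, self-contained implementation of the full analysis chain:

1. **Signal simulation & dictionaries** — spoiled gradient-echo
   transient-state model with variable flip angle / TE / TR and global
   inversion pulses; per-slice dictionaries over a geometric
   (T1, T2*) x arithmetic B1 grid (the published acquisition grid —
   T1 30–4000 ms and T2* 5–3000 ms in 5% steps, B1 0.65–1.35 step 0.05,
   T1 >= T2* — has exactly 131,580 entries), with SVD compression.
2. **MP-PCA denoising** — Marchenko–Pastur random-matrix denoising of the
   4D magnitude series, per slice, across timeframes, in sliding
   15 x 15-voxel patches.
3. **Single-component matching** — maximum absolute normalized inner
   product, yielding T1, T2*, flip-angle-efficiency and M0 maps and the
   brain mask (largest connected component of relative M0 > 5%).
4. **Joint-sparse multi-component decomposition** — a SPIJN-style
   iteratively reweighted non-negative least-squares solver that finds a
   small *global* set of (T1, T2*) components and per-voxel magnetization
   fractions:

   c_j = argmin_{c >= 0} ||D_j c − x_j||² + λ Σ_i c_i² / (r_i² + ε²),

   with row norms r_i reweighted across iterations (an l0-like log
   row-norm surrogate), λ-continuation, and deterministic local support
   polishing. λ = 11 on the normalized scale by default.
5. **Component analysis** — k-means clustering of log relaxation times,
   long-T2* component selection (500 < T1 < 2500 ms and
   500 < T2* < 2500 ms), white-matter masking, normalized regional
   fraction volumes, and lesion-overlap scoring at the 15% threshold.
6. **Cohort statistics** — Gaussian-identity GLM of volume ~ group + age
   + sex (control = 0 / patient = 1, so positive coefficients mean larger
   volumes in patients), site-corrected partial Spearman correlation
   against severity scores, paired t-test of MC-MRF vs lesion-map
   volumes, and single-predictor secondary regressions.
7. **Synthetic data** — digital multi-tissue brain phantoms
   (myelin-water, white-matter, gray-matter, long-T2* and CSF components,
   lesions, a periventricular/perilesional rim with an exactly solved
   target volume, a smooth B1 field, Rician noise) and synthetic
   two-group cohorts matching the published group statistics, all with
   known ground truth.

The methods vignette (`vignettes/mcmrf-methods.Rmd`) documents the models,
the algorithmic design decisions and what the phantom validation does and
does not show.

## Worked example

End-to-end run on a digital brain phantom (64 x 64 x 4 voxels of
1 x 1 x 2 mm, 50 frames, 10% dictionary steps), noiseless:

```r
library(mcmrf)

grid <- phantom_grid()                       # 10% steps, 2311 (T1,T2*) pairs
pl <- run_phantom_pipeline(
  spec  = phantom_spec(grid = grid),         # patient phantom, target 0.0088
  train = default_train(50),
  grid  = grid)
pl
#> MC-MRF phantom pipeline run
#>   ground-truth WM long-T2* volume: 0.0088
#>   recovered  WM long-T2* volume: 0.0080
#>   components: 7, SPIJN iterations: 16
```

The phantom's white matter truly contains a long-T2* fraction volume of
0.0088 (the patient-level group mean); the full pipeline — acquisition
simulation, MP-PCA denoising, matching, the joint solve with the *matched*
B1 map, long-T2* selection and white-matter volumetry — recovers 0.0080,
i.e. within the package's validated 0.002 absolute tolerance. The
component table lists the recovered global (T1, T2*) pairs; white matter
(T1 970 ms), cortical and deep gray matter, CSF and the long-T2* component
appear as distinct entries, while the myelin-water component is the one
piece the matched-B1 pipeline blurs (see the vignette's limitations
section).

Cohort-level statistics on a synthetic cohort:

```r
tab <- make_cohort(cohort_spec(seed = 1))
glm_group(tab)[c("b", "ci95", "p")]
#> $b
#> [1] 0.005777661
#> $ci95
#> [1] 0.000933176 0.010622146
#> $p
#> [1] 0.0230126
```

The cohort's generative group difference is 0.0058 (patient mean 0.0088
minus control mean 0.0030); the age- and sex-adjusted coefficient and its
significance land in the range the published adjusted analyses report for
this marker.

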