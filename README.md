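# cestfit

Multi-pool Lorentzian quantification of CEST MRI Z-spectra in R.

Chemical exchange saturation transfer (CEST) imaging detects dilute
exchangeable protons — amide protons of mobile proteins at +3.5 ppm,
fast-exchanging amine protons near +2.0 ppm, the relayed nuclear
Overhauser effect at −3.5 ppm — as frequency-dependent losses of water
signal. The normalized Z-spectrum `Z(Δω) = Ssat(Δω)/S0` is decomposed
into five Lorentzian pools,

    Z(Δω) = c − L_DS − L_MT − L_amide − L_amine − L_NOE,
    L_x(Δω) = A_x (Γ_x²/4) / (Γ_x²/4 + (Δω − δ_x)²),

via the staged procedure used in quantitative glioma CEST studies:
subpixel motion correction and multilinear-SVD denoising, a two-pool
(water + semisolid MT) background fit on background-only offsets whose
water position doubles as a B0 map, voxelwise B0 correction, the
Lorentzian-difference spectrum `MTR_LD = Z_fit,ref − Z`, and a
three-pool fit of its amide/amine/NOE peaks — followed by a joint
five-pool refinement that removes the residual bias of the staged pass
(see the methods vignette, `vignettes/cest-quantification.Rmd`).
Downstream it computes MTR asymmetry (`MTR_3.5`, and the amine-weighted,
pH-sensitive contrast at 3.0 ppm), ROI histogram features, and the
group-analysis workflow used for grading/genotyping studies:
normality-adaptive two-sample tests, VIF/tolerance collinearity
screening, combined logistic models, ROC with DeLong intervals and
Youden cutoffs, and inter-observer ICC.

The package is aimed at CEST methods researchers and analysts who need
a reproducible, fully testable implementation: a synthetic phantom and
cohort generator with exact ground truth (`generate_phantom()`,
`generate_cohort()`) makes every stage verifiable without scanner data.

## Worked example

Simulate a phantom, run the full pipeline, and summarize the tumor ROI:

```r
library(cestfit)

res <- run_pipeline(
  list(seed = 42,
       phantom = list(grid_shape = c(20, 20), noise_sd = 0.005),
       metrics = list(roi = "tumor")),
  out_dir = "demo_run")

print(res$maps)
#> <metric_maps> 20 x 20, 220 voxels fitted, convergence 100.0%, 0 failed

subset(res$features, metric %in% c("ds", "mt", "amide", "mtr35", "ph_weighted"))
#>       metric     mean   median      p10      p90 n_voxels
#>           ds  0.82820  0.83166  0.75667  0.88619       22
#>           mt  0.13455  0.13706  0.11040  0.15360       22
#>        amide  0.05400  0.05206  0.04733  0.05965       22
#>        mtr35  0.00250  0.00157 -0.00875  0.01087       22
#>  ph_weighted -0.00953 -0.00999 -0.01688 -0.00422       22
```

The five maps are the fitted pool amplitudes in Z units: the tumor here
shows DS ≈ 0.83 (water content), MT ≈ 0.13 (semisolid pool), and
amide ≈ 0.054 — the ranges typical of 3 T tumor tissue, and exactly the
values planted by the generator (the truth maps live in
`generate_phantom()`'s output). `mtr35` is the conventional asymmetry at
3.5 ppm and `ph_weighted` the amine-weighted asymmetry at 3.0 ppm, both
small signed numbers in Z units. `demo_run/` receives the NIfTI maps, a
B0 map, `features.csv`, and a `results.json` with seed/config/hash
provenance.

A group analysis on features runs the same way it would on real
subjects:

```r
r <- roc_analysis(c(rnorm(20), rnorm(20, 2)),
                  rep(c("a", "b"), each = 20), positive = "b")
print(r)
#> AUC 0.95 (0.88-1.00), cutoff 0.7695, sens 90.00% (18/20), spec 90.00% (18/20)
```

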