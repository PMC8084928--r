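# cardiofat3d

Quantifying fibro-fatty myocardial remodeling — the structural substrate
of arrhythmias such as arrhythmogenic right ventricular cardiomyopathy
(ARVC) — from high-resolution 3D MRI of fixed ex vivo hearts.
`cardiofat3d` turns multi-coil, multi-echo gradient-echo volumes and
magnetization-transfer (MT) volume pairs into:

* **water/fat images and a B0 field map** via a per-voxel iterative
  least-squares decomposition (IDEAL-type, three echoes) inside a
  coarse-to-fine hierarchical field-map search that avoids fat-water
  swaps,
* **proton-density fat-fraction (PDFF) maps**, after correcting the
  steady-state amplitudes for T1 saturation and T2\* decay,
  `M_x = X (1 - cos a E1x) / (sin a (1 - E1x)) exp(+TE_ref/T2*_x)`,
  `PDFF = 100 M_f / (M_w + M_f)`,
* **data-driven fat thresholds** from a 4-component Gaussian mixture
  fitted to the 1000-bin PDFF histogram (the water-only threshold `T_C`
  is the 99.99% point of the water component, `mu_w + 3.71902 s_w`,
  snapped up to a bin edge; the Dixon threshold `T_D` is 50%),
* **MTR maps** (`100 MT_on / MT_off`) on the PDFF grid after zero-fill
  k-space upsampling — a fibrosis-sensitive contrast, and
* **regional fat/tissue volumes** in anatomical boxes (the "ARVC
  triangle": RVOT, RV free wall, RV apex septum) plus PDFF-over-MTR
  composites separating fat from fibrosis-like high-MTR tissue.

T1 maps (saturation recovery, `S = k S0 (1 - exp(-TR/T1))`) and T2\*
maps (multi-gradient-echo, `S = k S0 exp(-TE/T2*)`) are fitted per voxel
to supply the correction's species constants.

Because raw specimen data of this kind are not publicly available, the
package ships a **digital heart phantom** (epicardial fat rim,
myocardium, fibro-fatty patches, zero-signal background, smooth field
map and coil sensitivities, seeded noise) that simulates every
acquisition the pipeline consumes, with full ground truth.

## Worked example

```r
library(cardiofat3d)
res <- run_pipeline(pipeline_config(seed = 1, thresholds = "fixed",
                                    fixed_threshold = 40),
                    out_dir = "cf3d_out")
res$report
#>         region total_cm3 fat_cm3 tissue_cm3 fat_voxels fat_ratio_pct
#> 1 whole_volume   0.09094 0.05638    0.03457       7047         61.99
#>   threshold_pct voxel_mm3
#> 1            40     0.008
```

The default configuration simulates a noise-free 32-voxel-cube phantom
at 200 um isotropic resolution, runs coil combination, the hierarchical
water-fat solve, slice relaxometry, the PDFF correction, MT processing
and quantification, and writes all NIfTI/JSON/CSV artifacts to
`cf3d_out/`. In this run the fitted ROI relaxation constants are
T1 = 241.9/156.3 ms and T2\* = 19.67/15.38 ms (tissue/fat — the
fat-fraction-weighted blends of the configured species values), the
PDFF map deviates from the ground-truth fat fraction by at most 0.19
percentage points, and the reported whole-volume fat ratio (61.99% of
masked voxels above the 40% threshold) matches the phantom truth
exactly. Reruns with the same seed produce byte-identical reports.

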