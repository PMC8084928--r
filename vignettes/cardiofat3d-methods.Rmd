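---
title: "Water-fat separation and transfer-ratio mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-fat separation and transfer-ratio mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofat3d)
```

`cardiofat3d` post-processes high-resolution 3D gradient-echo MRI of
fixed ex vivo hearts into quantitative maps of fat content and
macromolecular (collagen-sensitive) contrast. The pipeline has six
stages: coil combination, water-fat-field-map decomposition, T1/T2*
relaxometry, proton-density fat-fraction (PDFF) mapping with
histogram-derived thresholds, magnetization-transfer-ratio (MTR)
mapping, and regional quantification. A digital heart phantom with full
ground truth drives all testing.

## Signal model

A spoiled gradient echo at echo time $t_n$, repetition time $TR$ and
flip angle $\alpha$ from a voxel holding water and fat proton densities
$W_0$, $F_0$ gives, per coil $c$ with sensitivity $C_c$,

$$ s_{c,n} = C_c\,\bigl(A_w(t_n) + A_f(t_n)\,
   e^{i 2\pi f_F t_n}\bigr)\, e^{i 2\pi \psi t_n} + \varepsilon, $$

with steady-state amplitudes

$$ A_x(t) = X_0 \sin\alpha\,\frac{1 - E_{1x}}{1 - \cos\alpha\,E_{1x}}
   \, e^{-t/T_{2x}^*}, \qquad E_{1x} = e^{-TR/T_{1x}}, $$

$f_F$ the water-fat chemical-shift offset (default $-1361$ Hz, $-3.4$
ppm at a 400.2 MHz proton frequency; a single-peak fat model), $\psi$
the B0 field offset in Hz, and $\varepsilon$ complex Gaussian noise per
channel. The phantom simulates exactly this model, so every downstream
estimate has a closed-form ground truth.

## Coil combination

Magnitude is the root sum of squares over coils. For phase the package
implements two rules:

* `"sum"` — the per-voxel *sum of the coil phases*, wrapped. This is
  the combination described for the protocol the package reproduces.
  For a single coil it is exact. For $n$ coils it multiplies the
  echo-to-echo signal phase by $n$, which is inconsistent with the
  water-fat model; it is retained verbatim as the default of
  `combine_coils()` for fidelity and single-coil use.
* `"reference"` — each coil is first referenced to its own first echo
  (`arg(sum_c s_{c,n} e^{-i\,\arg s_{c,1}})`), which cancels static coil
  phases exactly for any coil count. `run_pipeline()` selects this mode
  automatically whenever more than one coil is present.

Relative phases are then referenced to the shortest echo; the solver
works on effective echo times $\tau_n = t_n - t_1$ with *complex*
species amplitudes, because the echo-1 reference phase is
unrecoverable and must be absorbed by them. Reported water/fat maps are
the amplitude magnitudes.

## Water-fat decomposition

For fixed $\psi$ the model is linear in the two complex amplitudes;
$\psi$ is the only nonlinear parameter. `solve_voxel()` alternates the
linear solve with a Gauss-Newton update of $\psi$ on the
variable-projection residual, with step halving so the residual never
increases; convergence is declared when the update falls below `tol_hz`
(default 0.1 Hz, at most 30 iterations). With three echoes the field
map aliases with period $1/\Delta\tau$; estimates are reported in the
principal interval $[-1/2\Delta\tau, +1/2\Delta\tau)$.

The classic degeneracy of the problem is the fat-water swap: a pure
species at $\psi$ fits equally well as the other species at
$\psi - f_F$. For mixed voxels the swap is only an approximate second
minimum — but echo-train $T_2^*$ decay, which the three-point
constant-amplitude model cannot represent, can make the *global*
residual minimum land on the swapped branch in fat-dominant voxels.
This is why the decomposition is anchored hierarchically rather than
voxel-by-voxel:

1. complex block-averaging builds a dyadic pyramid down to a coarsest
   grid (default 4 voxels);
2. at the coarsest level a global grid search over one aliasing period
   (10 Hz steps, ties resolved toward 0 Hz) seeds Gauss-Newton — a few
   dozen coarse voxels make the scan cheap and deterministic;
3. at each finer level the coarse field map is median-filtered (radius
   1) and trilinearly upsampled to initialize the per-voxel solves.

On fat-sparse anatomy the hierarchy anchors on the true branch; on a
uniformly fat slab it picks one branch *consistently*, so the field map
stays spatially smooth and the swap is a global relabeling rather than
salt-and-pepper corruption. `brute_force_oracle()` provides an
independent global check: a dense $\psi$ grid with a derivative-free 1D
polish, used in the tests against the iterative solver.

## Relaxometry

Saturation recovery, $S(TR) = kS_0(1 - e^{-TR/T_1})$, and multi-echo
decay, $S(TE) = kS_0 e^{-TE/T_2^*}$, are fitted voxel-wise by
Levenberg-Marquardt. Initialization: $kS_0$ from the signal maximum;
$T_1$ from the first half-maximum $TR$ divided by $\ln 2$; $T_2^*$ from
a log-linear regression on the positive signals. Voxels below the
signal floor (3x the background SD, the same constant as the tissue
mask), constant series, and non-converging fits are flagged invalid
rather than zeroed. Magnitude (Rician) noise bias is not corrected, so
$T_2^*$ is slightly overestimated at low SNR. Species values for the
PDFF correction are ROI means over tissue and pericardial fat; with the
phantom's mono-exponential voxel blend (fat-fraction-weighted rate
mixing) a mixed-compartment ROI returns the blended constant, which is
what the correction actually needs.

## PDFF mapping and thresholds

The relaxation correction inverts the steady-state factor and the decay
at the reference echo,

$$ M_x = X\,\frac{1-\cos\alpha\,E_{1x}}{\sin\alpha\,(1-E_{1x})}\,
   e^{+TE_{\mathrm{ref}}/T^*_{2x}}, $$

with $TE_{\mathrm{ref}}$ = the first echo time (3.08 ms): after phase
referencing the solver amplitudes are amplitudes *at echo 1*, so that
is the decay the correction must undo. Then
$\mathrm{PDFF} = 100\,M_f/(M_w+M_f)$, clipped inputs logged, zero
denominators mapped to 0.

The tissue mask thresholds the root sum of squares of the echo
magnitudes. The classical rule is "3x the noise SD", and that is the
default (`mu = 0`); but a sum-of-squares magnitude image has a
chi-distributed background whose mean exceeds a few multiples of its
SD, so for combined images the threshold must be referenced to the
background level — the pipeline passes the noise-ROI mean as `mu` and
thresholds at `mu + 3 sigma`. The interactive cleanup of the original
protocol is replaced by a deterministic refinement (morphological
closing, largest 26-connected component) plus an optional user-edit
mask, all logged.

Masked PDFF values are pooled into a 1000-bin histogram on [0, 100] and
fitted with a 4-component Gaussian mixture by weighted EM on the bin
centers (max 500 steps, absolute log-likelihood tolerance 1e-8;
components collapsing under one bin width are pruned and the fit
restarted with one fewer). Initialization: water at the histogram mode,
fat at the second-highest local maximum at least 10 points away, and —
a deliberate design choice — the two residual components spread *evenly
between* the water and fat means. Initializing the spares at mixture
percentiles places them inside the dominant water peak, and EM then
splits that peak across three equal-likelihood components, destroying
the water estimate the threshold depends on; between-peaks spares
absorb partial-volume fat fractions (the 40-70% range where fibro-fatty
infiltration lives) and leave the water peak intact. Even so, with
truly two-component data a spare retains a percent-level weight on the
water shoulder, biasing the fitted water mean downward by up to about
0.1 — an intrinsic property of maximum likelihood with surplus
components, not a convergence failure.

The water-only threshold is the 99.99% point of the fitted water
Gaussian, $T_C = \mu_w + 3.71902\,\sigma_w$, snapped *up* to the next
histogram bin edge; the Dixon threshold $T_D$ is fixed at 50%. A voxel
exactly at a threshold counts as water/tissue. On noise-free phantoms
the histogram degenerates to spikes and the mixture fit is not
meaningful; the pipeline then falls back to (or is configured with) the
fixed or Dixon threshold.

## MTR mapping

MT on/off pairs are acquired at half the spatial resolution and
interpolated by zero-filling the centered k-space (the Nyquist bin of
even-length axes is split evenly so real inputs stay real; constants
and original-lattice samples are preserved exactly). The ratio
$\mathrm{MTR} = 100\,MT_{on}/MT_{off}$ is computed where $MT_{off}$
exceeds a noise floor (default 3x the background SD of $MT_{off}$);
other voxels are marked invalid, and values above 100% are retained.
The MT preparation is simulated at the ratio level, not via
Bloch-McConnell exchange: the pipeline consumes only the ratio.

## Quantification

Voxels are tagged fat (`PDFF > T`) or tissue within the mask; anatomical
boxes are specified in mm from the volume origin and converted to
half-open voxel ranges (floor/ceiling). Volumes are voxel counts times
the voxel volume, so fat + tissue = total exactly, and the fat ratio
uses the masked voxels in the box as denominator (the "volume of
tissue"). Composites overlay PDFF (at the working threshold, default
40%) on the MTR base with a three-way label: fat, high-MTR-without-fat
(candidate fibrosis, default cut 70%), other.

## What the phantom does and does not emulate

The phantom provides concentric-ellipsoid anatomy (epicardial fat rim
at 90% fat, myocardium at 5%, fibro-fatty patches at 45/55/70% — within
the 40-70% range reported for infiltrations and off the 40/50%
thresholds so classification tests are well-posed), a zero-signal
background, smooth polynomial field maps, smooth complex coil
sensitivities, additive complex Gaussian noise, ratio-level MT
contrast, and mono-exponential relaxometry. Default relaxation times
(T1 250/150 ms, T2* 20/15 ms for water/fat) are plausible for fixed,
gadolinium-doped tissue and are configurable inputs, not measured
values. Test problem sizes are 16-32 voxels per axis at 0.2 mm — scaled
phantoms that exercise every code path with meaningful hierarchy depth.

Passing phantom tests therefore demonstrates correctness of the
*processing*, not robustness to everything real data contains: no
multi-peak fat spectrum, no susceptibility artefacts (e.g. trapped air
bubbles), no motion or ghosting, no undersampling artefacts, no
spatially varying flip angle, and Rician noise only insofar as it
arises from magnitude operations on Gaussian channels.

## Numerical conventions

* Phases wrap to $(-\pi, \pi]$; field maps to $[-1/2\Delta\tau,
  +1/2\Delta\tau)$ Hz.
* All-zero voxels: W = F = 0, field map kept at its initialization,
  residual 0.
* `PDFF` with zero denominator is 0; outside the mask it is `NA`.
* Boundary conventions: `PDFF == threshold` is tissue; box voxel ranges
  are half-open.
* Determinism: every stochastic stage is seeded; a pipeline rerun with
  the same configuration produces a byte-identical CSV report.

## Known limitations

Single-peak fat model; no joint $T_2^*$ (R2*-aware) decomposition, so
echo-train decay leaks into a small PDFF bias (a fraction of a
percentage point at these echo spacings) and can re-label uniformly
fatty volumes as a whole; phase-sum coil combination is only meaningful
for single-coil data; relaxometry fits are per-voxel R loops, adequate
for slices and ROIs rather than full 3D volumes at native resolution;
the GMM water component carries the surplus-component bias described
above.
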