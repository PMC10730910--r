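---
title: "From sagittal power profiles to through-focus visual quality"
author: "segwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sagittal power profiles to through-focus visual quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segwave)
```

## The problem

Refractive multifocal corrections — multifocal contact lenses, multifocal
intraocular lenses, small-aperture designs — place different optical powers
in different annular regions of the pupil. Optical metrology instruments
based on phase-shifting Schlieren deflectometry report such lenses as a
*sagittal (axial) power profile*: the local power, in diopters, as a
function of the radial pupil coordinate, typically sampled at 28 points per
millimetre. Those profiles cannot be turned into a single Zernike expansion:
adjacent zones can carry radically different powers, and a smooth global
polynomial fit destroys exactly the structure that makes the lens
multifocal.

`segwave` closes the gap between the metrology output and a visual-quality
prediction. It converts a sagittal power profile into a *segmented
multifocal wavefront*, superposes measured ocular higher-order aberrations,
and scores the combined optics through focus with a neural-CSF-weighted
visual Strehl ratio, producing the simulated analogue of a clinical defocus
curve without a prototype lens or an optical bench.

## The model

### Pupil segmentation

The aperture of radius $R$ is divided into $n$ annuli of equal radial
width. For zone $l \in \{0, \dots, n-1\}$ a masking function
$\sigma_l(\rho)$ is 1 on $[R\,l/n,\; R\,(l+1)/n)$ (the outermost zone is
closed at $R$) and 0 elsewhere. Each zone receives the monofocal defocus
wavefront $w_l$ of its zone power $D_l$, evaluated over the *full* aperture
and then masked:

$$W_\mathrm{CL} = \sum_{l=0}^{n-1} w_l(D_l)\,\sigma_l .$$

Because zone membership is computed once per pixel
($\min(\lfloor \rho n / R \rfloor, n-1)$), the masks are pairwise disjoint
and cover the pupil exactly — spatial overlap or gaps cannot occur, and the
$n = 1$ case degenerates to a plain monofocal wavefront, pixel for pixel.
No piston matching is applied between zones: the optical-path steps at zone
boundaries are part of the model. Zone powers come from the profile as the
mean of the samples inside each annulus, falling back to linear
interpolation at the annulus midpoint when an annulus contains no sample
(this happens when the computation aperture is much smaller than the
measured radius). By default $n$ equals the number of profile samples inside
the aperture, mirroring the instrument's sampling.

### Eye aberrations and the effective aperture

Per-eye wavefronts are OSA/ANSI-indexed Zernike coefficient sets (orders 2–5
plus sixth-order spherical aberration) defined over the eye's measured
pupil. The combined wavefront is a superposition in the pupil plane,

$$W_T = W_\mathrm{CL} + W_\mathrm{Eye},$$

computed over the effective aperture
$R = \min(\text{pupil radius}, \text{measured lens radius})$. The eye map is
synthesized over the eye's own measurement pupil and *spatially cropped* to
$R$; coefficients are never algebraically rescaled to a smaller pupil. The
two interpretations differ only in bookkeeping, but cropping matches the
spatial-superposition picture of the segmentation itself and keeps the
coefficients interpretable over the pupil they were measured on.

### From wavefront to VSOTF

The generalized pupil is
$P(x,y) = A(x,y)\exp\!\left(i\,2\pi\,\mathrm{OPD}(x,y)/\lambda\right)$ with
uniform amplitude. The PSF is $|\mathcal{F}(P)|^2$ and the OTF its
normalized (inverse) transform — equivalently the normalized
autocorrelation of the pupil. The metric is the visual Strehl ratio in the
frequency domain,

$$\mathrm{VSOTF} =
\frac{\iint \mathrm{CSF}\,\lvert\mathrm{Re}\,\mathrm{OTF}\rvert\, \mathrm{d}f}
     {\iint \mathrm{CSF}\;\mathrm{OTF}_\mathrm{DL}\,\mathrm{d}f},$$

integrated over the spatial-frequency disk up to 60 cyc/deg (decimal acuity
2.0). The numerator uses the absolute value of the real part of the OTF, as
the metric is defined in the visual-optics literature; the denominator uses
the diffraction-limited OTF of the same aperture, computed through the
identical FFT path so that perfect optics score exactly 1. The integral is
evaluated as a Cartesian quadrature on the OTF grid applied identically to
numerator and denominator, so the area element cancels; a polar Jacobian
weighting would change both integrals by the same factor and therefore the
ratio not at all only if applied to both — we apply neither.

The neural CSF weights frequencies by the sensitivity of the post-optical
visual pathway (as measured interferometrically, bypassing the eye's
optics). Its exact published form is not pinned down numerically anywhere,
so `segwave` uses a truncated log-parabola: a Gaussian in $\log_2 f$ around
a peak at 4 cyc/deg with an SD of 1.4 octaves, floored at 80 % of peak below
the peak (the neural pathway loses little low-frequency sensitivity). All
four parameters are exposed in `csf_params()` and frozen as defaults; the
overall gain cancels in the ratio, which the tests verify. Absolute VSOTF
values therefore depend smoothly on this choice, but ratios and rankings
between lenses — the quantities the package reports — are robust to it.

### Through focus

A through-focus curve evaluates $W_T$ plus an added defocus term over a
vergence grid. The default grid is 193 samples spanning $-1.00$ to
$+5.00$ D (step $6/192 = 0.03125$ D), which guarantees that 0.00 D is
sampled exactly.

**Sign convention.** The axis is *defocus demand*: positive vergences are
near demands (an object at vergence $-d$), so a lens zone carrying a $+A$ D
addition peaks near $d = +A$, as in clinical defocus curves. Concretely the
sweep adds the defocus coefficient of power $(s - d)$ at the aperture, where
$s$ is the equivalent-sphere shift. An eye whose defocus coefficient equals
`defocus_coeff_from_diopters(ES, r)` peaks at $d = ES$ and
`equivalent_sphere_shift()` recovers $-ES$.

Eyes are "refracted" in software the way the clinic refracts them: the
monofocal reference lens is swept through focus, the vergence of its VSOTF
maximum defines the eye's equivalent-sphere shift, and that shift is applied
as extra defocus — a true optical re-evaluation, not a curve translation —
uniformly to every lens evaluated on the same eye.

### Comparison metrics

Three metrics summarize a curve: the **area under the curve** (the literal
sum of the 193 VSOTF samples; a step-weighted variant in diopters is
attached as metadata), the **range above threshold** (count of samples
strictly above 0.12, each weighted $6/193$ D — 0.12 corresponds to logMAR
0.20 acuity), and the **peak performance** (maximum VSOTF and its vergence,
ties broken toward the smallest absolute vergence). Note the deliberate
inconsistency inherited from the metric's definition: the grid spacing is
$6/192$ D while the per-sample weight is $6/193$ D; both constants are
implemented literally rather than "fixed", and the ~0.5 % discrepancy is
documented here instead. Metrics are reported raw and normalized as
percentages of the monofocal reference (mean over mean when aggregating
across eyes).

## Numerical choices

* **Grid.** Default 512 × 512 with the pupil spanning a quarter of the grid
  side (`pupil_fill = 0.25`): four-fold zero padding gives a clean PSF/OTF
  and frequency headroom well past 60 cyc/deg at ocular pupil sizes. Fills
  above 0.5 are rejected because the pupil autocorrelation would wrap
  around. The frequency step in cyc/deg follows from the pupil pitch:
  $\Delta f = (\Delta x / \lambda)(\pi/180)$.
* **Wavelength.** 555 nm (photopic peak), configurable.
* **Pixel membership.** A pixel belongs to the pupil iff its centre lies at
  $\rho \le R$; annuli are half-open with interior boundaries belonging to
  the outer zone. This removes double counting exactly rather than to
  tolerance.
* **Compiled sweep.** Through-focus sweeps run in C++ (RcppArmadillo). The
  FFT stages are pruned: the pupil occupies a centred sub-block, so the
  first column pass transforms only its non-zero columns, and the CSF
  weight vanishes beyond the cutoff, so the inverse pass produces only the
  low-frequency OTF rows. The compiled path is verified against the plain-R
  `vsotf()` to 1e-12 and both against a direct $O(N^4)$ autocorrelation
  oracle in the test suite.
* **Problem sizes.** The full synthetic study (36 multifocal profiles × 65
  eyes plus the monofocal references, 193 vergences each) runs at the
  reduced 128 × 128 resolution of the `fast` profile, about nine minutes on
  one CPU; single-lens evaluations and all normalization examples use the
  full 512 × 512 grid. The 512-vs-256 grid difference in VSOTF is below
  0.01 for the synthetic test lenses (tested).

## What the synthetic generator emulates — and what it does not

The lens measurements and the 65-eye aberration database this methodology
was developed on are not public, so `segwave` ships a generator that stands
in for both. Lens profiles follow five morphologies (monofocal,
centre-near, centre-distance, aspheric, concentric bifocal) with additions
0.75–3.00 D over a 5 mm radius at 28 points/mm, raised-cosine zone
transitions, three base prescriptions (−6, −3, +1 D) and optional Gaussian
measurement noise (0.05 D SD by default, the order of profile-to-profile
repeatability of Schlieren metrology). Eye populations draw pupil diameters
uniformly on 2.45–6.27 mm and independent Gaussian Zernike coefficients
with order-decaying scales (0.12, 0.07, 0.035, 0.015, 0.008 µm for orders
2–6) and a +0.05 µm mean fourth-order spherical aberration — realistic
orders of magnitude for healthy adult eyes.

What passing tests on these data do **not** show: real populations have
correlated coefficients (e.g. defocus–SA coupling with age), non-uniform
pupil distributions, and instrument-specific profile artefacts; commercial
lens families differ in ways the five templates do not span. The generator
validates the *machinery* — segmentation exactness, metric arithmetic,
shift recovery, the peak-performance cost of splitting the pupil — not the
clinical numbers of any specific lens. Note in particular that on strongly
aberrated eyes the monofocal reference already has an extended depth of
focus and a low peak, so a high addition need not enlarge the range above
threshold the way it does on a lightly aberrated eye (compare the
aberration-free worked example in the README, where the centre-near design
extends the range to ~131 % of the monofocal).

## Known limitations

* Radial symmetry of the lens is assumed; angular segmentation (e.g. toric
  multifocals) is out of scope, as are lens decentration and tilt.
* Monochromatic evaluation; no Stiles–Crawford apodization or scatter.
* The absolute VSOTF scale depends on the CSF parameterization; compare
  ratios, not raw values, across configurations.
* Binocular combination and visual-acuity prediction beyond the fixed
  0.12 ↔ logMAR 0.20 anchor are not modelled.

## A worked example

```{r example, eval = FALSE}
library(segwave)

# a centre-near lens: +2.50 D addition inside 1.5 mm, -3.00 D base
spec <- lens_design_spec("center_near", base_power_D = -3, addition_D = 2.5,
                         zone_boundaries_mm = 1.5, transition_width_mm = 0.5,
                         label = "CN +2.50")
lens <- remove_base_power(generate_lens_profile(spec), -3)

eye <- generate_eye_population(eye_population_spec(n_eyes = 1, seed = 7))[[1]]
cfg <- run_config(fast = TRUE)

mono <- sagittal_profile(c(0, 5), c(0, 0), meta = list(lens = "monofocal"))
mono_curve <- through_focus(combine_with_eye(mono, eye, cfg$grid))
shift <- equivalent_sphere_shift(mono_curve)

cn_curve <- through_focus(combine_with_eye(lens, eye, cfg$grid),
                          shift_D = shift)
metrics_report(cn_curve,
               reference = metrics_report(
                 through_focus(combine_with_eye(mono, eye, cfg$grid),
                               shift_D = shift)))
```
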