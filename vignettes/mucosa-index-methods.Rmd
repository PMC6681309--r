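---
title: "Measuring nasal mucosa swelling from micro-CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nasal mucosa swelling from micro-CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinoct)
```

## The measurement problem

Upper-airway hyperresponsiveness in rodent models of allergic rhinitis
manifests as swelling of the nasal mucosa after a cholinergic challenge
(intranasal methacholine, MCh). Nasal resistance measurements confound this
swelling with secretions, lower-airway effects, and body motion, so
`rhinoct` instead quantifies the swelling directly on micro-CT: on a small
set of standardized head slices, it measures what fraction of the nasal
cavity cross-section is occupied by soft tissue. The package's headline
statistic, the **mucosa index**, is

$$\mathrm{MI} = \frac{1}{K}\sum_{k=1}^{K}
\frac{A_{\mathrm{mucosa}}(k)}{A_{\mathrm{ROI}}(k)},$$

the unweighted mean over the $K$ analysis slices of the mucosal area
divided by the total nasal-cavity ROI area. A swollen mucosa narrows the
air-filled lumen, so the index rises with swelling; it is dimensionless and
bounded in $[0, 1]$.

We deliberately use the mean of per-slice ratios rather than the pooled
ratio $\sum_k A_{\mathrm{mucosa}}(k) / \sum_k A_{\mathrm{ROI}}(k)$: the
mean-of-ratios weights every anatomical level equally rather than
overweighting the largest cross-sections. The pooled form is available via
`compute_index(..., pooled = TRUE)` for sensitivity analyses.

## Slice planning from skull landmarks

Slices are planned from six manually annotated skull landmarks so that the
measured levels are anatomically comparable across animals:

* **Axial plan** (`build_axial_plan()`): the base plane connects the
  anterior tip of the nasal bone and the anterior arch of the atlas,
  constructed perpendicular to the mid-sagittal plane. The span from this
  plane up to the midpoint of the nasal bone is divided into **seven**
  parallel slabs of equal thickness. The two lowest slabs contain the oral
  cavity and are excluded; the remaining five are labelled A1–A5 from
  bottom to top.
* **Coronal plan** (`build_coronal_plan()`): the anterior plane connects
  the root of the upper incisor tooth and the sagittal suture; the
  posterior boundary is the parallel plane through the fronto-parietal
  joint; the interval is divided into five slabs C1–C5, none excluded.

Each slab is represented by a single 2D image resampled at the slab's
*centre* plane (trilinear interpolation, `reslice()`). Sampling the centre
is the least biased single-image representative of a slab; averaging many
planes per slab would change the statistic the method defines. One genuine
ambiguity deserves a note: for the coronal plan the source description can
be read either as five slices spanning suture-to-joint or as spanning the
anterior plane to the joint. We chose the anterior-plane-to-joint rule
because it uses the anterior plane that is explicitly constructed and
keeps both plans structurally identical (a boundary plane plus a parallel
partition); the slab count and labels are unaffected.

Sample points that fall outside the scanned volume are filled with
−1000 HU (air). Because air lies below the mucosa threshold, padding can
never masquerade as tissue.

## Segmentation inside the cavity ROI

The nasal cavity outline is drawn manually per slice (the package reads
ROI polygon files; it does not auto-segment the cavity). Within the
rasterized ROI, a pixel is mucosa iff its HU value lies in the closed
interval $[-700, +700]$: this bi-threshold excludes both the air-filled
lumen (≈ −1000 HU) and bone (> +700 HU). Both bounds are inclusive; the
interval is stated as a closed range and fixing inclusivity makes the
segmentation deterministic. Consequences worth knowing:

* Turbinate bone inside a drawn ROI counts in the denominator but never as
  mucosa.
* Nasal secretions have soft-tissue attenuation and are indistinguishable
  from mucosa by CT; the index measures "soft-tissue fraction", which is
  exactly what the in-vivo method measures too.

Rasterization uses the pixel-centre even–odd rule with centres exactly on
an edge counted inside — simple, unbiased for closed curves, and
deterministic, so areas are reproducible to the bit. Areas are pixel
counts times pixel area; the per-slice fraction is exactly invariant to
whole-pixel translations of image and polygon together.

## Display calibration

Preview images use a linear window/level mapping with half-up rounding
after clipping (`render_window_level()`), defaulting to a 10,000 HU window
at a 2,000 HU level — wide enough to show air, soft tissue, and bone on
one grayscale. Rounding is pinned so previews are identical across
platforms.

## Volume I/O and coordinates

The world frame is LPS (the DICOM patient convention) in millimetres;
voxel indices are 0-based with the origin at the centre of voxel
(0, 0, 0). DICOM series are calibrated to HU through the rescale
slope/intercept and validated for a single orientation and uniform slice
spacing. NIfTI files are assumed already HU-calibrated — `scl_slope`
handling varies between producers, and a single rule avoids accidental
double scaling. NIfTI affines (RAS) are converted to LPS on read and back
on write; the sform carries the full affine. The DICOM reader/writer
covers explicit-VR little-endian single-frame CT slices — the subset this
pipeline needs.

## The synthetic head phantom

No public scans accompany the method, so validation rests on a parametric
phantom (`generate_phantom()`) with analytic ground truth: an air
background, a high-HU bone shell, and an air-filled lumen lined by a
soft-tissue mucosa layer — an annular cylinder with outer cavity radius
$R(z)$ and lumen radius $r(z)$, plus an optional soft-tissue septum. For a
circular section the true mucosa fraction is $(R^2 - r^2)/R^2$ (with a
chord-strip correction when a septum is present). The phantom carries a
landmark set consistent with its geometry and exact cavity-outline ROI
polygons, so every stage of the pipeline — plan, reslice, rasterize,
threshold, aggregate — is exercised against known truth.

Default conditions: $R = 2$ mm, $r = 1$ mm (fraction 0.75), 20 µm
isotropic voxels (near the 19.71 µm voxels of high-resolution micro-CT),
HU class means −1000 / +40 / +1500 (air / mucosa / bone), optional
Gaussian HU noise and PSF blur, and a fixed integer seed making volumes
byte-identical across runs. In this phantom the "coronal" landmark pair is
placed so that C-slices also cut the cylinder transversely; this is an
idealization that gives the coronal code path analytic truth, not an
anatomical claim.

What the phantom does *not* emulate: the turbinate labyrinth, partial
bone/soft-tissue interfaces, beam hardening, scanner reconstruction
artifacts, and secretions. Passing the phantom suite therefore shows the
*measurement chain* is correct and stable, not that segmentation of real
turbinates at −700 HU is biologically optimal.

## The swelling model behind the experiment simulators

Methacholine-induced thickening is modelled with a saturating Emax dose
term and a piecewise-linear kinetic pulse:

$$t(\mathrm{dose}, \tau) = t_0 + m_g\,\Delta_{\max}
\frac{\mathrm{dose}}{\mathrm{dose} + EC_{50}}\,k(\tau),$$

with the lumen shrinking as $r = R - t$ and the outer wall fixed. Default
constants (all configurable, none hard-coded in the drivers):

| parameter | default | rationale |
|---|---|---|
| $t_0$ | 0.25 mm | plausible baseline murine nasal mucosa thickness; baseline index ≈ 0.23 at $R = 2$ mm |
| $\Delta_{\max}$ | 0.5 mm | a strong but lumen-preserving maximal response (~2-fold index increase at 1 mg/mL) |
| $EC_{50}$ | 0.5 mg/mL | places 2.0 mg/mL at 80 % of saturation, i.e. near-plateau |
| $k(\tau)$ knots | 0→0, 15→1, 60→1, 120→0 | full effect at 15–60 min, recovery by 120 min |
| multipliers | control 1, AR 2, AR_dex 1 | AR doubles the gain; dexamethasone collapses AR onto control |
| $t_0$ SD | 0.02 mm | between-animal variability; gives index SDs comparable to modest SEM error bars at $n \approx 5$ |

The between-animal baseline jitter is ours, not a measured quantity: some
biological variance is required for group comparisons to be a test at all,
and 0.02 mm yields realistic within-group scatter. The dexamethasone
multiplier of 1.0 emulates complete abrogation of the AR response; it is a
phenomenological setting, not pharmacology. Note one consequence of
multiplying $\Delta_{\max}$: the AR–control separation persists at
2.0 mg/mL, whereas a hyperresponsiveness model acting on $EC_{50}$ (a
leftward shift) would close the gap at saturating doses. The multiplier
form is the simpler mechanism and reproduces every pattern the simulators
are asked for.

Experiment drivers (`run_dose_response()`, `run_kinetics()`,
`run_treatment()`) push every simulated animal through the *full* imaging
pipeline — phantom volume, landmark plan, oblique reslice, ROI
rasterization, bi-threshold, index — then summarize cells as mean ± SEM
and test them with the Mann–Whitney U test. Experiment phantoms default to
40–60 µm voxels and 20 HU noise so a full cohort simulates in seconds; at
these sizes the pipeline's recovery error (< 0.01) is far below the
modelled effect sizes (> 0.1).

## Statistics

Group comparisons use the two-sided Mann–Whitney U test at α = 0.05
without multiplicity correction, matching how such animal experiments are
conventionally analysed; SEM is the sample SD over $\sqrt{n}$, with the
$n = 1$ case reported as SEM 0 plus an explicit `sem_defined = FALSE`
flag, and groups of one are never tested. For $n + m \le 16$ the
permutation null is enumerated exactly over all $\binom{n+m}{n}$ splits of
the observed midrank vector, which handles ties by construction; beyond
that the normal approximation with tie-corrected variance and a 0.5
continuity correction is used. The two-sided p-value is
$\min(1, 2\min(P(U \le u), P(U \ge u)))$. The exact path is verified
against an independent brute-force enumeration and against
`wilcox.test(exact = TRUE)` on tie-free data; its null calibration
(rejection rate just below 0.05, as expected for a discrete exact test) is
checked by simulation.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere a plane is sampled; out-of-volume
  fill −1000 HU.
* Threshold bounds inclusive; rasterization edge pixels inside; window
  rounding half-up. All three pin otherwise-arbitrary boundary behaviour.
* Plans reject degenerate landmark sets (coincident points, a nasal-bone
  midpoint on or below the base plane, a fronto-parietal joint on the
  anterior plane) rather than producing empty slabs.
* Empty ROIs (no pixel centre inside) are an error, not a zero: a silent
  0/0 would propagate NaN into the index.
* Phantom specs are validated against the invariant
  $\mathrm{air} < -700 < \mathrm{mucosa} < +700 < \mathrm{bone}$, so a
  misconfigured phantom cannot silently produce an unmeasurable class
  layout; `swell()` refuses to close the lumen.

## Problem sizes used in the test-suite and validation runs

Validation balances resolution against run time, and states its choices:
recovery and rigid-motion checks run at 20 µm voxels (the paper-scale
resolution), the convergence study at 40/20/10 µm with the cavity
deliberately off-centre so symmetric discretization errors cannot cancel,
and cohort simulations at 60–80 µm where the discretization error is an
order of magnitude below the modelled effects. Observed behaviour at these
sizes: recovery error ≈ 7×10⁻³ at 40 µm and ≈ 2×10⁻⁴ at 20 µm;
rigid-motion shifts ≈ 1.5×10⁻³ at 20 µm.

## Known limitations

* The 2D slice-based index is not a volumetric measurement; slabs
  contribute equally regardless of thickness-weighted tissue volume.
* Landmarks and cavity ROIs are user-supplied; annotation variability is
  outside the model. Whether paranasal sinuses are excluded is the
  annotator's choice, encoded in the ROI polygons.
* CT cannot separate secretions from mucosa; neither does this index.
* The phantom's analytic geometry validates the pipeline, not the
  biological appropriateness of the −700/+700 HU bounds for real murine
  tissue.
* The exact-test cutoff ($n + m \le 16$) bounds enumeration cost; at the
  design sizes used here (n ≤ 8 per group) every test is exact.
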