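---
title: "Methods: edge-based MRI assessment of hemophilic arthropathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-based MRI assessment of hemophilic arthropathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamri)
```

## What the package models

Hemophilic arthropathy (HA) is the joint damage caused by recurrent
intra-articular bleeding in hemophilia: synovial hyperplasia, hemosiderin
deposition, effusion, and eventually osteochondral destruction. Radiation
synovectomy (RS) ablates the hypertrophied synovium with an intra-articular
β-emitter; its effect is monitored on MRI, where the joint is graded with the
additive IPSG score (three soft-tissue lesions graded 0–3, eight binary
osteochondral items; maximum 17 = 9 + 8).

The package implements a complete, seeded simulation of such an evaluation
study:

1. a **synthetic joint phantom** with known lesion geometry and Rician noise;
2. the **Canny edge-detection chain** (Gaussian smoothing → Sobel gradients →
   non-maximum suppression → double-threshold hysteresis) used to denoise and
   delineate the synovial contour;
3. **PSNR and sliding-window SSIM** to quantify reconstruction quality
   against the clean reference;
4. **IPSG scoring** from lesion masks;
5. the **study statistics**: per-score-level detection-rate chi-square
   against pathology, paired t-test of pre/post synovial volume, one-way
   ANOVA of bleed counts — all tail probabilities computed in-package via a
   continued-fraction regularized incomplete beta / incomplete gamma, so the
   inferential core has no runtime statistics dependency.

`run_study()` composes all five stages from one `study_config()` and a master
seed; every stage seed is derived deterministically from it, so any single
joint or phantom can be replayed in isolation.

## The edge-detection chain

The image is smoothed by discrete convolution with a normalized Gaussian,
`I' = I * G`, `G ∝ exp(-(x² + y²) / 2δ²)`, with replicate padding so constant
images are fixed points. Gradients use the 3×3 first-difference (Sobel)
templates: the horizontal derivative is the 1-2-1-weighted column at `x + 1`
minus the weighted column at `x - 1`; the vertical derivative is the weighted
row above minus the weighted row below. Magnitude is `sqrt(gx² + gy²)`.

Two conventions deserve note:

* **Direction.** The stored direction is the four-quadrant angle
  `atan2(gy, gx)`; a two-quadrant `atan(gx / gy)` compatibility mode exists
  (`literal_direction = TRUE`) but non-maximum suppression derives its sector
  directly from `(gx, gy)`, so the mode cannot change edge output — a
  property the test suite asserts.
* **Strict suppression.** A pixel survives NMS only if *strictly* greater
  than both neighbors along its quantized (0°/45°/90°/135°) gradient
  direction; magnitude plateaus therefore vanish entirely. Out-of-bounds
  neighbors count as zero, so a lone border maximum survives.

The double threshold is quantile-derived per image when not given absolutely:
`t_high` is the 0.90 nearest-rank quantile of the *nonzero* suppressed
magnitudes and `t_low = 0.4 · t_high`. Weak pixels (in `[t_low, t_high)`)
become edges only when transitively 8-connected to a strong pixel.
Zero-magnitude pixels are never edges, even at `t_high = 0`; without this
rule a blank image would be all edge under the `≥ t_high` test. The quantile
defaults follow the common Canny heuristic (keep the strongest ~10% of
candidate edge pixels, link down to 40% of that strength); both are exposed
in `canny_params()` and absolute thresholds are accepted for fixed-threshold
workflows.

`extract_synovial_contour()` returns the largest 8-connected edge component
and flags whether it encloses a nonempty interior (flood fill of the
complement from the raster border, 4-connected so a one-pixel 8-connected
ring is watertight). Size ties break toward the component whose minimal
(row, col) pixel is lexicographically smallest.

## Quality metrics

`mse()` and `psnr()` follow the standard definitions with
`MAX = 2^bit_depth − 1`; identical images signal an infinite PSNR as a
classed warning and return `Inf`. SSIM uses an unweighted `H × H = 8 × 8`
window sliding at stride 1 over every fully interior position; per window

\[
SSIM = \frac{2\mu_M\mu_N + C_1}{\mu_M^2 + \mu_N^2 + C_1}\cdot
       \frac{2\sigma_M\sigma_N + C_2}{\sigma_M^2 + \sigma_N^2 + C_2}\cdot
       \frac{\sigma_{MN} + C_3}{\sigma_M\sigma_N + C_3},
\]

with `C1 = (0.01 L)²`, `C2 = (0.03 L)²`, `C3 = C2/2`, `L = 255` for 8-bit
data, and sample (`n − 1`) variances and covariance. The overall value is the
arithmetic mean over windows. Three deliberate readings, each configurable or
test-asserted: the dynamic range is 255 (the usual `2^8 − 1`); the structure
term uses the true cross-product covariance; and windows are uniform, not
Gaussian-weighted — the plain sliding-window definition. With these choices
`SSIM(M, M) = 1` exactly and every window value lies in `[−1, 1]`, which the
suite checks. The implementation uses integral images; a brute-force
per-window oracle pins it down in the tests.

## The phantom and what it does (not) emulate

The phantom is concentric joint geometry on a 128 × 128, 8-bit raster: two
elliptical bone cross-sections (intensity 200), a synovial annulus
(intensity 120) whose filled outer disk is the *joint region*, an effusion
disk sized to a target fraction of that region (intensity 170), and
hemosiderin foci rendered near zero (intensity 2) — hemosiderin is markedly
hypointense on MRI. Layers render in that order; each class's mask holds the
pixels where it is topmost, and ground-truth grades are computed from the
rendered masks, so mask/grade consistency holds by construction.

Condition choices, made once:

* **Raster 128 × 128.** The study's acquisition matrices are 320–512; at
  desk scale 128 keeps the edge-pixel share of the image realistically small
  (on much smaller rasters the step edges dominate the area and blur error
  swamps any denoising gain, inverting the blur-versus-noise tradeoff the
  comparison rests on).
* **Rician noise, σ = 20** (~8% of the 8-bit range): magnitude-MRI
  statistics at a magnitude SNR of roughly 6–10 across the phantom's
  tissues — the noisy-acquisition regime in which reconstruction is
  clinically warranted. Gaussian noise is retained for closed-form tests
  (sample-mean CLT bound; Rayleigh mean `σ√(π/2)` on a zero image).
* **Smoothing δ = 1 px** with kernel radius `⌈3δ⌉`: the classic light Canny
  scale; heavier kernels visibly blur the thin synovial ring whose contour
  is the object of interest.

The phantom does **not** emulate: 3-D partial-volume structure, coil
inhomogeneity, pulse-sequence contrast (T1WI vs PDWI-FS), gadolinium
enhancement, or anatomically realistic lesion shapes. Passing tests
demonstrate that the chain is implemented correctly and behaves as claimed
under controlled conditions — not that it would reach any particular
accuracy on patient images.

## IPSG scoring from masks

Soft-tissue grades map lesion area fractions of the joint region through
half-open cuts: `< 0.01 → 0`, `[0.01, 0.05) → 1`, `[0.05, 0.15) → 2`,
`≥ 0.15 → 3`. These cuts are package conventions standing in for the
qualitative small/medium/large sizes; they are not clinical IPSG definitions
and are fully configurable (`grade_thresholds()`). Osteochondral binaries
come from mask overlap: erosion touching a bone's cortical boundary; erosion
of ≥ 50% of one bone; any cyst inside a bone; cysts in more than 2 bones or
more than 1/3 of a single bone; cartilage damage anywhere / ≥ 50% of one
bone's cartilage / focal full thickness / full thickness over ≥ 50% of one
bone's cartilage. The additive reading of the scoring table (both erosion
rows, both cyst rows countable together) is adopted because the published
maximum — 17 split 9/8 — forces it; the suite verifies the bound over the
entire 16,384-card space.

## The synthetic cohort

`default_cohort_spec()` is the published cohort verbatim: 146 joints
(84 knee / 38 ankle / 10 elbow / 14 hip) over 60 patients; pathology grade
counts (14, 59, 37) for effusion scores (0, 1, 2–3), (15, 50, 27, 54) for
synovial hyperplasia 0–3, (36, 46, 22, 44) for hemosiderin 0–3; a 42-joint
RS-treated subgroup. Grades are assigned by seeded *permutation* of exactly
these counts, never by sampling, so the distributions are reproduced
verbatim. Two of the printed distributions are internally inconsistent with
the 146-joint total (the effusion counts sum to 110, the hemosiderin counts
to 148); the package keeps the printed values rather than reconciling them —
the sum-consistency check is disabled for exactly those lesions, joints
beyond the effusion counts stay ungraded (`NA`), and the two excess
hemosiderin grades are dropped from the last bin with a warning. Any other
mismatch is an error reporting both sums.

The three detection methods are modeled as three *measurement arms over the
same joints* (the published per-level comparisons share one 146-joint
denominator); a conventional-MRI arm re-grades each joint with mis-grading
probability 0.25 and the Canny arm with 0.04. Mis-grading is
*downward-biased* — a hit joint's grade drops one level, clamped at 0 —
because missed or underestimated small lesions are the disagreement
mechanism attributed to conventional MRI; symmetric re-grading would leave
per-level detection rates nearly unchanged (in-flow from adjacent levels
cancels out-flow) and make the arm comparison null by construction. Volumes are lognormal around a 30,000 mm³ pre-surgery
mean with CV 0.20; the post volume is `pre × 0.7 ×` mean-one lognormal noise
(CV 0.20) — the multiplicative encoding of "volume reduced after surgery",
with 0.7 a clinically plausible effect size that the power analysis in the
test suite exercises at the published subgroup size n = 42. Bleed counts are
Poisson with means 4.0 (pre) and 1.2 (post) per 6 months, typical for target
joints before and after synovectomy.

## Statistics

The paired t-test, one-way ANOVA, and per-level detection-rate chi-square
are implemented from their definitions. The detection-rate table is
rater × (graded-at-level / not) over the same m joints, n = 2m gradings, and
the df-1 statistic `n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`; identical raters
give exactly 0 and a swap of raters leaves the statistic unchanged. Yates
correction is available but off by default (the standard uncorrected form is
the common choice at these cell sizes and is what the closed-form example
values assume). Tests are two-sided at α = 0.05; no multiplicity correction
is applied across levels or lesions — deliberately mirroring the analysis
style being reproduced, and a known caveat. t and F tails are computed with
an in-package continued-fraction incomplete beta (relative tolerance 1e-12,
Lentz's algorithm, the usual symmetry switch at `x = (a+1)/(a+b+2)`); the
chi-square tail uses the regularized upper incomplete gamma (series below
`s + 1`, continued fraction above). The suite cross-checks them against
base R's distribution functions and against direct quadrature of the t
density to 1e-6.

Degenerate inputs fail loudly rather than silently: zero-variance
differences in the paired test, zero within-group variance in the ANOVA, a
level absent from both raters in the rate comparison.

## Problem sizes and determinism

The shipped tests run the oracle-equivalence suite on 100 seeded 16 × 16
rasters, the calibration study on 2,000 null replicates (level-1 rejection
rate must fall in 5% ± 2%), the power study on 1,000 replicates of the
n = 42 paired design (must exceed 90%), and the reconstruction-direction
check on 20 seeded phantoms (PSNR and SSIM must each improve on ≥ 95%);
these sizes keep each property statistically meaningful while the whole
suite stays interactive. Every random draw flows through seeds derived from
a single master seed by a stable label hash; `run_study()` twice with one
config is bit-identical, which is itself a test.

## Known limitations

* 2-D phantoms only; no volumetric scoring, no DICOM.
* The effusion/hemosiderin count inconsistencies in the source tables are
  reproduced, not resolved; per-joint tabulations can therefore differ from
  the stored distributions for those two lesions (by construction, and
  documented above).
* Grade thresholds and arm error rates are simulation conventions; they are
  not calibrated against clinical data.
* The osteochondral mask rules are geometric readings of the scoring table's
  wording; no signal-intensity modeling is attempted.
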