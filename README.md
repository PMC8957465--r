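# hamri

Edge-based MRI assessment of hemophilic arthropathy: a tested, seeded
pipeline for evaluating radiation synovectomy with Canny-processed MRI,
image-quality metrics, IPSG joint scoring, and cohort statistics.

## The problem

Hemophilic arthropathy (HA) — joint degeneration from recurrent
intra-articular bleeding — is monitored on MRI and graded with the additive
IPSG score: effusion/hemorrhage, synovial hyperplasia and hemosiderin
deposition each 0–3 (soft-tissue subtotal ≤ 9), plus eight binary
osteochondral items (subtotal ≤ 8), total ≤ 17. After radiation synovectomy
the questions are whether the processed MRI delineates the synovial contour
well enough to grade reliably, and whether synovial volume and bleed
frequency fall.

`hamri` implements that evaluation end to end for researchers who want the
method chain reproducible without patient data:

* **Canny edge detection** — Gaussian smoothing `I' = I * G`, Sobel
  gradients `ϑ = √(gx² + gy²)`, four-sector non-maximum suppression
  (strictly-greater rule), quantile double thresholds, 8-connected
  hysteresis linking, synovial-contour extraction;
* **quality metrics** — `MSE`, `PSNR = 10·log₁₀(MAX²/MSE)` in dB, and
  sliding-window SSIM `l·c·s` with uniform 8×8 windows and sample
  (n−1) statistics;
* **IPSG scoring** from lesion masks (area-fraction grade cuts,
  mask-overlap rules for the osteochondral binaries);
* **statistics from first principles** — paired t, one-way ANOVA, per-level
  detection-rate chi-square; all tails via an in-package continued-fraction
  incomplete beta/gamma;
* **synthetic data** — a joint phantom (bones, synovial ring, effusion,
  near-zero hemosiderin foci; Rician noise) with known ground truth, and a
  146-joint cohort generator that reproduces the published grade
  distributions verbatim by seeded permutation.

## Worked example

```r
library(hamri)

ph <- make_phantom(phantom_spec(seed = 42))
ph
#> <phantom_image> 128x128 8-bit, rician noise (sigma 20), true IPSG total 6

ph$true_grades
#> <ipsg_card> total 6 (soft tissue 6 / osteochondral 0)
#>   effusion 2, hyperplasia 3, hemosiderin 1

em <- canny(ph$noisy)                      # full chain on the noisy raster
em
#> <edge_map> 128 x 128, 772 edge pixels (554 strong, 218 weak-linked)
extract_synovial_contour(em)$closed
#> [1] TRUE

recon <- attr(em, "stages")$smoothed       # the denoised reconstruction
psnr(ph$clean, ph$noisy);  psnr(ph$clean, recon)
#> [1] 22.50155
#> [1] 24.66534
```

The phantom's ground truth: a 10% effusion fraction grades 2 under the
default cuts (0.01/0.05/0.15), the synovial ring grades 3, the two small
hemosiderin foci grade 1. On the noisy raster the Canny-smoothed
reconstruction gains ~2 dB PSNR and ~0.3 SSIM over the raw image —
the direction the method comparison turns on.

The full simulated study (cohort + phantoms + scoring + statistics):

```r
rep <- run_study(study_config(n_phantoms = 5, seed = 1))
rep
#> <study_report> 146 joints, 5 phantoms (seed 1)
#>   mean PSNR: conventional 22.52 dB, Canny 24.68 dB
#>   mean SSIM: conventional 0.4347, Canny 0.7545
#>   closed synovial contours: 4 / 5
#>   volume pre vs post (n = 42): t = 10.189, p = 8.45e-13
#>   bleeds pre vs post: F = 49.199, p = 6.02e-10

rep$agreement$synovial_hyperplasia
#> <agreement_summary> synovial_hyperplasia
#>  level pathology conventional canny p_conventional   p_canny
#>      0        15           27    20     0.04537703 0.3676589
#>      1        50           44    47     0.45233393 0.7093397
#>      2        27           39    27     0.09315522 1.0000000
#>      3        54           36    52     0.02253549 0.8076993
```

The pathology column reproduces the published hyperplasia counts
(15, 50, 27, 54) exactly; the conventional arm's detection rates drift from
pathology (under-detection of small lesions), the Canny arm's do not — the
qualitative contrast the pipeline is built to examine. The paired t on the
42-joint RS subgroup reflects the simulated 0.7 volume-reduction factor.

A thin command-line wrapper ships in `inst/cli/ha-study.R`:

```sh
Rscript inst/cli/ha-study.R --seed 1 --n-phantoms 20 --out results/
Rscript inst/cli/ha-study.R --fixtures --out fixtures/
```

See the methods vignette (`vignettes/hamri-methods.Rmd`) for the model
details, parameter rationale, and limitations.

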