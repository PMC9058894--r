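---
title: "Methods: MSI/dMMR pre-screening from H&E slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI/dMMR pre-screening from H&E slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microsatellite instability (MSI) and mismatch-repair deficiency (dMMR)
should be tested in every colorectal cancer patient, but molecular and
immunohistochemical testing is costly and not universally performed. A
tile-based classifier applied to routine H&E whole-slide images can act
as a *pre-screening* (rule-out) test: patients confidently predicted
MSS/pMMR skip confirmatory testing, while everyone else proceeds to the
gold standard. The quantities that matter for such a triage tool are not
only the AUROC but the **rule-out fraction** (true negatives over all
patients) and the **false-negative fraction** (MSI patients the
pre-screen would miss), both evaluated under an explicit decision
threshold. This package implements the full pipeline — tiling, quality
control, stain normalization, tile scoring, patient-level aggregation,
threshold calibration, triage evaluation, and multi-cohort study
orchestration — together with a synthetic-data module so every stage is
testable without clinical data. Labels are encoded 1 = MSI/dMMR,
0 = MSS/pMMR throughout (the two ground-truth modalities are treated as
interchangeable, as they are in clinical practice).

## Tiling and quality control

Slides are tessellated into non-overlapping square tiles of fixed
*physical* edge length (default 256 µm) and resampled bilinearly to a
fixed output edge (default 512 px), so tiles are comparable across
scanners with different resolutions. The source footprint is
`round(tile_edge_um / microns_per_pixel)` pixels; partial tiles at the
right/bottom margins are **dropped, not padded** — padding would distort
the texture statistics the classifier relies on. Coordinates are 0-based
with x = column, y = row and half-open footprints.

Background and blurred tiles are removed by an edge-quantity rule: the
tile's grayscale image (standard 0.299/0.587/0.114 luminance weights) is
passed through a Canny detector producing a binary 0/255 edge map, and
tiles whose **mean edge value falls below 4** are discarded (a tile at
exactly 4 is kept — removal is strictly below threshold). The Canny
parameters are this package's choices: Gaussian smoothing σ = 1.4 px and
hysteresis thresholds 40/100 on the 8-bit Sobel gradient magnitude,
chosen conservatively so that constant or defocused tiles yield empty
edge maps. They are configurable; tests rely only on parameter-robust
cases (blank tiles score 0, sharp texture scores far above 4, blurring
strictly lowers the score). One consequence of smoothing at σ = 1.4 is
that single-pixel alternation patterns are treated as noise rather than
edges; sharpness fixtures therefore use block sizes of several pixels.
Whether blur filtering runs before or after normalization is not
critical; this package filters first, so stain statistics are estimated
from tissue tiles only.

## Macenko stain normalization

Optical density is `OD = -log10((I + 1) / 256)` per channel; the +1
offset keeps OD finite at intensity 0. Pixels with all OD components
below 0.15 are treated as background. The remaining OD cloud is
projected onto its top-2 singular plane; the directions at the 1st and
99th percentile of the projection angle are taken as the two stain
vectors, sign-corrected to nonnegative OD and ordered so column 1 is
the more blue-absorbing (hematoxylin) vector. Per-stain concentration
scales are the 99th percentile of nonnegative-least-squares
concentrations (exact for two stains via active-set enumeration).
Normalizing a tile rescales its source concentrations by the ratio of
target to source scales and recomposes with the target stain matrix.

Numerical notes: rank deficiency (blank or single-dye input) is
detected as a second singular value below 1% of the first — 8-bit
quantization leaves roughly 0.2% residual energy off a genuinely rank-1
cloud, while true two-stain clouds carry well over 10%. Output is
clipped and rounded to valid 8-bit RGB, so normalization is
bit-deterministic.

## Tile scoring

The scorer is a plugin: anything answering `score_tiles(scorer, tiles)`
with per-tile probabilities in [0, 1] works, and a deterministic
`mock_scorer()` (a pure function of the pixel array) lets every
downstream stage be tested without training. The full-scale recipe is
recorded in `scorer_config()`: five epochs, mini-batch 1024, Adam with
learning rate 1e-4 and weight decay 1e-5, inputs resized to 224 px, the
first half of a pretrained backbone frozen.

The built-in trainable scorer is a *compact convolutional backbone*: a
fixed, seeded bank of eight 7×7 convolution filters (plus colour and
gradient statistics) acts as the frozen feature extractor, and a
two-class softmax head is fine-tuned with Adam and cross-entropy. This
mirrors the structure of transfer learning — frozen early layers,
trained late layers — at a size where training takes seconds on one
CPU. `desk_scale_config()` adapts the free parameters to that head
(64-px inputs, batch 32, 40 epochs, learning rate 0.05): a linear head
on standardized features converges at far larger steps than a deep
network, so the full-scale learning rate would be a poor default here.
The full-scale recipe values remain the documented defaults of
`scorer_config()`.

Training-set hygiene follows the pre-screening setting: at most 500
randomly selected tiles per patient; the more abundant class
undersampled to exact balance *in the training set only* (test tiles
are never balanced); training is bit-reproducible for a fixed seed.

## Patient aggregation

A patient's score is the fraction of their pooled tiles (across all
slides) whose MSI probability **strictly exceeds** 0.5. The boundary
rule at exactly 0.5 is unspecified in common descriptions of this
aggregation; strict comparison is the default and `strict = FALSE` is
available. The score times the tile count is always an integer — it is
a count fraction, which also motivates Beta models for synthetic
patient scores. Patients with no tiles after QC are flagged unevaluable
and excluded from metrics with a logged reason.

## Threshold calibration

Three strategies convert patient scores into rule-in/rule-out calls
(prediction is MSI when `score >= value`, so a threshold equal to a
positive's score counts that patient as detected):

1. **Cohort-specific**: the largest threshold with calibration-set
   sensitivity ≥ 95% (the k-th largest positive score,
   `k = ceiling(target * n_pos)`); achieved sensitivity on the
   calibration set is ≥ target by construction.
2. **Fixed**: global candidates 0.25, 0.50, 0.75 applied unchanged to
   every cohort.
3. **Learned**: within each training cohort, stratified threefold
   patient-level cross-validation yields out-of-fold scores; the
   cohort's optimum is the fixed-sensitivity threshold on those scores,
   and the learned value is the **unweighted mean** of per-cohort
   optima. The "optimal threshold" inside this procedure is interpreted
   as the same 95%-fixed-sensitivity threshold used cohort-specifically;
   this interpretation and the unweighted averaging are deliberate
   design decisions of this package.

## Evaluation

AUROC uses the rank-statistic (Mann–Whitney) formulation with ties
half-credited, which equals the trapezoidal ROC area; a brute-force
pair-counting oracle verifies it in the tests. Confidence intervals are
**percentile bootstrap** over patients (default 1000 resamples, 95%
level, unstratified); resamples containing a single class are redrawn
so the stated number of effective resamples is kept, and the procedure
fails honestly if the metric is undefined on most draws. Confusion
statistics report sensitivity, specificity, PPV, NPV, F1 (MSI as the
positive class), the rule-out fraction `tn / n` and the FN fraction
`fn / n`; internally everything is a proportion, and
`format_confusion()` renders the percentage scale. The identity
`fn_fraction = (1 - sensitivity) * prevalence` holds exactly on every
input and is asserted in tests.

## Study designs

`leave_one_cohort_out()` trains one model per held-out cohort on all
other cohorts, scores every patient exactly once with a model that
never saw them, and applies all three threshold strategies; the learned
threshold for a fold uses only that fold's eight (or fewer) training
cohorts, never the held-out one. `within_cohort_cv()` runs stratified
threefold patient-level cross-validation. Train/test disjointness is
asserted on every fold, and multi-slide patients always travel together
because splitting is by patient id.

## The synthetic-data module

Two generators define the desk-scale study conditions:

* **Slides**: texture primitives rendered as hematoxylin/eosin
  concentration fields and composed to RGB via Beer–Lambert with
  realistic stain vectors. Class 1 ("MSI-like") uses dense small discs
  (lymphocyte-like, radius 3–6 µm at 1500/mm²); class 0 ("MSS-like")
  uses larger ring/gland-like structures (radius 12–20 µm at 250/mm²).
  The primitives are deliberately simple: they provide a learnable,
  controllable class signal, not histological realism. Artifact
  injection (`blur` with σ = 6 × severity px, `fold`, `overstain`)
  stress-tests QC and normalization; severity 5 blur is the "severe"
  case used in tests and defeats QC on both texture classes.
* **Score cohorts**: labels are Bernoulli at prevalence 0.12 (the
  approximate MSI/dMMR rate in colorectal cancer) and scores are drawn
  from class-conditional Beta models, the natural family for bounded
  count fractions. The defaults Beta(4, 2) vs Beta(2, 4) give a
  closed-form generating AUROC of 0.897 — the regime of a
  well-performing slide classifier; `beta_model_auroc()` computes the
  exact value by numerical integration for any shapes.

What passing tests on this generator do **not** show: robustness to
scanner/site colour shifts beyond a global stain scale, tumor
heterogeneity, annotation-free tumor localisation, or any claim about
clinical cohorts. The generator's role is to verify the pipeline's
mechanics and statistics, not to reproduce clinical performance.

## Problem sizes and numerical choices in the shipped tests

Calibration and evaluation properties are exercised on synthetic
cohorts of 150–3000 patients; the bootstrap coverage simulation uses
200 cohorts of 200 patients (prevalence 0.3, Beta(3, 2) vs Beta(2, 3))
at 200 resamples each, a design large enough for the percentile
interval to be well calibrated; the homogeneity check for the learned
threshold uses cohorts of 3000 patients because the fixed-sensitivity
threshold is a tail order statistic whose sampling spread shrinks as
n^(-1/2); the end-to-end study runs four cohorts of eight patients with
256-px slides and 64-µm tiles through the full image pipeline,
including leave-one-cohort-out retraining of the compact backbone.
Stain-recovery tests synthesize OD clouds containing stain-dominant
subpopulations (nuclei-like and stroma-like pixels), since percentile
extreme angles can only recover vectors that some pixels approach.

## Known limitations

* The compact backbone is a deliberately small stand-in architecture;
  it demonstrates the training recipe's structure (frozen features,
  fine-tuned head, Adam, class balancing) but is not a deep network
  and will not match one on real histology.
* Macenko normalization assumes exactly two dyes; heavy artifacts or
  non-H&E stains violate its model (rank-deficient inputs are rejected
  rather than silently normalized).
* Pyramidal/proprietary WSI containers are out of scope; ingestion is
  plain rasters (PNG/TIFF) or pre-cut tiles.
* Fixed thresholds are only transportable to cohorts whose score
  distributions resemble the calibration cohorts'; the
  cohort-specific/learned machinery exists precisely because this often
  fails in practice.

## A worked example

```{r example}
library(msiprescreen)

# a synthetic multi-cohort study on disk
dir <- tempfile("study")
manifest <- make_synthetic_study(dir, n_cohorts = 4,
                                 patients_per_cohort = 8,
                                 prevalence = 0.5, size_px = 256, seed = 60)
man <- read_manifest(manifest)

# score patients with the deterministic texture-statistic scorer
cfg <- read_run_config()
cfg$tile_edge_um <- 64; cfg$out_edge_px <- 64
scorer <- mock_scorer(function(px) {
  dark <- rgb_to_gray(px) < 150
  if (!any(dark)) return(0.5)
  exp(-mean(tabulate(EBImage::bwlabel(dark))) / 300)
})
scored <- lapply(man$cohorts, function(co)
  score_manifest_cohort(co, scorer, cfg)$scores)

# leave-one-cohort-out evaluation with all three threshold strategies
res <- leave_one_cohort_out(scored, n_boot = 200, seed = 1)
res$auroc
res$metrics
write_results(res, file.path(dir, "results"))
```
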