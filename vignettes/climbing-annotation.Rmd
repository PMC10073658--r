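---
title: "Automated annotation of home-cage climbing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated annotation of home-cage climbing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(climbr)
```

## The problem

Laboratory mice housed in individually ventilated cages climb on the wire
cage lid, and the amount and circadian placement of that climbing — together
with cage-floor locomotion — is a sensitive, non-invasive read-out of
neurological phenotypes. `climbr` implements a complete pipeline for this
read-out: frame-by-frame recognition of climbing in grayscale home-cage
video, aggregation of the resulting ethogram into zeitgeber-time bins, and
mixed-model inference on group differences, with special attention to the
30-minute windows flanking the light transitions where hypoactivity
phenotypes (e.g. in Huntington's disease models) manifest earliest.

## The motion descriptor

Climbing happens in a fixed part of the image — a rectangular region of
interest adjacent to the cage lid, 690 × 385 px at the native camera
resolution. Motion inside that region is summarised per frame by a **local
trinary pattern** (LTP) descriptor. For every pixel `p` and each of the 8
neighbour offsets `n_i` at radius `r` (clockwise from top-left; bit `i`
encodes offset `i`), two patch distances are computed: `d_minus_i`, the SSD
between the `(2h+1)²` patch at `p` in frame `t` and the patch at `p + n_i`
in frame `t − Δ`, and `d_plus_i`, the same against frame `t + Δ`. The trit
is

* `+1` if `d_minus_i − d_plus_i > τ` (the past matches worse — motion
  *toward* this offset),
* `−1` if `d_plus_i − d_minus_i > τ`,
* `0` otherwise.

The +1 bits pack into a byte `B+`, the −1 bits into `B−`; the two bytes are
histogrammed (256 bins each) over an 8 × 4 cell grid covering the region and
concatenated, giving `8 × 4 × 512 = 16,384` dimensions. The dimension
depends only on the grid, never on the region's pixel size, so
reduced-resolution video yields vectors of the identical shape.

Parameter defaults (`ltp_params()`): 3 × 3 patches (`patch_half = 1`),
neighbour radius 2, temporal gap `Δ = 2` frames, `τ = 0`, L1-normalised
histograms. Patch size, radius, gap and threshold are not uniquely
determined by the method's description; these defaults follow common usage
of the representation and all are configurable. The pooling grid default is
the one that produces the canonical 16,384-dimensional vector. Pixels whose
own patch or any neighbour patch would leave the region are not coded;
remainder pixels when the region is not divisible by the grid belong to the
last row/column of cells. The first and last `Δ` frames of a segment, which
lack a symmetric temporal context, replicate the nearest interior
descriptor so every frame carries a label.

`τ` deserves a note: it is a noise floor in squared-intensity units. With
`τ = 0` any SSD asymmetry codes a trit, which is appropriate for clean
video; on noisy video a `τ` of a few times the background SSD-asymmetry
spread suppresses spurious codes. On the synthetic benchmark below the
background texture and sensor noise produce asymmetries with a spread of
roughly 50–60 squared-intensity units on non-climbing frames, so the
pipeline there uses `τ = 300` (about five times that floor); climbing
motion produces asymmetries three orders of magnitude larger, so the margin
is wide.

## Classification and temporal voting

Each frame's descriptor is classified climbing / non-climbing by a linear
support vector machine: L2-regularised L1 hinge loss at strength `C`,
solved in the dual by coordinate descent on sparse features (the standard
large-scale linear-SVM algorithm; the bias enters as a regularised
constant feature). A frame exactly on the decision boundary is classified
non-climbing — detection is conservative. Class imbalance (climbing is
roughly a fifth to a third of frames) is left unweighted by default;
per-class cost weights are available.

Raw frame labels are then smoothed by a **temporal voting window**: frame
`t` is finally labelled climbing iff the raw climbing votes in
`[t − k, t + k]` (truncated at the ends, no padding) strictly exceed a
fraction `θ` (default 0.5, strict majority) of the window. This removes
isolated single-frame detections and prevents a single misclassified frame
from splitting a long bout. `k = 0` is the identity; voting is monotone in
the raw labels.

`C`, `k` and `θ` are chosen by **leave-one-segment-out cross-validation**:
for every candidate, train on all annotated segments but one, score the
held-out segment (frame accuracy by default; balanced accuracy optional),
and select the candidate with the best fold-mean, breaking ties toward
smaller `C`, then smaller `k` — the simpler, smoother model. The final
model is retrained on all segments at the selected parameters. The default
grid is `C ∈ {0.01, 0.1, 1, 10} × k ∈ {0, 3, 6, 12, 25} × θ = 0.5`; the
procedure is deterministic given its inputs.

## Gold standards from multiple annotators

Human bout annotations are half-open frame intervals `[start, end)` on
0-based indices. Per-annotator intervals are expanded to frame-label
series; the **majority** rule (more than half of the annotators) defines
the evaluation gold standard, while the **any** rule (at least one
annotator) is used for training labels so that no candidate climbing frame
is lost. The any-rule series dominates the majority series pointwise, so
its climbing prevalence is never lower. Even annotator counts under the
majority rule require an explicit tie policy (default: error; optional
tie-to-non-climbing, consistent with conservative detection).

Frame counts convert to seconds as `n × 40 / 1000` at the default 40 ms
frame duration (25 frames/s), so 1,000 frames are exactly 40 s.

## Validation metrics

`frame_metrics()` reports frame accuracy, per-class recalls and prevalence
from exact integer counts; the identity
`accuracy = prevalence · recall_climbing + (1 − prevalence) · recall_nonclimbing`
holds on every input. `binned_agreement()` compares automated and human
climbing seconds over consecutive 5-min bins by Spearman's rank
correlation (average ranks for ties; two-sided p by the asymptotic t
approximation, exact permutation p optionally for ≤ 10 bins; trailing
partial bins are dropped, never padded, so only equal-duration bins are
compared).

## Ethogram aggregation

Activity is binned on **zeitgeber time** (ZT; hours since lights-on, ZT0 =
07:00 under the default 07:00–19:00 light schedule) into half-open 6-min
bins aligned to ZT0 — 240 bins per day. The dark phase is ZT `[12, 24)`,
so a sample exactly at lights-off is dark. Cage-floor distance is the sum
of Euclidean displacements between consecutive position fixes per mouse
(each step assigned to the bin of its starting fix), summed over the
cage's mice; climbing is a single cage-level label series (the detector
cannot attribute climbing to individuals), converted to seconds per bin.
The windows of interest are the 30 min before lights-on (*end of dark*,
ZT 23.5–24, clock 06:30–07:00) and before lights-off (*end of light*,
ZT 11.5–12, 18:30–19:00); each spans exactly 5 bins and is summarised by
their arithmetic mean per cage and day. Missing bins make the window mean
missing — nothing is imputed, since multi-day recordings make occasional
gaps ignorable and imputation untestable.

## Statistical model

Window or phase means (3 recording days per cage) are analysed with a
linear mixed-effects model: categorical fixed effects of age, genotype and
sex, a random intercept per cage and a random day-of-recording slope
(days numeric 1–3), fitted by REML after a Box-Cox transform whose
exponent is chosen by maximum likelihood per response (coarse scan of
`[−3, 3]` refined by golden-section search; non-positive responses are
shifted by `1 − min(x)` with a warning). The fixed part defaults to the
full factorial rather than the bare three-way interaction because
marginal-means contrasts require estimable cell means; an interaction-only
or reduced formula can be supplied. If the full random structure is
singular the day slope is dropped and the simplification reported, never
hidden. Model comparison refits by ML and reports likelihood-ratio
chi-squares. Pairwise group differences are estimated-marginal-means
contrasts (equal weights over out-of-scope factors, Satterthwaite degrees
of freedom) with Benjamini–Hochberg adjustment across the reported set;
significance stars follow the ns/*/**/***/**** convention.

## The synthetic substrate

No benchmark video or animal data ship with the package; seeded generators
provide a test substrate whose ground truth is known by construction.

**Video** (`video_scenario()` / `generate_video()`): a static background
(vertical gradient plus frozen fine-grained texture, as bedding and cage
furniture present to an infrared camera) with quantised Gaussian pixel
noise (sd 1 intensity unit); climbing bouts alternate with non-climbing
episodes as a renewal process with gamma-distributed durations (means 8 s
on / 60 s off, shape 2 — bouts of seconds to tens of seconds, long gaps),
during which a high-contrast blob oscillates vertically (1.5 Hz, ±18 px)
inside the lid region; a distractor blob moves continuously in the floor
strip below the region to ensure detection relies on the region of
interest. The default frame is 160 × 120 px with a 160 × 96 lid region and
2-min segments at 25 fps — a desk-scale stand-in for full-resolution
multi-hour video. What this emulates well: localised oscillatory lid
motion against static clutter, bout-structured labels, annotator noise.
What it does not: mouse shape and posture variation, illumination drift,
occlusion, multiple animals climbing simultaneously. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that
the descriptor separates planted lid motion from noise at realistic
contrast — not that the reported accuracies transfer to real video.

**Annotators** (`simulate_annotators()`): each human annotator misses a
bout with probability 0.05, jitters surviving boundaries by rounded
Gaussian noise (sd 5 frames = 200 ms), and adds spurious bouts at 2/h with
mean duration 2 s. Zero-noise annotators reproduce the gold exactly;
majority consensus of three such annotators is measurably closer to the
gold than the average individual.

**Activity** (`activity_scenario()` / `generate_activity()`): per-cage
6-min-binned distance and climbing channels with a dark-dominant biphasic
baseline (crepuscular cosine peaks at the two ends of the dark phase, 30%
relative amplitude; dark baselines 9,000 mm and 60 s per bin, light
baselines 2,500 mm and 10 s), multiplicative sex (M = 0.8) and age
(old = 0.7) effects, and a genotype deficit (Hemi × 0.5) confined to the
end-of-dark window — the earliest-manifesting phenotype pattern. Cages
carry random intercepts (6% of the dark baseline), random day slopes (2%)
and per-bin observation noise (8%), and values are floored at zero. The
expected window mean of every cell is available in closed form
(`expected_window_mean()`), which is what makes parameter-recovery
simulations possible.

## Problem sizes and numerical choices

The shipped test suite runs the full pipeline at these scales, chosen so
the whole suite completes in minutes on a single core while still
exercising every stage at realistic dimensionality: 10 segments × 2 min of
160 × 96 video (30,000 frames, 16,384-dim descriptors, 20-candidate CV
grid → 40 fold-fits), held-out metrics pooled over the leave-one-out folds
and rank agreement over the 4 complete 5-min bins those 20 min provide;
200 seeded replicates for coefficient coverage and 100 for the
window-localised power/specificity contrast.

Other numerical choices: the SVM dual coordinate descent uses a private
linear-congruential shuffle so results are bit-reproducible and
independent of R's RNG state; voting thresholds are strict inequalities;
degenerate inputs (single-class training folds, constant responses, empty
series, windows with missing bins) raise errors or explicit `NA`s rather
than being silently repaired.

## Known limitations

* The descriptor is not rotation- or scale-invariant and assumes a fixed
  camera; region drift would need re-registration upstream.
* Cage-level climbing cannot be attributed to individual mice; distance
  can, via the per-mouse position series.
* Contrasts are reported on the Box-Cox scale; back-transformed effect
  sizes are not currently provided.
* The exact permutation p-value for rank agreement is practical only for
  small bin counts (≤ 8–10).
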