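---
title: "Counting neutrophils per high-powered field: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting neutrophils per high-powered field: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrocount)
```

## The problem

Histological confirmation of periprosthetic joint infection (PJI) rests on a
simple but laborious count: the number of neutrophil polymorphs per
high-powered microscope field (HPF) in H&E-stained periprosthetic tissue,
with about five neutrophils per ~0.2 mm² field as the consensus threshold.
Pathologists sample five to ten fields; a detector that sweeps the whole
scanned slide can instead report the count in *every* field and expose the
spatial distribution of neutrophil "hot spots".

`neutrocount` implements the image-side machinery of that workflow:

1. **Calibrated tiling** — convert scanner calibration (pixels/mm) and the
   HPF area (mm²) into a square tile side, and tile the slide;
2. **Sliced detection** — run a detector over overlapping sliding windows
   and merge the per-window detections into slide coordinates;
3. **Evaluation** — match detections to annotated ground truth at an IOU
   cut and report precision/recall/F1;
4. **Diagnosis** — aggregate per-HPF counts to a per-case median, apply the
   threshold rule, tabulate against reference standards, and compare
   paired classifiers with an exact McNemar test.

The trained neural detector that motivates the pipeline is deliberately
*not* part of the package: any detector satisfying the contract
(`raster -> data frame of boxes + confidences`, pure in its input) plugs
into `detect_slide()`. The package ships a rule-based reference detector
and a synthetic slide generator so the full chain is executable and
testable on any machine.

## Geometry conventions

Boxes are half-open pixel intervals `[x0, x1) x [y0, y1)` with a 0-based
top-left origin. This makes integer boxes have exactly integer areas, lets
abutting tiles cover a slide without gaps or double counting (the HPF grid
conserves slide area exactly), and gives the IOU a clean continuous-area
definition. Normalized label files store `class x_center y_center width
height` as fractions of the image size; converting back to pixels rounds
the left/top edge half-up and derives the right/bottom edge from the
rounded width, so round trips are stable to half a pixel and box widths do
not drift.

## Calibration and windows

`hpf_side()` returns `round(sqrt(hpf_area) * px_per_mm)`: with the
reference calibration (4,050 px/mm, 0.2 mm²) one HPF tile is 1,811 px
square. Square tiles are used because only the field *area* is physically
specified; a square of equal area is the closest tileable approximation of
the microscope's circular field. Edge tiles are truncated and kept.

Sliding windows default to 512 px with 30% overlap, i.e. stride
`floor(512 * 0.7) = 358`. The last window on each axis is clamped flush to
the slide edge, so every pixel is covered and windows are always full-size
on slides at least one window wide. Note that with 30% overlap interior
pixels fall in one *or* two windows per axis — only the 154 px bands
between neighbours are double-covered; what the plan guarantees is
complete coverage plus at-least-30% overlap between adjacent windows,
which is enough for any object smaller than the overlap band to appear
whole in some window.

Detections from different windows are merged by translating to slide
coordinates and applying greedy non-maximum suppression (descending
confidence, duplicates at IOU ≥ 0.5 removed). The built-in detector also
suppresses candidates within 8 px of an interior window cut: such objects
are seen whole by a neighbouring window, so border fragments would only
create spurious, shifted boxes. With a 512 px window, 30% overlap, and
~40 px objects, every object sits at least 8 px inside some window, so
this never loses an object.

## Matching and metrics

Matching is the standard confidence-ordered greedy assignment: detections
in descending confidence each claim the unmatched truth with the highest
IOU strictly above the threshold (default 0.5). The suite verifies on
exhaustive small instances that greedy matching attains the
maximum-cardinality assignment whenever pairwise IOUs are distinct.
Unmatched truths are false negatives; unmatched detections false
positives. Degenerate metric denominators (no detections, no truths) are
flagged `undefined` rather than silently zeroed, because a silent 0 (or 1)
would corrupt pooled cohort summaries. Display rounding is half-up to two
decimals or whole percent; internal values keep full precision.

## Diagnosis rule

A case is called infected when the **median neutrophil count per HPF
reaches 5** (`rule = "ge"`, the default; `"gt"` is available). The
at-or-above reading is used because published case tables classify medians
of exactly 5 as infected and the underlying consensus criterion is phrased
as "five or more per high-powered field". Quartiles use the standard
linear-interpolation definition. For histology references an `uncertain`
level is carried in the confusion table but excluded from metric
computation (the only reading consistent with the published percentage
blocks); for microbiology, culture growth is the positive level.

The exact McNemar test uses the closed binomial form on the discordant
counts `b`, `c`: `p = min(1, 2 * P(X <= min(b, c)))`, `X ~ Binomial(b + c,
1/2)`, with `p = 1` when `b = c`. The suite cross-checks it against full
enumeration for all `b + c <= 12`.

## The synthetic fixture

Clinical slides cannot ship with a package, so the generator builds
H&E-like rasters with known ground truth:

* **Tiles** are 224 × 224 px, standing for one rescaled HPF — the working
  scale at which a neutrophil occupies roughly 40 × 40 px.
* **Neutrophils** are rendered as a lighter basophilic cytoplasm disc
  (radius ~19 px) containing 2–5 dark purple nuclear lobes arranged on a
  ring, with small gaps so the lobes remain separable components. The
  ground-truth box is the 40 px square centred on the cell. Targets are
  rejection-sampled so no two boxes overlap with IOU > 0.3.
* **Distractors** (unlabelled) are lymphocytes (one round dark nucleus
  with a thin rim), anucleate pink red cells, and necrotic fragments
  (2–3 tiny dark specks). Distractors keep a minimum spacing of 28 px from
  each other and from target cells: cell bodies do not interpenetrate, and
  free nuclei drawn on top of each other would fake a lobulated cluster
  that real tissue does not produce.
* **Noise** is achromatic, zero-mean, triangular with standard deviation
  `noise_sd = 0.025` intensity units — a cheap bounded stand-in for sensor
  noise that leaves stain hues intact.
* **Cases** draw per-HPF counts from a negative binomial with mean 8
  (infected) or 2 (sterile) and dispersion (size) 3. The overdispersion
  mimics clustered neutrophil infiltrates; the means straddle the
  diagnostic threshold of 5 with a separation comparable to published
  per-case medians (infected 5–167, sterile 1–3). With these defaults the
  true median of a 200-HPF infected case is ≥ 5 with probability well
  above 0.99. A case can be materialized as individual tiles or as a
  single mosaic slide (tiles on a raster-order grid), the plain-text
  stand-in for a pyramidal whole-slide image.

Everything is a pure function of its parameters and an integer seed;
per-tile sub-seeds are derived by a fixed hash of the case seed and tile
index, so any tile can be regenerated in isolation, byte-identically.

What the fixture does **not** emulate: stain variability, tissue
architecture (vessels, fibrin, granulation tissue), focus artefacts, and
the full morphological spectrum of real nuclei. Passing the synthetic
end-to-end tests therefore demonstrates that the *pipeline machinery*
(tiling, slicing, merging, counting, thresholding, statistics) is correct
and lossless — it says nothing about how a trained detector performs on
real tissue.

## The reference detector

The reference detector encodes the textbook morphological cues as an
explicit score. Nuclear material is segmented by darkness (mean RGB
< 0.5), 4-connected components above 4 px become candidate lobes, and
lobes within 11.6 px (0.29 × scale) of each other are single-linkage
grouped into candidate cells. Each candidate is scored on

* lobe count (2–5 favoured — the lobulated-nucleus cue; a single round
  nucleus scores 0.2),
* total nuclear area relative to the expected cell area `π (scale/2)²`
  (plateau between 5% and 60%), and
* a cytoplasm annulus probe: 48 points on a ring of radius 0.42 × scale
  must be lighter than nuclei, darker than background, and bluer than the
  eosin-pink stroma.

Confidence is the weighted sum `0.30 lobe + 0.35 area + 0.35 annulus`
clipped to `[0, 1]` — the simplest calibration that is monotone in each
cue. The weights and the palette were co-designed with the generator: a
planted neutrophil scores near 1, a lymphocyte ~0.3, a necrotic fragment
~0.3, so the default 0.5 confidence threshold separates them. On 100
seeded default tiles the detector reaches precision and recall ≥ 0.99 /
0.98; this is an end-to-end smoke property of the co-designed pair, not a
claim about real tissue.

## Numerical and degenerate-input choices

* Rounding of pixel coordinates and display values is half-up (base R's
  `round()` is banker's rounding).
* `count_by_hpf()` assigns a detection to the tile containing its box
  centre; a centre exactly on an interior boundary goes to the lower-index
  tile, so each neutrophil is counted exactly once.
* Tie-breaks in greedy matching go to the lowest truth index; in
  interobserver matching (uniform confidences) pairs are claimed in
  descending IOU.
* Empty inputs: an empty label file is a valid empty annotation set; an
  empty detection set evaluates to `fn = n_truths` with undefined
  precision; a cohort below 5 cases is flagged `low_n`.
* Generator capacity: if rejection sampling cannot place a target after
  200 tries the tile raises a capacity error rather than silently
  under-planting.

## Problem sizes used by the test-suite simulations

The end-to-end recovery experiment runs 50 replicate cohorts of 20 cases
(10 infected / 10 sterile) at 200 HPFs per case — 200,000 rendered and
re-detected fields per full run — and requires at least 19 of 20 labels
recovered in every cohort. Distributional checks use ≥ 1,000 simulated
HPFs (counts only). The per-pixel rendering and detection cores are
implemented in C++ for this reason; the R surface stays thin.

## Known limitations

* The reference detector is a fixture-solving oracle, not a clinical
  detector; plug a trained model in through the detector contract for real
  slides.
* Pyramidal scanner formats are out of scope; slides enter either as
  in-memory arrays or as mosaic directories (PNG tiles + CSV manifest).
* Intravascular neutrophils are not excluded — all detections on the
  slide are counted, so the pathologist stays in the loop.
* Published per-case tables print some medians outside their own IQRs;
  the package computes both by the standard definitions and makes no
  attempt to reproduce those particular rows.
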