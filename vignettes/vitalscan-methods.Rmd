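---
title: "How vitalscan scores worm vitality and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How vitalscan scores worm vitality and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vitalscan` converts hourly flatbed-scanner images of multi-arena
microfluidic worm chips into death times, Kaplan–Meier survival curves,
log-rank comparisons, and power-law LT50 dose–response fits. This
vignette explains the model behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

## The measurement model

A nematode in a transilluminated arena is a dark, roughly 1000-pixel
elongated blob at 3200 dpi (≈ 7.9 µm/pixel; an adult is ~1 mm long).
Death is not directly observable in a single image: the observable is
*movement*, the displacement of a worm's centroid between consecutive
hourly scans. The pipeline therefore reduces each arena to a time series
of moving-object counts and applies a quiescence rule to date death.

### Coordinates and containers

Images are numeric matrices indexed `[row, col]`, 1-based, origin
top-left, gray levels on a 0–255 scale whatever the file bit depth. All
rectangles (array bounds, arena regions) are half-open pixel intervals
`[start, stop)` so that regions tile exactly with no off-by-one overlap.
A `frame_series` holds equal-shaped frames with strictly increasing
times rebased so the first frame is hour 0.

### Alignment

Chips sit at slightly different angles on each scanner, so frames are
mapped into the grid's coordinate system with a rigid transform
(rotation + translation, optionally uniform scale) estimated from ≥ 2
user reference-point pairs by 2-D orthogonal Procrustes: centre both
point sets, take the SVD of the cross-covariance, and constrain the
orthogonal factor to a proper rotation. A full affine family was
rejected deliberately — shear has no physical source here and would
distort the thin filter channels. Resampling is bilinear; out-of-bounds
regions are filled with the median border intensity so the frame edge
cannot masquerade as a dark object. Integer translations bypass
interpolation entirely.

### Segmentation and detection

The array bounds are tiled into `rows × cols` equal rectangles in
row-major order from the top-left; when the bounds are not divisible the
remainder pixels go deterministically to the last cells, so cell sizes
differ by at most one pixel. Arena indices are the longitudinal identity
of individuals and never change; excluded arenas are flagged, not
dropped.

Each arena crop is thresholded independently per frame. The scanner's
residual exposure gradient across the bed makes one global threshold
unsafe, while within a ~1 × 4 mm arena the gradient is negligible —
hence per-arena Otsu. Two degenerate cases return an empty mask rather
than an arbitrary split: a constant image, and an image whose two Otsu
classes differ by less than `min_contrast` (default 20 gray levels). The
second guard matters in practice: on a wormless arena Otsu happily
bisects sensor noise near its median, and at ~50% foreground density an
8-connected mask percolates into arbitrarily large "objects". Twenty
gray levels sits far above the noise floor (default noise sd 2) and far
below worm contrast (~140).

Connected components are labeled with 8-connectivity — thin diagonal
worm segments must not fragment — by a small C++ flood fill (the
labeling available in the installed image stack is 4-connected).
Components with `area >= min_area` (default 300 px) are kept: "too
small to be a worm" removes *strictly* smaller objects, applied
consistently and tested at the boundary. Each object carries area,
centroid (mean of member pixel coordinates), bounding box, and mean
intensity. Polarity defaults to dark objects on a light background
(transillumination); both the polarity and the threshold method are
configuration keys.

### Movement, frameshifts, and occupancy

Objects in adjacent frames of one arena are matched greedily by nearest
centroid (smallest Euclidean distance first, each object used once);
leftovers are appearances/disappearances. A matched object *moves* when
its displacement is strictly greater than `move_threshold` (default
7 px — exactly 7 px is not movement). Appearances and disappearances
each count as one moving worm, capped at the larger object count of the
pair: a worm crossing pillar shadows can fragment or vanish from
segmentation, and treating topology change as motion errs on the side
of keeping an animal alive.

A physical disturbance translates the whole image between two scans and
mimics movement in every arena at once. Per frame pair, displacement
vectors are pooled across arenas: if more than `agree_frac` (0.5) of
populated arenas lie within `min_shift` (3 px) of the pooled median
vector, and that median is itself at least `min_shift` long, the median
is subtracted from every displacement and the pair is flagged. With
fewer than three populated arenas there is no consensus to act on. Early
in an experiment, when most animals genuinely move, the consensus test
fails and nothing is subtracted — harmless, because live animals are
moving anyway and a single apparent-movement frame cannot revive a dead
one (see `confirm_m` below). Late in an experiment, when most animals
are still, the consensus is strong and the subtraction prevents the
shift from re-anchoring death times.

Occupancy is the modal detected object count over the first
`occupancy_window_h` hours (default 10), ties broken toward the larger
count. Class 0 arenas are reported `empty`; class "4+" arenas — almost
always bubbles or debris — are `excluded`. Classes 2–3 are scored (the
call dates when the *last* resident stops) and flagged
`multi_occupancy` so users can drop them.

### The death call

Time of death is the last time point with observed movement before a
quiescent run of at least `quiescent_h` hours (default 4) with no
movement. Quiescence is converted to frames via the series' median
interval (ceiling), so sub-hourly series work. To avoid spurious death
calls from stray late movement, movement observed *after* a qualifying
quiet run only resets the call when confirmed by at least `confirm_m`
consecutive moving frames (default 2; `confirm_m = 1` restores
always-reset behaviour). The multi-observation guard is deliberately
configurable because the right count depends on how noisy segmentation
is for a given assay.

The implementation walks backward from the final frame — locate the
last confirmed movement run, then the earliest qualifying quiet run
after it, then the last moving frame before that run — and is proven
equivalent to the forward reading of the rule by a property test
against a brute-force forward state machine on randomized series. If no
qualifying quiet run survives to the end of the series the animal is
censored at the last time point. An occupied arena that never moves is
called dead at the first time point. A series shorter than the
quiescence window is censored with a warning.

One consequence worth knowing: a death within the final `quiescent_h`
hours of a run cannot accumulate a qualifying quiet tail and is
censored, exactly as in a real experiment. The `expected_calls()`
helper translates simulation ground truth through this observability
rule so recovery can be scored honestly.

### Survival statistics

Death calls become subject-level records (event time for `dead`,
censoring time for `censored`; `empty`/`excluded` arenas drop out). The
Kaplan–Meier estimator, two-group log-rank test, and their machinery
are delegated to the `survival` package; tests pin them to
hand-computed product-limit values and an explicit O/E/V table. Median
and quartile lifespans are read off the curve as the smallest time with
S(t) ≤ 0.5 (0.75, 0.25) with *no interpolation*: hourly sampling makes
interpolated precision spurious. Mean ± SEM are computed over observed
deaths only — censored animals cannot contribute a lifespan without
imputation — with the censored count reported alongside and the output
annotated whenever censoring is present. Lethality at time *t* is the
fraction of events at or before *t* among subjects with an event by *t*
or still under observation at *t*.

The LT50 dose–response model `median = a · dose^b` is fitted by least
squares on the log–log scale, matching the convention of standard
"power fit" trendlines (a nonlinear fit would weight doses
differently and not reproduce published coefficients). Its R² is the
log–log regression R²; exactly flat inputs are reported as R² = 1
(zero residual). The fitted model inverts analytically,
`dose = (median/a)^(1/b)`, giving the equivalent dose for an observed
median and the relative sensitivity
`100 · (equivalent_dose/actual_dose − 1)`; inversion refuses `b = 0`.

## The synthetic-data generator

`generate_experiment()` emulates the features of real stacks the
pipeline must survive:

* worms as thickened random-walk polylines whose bounding boxes vary
  with posture, re-drawn each frame while alive; blob pixel area is grown
  to the `worm_area_px` target (default 1000 px), so rendered area is
  insensitive to self-overlap;
* live centroid displacement drawn per frame from
  `Normal(mean, sd)` truncated at zero (defaults 12 ± 2 px), direction
  resampled to stay inside the arena so the commanded step length is
  preserved;
* death at a ground-truth time drawn from exponential, Weibull, or fixed
  distributions — displacement is zero for every frame pair whose
  earlier frame is at or past the death time, which makes ground truth
  unambiguous against the death-call rule; optional post-mortem fading
  (exponential contrast decay per hour) emulates loss of opacity during
  matricidal "bagging", while the default of no fading matches rod-like
  deaths;
* occupancy drawn per arena from a configurable distribution whose
  default (38.8/50.5/9.2/1.2/0.3% for 0/1/2/3/4+) matches observed
  loading statistics; static sub-threshold debris and supra-threshold
  bubbles exercise both sides of the size filter;
* persistent, cumulative whole-frame translations at configurable
  frames; Gaussian gray-level noise added last.

Everything derives from one seed; identical configurations produce
bit-identical stacks and ground truth.

What the generator does **not** emulate: pillar arrays and their
shadows, illumination gradients within an arena, worm–worm contact
postures, embryos/progeny, intensity flicker between scans, and real
scanner noise statistics (assumed Gaussian; the source data do not
characterise it). Passing the recovery tests therefore demonstrates the
correctness of the algorithmic chain under controlled imaging, not
robustness to every artifact of a particular scanner installation. The
parameters most likely to need retuning on real data are
`detection.min_contrast`, `detection.min_area`, and
`vitality.confirm_m`.

## Validation sizes and numerical choices

The test suite validates the full chain at the scale of one array: a
50-arena, 72-frame stack at default geometry (126 × 456 px arenas),
once clean and once with frameshifts injected at frames 59 and 66, with
ground-truth recovery required for ≥ 99% of arenas within ±1 h. The
replicated parameter-recovery check pools three 12-arena, 72-frame
single-occupancy arrays (seeds fixed in the tests) and requires the
true exponential median (40 ln 2 h) to fall in the Brookmeyer–Crowley
95% CI of the pooled Kaplan–Meier median. The death-call rule is
compared with its forward oracle on 1000 random series, and component
labeling with a pure-R flood fill on 100 random masks. These sizes were
chosen to exercise every code path at one-array realism while keeping
the suite fast enough to run routinely.

Numerical conventions, collected: gray levels clipped to [0, 255];
8-bit TIFF output rounds (not truncates) gray levels; Otsu computed on
256 levels over the 0–255 range; rigid-transform estimation tolerates
no fewer than 2 distinct points and reports its residual RMS; automatic
arena-frame QC flags a frame when its mean intensity deviates from the
arena's series median by more than `n_sd` (default 5) robust standard
deviations (MAD scaled for normal consistency — a plain sd would be
inflated by the very outliers being hunted); yield is
`100 · scored / capacity` with one decimal at the reporting layer;
p-values print to 4 significant figures, with "p < 0.0001" applied only
when formatting reports.

## Known limitations

* Individuals are not tracked through identity swaps within an arena;
  multi-occupancy calls date the last survivor.
* Arena-level exclusion granularity only (no sub-arena masks), and
  rectangular arenas only.
* The moving-count series, not per-worm tracks, drives the death call;
  two animals alternating movement are indistinguishable from one
  animal moving continuously.
* Log-rank is two-group; stratified or trend tests, Cox models, and
  mean-comparison ANOVA are out of scope (standard tools consume the
  exported CSVs).
* Greenwood/confidence bands beyond the median CI used in validation
  are not exported.
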