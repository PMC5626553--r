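---
title: "filotrack: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{filotrack: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `filotrack`, the parameters
that matter, the numerical choices made where the procedure was
genuinely open, and what the synthetic fixtures do and do not
establish about real data.

## Segmentation model

Filopodia are thin (a few hundred nm, i.e. a few pixels at 65 nm
sampling) and dim relative to the cell body, so raw thresholding
either loses them or floods the background. The pipeline therefore
convolves each mapping-channel frame with a Laplacian-of-Gaussian
kernel of scale $\sigma$ (in pixels),

$$f(x,y) = -\frac{1}{\pi\sigma^4}\Bigl(1-\tfrac{x^2+y^2}{2\sigma^2}\Bigr)
e^{-\frac{x^2+y^2}{2\sigma^2}},$$

which acts as a band-pass matched to ridge-like structures of width
$\approx 2\sqrt{2\ln 2}\,\sigma$ px (the Gaussian FWHM). **Sign
convention:** the kernel is applied exactly as written, so bright
structures give *negative* responses; segmentation thresholds the
negated response, making the cell interior high. The response of a
homogeneous interior is near zero (the kernel integrates to ~0), so
binarization yields an edge ring; the mask is hole-filled to recover
solid objects before the largest 8-connected component is taken as the
cell.

Body and protrusions are separated by $n$ binary erosions followed by
$n$ dilations (the morphological opening deletes structures thinner
than $\approx 2n{+}1$ px); subtracting the opened body from the mask
leaves the filopodia. Two numerical details:

* **Structuring element.** Default is the 3×3 square (the common
  binary-morphology default); a diamond ("disc") element is an option.
  Opening a curved boundary with a square element leaves occasional
  1–few-px residues at diagonal extremes. Components smaller than
  `min_protrusion_px` (default 9 px, well below the cross-section of
  any resolvable filopodium, which is at least the FWHM width of
  ~6 px across by a few pixels long) are therefore merged back into
  the body rather than reported as protrusions.
* **Over-erosion.** If $n$ erosions empty the mask entirely the
  function stops with an explicit error instead of returning an empty
  segmentation; `suggest_ed_iterations()` (experimental) proposes the
  smallest $n$ whose opening has converged.

The base of a protrusion is the centroid of its body-contact pixels
snapped to the nearest body-boundary pixel (the boundary is an ordered
8-connected contour); the tip is the protrusion pixel farthest from
the base. For backward-turning or looping shapes the farthest-pixel
rule misassigns the tip; such shapes are outside the intended scope
and are meant to be removed via track edits.

## Length, width and the end correction

Length is estimated as half the protrusion-mask perimeter minus an end
correction. For a capsule (rectangle of axis length $\ell$ and width
$w$ with a semicircular cap), half the closed-mask perimeter is
$\ell + \pi w/4 + w/2$, while the true base-to-tip extent is
$\ell + w/2$; the overestimate decomposes into the cap's half-arc
excess $(\pi-2)w/4$ plus half the base edge $w/2$, i.e. $\pi w/4$
total. The correction constant defaults to $\pi/4$ (in units of $w$)
and was validated against rasterized capsules of known length (2–15
µm): the package requires every capsule within 10% and Pearson
r ≥ 0.97 between true and measured lengths, which the test suite
verifies on ≥ 50 capsules. The width is not measured per protrusion
but taken as the detection-scale FWHM, $w = 2\sqrt{2\ln 2}\sigma\,px$
(≈ 398 nm at $\sigma = 2.6$, 65 nm pixels). The factor
$\min[(D/w)^2, 1]$ (D = base–tip distance) suppresses the correction
for stubs wider than they are long.

Perimeters are measured on the traced 8-connected contour with the
Vossepoel–Smeulders chain-code correction (0.980 per axial step,
1.406 per diagonal step, −0.091 per corner), which reduces the
staircase bias of digitized smooth outlines from ~5–8% to ~1–2%; this
matters because the length estimator inherits any perimeter bias
directly.

## Movement metrics

DCTM (direction-corrected tip movement) is the tip displacement from
the previous frame projected onto the *current* base→tip unit axis;
DCBM is the analogous base projection; both are reported in nm/s. The
projection removes apparent movement from sideways swinging: under a
rigid rotation by $\theta$ per frame the residual is exactly
$\sin(\theta/2)$ of the tip speed (the chord–axis angle), so slow
swinging (≲0.6°/frame) contributes < 0.5% while genuine elongation
passes through unchanged (for a static base and fixed angle, DCTM
equals dL exactly). DCTM assumes no retrograde flow; it is a proxy for
net polymerization at the tip, not for flux.

Movement series are cleaned with a 0.5–99.5 percentile filter (values
strictly outside the band become missing — this rejects out-of-focus
spikes) and smoothed with a centered five-step rolling mean (window
truncated at the ends, missing values ignored but never interpolated;
any window that is entirely missing stays missing). Missing frames
propagate: metrics that straddle a tracking gap are missing.

States are assigned by averaging the smoothed series over a centered
10-s window (window length `round(10 / frame_interval_s)` frames, so
non-2-s movies are supported) and comparing with ±32.5 nm/s — one
pixel per frame at the reference calibration (65 nm pixels, 2 s
frames). Tip persistence is the first zero crossing of the biased
sample autocorrelation of the mean-subtracted smoothed series,
linearly interpolated between lags and converted to seconds; because
the biased ACF sums to −1/2 over positive lags, a crossing always
exists within the available lags, and the censored flag exists only
as a guard.

## Fluorescence

All fluorescence means are computed on the measurement channel:
projection (protrusion mask), tip and base (disks of radius
`tip_radius_px`, default $w/2$; tip fitting can relocate the tip to
the intensity-weighted mean of strict local maxima within
$r = \mathrm{clamp}(\sqrt{(area/2)/\pi}, 3, 20)$ px and set the radius
to MSE/2), thresholded tip (Otsu within the tip disk, separating tip
signal from background), and body. Background is the mean of a 3-px
annulus starting 2 px outside the cell mask — "near the boundary"
made concrete; the gap avoids mask-edge blur. Normalized values are
$(x - bg)/(body - bg)$ and are flagged undefined when the body does
not exceed background. Adding a constant to the whole image leaves
normalized values unchanged (tested to 1e−9).

Pre-formation base prediction walks backwards from a track's first
frame: in each earlier frame the predicted base is the boundary point
nearest the (predicted) base of the following frame, up to
`base_back_frames` (default 20) frames; the pre-formation summary is
the mean normalized base fluorescence of the last 3 frames before
formation. Tracks that start in frame 1 have no observed formation and
yield no prediction — use `min_start_frame = 2` filtering when this
measurement is the point of the experiment.

## Tracking

The linking cost is read as
$\bigl(d_{base} + d_{tip}\bigr) / \text{overlap} \times \delta T$:
distances penalize, mask overlap rewards, longer gaps penalize. The
printed form of this cost is typographically ambiguous about what
multiplies $\delta T$; this parse is the one under which overlap acts
as the identity criterion and cost grows with gap length, and it is
fixed in code and covered by unit tests. Zero overlap makes a link
inadmissible (cost +∞). Births and deaths are handled by padding the
cost matrix with a no-link cost equal to the 95th percentile of the
finite candidate costs (capped by `max_cost` when finite); the
assignment itself is solved exactly (verified against exhaustive
permutation enumeration up to 6×6). Gap closing is off by default
(one-step linking); `max_gap` enables re-linking across short
detection dropouts, with the gap entering the cost through
$\delta T$.

Track filters default to: ≥ 3 frames, maximum length ≥ 1.8 µm, at
least one frame-to-frame |dL| ≥ 0.1 µm (removes perfectly static
specks), mean waviness ≤ 0.35. Edits (delete, trim, relink) are
explicit data, serialized to CSV and replayed identically; dangling
references fail loudly so an edit list cannot be applied twice
silently.

## Statistics layer

* **CCF.** Classical sample cross-correlation: overall means and
  standard deviations, denominator $n$; computed in-package so missing
  pairs can be dropped (with the biased-estimator rescaling), and
  verified equal to `stats::ccf()` on complete series. Negative
  offsets mean fluorescence precedes movement. Tracks with < 17 paired
  points are excluded — too short for meaningful block randomization.
* **Clustering.** Euclidean distance between CCF vectors restricted to
  −6…+6 s offsets; complete linkage by default (the linkage is not
  dictated by the method and is exposed as a parameter); the cut (k or
  height) is an explicit argument because choosing it is a judgement
  call. The "responding" subcluster is the cluster with the highest
  mean CCF at offset 0.
* **Block randomization.** Each track's smoothed DCTM is reshuffled in
  blocks of 8 time points (16 s — on the order of tip persistence, so
  short-range autocorrelation survives), CCFs are recomputed and
  reclustered identically, and a randomization is accepted only when
  the responding subcluster's size is within 15% of the real one
  (minimizing cluster-size bias). The p-value is the fraction of
  accepted randomizations whose subcluster mean CCF(0) reaches the
  observed one, reported as "< 1/n" when none do (no +1 correction by
  default). The test aborts with diagnostics if fewer than 1% of
  attempts are accepted.
* **Markov nulls.** Each series is binned into 9 equal-width intervals
  over its observed range ("equal-sized" read as equal-width, not
  equal-count — the reading under which the bins form a fixed grid of
  the variable's range); transition probabilities are estimated from
  observed transitions, and any *visited* state with no outgoing
  observation (e.g. an extreme reached only at the final time point)
  makes the matrix invalid and the track is discarded with a reason —
  constant series are degenerate for the same reason. Independent
  chains for fluorescence and movement, both started from the observed
  initial state, are simulated 10,000 times; the observed correlation
  of the binned series is compared one-sidedly (≥) with the simulated
  correlations. Simulated state occupancy is property-tested to
  converge to the fitted chain's empirical distribution.
* **Correlation mining.** Spearman ρ with pairwise-complete
  observations and Holm adjustment over all unique off-diagonal
  tests; constant columns yield flagged NAs.

Reproducibility: one top-level seed drives every stochastic stage;
two runs with the same configuration and seed produce byte-identical
tables (tested via checksums).

## Synthetic fixtures: scope and limits

`generate_movie()` emulates the reference imaging regime — 65 nm
pixels, 2 s frames, a bright body disk with capsule-shaped filopodia
(the geometry the length correction is derived for), tip-localized
Gaussian spots in the measurement channel, optional pre-formation
boundary accumulation, and additive Gaussian noise rounded to integer
camera counts. Intensity levels (body 200, protrusion 180, background
10, noise sd 4) give a contrast regime where auto-thresholding is
unambiguous. `generate_coupled_series()` produces AR(1) movement and
fluorescence with an exact population coupling at a configurable lead.

What passing tests on these fixtures shows: the geometry, linking,
metric and statistical machinery is internally correct at realistic
scales and calibrations. What it does not show: robustness to uneven
illumination, photobleaching, crossing or branching filopodia,
focus drift, or non-Gaussian camera noise — real data needs parameter
tuning (σ, threshold method, ED iterations) and manual review of the
reconstruction via the editing interface.

Problem sizes used by the test-suite and the acceptance script are the
package's own choices for desk-scale verification: 60 capsules for the
length oracle, a 6-filopodium 120-frame movie for tracking recovery,
100 replicates for CCF null bounds, 200 seeded runs (99 accepted
randomizations each) for the randomization calibration, and 10,000
simulations for the Markov null.

## Known limitations

* Coordinates are 1-based (row, col) matrix indices, the natural R
  convention; exported tables use x = column, y = row with a units
  header.
* Straightness/waviness are unreliable below ~2w and flagged; branched
  structures make both meaningless.
* The Euclidean-farthest tip rule fails on looping filopodia.
* Auto-threshold values may differ from other implementations by ±1
  gray level (different histogram binning); tests therefore assert
  classifications, not raw threshold values.
* `boundary_profile()`'s velocity is an intensity-kinetics proxy
  (signed temporal derivative at fixed boundary coordinates), not a
  tracked edge displacement.
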