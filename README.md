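# filotrack

Automated reconstruction and quantitative analysis of **filopodia** —
the thin, actin-rich protrusions that growth cones and other motile
cells extend — from multi-channel fluorescence time-lapse microscopy.
The package is aimed at cell biologists who image a membrane marker
("mapping" channel) together with a labelled protein of interest
("measurement" channel) and want per-filopodium morphodynamics and
fluorescence time series without manual tracing, plus the downstream
statistics to ask whether protein accumulation at filopodium tips is
coupled to tip movement.

## What it computes

**Segmentation.** Each mapping-channel frame is convolved with a
Laplacian-of-Gaussian kernel

$$f(x,y) = -\frac{1}{\pi\sigma^4}\Bigl(1-\frac{x^2+y^2}{2\sigma^2}\Bigr)\,
e^{-\frac{x^2+y^2}{2\sigma^2}},$$

binarized with a choice of auto-threshold algorithms (Renyi entropy,
Huang, Otsu, Triangle, Mean; an adaptive eight-direction variant is
available), and the largest object is taken as the cell body. *n*
erosions followed by *n* dilations delete thin protrusions; the
difference between the mask and this opened body yields the individual
filopodia, each with a base (contact with the body boundary) and a tip
(the pixel farthest from the base). Detached fragments can be rejoined
by drawing shortest connecting lines, and tips can be refined against
the measurement channel.

**Tracking.** Filopodia are linked frame to frame by a one-step
Hungarian linear assignment with cost

$$\mathrm{cost} = \frac{\operatorname{dist}(base_1,base_2) +
\operatorname{dist}(tip_1,tip_2)}{\text{overlap area}}\;\delta T,$$

where zero mask overlap forbids a link. Tracks are filtered on
duration, maximum length, length change and waviness, and can be
edited programmatically (delete / trim / relink) with a replayable
edits file.

**Morphodynamics.** Corrected length (half perimeter minus a
capsule-end correction scaled by $\min[(D/w)^2,1]$, with
$w = 2\sqrt{2\ln 2}\,\sigma\,px$ the FWHM width), straightness and
waviness, direction-corrected tip and base movement (DCTM/DCBM: the
displacement projected onto the current base→tip axis, in nm/s), tip
persistence (first zero of the movement autocorrelation), state
classification (extending / retracting / stalling at ±32.5 nm/s over a
10-s window), and the fluorescence panel (projection, tip, thresholded
tip, base, body means; background-corrected ratios to the body). The
base position can be back-predicted before a filopodium forms, giving
pre-formation fluorescence at the nascent site.

**Statistics.** Track summaries, Spearman correlation matrices with
Holm adjustment, fluorescence–movement cross-correlation functions
(negative offsets = fluorescence precedes movement), hierarchical
clustering of CCF profiles over −6…+6 s offsets, a block-randomization
significance test (DCTM reshuffled in blocks of 8 points to preserve
autocorrelation; acceptance requires a matched responding-subcluster
size), and discrete-time Markov-chain null models (series binned into
9 states; 10,000 independent-chain simulation pairs per track).

**Synthetic data.** `generate_movie()` rasterizes a ground-truthed
growth-cone-like body with capsule-shaped dynamic filopodia and
tip-enriched fluorescence; `generate_coupled_series()` makes
fluorescence/movement pairs with known coupling, lag, and
autocorrelation. Every stage of the pipeline is tested against these
generators.

## Worked example

```r
library(filotrack)

spec <- movie_spec(n_frames = 20, seed = 42, noise_sd = 4,
  filopodia = list(
    list(angle_deg = 30,  velocity_nm_s = 50,  initial_length_um = 1.2),
    list(angle_deg = 150, velocity_nm_s = 25,  initial_length_um = 1.8),
    list(angle_deg = 260, velocity_nm_s = -15, initial_length_um = 3.0)))
movie <- generate_movie(spec)

cfg <- pipeline_config(output_dir = file.path(tempdir(), "demo"),
                       n_channels = 2, measurement_channel = 2, seed = 1,
                       log_level = "quiet")
res <- run_pipeline(cfg, timelapse = as_timelapse(movie))
res$summaries[, c("track_id", "max_length_um", "median_tip_extension_rate",
                  "frac_extending", "frac_stalling", "tip_persistence_s",
                  "mean_tip_fluor")]
```

```
  track_id max_length_um median_tip_extension_rate frac_extending frac_stalling
1        1          2.95                        NA              0             1
2        2          2.92                      49.7              1             0
  tip_persistence_s mean_tip_fluor
1              1.69           1.24
2              3.48           1.26
```

Two of the three simulated filopodia pass the default track filters.
Track 2 is the 50 nm/s extender: its median tip extension rate is
recovered as 49.7 nm/s and it spends all classified time in the
extending state. Track 1 moves at 25 nm/s — below the 32.5 nm/s state
threshold — so it is classified as stalling throughout and has no
extension-rate entry. `mean_tip_fluor` is the normalized
(background-corrected, body-relative) tip fluorescence; values above 1
reflect the simulated tip enrichment. The output directory contains
label masks (TIFF), the boundary polygon, per-frame metrics, track
summaries, CCF profiles and cluster assignments (CSV with unit
headers), an analysis report (JSON) and the resolved configuration
(YAML).

A thin command-line wrapper for simulate / run / batch lives at
`inst/cli/filotrack`.

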