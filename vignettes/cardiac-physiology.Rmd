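---
title: "Quantifying zebrafish cardiac physiology from landmark tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zebrafish cardiac physiology from landmark tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Markerless pose estimation can track the beating ventricle of a zebrafish
embryo in ordinary bright-field video: eight boundary points, labelled 1-8
around the chamber, are located in every frame together with a tracking
likelihood. zebraheart turns those per-frame coordinates into a quantitative
cardiac physiology panel. The chain is:

1. **Likelihood filtering.** Samples below a confidence cutoff are replaced
   by linear interpolation between flanking confident frames (or whole
   frames are dropped).
2. **Geometry.** The short axis $D_s$ is the distance between points 1 and
   5, the long axis $D_l$ between points 3 and 7. The ventricle is modelled
   as a prolate spheroid with polar diameter $D_l$ and equatorial diameter
   $D_s$ in both transverse directions, so the per-frame volume is
   $V = \tfrac{\pi}{6} D_l D_s^2$.
3. **Beat segmentation.** Diastolic peaks of the volume trace define cardiac
   cycles; the volume minimum between consecutive peaks is the systolic
   frame.
4. **The panel.** Per cycle $i$: $SV_i = EDV_i - ESV_i$,
   $EF_i = SV_i / EDV_i \times 100$, and
   $SF_i = (D_{sd,i} - D_{ss,i})/D_{ss,i} \times 100$ where $D_{sd}$ and
   $D_{ss}$ are the short-axis diameters at diastole and systole. Heart rate
   is the average of $60/\mathrm{IBI}_i$ over the inter-beat intervals, and
   $CO = \overline{SV} \times HR$.
5. **Heart-rate variability.** The Poincaré plot scatters each interval
   against the next; with $d_n = \mathrm{IBI}_n - \mathrm{IBI}_{n+1}$ and
   $s_n = \mathrm{IBI}_n + \mathrm{IBI}_{n+1}$,
   $sd1 = \sqrt{\mathrm{Var}(d)/2}$ captures instantaneous beat-to-beat
   variability and $sd2 = \sqrt{\mathrm{Var}(s)/2}$ longer-term variability.

All of this is wrapped by the single fitting function `heart_scan()`, which
returns a classed object with `print`, `summary`, `coef`, `plot`,
`residuals` and `simulate` methods.

```{r, eval = FALSE}
library(zebraheart)
sim <- simulate_track(preset_spec("control", seed = 1))
fit <- heart_scan(sim$track)
coef(fit)
```

## Model assumptions

The spheroid volume model is deliberately minimal. It assumes the ventricle
is a prolate spheroid whose equatorial cross-section is circular with
diameter $D_s$ — the same assumption that makes single-plane
echocardiographic volume estimation possible. The eight boundary points are
used exactly as labelled: only the 1-5 and 3-7 pairs enter the axes, the
remaining points contribute to the centroid used for motion diagnostics. No
ellipse is fitted to the ring; the labelling scheme defines the axes, and
fitting would change the measurand. The atrium is out of scope: its
irregular shape defeats this kind of morphology-based quantification.

Because every quantity is a function of inter-landmark distances, the panel
is invariant under rigid whole-heart motion. Slide drift and sudden
displacement of the embryo move every landmark equally, change the centroid
trajectory — where they can be seen and diagnosed — and leave $D_s$, $D_l$,
$V$ and every derived parameter untouched. The test suite asserts this
invariance both algebraically (translation/rotation of all coordinates) and
through the simulator's drift and jump artifacts.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fps` | 30 | acquisition frame rate; the tables carry no timebase |
| `p_cutoff` | 0.6 | likelihood below which a sample is interpolated |
| `smooth_window` | 5 frames | moving average used only to *locate* beats |
| `min_prominence_frac` | 0.3 | peak prominence as a fraction of the trace's P5-P95 spread |
| `hr_min_bpm`, `hr_max_bpm` | 40, 400 | physiological band; sets minimum peak separation and flags outliers |
| `sf_denominator` | `"systolic"` | SF divides by $D_{ss}$; `"diastolic"` gives the conventional $D_{sd}$ form |
| `confidence` | 0.95 | Poincaré ellipse coverage |

The 0.6 cutoff is the conventional default for pose-estimation likelihoods.
The 5-frame window spans about 167 ms at 30 fps, comfortably shorter than
any cycle in the 40-400 bpm band. The prominence threshold is scale-free —
relative to the trace's own spread — which makes detection invariant to
affine rescaling of the volume (units, calibration, offset). The shortening
fraction is computed with the systolic diameter in the denominator by
default, matching the workflow this package reproduces; because the
conventional echocardiographic definition divides by the diastolic
diameter instead, that variant is one switch away and the convention used
is recorded in the output metadata.

Heart rate is reported two ways: the default averages the instantaneous
rates $60/\mathrm{IBI}_i$; `bpm_count_based` divides total beats by the
record span. They agree exactly for perfectly regular rhythms and diverge
slightly (arithmetic vs harmonic weighting) under variability; both are
retained because either reading of "one minute divided by the interval
between beats" is defensible.

## Beat detection and extreme-value estimation

The beat detector is an explicit re-implementation of the peak-analysis
stage that interactive tools perform: local maxima of the smoothed volume
trace, kept when their topographic prominence exceeds the threshold and
when they are at least $fps \cdot 60 / hr_{max}$ frames apart (greedy
thinning, highest peak first). A peak whose base is cut off by the start or
end of the recording is assessed on its complete side only — a beat
truncated by the recording window is still a beat; without this rule the
first and last beats of every record would be silently lost.

Extreme *values* need more care than extreme *locations*. Two systematic
errors afflict the naive "read the volume at the detected frame" rule at
these recording conditions (about 12 frames per beat, a systole of ~4
frames):

* a moving average shifts the extremum of an asymmetric pulse toward its
  flatter side, so the smoothed argmin sits 1-2 frames off the true trough;
* the true extremum falls between frames, and the narrow systolic trough
  rises several percent of the pulse amplitude within half a frame.

Together these bias ESV upward by 2-3% and ejection fraction downward by
2-3 percentage points — comparable to real treatment effects. The detector
therefore separates three roles: beat *timing* (intervals, heart rate, HRV)
comes from the stable heavy-smoother peak positions; the reported
diastole/systole *frames* are refined within ±2 frames on a light 3-frame
smoother; and the *values* (EDV, ESV, $D_{sd}$, $D_{ss}$) are estimated by
a local quadratic least-squares fit to the unsmoothed series over the
refined frame ±2, evaluated at the fitted vertex (falling back to the frame
value if the fitted curvature has the wrong sign). The quadratic read
removes both the discretization and the smoothing-shift bias while
averaging tracking noise over five frames; on simulated recordings with 2%
landmark jitter it brings EF recovery from about −3 to within ±1 percentage
point of the generating waveform. `value_read = "frame"` restores the
literal frame read for comparison. Smoothed values are never reported, so
the smoother cannot attenuate the measured volumes.

Cycles whose implied instantaneous rate leaves the physiological band are
flagged with a reason and kept: a sudden embryo movement typically produces
exactly one such cycle, and silently dropping it would hide the artifact
the centroid diagnostics are meant to expose.

## The synthetic beating heart

`simulate_track()` generates the landmark tracks the analysis assumes, with
complete ground truth. Inter-beat intervals are $60/hr$ plus a stationary
AR(1) Gaussian process — the minimal process that separates long-term from
instantaneous variability, so $sd2 > sd1$ for positive autocorrelation.
Within each beat the volume follows an asymmetric raised-cosine pulse from
EDV down to ESV over `systolic_fraction` (default 0.35) of the cycle and
back. Frame-wise, the landmark ring is placed at 45° increments on the
ellipse whose axes realize that volume at aspect ratio $D_l/D_s = 1.2$ (a
slightly elongated, primarily spherical ovoid), then translated by drift
and jump displacements, jittered per landmark, and given sub-cutoff
likelihoods at a `dropout_rate` fraction of samples with grossly corrupted
positions. The first diastolic peak is anchored half an interval into the
record so that every true peak is an interior maximum of the sampled trace.

Defaults encode a 1-minute, 30 fps recording of a 2-3 dpf embryo: 150 bpm,
EDV $4\times10^5$ px³, ESV $2\times10^5$ px³ (EF 50%), interval jitter SD
50 ms with lag-1 autocorrelation 0.4 — beat-to-beat variability of a few
tens of milliseconds is what embryonic recordings at this frame rate can
actually resolve, since peak timing is quantized at 33 ms. The treatment
presets move only effect *directions* that matter: `ethanol_like` lowers
rate and both volume extremes; `ponatinib_like` additionally shrinks the
ejected fraction of the pulse and inflates interval jitter and its
autocorrelation (arrhythmia). The magnitudes are simulator conventions, not
measurements, and the package asserts only their signs.

What the generator does not emulate: rasterized video and the pose
estimator itself (lighting, occlusion, network errors that correlate across
landmarks), pericardial-edema shape change beyond its volumetric signature,
two-chamber interaction, and non-stationary rhythm changes within a record.
Passing tests therefore validate the *post-tracking* analysis, not the
tracking.

## Numerical choices and degenerate inputs

* Flat peak plateaus collapse to their earliest frame.
* A volume trace with no variation (spread below $10^{-9}$ of its median)
  raises an insufficient-beats error rather than segmenting rounding noise.
* Leading/trailing likelihood gaps take the nearest confident value; no
  extrapolation. A point confident in zero frames is an unrecoverable
  track.
* Poincaré variances use the $n-1$ denominator, unbiased at the small beat
  counts of 1-minute records; the 0.95 ellipse uses the 2-df chi-square
  radius $\sqrt{\chi^2_{2,0.95}}$ and is purely descriptive.
* Sample sizes in the test suite: 1-minute simulated records (1800 frames,
  ~150 beats), ten seeds for recovery and directionality studies, and
  $10^6$ Monte-Carlo samples for the ellipsoid volume oracle.

## Limitations

Volumes are in cubed pixels unless a micrometer scale is supplied, so
cross-fish comparisons assume equal magnification. The spheroid model's
accuracy degrades if the ventricle's transverse section is far from
circular. Heart rates above ~400 bpm at 30 fps approach the 6-frame
resolvability floor, and sd1 estimates carry a quantization floor of about
10 ms at this frame rate. The HDF dialect of tracking tables is not
supported by this build; the three-header CSV dialect is.
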