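---
title: "From photon counts to paired circadian statistics: the glowtrack methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From photon counts to paired circadian statistics: the glowtrack methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glowtrack)
```

`glowtrack` converts time-lapse bioluminescence recordings of single
flies in capillary tubes into three simultaneous time series per fly —
peripheral molecular-clock activity, locomotor activity and sleep — and
quantifies the rhythmicity, period and cross-rhythm coupling of each.
This vignette explains the underlying model, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The measurement model

A fly expressing a clock-protein::luciferase fusion emits photons in
proportion to clock-gene expression. The camera integrates photons for
300 s per frame at 16-bit depth; 300 s is deliberately matched to the
operational definition of fly sleep (immobility exceeding five
minutes), so one frame is the natural unit of sleep detection. The
recording runs in constant darkness and starts at subjective dusk
(CT12), so hours since recording start map onto circadian phase with
the subjective night first.

Within a frame, the fly's photons are distributed along the tube
according to its movement: a fly that rested leaves a compact bright
spot, a fly that walked leaves a smear. Everything downstream is a
decomposition of that 1-D photon distribution.

### Preprocessing

1. **Global background**: the mean of the 64 x 64 pixel patch at the
   bottom-right of each frame (an area without tubes) is subtracted
   from all pixels, per frame, so slow camera drift is tracked.
2. **Alignment**: three bright marker spots at tray corners give the
   tray's rotation; every frame is rotated about the image centre by
   the opposite angle (bilinear interpolation) so tube long axes run
   parallel to the image y-axis. Marker clicks are refined to
   sub-pixel centroids by intensity-weighted centre of mass in a small
   window. The two shortest marker-to-marker segments are tray edges;
   their length-weighted mean angular deviation modulo 90 degrees is
   the rotation, which makes the estimate invariant to marker order.
3. **Tube geometry**: on a reference image (per-pixel mean of the
   first 24 h of frames, which washes fly positions out of the
   projection), the x-profile of intensities summed along y has one
   peak per tube column and the y-profile one band per tube row. Each
   tube gets a 17-px-wide rectangle centred on its column peak, and a
   paired 5-px-wide background rectangle centred midway to the
   neighbouring column (the outermost column uses its inner-side
   midpoint). The inter-tube rectangles also serve as a row-wise
   baseline when detecting row bands, which cancels the smooth
   vignette gradient that would otherwise bridge the gap between
   rows. When corner markers add flanking peaks to the x-profile, the
   window of peaks with the most uniform pitch is kept.
4. **Local background**: per tube and frame, the mean of its
   background rectangle is subtracted from that tube's pixels only,
   correcting the vignette. Negative pixels are retained on the
   quantitative path so sums stay unbiased.

### Activity/rest partition

Each tube rectangle is divided into 46 bins of 4 px along its length.
Resting-fly peaks are found on a contrast-enhanced copy of the frame:
a bin holds a resting fly when its maximum single-pixel intensity
strictly exceeds the tube's mean bin sum plus one standard deviation;
adjacent flagged bins merge into one peak (one sub-threshold bin
separates peaks), anchored at the intensity-weighted centroid.

The enhancement is a linear stretch of the globally
background-subtracted frame from its **median** to its **maximum**.
This choice was genuinely open. Percentile pairs that clip below the
frame maximum flatten the fly spot and destroy the peak-pixel contrast
the rule needs, and an upper percentile anywhere below ~99.95% falls
inside the background noise of a sparse bioluminescence scene (fly
spots occupy well under 0.1% of pixels); stretching from the median
sends the background to zero while leaving the spot shape intact. Only
peak/no-peak decisions depend on the enhanced data; all quantities are
measured on the raw data.

On the raw profile, with `m` the mean bin sum excluding peak bins
("mean without peaks"), activity contributes the rectangle
`A_active = max(0, m) * 46` over the whole tube (the active smear
underlies the peaks too) and rest contributes
`A_rest = sum over peak bins of max(0, s_b - m)`. The exposure is
split proportionally, `Time_active = 300 * A_active / (A_active +
A_rest)`, `Time_rest = 300 - Time_active`, so the two sum to 300 s
exactly by construction. Frames with `m < 0` (artefactual background)
or `A_active + A_rest = 0` (fly too dim) are flagged and their
partition and bioluminescence linearly interpolated from the nearest
good frames. Total tube bioluminescence — the molecular-clock signal —
is simply the background-adjusted pixel sum over the tube rectangle.

### Sleep and consolidation

A sleep episode is a maximal run of at least two consecutive frames,
each containing exactly one peak, with every anchor within one bin
(4 px, about one fly length) of the first frame's anchor; the run is
sleep when its summed rest time exceeds 300 s. Two readings of the
continuation rule are possible — every frame single-peak, or merely a
peak at the episode position — and both are implemented
(`assign_sleep_episodes(strict = )`); the strict reading is the
default because the assay is intentionally conservative about calling
brief rests sleep. Each frame of an episode carries the episode's
total rest duration (minutes) as its sleep-consolidation value; other
frames carry 0.

### Binning and rhythm analysis

Per-frame series are reduced to 30-min bins (six frames): sums for
times and bioluminescence (activity reported as percent of 1800 s),
mean of non-zero entries for consolidation. A 7-day recording gives
n = 336 samples per signal.

The slow trend — dominated by the exponential decay of the luciferin
substrate — is removed by **division**: the trend is the series passed
through a zero-phase order-2 Butterworth low-pass filter with cutoff
period 72 h (applied forward and backward over a full-length
reflection-padded copy; the filter is applied to the mean-removed
series and the mean restored afterwards, which makes a constant series
an exact fixed point), and the detrended series is the pointwise ratio,
renormalised by its own mean so the result has mean exactly 1.
Division rather than subtraction removes the measurement units, so
molecular and behavioural rhythms are directly comparable.

Rhythmicity uses the correlogram: the biased (divide-by-n) sample
autocorrelation over lags 0 to n/2. The rhythmicity statistic is the
height of the highest positive local maximum of the ACF at lags
between 14 and 38 h, divided by the white-noise 95% line `2/sqrt(n)`;
`RS > 1.5` defines rhythmicity, and the period is the peak lag refined
by three-point parabolic interpolation. Three numerical points are
worth recording:

* the biased ACF estimator tapers a noiseless sinusoid's 24-h peak to
  `(n - 48)/n ~ 0.86` at n = 336, so the ideal RS is ~7.9 rather than
  `sqrt(n)/2 ~ 9.2`; the unbiased estimator would undo the taper but
  its variance grows with lag and inflates the white-noise
  false-positive rate well beyond 5%, so the biased form is used;
* the 14–38 h window excludes the lag-0 shoulder and accommodates
  strongly shortened or lengthened mutant periods;
* the flat `2/sqrt(n)` confidence line is used rather than a
  lag-dependent band; at circadian lags and n = 336 the two are close,
  but absolute RS values are therefore comparable only within this
  convention.

Behavioural series pass through the same detrend for symmetry; when a
behavioural series' low-pass trend touches zero (long stretches
without sleep make the consolidation trend non-positive), the fit
falls back to plain mean normalisation, which leaves the
autocorrelation — and hence RS and period — unchanged, since the ACF
is affine-invariant.

### Cohort statistics

Per-fly results feed paired statistics: Pearson correlation of RS
values and of periods between signal pairs, restricted to flies
rhythmic on both signals (p-values from the exact t-transform,
two-sided — the direction of an effect is not assumed), a paired
t-test on the per-fly period difference, percent-rhythmic summaries,
population mean ± SEM traces, and a chi-square comparison of the
three-way time partition (sleep / rest shorter than 5 min / activity)
across cohorts, with the contingency table counted in 300-s
frame-equivalents so the test operates on event counts.

## The synthetic-data generator

The simulator produces multi-page 16-bit frame stacks with exported
ground truth, so the full pipeline can be validated at desk scale.

**Behaviour** is a two-state semi-Markov chain at 10-s resolution:
alternating active and rest bouts with exponential lengths whose means
are sinusoidally modulated over the circadian cycle in the `control`
scenario. Defaults (units: minutes; means modulated as
`base * exp(k * cos)`):

| parameter | default | meaning |
|---|---|---|
| `rest_mean_min`, `rest_mod` | 32, 0.84 | rest-bout mean 14 min at the daytime trough, 75 min at the early-night peak (`rest_peak_h = 3`) — consolidated night sleep with episodes of several hours, day naps of tens of minutes |
| `act_mean_min`, `act_mod` | 4, 1.6 | active-bout mean peaking twice per cycle just before subjective dusk and dawn (`act_peak_h = 11.5`) — the bimodal activity profile, with about half the time active at the evening peak |
| `homog_rest_mean_min`, `homog_act_mean_min` | 10, 4 | bout means for the time-homogeneous scenarios; dysrhythmic flies are restless with short fragmented sleep |
| `step_sd_bins` | 12 | active random-walk step per 10-s tick; the fly covers the tube within a bout, so successive rest positions are nearly independent |

`clock_only` keeps behaviour time-homogeneous while the photon clock
still cycles; `arrhythmic` also sets the clock amplitude to zero.
Ground-truth sleep episodes are rest bouts longer than 300 s spanning
at least two frames.

**Photons**: the clock rate is
`base * 2^(-t/halflife) * (1 + A cos(2 pi t / period))`, maximal at
subjective dusk, with defaults `base = 20` counts/s, `A = 0.4`,
`halflife = 70 h` (the signal decays to ~20% over a week, which is
what makes detrending necessary). A resting fly renders as a Gaussian
spot (sigma 0.6 px; a fly-sized spot of ~2 px FWHM — the rule
comparing a single-pixel maximum with mean+SD of 68-pixel bin sums
structurally requires a compact spot, and this width puts detection at
a comfortable but not trivial margin); an active fly's photons spread
over the bins it visited in proportion to dwell time, so photon count
is conserved per frame up to PSF truncation (< 1%). The camera model
adds a vignette-scaled background (5 counts/px/frame, radial vignette
gain 0.25), a faint uniform in-tube glow (0.15 counts/px/frame,
emulating light scattered by the glass capillary — without it the
tube interior would average exactly to the inter-tube background and
about half of all frames would hit the negative-mean bad-frame path,
versus the ~6–8% the glow reproduces), three bright corner markers,
optional global rotation, Poisson shot noise and Gaussian read noise
(sd 1.5), clipped to 16 bits. Each fly draws from its own RNG stream
derived from `(seed, fly_id)`, so flies are independent and any
subset of the tray is reproducible.

**What the simulator does not emulate**: optical realism (no full PSF
or EM-gain register model), grooming and other micro-behaviours,
position preferences along the tube (real flies sleep near the food
end), ageing trends in behaviour, and inter-fly optical crosstalk.
Passing tests therefore demonstrate that the pipeline correctly
inverts this generative model at realistic signal-to-noise, not that
it is robust to every artefact of a physical rig.

## Validation design and problem sizes

The test-suite checks run at deliberately small scale: a 3-tube 1-day
stack (200 x 280 px) for pipeline properties; a 12-tube 2-day stack
(480 x 280 px) for sleep-episode recovery (sensitivity and precision
≥ 0.9 against ground truth at ≥ 50% frame overlap, greedy one-to-one
matching normalised by the longer episode); 20 flies x 7 days at the
series level for period recovery (±0.5 h for every fly with RS > 3);
500 white-noise series of n = 336 for the null calibration of
`RS > 1.5` (≤ 5%); and 5 coupled plus 12 uncoupled 30-fly cohorts for
the period-coupling logic. The cohort generator's shared per-fly
period modifier defaults to SD 1.5 h — a period-mutant-scale spread,
chosen so the modifier dominates the ~0.5 h single-fly
period-estimation noise of the behavioural series, which is what the
coupled/uncoupled contrast presumes.

Two empirical properties of the statistic are documented rather than
tuned away. First, sleep-consolidation series violate the white-noise
assumptions behind `2/sqrt(n)`: an episode's duration value repeats
across all its 30-min bins, so the series is serially correlated and
its effective sample size is the episode count, not n; consolidation
RS values near the threshold are therefore less trustworthy than
clock or locomotor ones, and even genuinely arrhythmic sleep patterns
cross `RS > 1.5` more often than 5%. Second, episode recovery from
images degrades exactly where the assay is blind by construction:
naps whose true duration is barely over 300 s and whose boundary
portions are too dim to form a peak in their frames.

## Known limitations

* Geometry is static per recording: no per-frame drift correction,
  and markers need an approximate manual location.
* One fly per tube is assumed; a second fly would merge into the same
  profile.
* The global background patch is fixed at the bottom-right corner; a
  tray layout covering that corner would bias it.
* Sub-bin (< 4 px) position changes are invisible, so the
  "same-position" sleep criterion cannot distinguish true immobility
  from movement within one bin.
* RS values are comparable only under this package's conventions
  (biased ACF, flat confidence line, 14–38 h window).
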