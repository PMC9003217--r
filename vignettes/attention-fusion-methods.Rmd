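---
title: "Methods: redundant attention detection from facial expressions and heart-rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redundant attention detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnfusion)
```

# The problem

Gauging whether a class is paying attention is easy in a seminar room and
hopeless in a lecture hall of fifty. Two non-invasive signals are available
at scale: facial expressions captured by ordinary cameras, and heart data
(heart rate and beat-to-beat intervals) streamed at 1 Hz by consumer
smartwatches. Neither signal is a ground truth for attention; the premise of
this package is *redundancy* — each source is converted into the same
per-second binary representation (an **Attention Array**), the arrays are
aggregated across students, and the agreement between the two aggregated
readouts is used both to validate the cheaper facial source and to select
the one free parameter both pipelines share, the window size **WS**.

Privacy is structural, not procedural: only classroom-level aggregates ever
leave the fusion layer. Per-subject binary arrays exist in memory inside the
pipeline and are absent, by construction, from every report object.

# The facial route

Each video frame is classified (upstream of this package) into one of eight
emotion labels: anger, contempt, disgust, fear, happiness, neutrality,
sadness, surprise. Following the circumplex model of affect we use only the
**arousal** axis and ignore valence entirely: anger, fear, happiness and
surprise are *active* moods; contempt, disgust and sadness are *passive*;
neutrality is unclassifiable on this axis and is excluded.

Over a sliding window of `WS` one-second samples the **activation level** is
the active-mood count normalised to `WsNN = 300`:

$$ a = \mathrm{WsNN} \cdot \frac{n_\text{active}}{n_\text{active} + n_\text{passive}} $$

so 300 means an all-active window and 0 an all-passive one, independent of
how many neutral frames the window carries. The window is labelled
`Attention` when `a` is *strictly* greater than `Tfe = WsNN / 3`, else
`Distraction`; the labels form the facial Attention Array (AAfe).

Two choices here were genuinely open:

* **The normalising denominator.** "Normalised to 300" admits two readings
  once the window length differs from 300: divide by the non-neutral count
  (an all-active window always scores 300) or by the window length (neutral
  frames dilute the score). Only the first is consistent with "300 = only
  active moods, 0 = only passive", so it is the default; the second is kept
  as `activation_params(denominator = "window")`.
* **All-neutral windows.** A window with no classifiable mood carries no
  arousal evidence. We score it 0 (hence `Distraction`) rather than erroring,
  and the session report carries a neutrality-fraction diagnostic so a
  heavily neutral session — typical of remote lectures, where expressions
  are subdued — is visibly flagged as one where the facial source is weakly
  predictive.

The raw facial stream arrives at a nominal 2 Hz. It is resampled to 1 Hz
before windowing (modal label per second, ties to the earliest sample,
missing seconds imputed as neutrality and flagged) so that a window of `WS`
*samples* covers the same `WS` *seconds* in both routes. The source material
mixes "100 s", "100 samples" and a 2 Hz capture rate without reconciling
them; resampling makes the ambiguity moot at the cost of deciding it.

# The physiological route

From the 1 Hz beat-to-beat (BB) interval series three time-domain
heart-rate-variability statistics are used: SDNN (sample standard deviation
of the intervals), RMSSD (root mean square of successive differences) and
SDSD (standard deviation of successive differences). pNN50 is implemented
for completeness (strict "> 50 ms" boundary) but does not enter the
classifier. Standard deviations use the `n - 1` denominator throughout.

**Calibration** is per subject and two-level. Level 2 computes the three
statistics over a pre-lecture resting baseline (default 120 s). Level 1 is
demographic: an age-banded plausibility band (5–250 ms below 40 years,
tighter ceilings above, reflecting the age-related decline of short-term
HRV) that clamps the level-2 values and supplies a band-midpoint default
when no baseline exists. The band is deliberately wide — it guards against
degenerate baselines (a constant BB series would otherwise yield 0 ms
thresholds that nothing can undercut), not against individual variation.

**The Grade of Attention.** For every second of the session the *punctual*
value of each statistic is computed over the `inner_len = 30` samples ending
at that second (the first 29 seconds reuse the first complete inner window).
Within a `WS`-sample window, GA gains one point per statistic per second
that lies strictly on the calibrated *attention side* of its threshold, so
GA ranges over `[0, 3·WS]` and the threshold `Tp = (3/2)·WS` is exactly the
midpoint of that range — the only constant for which the printed formula
(three emotional stages, factor 3/2) is coherent. `Attention` requires
GA strictly above `Tp`.

Which side of the threshold indicates attention is nowhere stated in the
source material, so it is a first-class calibrated parameter. The default is
`below`: sustained mental effort is well documented to suppress short-term
vagally-mediated HRV relative to rest, so lecture seconds whose punctual
variability drops below the resting baseline vote for attention, and
relaxed, mind-wandering seconds (higher variability) vote against. Both
directions are supported and recorded in the profile.

A consequence worth knowing: a 30-sample dispersion estimate is biased low
relative to the same statistic over a 120–600-sample baseline (small-sample
bias compounded by positive autocorrelation of the BB series). When the
lecture process *equals* the baseline process, the three comparisons are
therefore not exactly fair coins — the "below" side wins slightly more than
half the time and mean GA sits near `1.8·WS` rather than the naïve `1.5·WS`
midpoint. The test suite pins this with an exact per-window recount oracle;
it is a property of windowed dispersion statistics, not a defect of the
implementation.

# Fusion, Attention Behavior and window-size selection

Per-subject arrays from one source are averaged arithmetically
(`Attention` = 1) into a per-second classroom **fraction series** — a mean,
not a majority vote, so graded classroom states survive aggregation.
Two summaries are derived:

* **Attention Behavior (AB)**: the trailing 5-minute moving average of the
  fraction series (half-open window `(t-300, t]`, one value per second), the
  smoothed curve a teacher would watch. It is undefined for the first five
  minutes by construction.
* **Attention Gain (AG)**: `100 · mean` of the *raw* (unsmoothed) fraction
  series over the whole session — the percentage of attention the source
  detected. An optional binarised variant (classroom fraction > 0.5) is
  provided since the published figures do not say which was used; the raw
  fraction mean is the default.

With the mean of the two gains as reference, the inter-source RMSE

$$ \mathrm{RMSE} = \sqrt{\tfrac{1}{2}\left[(\hat{AG}-AG_p)^2 + (\hat{AG}-AG_{fe})^2\right]}, \qquad \hat{AG} = \tfrac{AG_p + AG_{fe}}{2} $$

reduces algebraically to `|AG_p − AG_fe| / 2`; the implementation evaluates
the full formula and the tests verify the identity independently. `WS` is
chosen empirically as the candidate (default grid
`{25, 50, 75, 100, 150, 200, 300}`) minimising this RMSE, ties to the
smaller window. During selection the inner HRV window is clamped to
`min(inner_len, WS)` so the 25-sample candidate remains evaluable — an
inner window cannot meaningfully exceed the window it serves.

# Self-report baseline

The reaction-time tool shows a yes/no "are you paying attention?" prompt at
random times and logs both timestamps. Affirmative answers with a reaction
time strictly above `max_rt` are reclassified as negative — a slow "yes" is
not credible evidence of attention. No reaction-time limit is empirically
established anywhere we know of; the default 10 s is an arbitrary,
deliberately generous bound and is flagged as such. The pooled level across
volunteers is prompt-weighted. Encoding the published remote-campaign counts
(25 prompts, 20 yes of which 2 late, 5 no) reproduces the published 72 %
exactly; this is the only published number reproducible without the original
recordings.

# The synthetic world

Because no recordings are deposited, the package ships a seeded simulator
whose defaults *are* the stated experimental conditions: 8 subjects (the
in-presence campaign size), hour-long two-regime sessions, 2 Hz emotion
streams, 1 Hz BB/HR streams, 120 s resting baselines.

* **Emotion streams** are i.i.d. draws per regime: attentive mostly active
  plus 35 % neutrality, distracted mostly passive plus 40 % neutrality. A
  neutrality-inflation factor reproduces, qualitatively, the remote-lecture
  failure mode in which neutral frames swamp the facial source.
* **BB streams** follow a regime-switching AR(1) with stationary mean
  800 ms (75 bpm) in every state and stationary sd 15 ms (attentive), 50 ms
  (distracted) and 30 ms (rest); lag-1 autocorrelation 0.5. AR(1) rather
  than white noise so successive-difference statistics (RMSSD/SDSD) are
  controllable separately from SDNN. Intervals are floored at 300 ms.
* **The resting baseline is a distinct third state.** Its 30 ms sd sits
  between the two lecture regimes, which is what makes a single calibrated
  threshold informative in both directions: attention suppresses HRV below
  rest, distraction relaxes it above. Had the baseline been drawn from the
  attentive regime itself, every comparison there would be a near-coin and
  regime recovery would be structurally impossible — a useful reminder that
  the method's power lives in the calibration protocol.

What a green simulation test establishes: the pipeline recovers a known
regime schedule (≥ 85 %, in practice ≈ 98 %, post-warm-up agreement for
both sources at WS = 100) when the regimes are separated as above. What it
does not establish: performance on real faces (the upstream classifier's
errors are not modelled), real wrist-worn PPG (motion artifacts, dropouts
beyond simple gaps), or any claim that the simulated separations match real
classrooms.

# Numerical and degenerate-input choices

* All attention thresholds compare strictly (`>`); scores exactly at
  `Tfe`, `Tp` or `max_rt` fall on the non-attention / non-reclassified side.
* Arrays are emitted only for complete windows: the first label of either
  array sits at elapsed second `WS`, and AB at `span + first` − 1.
* Timestamps are seconds from session start; prompt-log `delta` mismatches
  beyond 1 ms trust the timestamps and warn.
* Physio gaps > 1.5 s are flagged, never interpolated; emotion seconds with
  no frame become flagged neutrality.
* Reports serialise as canonical JSON; identical inputs and configuration
  give byte-identical files.

# Known limitations

The demographic calibration bands are plausibility clamps, not physiology;
frequency-domain HRV is out of scope; the 1 Hz smartwatch export is treated
as the interval series itself (no beat-level resampling); live/BLE operation
is emulated by batch reruns; and the self-report `max_rt` threshold is a
convention, not a measurement.
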