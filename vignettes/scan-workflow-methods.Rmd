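---
title: "Methods: synthetic scan sessions and the workflow-analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic scan sessions and the workflow-analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoflow)
```

# The problem

Routine obstetric ultrasound is operator-driven: what gets imaged, for how
long, in what order, and with how much attention to the machine's safety and
measurement displays is decided second-by-second by the sonographer.
Quantifying that workflow requires fusing several concurrent recordings of a
scan room: the machine's video output (including its graphical interface),
the sonographer's gaze on the screen, the motion of the hand-held
transducer, and spoken commentary.  Clinical recordings of this kind cannot
be shared, so `sonoflow` pairs every analysis stage with a seeded synthetic
session generator whose statistical structure matches published cohort
summaries.  Every detector and statistic in the package is therefore
testable as a *recovery* problem: plant known structure, run the pipeline,
and check that the structure comes back.

# The synthetic session generator

`simulate_session()` draws one multimodal scan from a
`generator_config()`.  Its components, and what they emulate:

**Scan duration.** Normal with mean 36.2 and SD 11.6 minutes, truncated to
[10, 90] by resampling.  Second-trimester anomaly scans of this length are
the cohort the default profile describes.

**Anatomy timeline.** A semi-Markov chain over 13 labels (12 common
anatomy/standard-plane labels plus `other`).  Segment labels are i.i.d.
with probability proportional to `time_shares / mean_dwell`, and dwell
times are gamma with shape 2 and a label-specific mean
`dwell_base * sqrt(share / mean share)` (default `dwell_base` 20 s).  By
the renewal-reward theorem the long-run fraction of scan time per label
equals `time_shares` regardless of the dwell scaling; the square-root
scaling is a modelling choice that gives frequently examined structures
both more and longer segments, and gamma(2) was picked as a positive,
right-skewed, two-parameter family.  The default `time_shares` are the
published per-label proportions of scan duration (cardiac imaging ~21.5%,
head and brain ~11.4%), normalized to sum to 1.

**Machine events.** Frozen acquisition intervals are placed at anatomy
segment boundaries with probability 0.5 each (mean length 8 s), plus one
dedicated frozen interval per planned biometric measurement display
(HC/AC/FL, default plan 1/2/1 per scan).  Within a frozen interval an image
save occurs with probability 0.7 and a clip save with probability 0.08.
These rates were fixed once so that a typical simulated scan shows a few
dozen saves and roughly three-quarters live scanning, the regime described
for representative real scans.  All event times are snapped to the video
frame grid (30 frames/s), which makes the structured UI channel lossless:
extraction must recover the ground truth *exactly*, and the tests assert
that.

**UI stream and rasters.** Each frame carries a frozen flag, a save kind,
the active measurement display (type and value in mm, shown from one second
after freeze onset until the freeze ends) and a thermal index.
`render_ui_frame()` can draw the state into a small binary raster using
fixed 3x5 glyphs at documented rectangles; the rasterized channel exists so
the character-recognition path can be tested end-to-end, while fast tests
use the structured records directly.  No ultrasound image content is
synthesized — rasters carry only interface glyphs.

**Gaze.** 90 samples/s (a typical remote eye-tracker rate; the source
cohort's tracker rate is not public), isotropic Gaussian noise of 15 px
around the current attractor, 2% invalid samples.  The attractor is the
live image centre, except around measurement displays that the synthetic
sonographer chooses to read (probability `measurement_look_prob`, default
0.93, consistent with "more than 90%" of measurements being looked at) and
a brief thermal-safety ("bioeffect") box visit in a
`bioeffect_look_prob = 27/637` fraction of scans.

**Transducer IMU.** 100 Hz gyroscope/accelerometer/magnetometer from a
scripted smooth trajectory: sinusoidal roll/pitch/yaw (amplitudes
0.5/0.35/0.9 rad at 0.20/0.13/0.045 Hz, random phases) plus a centimetre-
scale sinusoidal translation.  Body rates follow from exact Euler-angle
kinematics; the accelerometer reads the world-frame specific force rotated
into the sensor frame, so in noise-free mode
`rotate(q_true, accel) - (0, 0, 9.81)` equals the true linear acceleration
to machine precision (a tested invariant).  Default sensor noise: gyro
0.005 rad/s, accel 0.05 m/s², mag 0.01 (re-normalized) — small enough to be
recoverable, large enough that fusion is not trivial.

**Speech.** Sentence lengths are capped negative-binomial (cap 83 words);
each token's part of speech is drawn from
adjective/determiner/noun/verb/other weights 12.7/22.2/28.0/16.0/21.1 (%),
and the word uniformly from the tagged lexicon.  The lexicon combines ~170
real scan-commentary words with deterministic synthetic filler up to 344
unique entries.  Because tags live in the lexicon, the printed POS mix is
reproduced under this lexicon convention, not under any statistical tagger.

## What the generator does *not* emulate

No ultrasound image content, no probe-position ground truth (only
orientation and linear acceleration), no speaker diarization or acoustic
modelling, no annotator-specific confusion structure (label corruption is
symmetric), and no correlation between modalities beyond what the shared
timeline and event list induce.  Passing recovery tests therefore
demonstrates the correctness of the *analysis machinery*, not the clinical
fidelity of any individual stream.

# Analysis stages

**UI extraction.** `read_numeric_box()` splits a raster region into
fixed-pitch character cells and scores each against the glyph set by the
fraction of agreeing pixels, requiring the best match to reach 0.99 —
i.e. exact agreement for 15-pixel glyphs.  Any corrupted, ambiguous, or
internally gapped cell makes the whole value unreadable; no value is ever
fabricated.  `extract_event_timeline()` unions freeze transitions
(first differences of the frozen flag, timestamps `frame / frame_rate`,
0-based), save events, and measurement displays, which fire on value
change with a 0.5 s debounce against flicker.

**Clip partitioning.** Each qualifying event (freeze on, image save, clip
save) anchors a 5-s clip *ending* at the event: sonographers freeze or
save once satisfied, so the informative approach context precedes the
event.  The published description does not state window alignment; this is
a documented convention.  Clips overlapping an earlier kept clip by at
least 50% of their own length are dropped so that a freeze followed
immediately by a save counts one acquisition.

**Fixation episodes.** A fixation is a maximal run of consecutive in-AOI
samples whose first-to-last timestamp span is at least 100 ms (inclusive,
and rate-independent because it is measured in time, not samples).
Fixations separated by at most 400 ms (inclusive) merge into one episode.
Invalid samples break runs — the conservative reading.  The detector is
checked against a brute-force run-scan oracle on 1,000 random streams,
including the exact 400/401 ms boundary pair.

**Orientation fusion.** A gradient-descent complementary AHRS in Hamilton
sensor-to-world quaternion convention: world z up, gravity (0, 0, -9.81)
m/s², magnetic reference horizontal +x.  The gyro increment is applied as
an exact quaternion exponential (first-order integration of the quaternion
derivative leaves a measurable heading bias at scan-typical rates), and
the normalized gravity+magnetic gradient step — scaled by the gain,
default 0.1 — is evaluated at the gyro-propagated state, since the
accelerometer/magnetometer sample is concurrent with the post-step time.
Zero-norm accelerometer samples (free fall) fall back to gyro-only
updates and are logged per stream.  Initialization is TRIAD-style from the
first accel/mag sample.  Gain 0.1 trades ~1.9° RMS tracking error on noisy
scripted trajectories against sub-degree recovery from a 30° initial error
within 5 s; smaller gains track better but converge too slowly, larger
gains chase the linear-acceleration disturbance.

**Workflow statistics.** Per-frame label regularization is a 31-frame
sliding mode (ties keep the previous output label) followed by absorbing
segments shorter than 1 s into the longer neighbour; both parameters are
package choices, the published pipeline states none.  Time shares are
segment sums over duration; cohort summaries use Student-t 95% confidence
intervals on per-scan share percentages (the CI method behind the published
tables is unstated).  Agreement is compared at clip level, and the
correlation between two labelings is the Pearson correlation of flattened
per-scan-per-label share vectors — the published ρ's exact operand is
ambiguous, so this is a documented convention.  The deep video classifier
is out of scope and is stood in for by a nearest-centroid classifier over
generator features (one-hot centroids, isotropic noise); for that geometry
the expected accuracy has the closed form
`P(Z1 + 1/sigma > max of K-1 standard normals)`, which
`calibrate_feature_noise()` inverts, so any target accuracy can be planted
and recovered.

# Numerical choices and degenerate inputs

Half-open AOI rectangles (pixel origin top-left); episodes with exactly
100 ms dwell or 400 ms gaps are kept/merged (inclusive thresholds, as the
rules are stated with ≥ / "or less").  Classifier distance ties break to
the lexicographically first label.  Timeline truncation at scan end keeps
the partition exact to 1e-6 s.  Empty gaze streams, constant freeze flags,
zero-measurement scans, and single-label timelines all return well-defined
empty or degenerate results rather than errors, except where the contract
of the operation demands an error (zero-duration timelines, < 2 scans for a
cohort CI, out-of-lexicon words, zero-variance correlations).

# Problem sizes

The cohort experiments simulate 341 timeline-only scans (time-share
recovery), 20,000 sampled clip labels (prevalence recovery), 637 short
gaze streams with 27 planted safety-box fixations, 272 four-minute UI
streams carrying 354/703/352 planted HC/AC/FL displays, 28 scans of clips
for the agreement channel, and 40-s IMU streams for orientation recovery.
These sizes were chosen so the full suite runs in about a minute and a
half on one CPU while keeping Monte-Carlo error well inside each check's
tolerance; the biometry and safety experiments count planted events, which
is duration-independent, so short scans lose nothing.

# Known limitations

- The generator's dwell law, gaze noise, IMU trajectory and event rates are
  plausible but not fitted to any real recording; only the quantities the
  published cohort summaries pin down (time shares, prevalences, duration
  model, POS mix, audit rates) are calibrated.
- The AHRS tolerance (< 2° RMS) is defined against this package's own
  synthetic ground truth, not against any commercial reference filter.
- The label-corruption channel is symmetric; real annotator confusion is
  structured (e.g. adjacent anatomy), so confusion *matrices* from the
  channel are realistic only in their overall agreement, not their
  off-diagonal pattern.
- Raster extraction assumes the package's own renderer (exact glyph match);
  it is not a general OCR and will refuse, not guess, anything else.
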