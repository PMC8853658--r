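---
title: "Methods: event-aligned spike classification, photoidentification, and behavior detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-aligned spike classification, photoidentification, and behavior detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflictephys)
```

`conflictephys` analyzes recording sessions from an approach–avoidance
conflict task: a subject trained on a reward cue (lever press for food) and a
threat-conditioned odor is tested in three phases — reward cues alone, odor
alone, then both at once ("conflict") — while prelimbic-cortex single units,
field potentials and pose-tracked behavior are recorded. Subjects split into
two phenotypes by a binary criterion: *pressers* emit at least one rewarded
lever press during conflict-phase cue presentations, *non-pressers* show
complete suppression. Every stage of the analysis is exercised against a
synthetic-session generator with known ground truth.

All times are seconds, session-relative, with half-open windows $[a, b)$;
pixel coordinates use the image convention (origin top-left, y downward).

## Event-aligned Z-scored PSTHs

For each unit and event type, spike counts are averaged across events in
300-ms bins covering $[-6, +3)$ s around onset. The 20 pre-onset bins form
the baseline; each bin's Z-score is

$$ z_b = \frac{\bar c_b - \mu_{\text{base}}}{\sigma_{\text{base}}}, $$

where $\mu_{\text{base}}$ and $\sigma_{\text{base}}$ are the mean and
*population* (n-denominator) SD of the 20 baseline bin means. The population
formula is a documented convention so results reproduce bit-for-bit; with 20
bins it differs from the sample SD by ~2.6%. If $\sigma_{\text{base}} = 0$
(e.g. a silent unit), Z is defined as 0 where the bin mean equals the
baseline mean and a signed-infinity sentinel elsewhere.

A unit is **excited** if Z exceeds 2.58 (two-sided p < 0.01) in the first two
post-onset bins, **inhibited** if Z falls below −1.96 (p < 0.05) there, and
unresponsive otherwise; excitation takes precedence when both thresholds are
crossed across the two bins. "During the first two bins" is read as *either*
bin by default (`detection_rule = "any_of_first_two_bins"`): a single-bin
(300-ms) response must be detectable, otherwise the sub-600-ms "transient"
class would be empty by construction. The stricter `both_of_first_two_bins`
variant is retained as a configuration switch for false-positive-sensitive
analyses; under it the chance level of calling a stationary Poisson unit
responsive at a random timepoint is measured at well under 1% (the
acceptance script recomputes this fraction on 2,000 simulated units).

Excited responses receive a temporal profile from the longest run of
consecutive supra-threshold bins intersecting the first two, within the
first 3 s: **transient** below 600 ms, **sustained** at or above 900 ms.
A run of exactly two bins (600 ms) falls between the published definitions
and is reported as an explicit **intermediate** class rather than silently
merged into either. Signed areas under the Z curve (`response_auc`) integrate
the positive or negative part of Z over $[0, 3)$ s, in Z·seconds.

Spontaneous-rate changes between session epochs compare spike counts in
thirty 1-s sub-bins of each 30-s window with a two-sided rank-sum test at
$\alpha = 0.05$ (direction from the sign of the mean difference). The source
analysis names no statistic for this comparison; the rank-sum was chosen for
distribution-freeness on small counts.

## Photoidentification

Laser-aligned activity is binned at 1 ms against a 20-ms pre-pulse baseline.
The **latency** is the start of the first post-pulse bin with Z > 3.29
(p < 0.001), searched over 0–12 ms (longer latencies are treated as likely
synaptic, not opsin-driven). The cohort-level latency criterion comes from
the **triangle method**: the latency histogram is min–max normalized on both
axes, a line is drawn from the peak bin to the last bin of the range, and
the threshold is the bin at maximum perpendicular distance from the
histogram profile to that line — the elbow between the short-latency cluster
and the tail. Distance ties (within numerical noise) break toward the
shorter latency, and a histogram with a single nonzero bin returns that bin.

**Reliability** uses the Fano factor (FF, variance-to-mean ratio of spike
counts; 1 for a Poisson process). For each of the 10 stimulation trains
(50 pulses at 200-ms intervals), FF is computed from the per-pulse counts in
the 6-ms windows before and after pulse onset, using the sample
(n−1) variance; per-train FFs are averaged with equal weights and the ratio
is FF_after / FF_before. A train whose windows contain no spikes at any
pulse has FF defined as 0; if FF_before is 0 overall the ratio is undefined
and the unit is not photoidentified.

A unit is **photoidentified** when all three hold: a significant aggregate
rate increase in the 6-ms post-pulse window (Z > 3.29 against the same
baseline, with the window variance scaled as a sum of independent bins),
latency below the cohort cut (default 6 ms), and FF ratio > 1. The aggregate
rate gate matters: the per-ms bin scan alone is poorly calibrated (a 20-bin
baseline SD estimate plus Poisson discreteness lets single-bin count flukes
cross Z = 3.29 far more often than the nominal level), so it is used to
*date* the response, not to declare it.

Two properties of the FF-ratio criterion deserve emphasis, because they
shape both the generator and what a validated pass means:

* Counts confined to {0, 1} are sub-Poisson — for a Bernoulli count,
  FF = 1 − mean — so a unit that reliably fires exactly one spike per pulse
  has FF_after far *below* its baseline FF and fails the gate. The
  criterion's "reliability" is really supra-baseline count *dispersion*:
  it selects units whose evoked response is an all-or-none multi-spike
  burst. The generator therefore models direct responses as a mixture of
  single spikes and short high-frequency bursts (`burst_prob = 0.45`,
  `burst_size = 4`, ~0.9-ms intra-burst intervals), the response mode that
  5-ms high-power opsin pulses produce.
* The gate's power collapses as the baseline rate grows: pre-pulse 6-ms
  windows fill, FF_before approaches 1, and no physiological burst
  statistics keep FF_after above it. Validation cohorts therefore use
  sparsely firing direct units (1–2 Hz); below ~1 Hz the statistic becomes
  undefined (all pre-pulse windows empty). This operating range is a
  property of the published criterion, not of the implementation.

The generator's per-pulse latency jitter is 0.5 ms (direct) / 1.5 ms
(indirect) around a per-unit latency mean, with a 1.5-ms conduction floor;
across-unit latency spread (for triangle-method histograms) comes from
drawing each unit's mean from the population distribution (direct
3.3 ± 1.0 ms, indirect 21 ± 3.7 ms). First-significant-bin latencies date
the *onset tail* of the evoked distribution, so they land 1–2 ms below the
latency mean.

## Behavior detection

Pose tables carry six body parts (nose, ears, head center, spine, tail
base) with per-frame likelihoods; frames below the 0.9 likelihood cutoff
are masked, masked gaps up to 0.5 s are linearly interpolated, and longer
gaps are excluded from bout detection.

* **Freezing**: a frame is still when *every* tracked part moved at most
  1.05 px from the previous frame (the source defines stillness by position
  tolerance but names no part; the all-parts conjunction is the
  conservative reading). Still runs strictly longer than 500 ms become
  bouts.
* **Avoidance**: head center inside the hidden zone (closed rectangles).
* **Risk assessment** (stretch-attend): spine and tail base in the hidden
  zone, nose across the divider within the slot's lateral extent, and
  nose-to-tail length at least the session mean plus `stretch_z` SDs
  (default 1; the source gives no quantitative stretch definition).

For neural alignment, bout onsets are kept only if the bout lasted more
than 1 s and no same-type bout intersected the preceding 6 s, so the
pre-onset baseline is clean; this filter returns a subset of its input and
is idempotent. Units are aligned on at least six usable onsets (odor- and
conflict-phase bouts pooled) with 100-ms bins — the ±600-ms interval
criterion needs sub-300-ms resolution — against a 6-s baseline ending
600 ms before onset. A threshold crossing within (0, +600 ms] classifies
the unit as responding after onset, within [−600 ms, 0] as before (the
post-onset window wins if both cross). Note the rule tests 12 fine bins, so
its family-wise false-positive rate on stationary units is ~15% by
construction; counts of "behavior-responsive" units must be read against
that chance level.

## Field potentials

PSDs use Welch's averaged periodogram: 2-s Hann-tapered segments with 50%
overlap (0.5-Hz resolution, chosen to resolve the 4-Hz delta/theta
boundary; the source does not state estimator parameters). Band fractions
integrate the PSD over delta (0–4), theta (4–10), alpha (10–14), beta
(14–35) and gamma (35–100 Hz) as percentages of total 0–100 Hz power; the
gamma upper edge is fixed at 100 Hz so a full partition sums to 100. The
spectrogram is the same transform over time, in dB (10·log10 power/Hz).
Group contrasts integrate each session's percent-PSD per band and compare
groups with Welch's t-test. Line-noise notching is off by default for
synthetic data.

The LFP generator is 1/f (pink) background noise of unit variance plus one
oscillator, 3 Hz (delta-dominant, the presser profile) or 7 Hz
(theta-dominant, non-pressers) at amplitude 1.5 background-SD units —
enough for the planted band to dominate against the 1/f low-frequency bias
in both directions.

## Group statistics

Responsive-proportion contrasts use Fisher's exact test with the two-sided
"sum of probabilities ≤ observed" convention (the common exact definition;
other two-sided conventions exist, and the test suite pins this one against
an enumeration oracle). The behavioral PCA is an eigendecomposition of the
*correlation* matrix — features mix percentages and seconds, so covariance
PCA would be unit-dependent — with components ordered by eigenvalue and each
loading vector's sign fixed so its largest-magnitude entry is positive.

## The synthetic generator: what it does and does not emulate

Sessions reproduce the study conditions: 12 food cues of 30 s per cue phase
with 25–40-s intervals, a 10-min odor phase between them, phenotype mix
0.78 pressers, about a third of units cue-responsive in the reward phase
(60% excited, split transient/sustained) of which 40% stay responsive under
conflict, unit baselines 4–9 Hz, and behavior features drawn from
phenotype-specific distributions (non-pressers freeze and avoid several-fold
more, pressers occupy the food area and press quickly). Spiking is a thinned
inhomogeneous Poisson process with a 2-ms absolute refractory period and
dead-time-compensated intensity, so empirical rates converge to nominal and
the Fano factor of 300-ms counts stays near 1 (slightly below: dead time
removes variance, about $1 - 2\lambda\tau$).

Not emulated: spike-waveform shape and sorting artifacts, bursting
statistics beyond the laser-evoked mixture, odor-plume dynamics, video
rendering, within-session learning or extinction, and electrode drift.
Passing closure tests therefore shows the analysis rules recover the
planted structure under Poisson-like variability — not that they are robust
to sorting errors or nonstationarity in real recordings.

Test and validation cohorts are deliberately small (tens of units, tens of
seconds of pose or field potential, a handful of sessions); these sizes
give the closure checks comfortable statistical margins while keeping the
full suite quick to run.

## Numerical conventions and degenerate inputs

* Bins are genuinely half-open: a spike exactly on an edge belongs to the
  bin it starts (`findInterval(..., left.open = TRUE)`).
* Baseline SDs use the population formula in PSTHs (documented above) and
  the sample formula inside Fano factors (pinned by a hand-computed case in
  the tests).
* Zero-variance baselines produce signed-infinity Z sentinels, never NaN;
  AUCs ignore non-finite bins.
* `validate_session` reports every violation rather than stopping at the
  first; loaders turn any violation into a hard error naming the offender.
* The video frame rate is not part of the source description; the default
  is 30 Hz and is overridable in the configuration and session manifests.
* Master seeds fan out to per-session/per-unit child seeds through a
  counter-based recurrence (`child_seed`), so any subset of a cohort is
  reproducible in isolation; all seeds stay below $2^{31}$.

## Known limitations

* The exact statistic behind the published per-neuron spontaneous-rate
  calls is unstated; the rank-sum choice here is defensible but not
  verifiable against the source.
* Whether the original analysis required one or both of the first two bins
  to cross threshold is ambiguous; both variants are implemented and the
  default is documented above.
* The FF-ratio reliability gate is informative only for sparse baselines
  (see above); at population-average rates (5–8 Hz) it rejects nearly
  everything, including genuinely reliable responders.
* Vendor acquisition formats (PLX/PL2/NEX) are out of scope; sessions are
  read from the manifest-based directory layout documented in
  `?load_session`.
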