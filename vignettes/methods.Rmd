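---
title: "Models and methods behind aatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aatrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aatrack)
```

# The scientific setting

`aatrack` analyzes rodent approach–avoidance conflict on an L-shaped linear
track whose far end is guarded by a threatening robot. A rat shuttles between
a nest feeder and a track feeder; on Attack sessions, crossing an unmarked
mid-track threshold triggers a robot attack with probability 0.2 per lap,
never before the 15th lap. The analyses quantify (a) "worry-like" behaviors —
hesitation in the nest/doorway, mid-track aborts (MTAs), on-track pauses —
and (b) how the dorsal hippocampal representation of space changes after the
first attack, measured through occupancy-normalized tuning curves, sharp-wave
ripple (SWR) and high-synchrony event (HSE) detection, and one-step Bayesian
decoding of ensemble spiking.

Because raw animal recordings are not redistributable, the package ships a
synthetic-session generator whose statistical structure matches what the
downstream analyses assume. Every stage can therefore be validated by
generator/detector round trips with exact ground truth.

# The decoding model

Ensemble activity is decoded with a one-step Bayesian decoder under
Poisson-independent firing and a uniform spatial prior:

$$P(x \mid n) \propto \prod_{i=1}^{N} A_i(x)^{n_i} \cdot \frac{1}{X} \cdot
e^{-\tau \sum_i A_i(x)},$$

where $A_i(x)$ is cell $i$'s occupancy-normalized expected rate on the
tuning grid, $n_i$ its spike count in the decoded window, $\tau$ the window
duration, and $X$ the number of grid bins. The grid has 64 positional bins
along the 111 cm long axis crossed with three direction-of-travel bins
(toward the robot, stationary, toward the nest): 192 bins in all. Decoding
refuses ensembles smaller than 10 putative pyramidal cells (mean rate
< 10 spikes/s and peak-to-valley duration ratio > 0.4, both strict).

Evaluation is in log space and normalized by log-sum-exp; `decode_posterior`
is verified in the tests against a brute-force product-arithmetic oracle on
small instances to $10^{-9}$. Two numerical choices matter:

* **Rate floor.** Bins where a cell's estimated rate is zero (but occupancy
  is defined) receive a configurable floor, default 0.01 spikes/s, so one
  silent cell cannot zero the whole posterior. Bins with *undefined* tuning
  (zero occupancy) get zero posterior mass and are excluded from the
  normalization — 0/0 never masquerades as rate 0.
* **Curve smoothing.** Spike counts and occupancy are smoothed along
  position with a mass-preserving Gaussian (SD 1 positional bin ≈ 1.7 cm,
  column-normalized so totals are exactly conserved) before the ratio is
  taken. This is the standard stabilization for occupancy-normalized rate
  maps; without it, sparsely visited bins (for example the feeder platform
  in a short pre-attack epoch) leave many cells at the rate floor, and the
  floor's heavy log-penalty systematically distorts decoding between epochs
  of different lengths. The conservation identity
  $\sum_x A_i(x)\,\mathrm{occ}(x) = \text{included spikes}$ remains exact.

Tuning curves use spikes only while the LFP is theta-dominated (the
session-normalized log theta/delta power ratio is at least 0.5) and only
during the descending phase of each theta cycle, which minimizes the
influence of ripples and prospective theta sweeps. By default occupancy is
restricted to the same mask, so rates are spikes per second of *included*
time; an alternative reading (occupancy = all time in the direction bin) is
available via `occupancy_mode = "direction_all"`.

# LFP machinery

Spectrograms use consecutive Hann-windowed bins (1 s by default, 0.25 s for
event-aligned analyses) scaled so the one-sided density integrates to the
signal variance; Welch PSDs average the selected bins. The aperiodic (1/f)
component is removed by a robust linear regression (`MASS::rlm`) on the
log-log PSD over 80–400 Hz; the ripple channel is the one with the largest
residual power over 120–250 Hz (ties go to the lowest channel index).

SWRs are detected on the 150–250 Hz band-passed signal via the analytic
(Hilbert) envelope, z-scored over the whole session (mean and SD include
event epochs; an exclusion-refit variant was considered and rejected as a
non-literal reading), thresholded at 4 SD, merged when the end-to-start gap
is under 5 ms or the start-to-start gap under 20 ms (applied iteratively to
a fixpoint, which makes the merge order-independent and idempotent), and
kept when longer than 20 ms. HSEs sum putative-pyramidal spiking in 1 ms
bins, smooth with a 7 ms SD Gaussian kernel, threshold at 3 SD over the
session, and keep events strictly between 20 and 750 ms.

Theta cycles are segmented cycle-by-cycle: candidate peaks and troughs are
extrema of the 6–10 Hz narrow-band signal between its zero crossings, each
refined to the extremum of a broad-band signal within the same bracket. The
broad filter is a *first-order* zero-phase Butterworth over 6–40 Hz: its job
is to preserve the saw-tooth waveform shape, and steeper filters audibly
symmetrize asymmetric cycles (a 2:1 triangle read as ~0.88 on the log2 scale
under an order-3 filter versus ~1.03 under order 1). The per-cycle asymmetry
index is `log2(ascending / descending)` duration, summarized by the median;
the index formula is isolated in one place so an alternative definition can
be swapped in.

# The synthetic generator

The generator's defaults are the study conditions; they were chosen once to
emulate the task and the electrophysiological regimes the analyses assume.

**Behavior.** Laps alternate feeder ends at ~35 cm/s with a slow (12 cm/s)
deceleration into the feeder platform, as rats do; hesitations are log-normal
nest/doorway dwells; scripted aborts advance 10–25 cm past the doorway for
at least 0.8 s before turning; scripted pauses stop the animal for 0.7–1.5 s
mid-track; attacked laps retreat to the nest immediately after the threshold
crossing and then re-run. After the first attack, abort/pause rates double
and hesitations lengthen 1.5-fold, emulating the post-attack behavioral
phenotype. Tracking noise is 0.15 cm per 30 Hz sample.

**Place fields.** Established fields tile the nest, doorway and running
track uniformly (alternating direction preference, peaks 4–10 spikes/s, SD
4–8 cm), with the feeder platform over-represented (20% of cells), as
hippocampal maps over-represent goal sites. The robot bay frontage — walled
off outside Attack sessions — carries passage occupancy but no established
field centers. After the first attack, 30% of cells (drawn preferentially
from reward-site cells) gain a field clustered on the robot bay center, so
the remapped population carries a coherent threat representation traded
against the reward representation. Keeping new-field peaks in the same 4–10
spikes/s range keeps the total-rate landscape flat, which matters because
the decoder's $e^{-\tau \sum A}$ term otherwise attracts evidence-poor
posteriors into whichever curve set has the quieter zone.

**Spiking.** During movement, cells fire as inhomogeneous Poisson processes
from their field map at the current position/direction; the local component
is gated to the descending theta phase and the ascending phase evaluates the
map 8 cm ahead of the animal (a fixed look-ahead standing in for theta
sweeps). Gating is compensated by the inverse half-cycle fraction so
expected in-field counts equal rate × occupancy time. A 0.3 Hz baseline runs
throughout (silent cells stay silent).

**Offline events.** Scripted population bursts (40–90 ms) occur in
stillness; each carries a content location drawn 30% at the feeder, 25% at
the robot, otherwise uniformly over the covered track. A cell joins a burst
with probability proportional to its field value at the content location on
the *epoch-invariant union map* (pre fields plus threat fields, normalized
per event so the best-tuned cell joins at 0.85), plus a 0.05 content-free
floor; participants emit 1 + Poisson(1.5) spikes. Epoch-invariant
participation is deliberate: the empirical finding is that the attack
changes *tuning*, not which cells fire in events. Sparse stochastic
participation keeps single-event posteriors informative but graded; Poisson
rate-style emission makes them near-degenerate and was rejected. Ripple
bursts (180 Hz carrier, raised-cosine envelope, peak 6 SD of the background
ripple-band envelope) coincide with the population bursts, padded to at
least 80 ms so the supra-threshold envelope core clears the 20 ms duration
criterion; one channel (the second) carries them at full amplitude.

**LFP.** Channels combine a 1/f² background, movement-locked theta from a
phase-warped cosine that follows the scheduled peak/trough times exactly
(so cycle segmentation has a closed-form truth), stillness-locked 1–4 Hz
activity, a small 60 Hz line component, and the injected ripples, at
1250 Hz.

One master seed derives labeled per-component seeds, so identical
configurations reproduce byte-identical sessions and individual components
are independently reproducible.

# What the round trips do and do not show

Passing round trips show the detectors implement their stated definitions
and that the pipeline recovers a known generative model at realistic signal
strengths. They do not certify performance on real recordings: the generator
has no electrode drift, no sorting errors, no multi-modal or non-Gaussian
fields, no genuine theta sequences (only a fixed look-ahead), and its LFP
states are cleanly bimodal. Conclusions about real data still require the
usual physiological controls.

Specific calibration notes, decided during design and kept fixed:

* HSE detection is z-scored over the whole session, so movement-epoch theta
  co-firing can legitimately cross threshold; recovery is therefore scored
  within stillness, where ground-truth events live, and downstream decoding
  restricts to in-nest events, mirroring how such events are analyzed.
* The look-ahead offset is recovered as the *ascending-minus-descending*
  posterior displacement rather than the raw ascending offset: both halves
  share a small window/COM bias that the difference cancels — the same
  differencing used for the descending−ascending maps.
* Decoding error and displacement are summarized over half-cycles with at
  least two ensemble spikes in the central track (edge bins clip the
  look-ahead target); zero-spike halves decode to the closed-form no-spike
  posterior and are flagged, not dropped silently.
* The pre/post cross-decoding suite uses 900 s attack sessions with 50
  cells and 0.8 scripted bursts per second of stillness — scaled down from
  hour-long real sessions but long enough that both epochs' curves are
  estimable; events are the *detected* in-nest HSEs, since sub-threshold
  scripted windows are not events under the analysis's own definition.

# Design decisions where the field leaves latitude

* **Attack eligibility** is inclusive at lap 15, reconciling the task
  description with the worked lap-count example (15, 19, 16, 18).
* **Zone boundaries** are derived proportionally from the published arena
  dimensions (nest 19 cm with a 4 cm doorway, 67 cm track split at the
  52.5 cm attack threshold, robot bay frontage to 104 cm, feeder platform
  104–111 cm) and are fully configurable, since exact coordinates are not
  published. The feeder segment is wide enough (4 positional bins) for
  feeder-zone posterior mass to be statistically meaningful.
* **MTA timing** uses an automated head-turn proxy — the first sample where
  the smoothed along-track velocity changes sign within the abort — in place
  of manual video annotation; doorway "stretches" are flagged by requiring
  the excursion to clear 5 cm beyond the doorway.
* **Standard deviations** use the n−1 denominator throughout.
* **Stationary band** is |along-track speed| < 5 cm/s everywhere it is
  needed.
* **Cross-frequency correlation** uses log power (variance stabilization).
* **Tracking loss** is bridged by linear interpolation up to 0.5 s; longer
  gaps flag the enclosing event as uncertain.
* **Per-target control cap** for matched theta cycles defaults to 10 with a
  1 s exclusion margin around behavioral events.

# Problem sizes used by the test suite

Unit tests run on 2–10 minute synthetic sessions; parameter-recovery checks
use one 30-minute, 50-cell session; the cross-decoding suite runs twenty
15-minute attack sessions. These sizes were chosen so the full suite settles
in minutes while every estimate is comfortably inside its tolerance.
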