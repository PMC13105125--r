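---
title: "Methods: from raw home-cage streams to circadian and preference analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw home-cage streams to circadian and preference analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homecagr)
```

`homecagr` processes the three raw data streams an automated home cage
records from a single-housed mouse — operant beambreak/dispense event
logs, running-wheel encoder voltage, and video-scorer ethograms — into
tidy tables for circadian and preference analysis. This vignette explains
the models and conventions behind each stage, the parameters that matter,
and what the synthetic-session generator does and does not emulate.

## Time conventions

All timestamps are POSIX seconds and all clock arithmetic is pure UTC.
Zeitgeber time anchors ZT0 at lights-on (by default 05:00 UTC under a
12:12 photoperiod), so

$$\mathrm{ZT}(t) = \left(\frac{(t \bmod 86400) - \text{lights\_on}}{3600}\right) \bmod 24 .$$

Daylight-saving rules are deliberately ignored: animal facilities schedule
lights in UTC, and the conversion must be periodic with period exactly
86,400 s. Binned series are half-open `[start, start + w)` with widths 60,
3600 or 86,400 s; an event exactly on a boundary belongs to the later bin.
Bins with no events are present with value 0 — a gap in a series is
therefore always an explicit, masked exclusion, never a missing row. The
mask is the central cleaning device: QC failures remove data *in hour
chunks* by masking, keeping the series rectangular and the exclusion
auditable, and beambreak and dispense series are always masked as a pair.

The raw CSV dialects (timestamp + eight 0/1 channel states; timestamp +
volts) are not standardized by any vendor, so the readers auto-detect an
optional header and are strict about everything else: non-monotone
timestamps and malformed rows are hard errors naming the offending line,
and duplicate timestamps collapse keeping the last state. A channel that
is already active on a file's first record is counted as one rising edge
at that record's time — the poke began before logging started, and
silently dropping it would bias counts at every 4-hour file restart.

## Wheel kinematics

The wheel's absolute rotary encoder reports angular position as a voltage
in [0, 5] V that wraps at a full revolution; the calibration constant
0.07690168 m/V converts a voltage change to meters of circumference
(implying a circumference of ≈ 0.3845 m). Because the encoder is absolute,
a step from 4.9 V to 0.1 V is ambiguous; the decoder takes the
minimal-magnitude circular displacement, $|\Delta v^\*| \le 2.5$ V, which
is the only recoverable reading: at full running speed the wheel moves
about half a revolution between 16 Hz samples, so any true per-sample
motion beyond half a revolution is aliased and unrecoverable regardless of
convention. Ties at exactly 2.5 V resolve to forward motion; since
distance is reported unsigned (direction is discarded), the tie-break has
no effect on any downstream quantity. Voltages outside [0, 5] V by more
than 10⁻⁶ V are errors, not clamped.

Per-step distances are summed over tumbling 1-s windows anchored at the
trace's first sample, with the final partial window running to the end of
the data. Displacement timestamps are interval *ends*, so windows are
left-open/right-closed in displacement time: a step stamped exactly on a
window boundary carries motion from inside that window. Windows with zero
displacement emit nothing, which makes the measurement stream sparse and
gap-structured — exactly what bout segmentation consumes.

A running bout is a maximal run of measurements with inter-timestamp gaps
≤ 2 s, boundary inclusive. Bout speed is distance over the span
(t_end − t_start) with the span floored at one window, so a
single-measurement bout has a defined speed rather than a division by
zero. Whether speed should use active time or span time is genuinely open;
span time was chosen because it is what the recorded start/end times
imply, and the floor keeps the two identical for the shortest bouts.

Cleaning of hourly distance series is flag-then-mask: hours above
`spike_max_m` (default 700 m/h, roughly twice the busiest plausible hour
for an animal running ~7 km/day) or runs of ≥ 12 consecutive nonzero
light-phase hours (running through the entire rest phase) are *flagged*;
converting flags to masks is an explicit caller action. The original
cleaning procedure was manual video review, so the automated rule is
conservative and keeps a human-in-the-loop seam rather than deleting data.

## Operant events

The dispenser firmware's refractory rule is reproduced exactly: the first
poke dispenses, and a later poke dispenses iff at least `timeout` (default
3 s) has elapsed since the last *dispense* — not the last poke — with the
comparison inclusive (an interval of exactly 3.0 s is allowed, because the
rule forbids intervals of *less than* the timeout). Dispenses only trigger
on rising edges; a beam held across the boundary does not fire on release.
Beambreaks, being the animal's action, are the primary consumption proxy;
dispenses are retained for device QC. The QC rule flags hours with
*strictly more than* 500 beambreaks.

Aggregation offers three scales: day and week sums over unmasked member
hours (with the masked-hour count reported alongside — whole-day exclusion
is a caller decision), and an hour-of-day profile that averages all
unmasked instances of each ZT hour. Cohort summaries are per-bin mean ±
SEM over the animals contributing an unmasked value.

## Ethogram

Video scorers emit behavior labels in frame units per 4-hour segment;
absolute time is resolved as `segment_start + start_frame / fps` (default
30 fps). The fine-grained vocabulary (~40 labels) collapses onto 15 named
groups plus "Other" through a mapping that ships as a configuration CSV,
not code: the full vocabulary is scorer-specific, so the shipped map is an
editable, explicitly provisional default, and unmapped labels always fall
through to "Other". Ranking behaviors to keep the top 15 is done globally
by total duration (per-animal ranking would make group identities
incomparable across animals).

Hourly occupancy splits intervals pro-rata at hour boundaries — the only
rule that conserves seconds exactly — then divides each ZT hour's total by
the number of distinct absolute hours overlapped by any scored interval.
Partially scored hours count as full occurrences; with gap-free scoring
(as the simulator produces) this is exact, with patchy real scoring it
biases occupancy downward in the ragged hours. Percent-of-day is total
seconds per group over 86,400; under complete scoring the percentages,
including "Other", close to 100 within 10⁻⁹.

## Circadian statistics

Any non-negative 24-bin hourly profile is summarized by its mean resultant
vector: hours map to angles, the weighted cosine and sine sums give the
direction via `atan2`, and the magnitude is normalized by the total weight
so it lies in [0, 1] — 1 exactly when all weight is in one bin, 0 for a
uniform profile. Magnitudes below 10⁻⁹ report an undefined (NA) direction
rather than the noise of `atan2(0, 0)`, and an all-zero profile is an
error.

Two conventions are exposed for the hour-to-angle map. The default
represents each bin by its start hour. However, representing binned data
by bin starts biases the recovered direction by −0.5 h systematically: a
symmetric peak at phase φ puts equal mass in the bins starting at φ−1 and
φ, whose start-labelled mean is φ−0.5. `hour_offset = 0.5` (bin centers)
removes this quantization bias, and all phase-recovery checks in the
package use it. The half-bin choice is a rigid rotation: magnitude is
unaffected.

Cohort dispersion of per-animal directions uses unit vectors (each animal
weighted equally): the mean direction is the direction of their sum, and
spread is reported as a circular SEM, $\sqrt{-2\ln \bar R}\cdot
\tfrac{24}{2\pi} / \sqrt{n}$ hours — the output labels it explicitly,
since a bare "±" on a circular quantity is ambiguous.

## Preference

Contents swap positions on fixed periods (water every 3 days, food every
7) from a known day-1 assignment, with the swap effective at ZT0 of the
swap day (the physical swap happens during a daily check at an unrecorded
time; attributing the whole day to the new configuration is the simplest
consistent rule, and a configurable post-swap exclusion window is provided
because behavior can take days to renormalize after interventions).
Labeling each (day, position) count with that day's content makes content
totals and position totals two partitions of the same events, so totals
are conserved by construction. Daily differences use fixed sign
conventions — (position 2 − position 1), (treat − regular) — and grouping
them by where the treat sat yields the diagnostic sign pattern: content
preference keeps the type difference's sign across both swap groups while
the position difference flips; place preference is the mirror image. In
simulation this pattern classifies 3:1 effects correctly in well over 95%
of replicates at 28 days.

Per-animal differencing is the default (cohort pooling before differencing
is also possible by summing ledgers first); per-animal preserves the
pairing structure the downstream tests need. Water volume summaries are
dispense counts × a configured drop volume and are labelled estimates —
the hardware cannot confirm what was consumed.

## The synthetic session generator

`simulate_session()` is first-class, tested code, not a fixture. Event
streams are inhomogeneous Poisson processes with von Mises-shaped
intensity $r(t) = r_0 \exp(\kappa\,[\cos(2\pi(\mathrm{ZT}(t)-\phi)/24)-1])
\cdot e^{\kappa}$, simulated by thinning; the ethogram is a
circadian-modulated semi-Markov chain over the behavior repertoire with
log-normal dwell times, covering every frame of every 4-hour segment; wheel
bouts get log-normal durations and per-bout speeds, and are rendered to
encoder voltage on a regular 16 Hz grid while moving (the event-driven log
is silent otherwise), wrapping at 5 V. Dispenses are generated *through*
the same refractory controller the analysis implements, so the emitted
dispense stream satisfies the 3-s minimum by construction. All event times
are quantized to the millisecond at generation, so files round-trip
exactly, and a fixed seed yields byte-identical output.

Defaults are calibrated once to the study conditions of a nocturnal
C57BL/6J mouse: poke phases in the early dark period (sucrose water
ZT18.29, regular water ZT16.97, foods ≈ ZT17.7), running peaking at
ZT15.67 with ~7 km/day at steady state, a 3:1 sucrose-to-regular poke
ratio, no place bias, and sleep concentrated in the light phase at ≈ 43%
of the day. Concentrations default to κ = 2 for pokes and running.

What the simulator does *not* emulate: acclimation dynamics (rates are
stationary across days, whereas real animals take ~2 weeks to reach
steady-state running), dispenser malfunctions and leaks (so QC flags are
exercised with constructed fixtures, not emergent failures), scoring gaps
and misclassification in the ethogram, inter-individual variability beyond
the seed, and any biomechanics. Passing recovery tests therefore shows the
*analysis chain* is correct and unbiased under the generative model, not
that the model captures every property of real recordings.

## Numerical choices and test scale

- Voltage tolerance 10⁻⁶ V outside [0, v_max] before erroring; encoder
  tie at exactly half a revolution resolves forward (no downstream
  effect, distances being unsigned).
- Direction values within 10⁻⁹ h below 24 normalize to 0, so wraparound
  comparisons are stable.
- Occupancy assertions allow 10⁻⁶ s of slack: at POSIX magnitude (~10⁹ s)
  double rounding leaves ~10⁻⁷ s in hour-boundary splits.
- Degenerate inputs are contracts, not crashes: empty files parse to empty
  tables, a single analog sample decodes to an empty displacement list,
  fewer than two bouts yield no intervals, an all-zero profile is an
  explicit error, and a zero-day simulation is rejected.

The shipped tests run the oracle-equivalence suites at 1,000 random
instances per operation and the recovery checks on one 14-day
(wheel-phase) and eight 28-day (sucrose-ratio) simulated sessions, sizes
chosen so the full suite completes in about two minutes while keeping the
Monte-Carlo margins comfortable; all larger inputs are generated in memory
at run time rather than stored.

## Known limitations

- The behavior-group map is an informed default; real deployments must
  align it with their scorer's vocabulary.
- Occupancy treats partially scored hours as full occurrences (see above).
- Motion faster than half a revolution per encoder sample is aliased by
  physics; the decoder cannot and does not try to recover it.
- The package emits analysis-ready tables; cohort inferential statistics
  (ANOVA, paired tests) are intentionally left to the analyst.
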