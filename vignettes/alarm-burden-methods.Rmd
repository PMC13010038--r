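---
title: "Methods: quantifying pulse-oximetry alarm burden in a newborn unit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pulse-oximetry alarm burden in a newborn unit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoalarm)
```

## The problem

Continuous pulse-oximetry monitoring of preterm neonates produces a stream
of SpO2 (oxygen saturation) and PR (pulse rate) readings at 0.5 Hz — one
data cell every 2 seconds — together with device alarm annotations.
When alarm thresholds are not tailored to the patient, the alarm stream is
dominated by brief, self-resolving excursions: clinicians habituate, true
emergencies risk being missed, and neonates are repeatedly aroused. This
package provides the computational machinery to quantify that burden from
monitor trace exports, and to ask *what-if* questions about alternative
thresholds and delays by re-deriving the alarm stream from the raw values.

Because raw unit data are typically not shareable, the package also ships a
synthetic cohort generator whose pooled statistics are calibrated to the
summaries a tertiary-care newborn unit reported for 49 monitored
neonates; every pipeline stage can therefore be exercised end to end, with
planted ground truth, at desk scale.

## Trace model and quality rules

A trace is one neonate's ordered sequence of 2-second cells: `t` (seconds
from trace start, gaps allowed, never imputed), integer `spo2` (%), integer
`pr` (bpm), perfusion index `pi`, a signal-quality flag `siq` (`ok`/`low`),
and a set of event tokens per cell. Invalid readings are encoded by the
device as literal tokens ("Invalid functional SpO2", "Invalid PR"); the
reader converts them to nulls while retaining the token as a label, so the
CSV round-trip is lossless and the count of nulls equals the count of
invalid tokens.

`apply_quality_rules()` implements the data-integrity exclusions:

* cells carrying invalid-reading tokens or system-event tokens (sensor
  off, low perfusion, cable disconnect) are marked **excluded**; clinical
  alarm labels on them are removed from the alarm stream and tallied
  separately;
* clinical alarm labels on low-SIQ cells are removed from the alarm stream
  (the values themselves are kept when valid, since they remain usable for
  re-simulation);
* exclusion is a **union** over rules — excluded duration is the total time
  of cells flagged by any rule — because the burden accounting needs a
  single excluded-time figure.

All downstream denominators (alarm densities, pooled marginals) use
quality-passing hours and valid samples only. Whether per-hour densities
should instead use total monitored hours is genuinely open; the package
states its choice in every quality report it writes.

## Alarm events: the 30-second gap rule

Raw annotations mark individual cells. To avoid overcounting, consecutive
alarm cells are grouped into **alarm events**: within one category stream,
a new event starts only when the silence between flagged cells exceeds
30 s (a separation of exactly 30 s merges; strictly more splits), or when
the alarm category changes. Numerical conventions, fixed once:

* the silence between a cell starting at $t_1$ (cells are 2 s wide) and a
  later cell starting at $t_2$ is $t_2 - t_1 - 2$ seconds;
* event duration counts **active cells only**, at 2 s per cell
  (`duration_s = 2 × active_cell_count`); bridged gap cells are not
  monitoring time in alarm, so they are not counted;
* each clinical category (`spo2_low`, `spo2_high`, `pr_low`, `pr_high`)
  and the system stream is segmented independently, so overlapping SpO2
  and PR alarms are distinct simultaneous events and SpO2/PR counts can be
  reported separately. The gap rule is applied within category; the
  alternative (a joint stream) would conflate a saturation alarm that
  bridges a pulse-rate alarm;
* an event is `audio_visual` if both audible and visual cells occur within
  it; in modality-specific densities an audio-visual event contributes to
  both the audible and the visual stream, which is why those densities
  overlap in the totals;
* `gap_s = 0` degenerates to maximal contiguous runs; events are never
  merged across trace files because each file restarts its own timeline.

Correctness is anchored by a brute-force oracle: an independent scalar
run-merger written directly from the rule above, compared exactly on
thousands of randomized traces (including grid gaps) in the test suite.

## The monitor's alarm logic

`simulate_alarm_stream()` re-derives per-cell alarm state from raw values
so alarm burden can be recomputed under alternative settings. The state
machine mirrors the device configuration used at study setup (averaging
8 s, alarm delay 15 s, rapid desaturation 10%, SpO2 85–96%, PR 90–200 bpm;
"Fast sat" off and sensitivity "normal" are carried as metadata with no
computational effect):

1. **Averaging.** A trailing boxcar over `averaging_s / 2` samples.
   Partial windows at the series start average the available samples
   (avoiding dead time), nulls are excluded from the window, and an
   all-null window yields null. The window is sample-based; a timestamp
   gap additionally breaks violation continuity in step 3.
2. **Threshold check.** Strict inequalities on the averaged series:
   a value equal to a threshold is in range. This matches reading the
   configured 85–96% as *within-range limits*; it is stated as an
   assumption wherever fractions are reported.
3. **Delay.** The alarm asserts at the first cell where the violation has
   been continuously true for at least `delay_s`, measured in whole 2 s
   cells (`ceil(delay_s / 2)` cells); with the 15 s default that is the
   8th violating cell. The device's internal clocking is unpublished;
   whole-cell semantics match the sampled data model. The delay applies to
   high- as well as low-threshold alarms (also not stated by the vendor;
   applied symmetrically and flagged).
4. **Rapid desaturation.** If the averaged SpO2 falls to or below
   `spo2_low - rapid_desat_pct` (default 75%), the low-SpO2 alarm asserts
   immediately — the latch holds until the violation clears. This is an
   interpretation of the configured "rapid desaturation 10%" setting; the
   vendor's exact semantics are unpublished.
5. **De-assertion** occurs as soon as the violation clears; asserted cells
   are then segmented into events by the same gap rule as recorded
   annotations.

A second, deliberately independent scalar implementation of steps 1–5
lives in the test helpers and is compared cell-for-cell against the
vectorized implementation on randomized traces.

### Which count is monotone in the delay?

Intuitively a longer delay filters alarms, and for **activations**
(assertion onsets; equivalently events at gap 0) this is a theorem: each
maximal violation run asserts iff it survives the delay, so the activation
count is non-increasing in `delay_s`. For **gap-merged event counts** it
is provably false in edge cases: trimming the leading cells of a run can
push a 30 s silence past the threshold and split one merged event in two
(e.g. two 40 s violation runs separated by 20 s of silence: one event at
delay 0, two events at delay 15), and removing the middle run of a merged
chain splits the chain. `what_if_sweep()` therefore reports both counts
(`n_*` merged events, `act_*` activations), and the monotonicity
guarantees in the test suite are stated for activations and for the
below-threshold *fraction* (monotone in the threshold by construction).
The analogous knife-edge caveat applies to threshold monotonicity of event
counts: an averaged plateau exactly at a new threshold can split a run.

## Burden metrics

Per neonate: event counts, alarms per quality-passing hour, median and IQR
of event durations, split by category and modality. Cohort summaries take
the median and IQR **across per-neonate values**, never across pooled
cells, because monitoring durations differ by two orders of magnitude.
Conventions: IQR is reported as the single width Q3 − Q1 with quartiles by
linear interpolation (type-7, the `stats::quantile` default); duration
buckets are left-open right-closed so "30 seconds or less" includes
exactly 30 s; hourly/daily maxima use clock-aligned windows from each
neonate's first sample (reproducible without wall-clock metadata);
out-of-range fractions use strict inequalities over valid samples, with a
disabled threshold contributing zero.

A known ambiguity: a reported share like "44.5% greater than the upper
threshold" can be read against all values or against out-of-range values
only. The package computes both readings (`out_of_range_fraction()`
returns the parts separately) and privileges neither.

## The synthetic cohort generator

The generator emulates the *data-generating process* of a monitored
neonate rather than resampling any real data:

* **SpO2 baseline (85–96%)** — a sticky semi-Markov run process: integer
  run values drawn from a fixed law, geometric run lengths with
  value-dependent means (3 cells at 85–92, 6 at 93–95, 10 at 96). The
  cell-level marginal of such a process is proportional to
  `P(value) × mean run length`, which makes the in-range marginal directly
  designable while keeping realistic short-range dynamics. A literal
  first-order Markov chain was rejected because it cannot decouple the
  marginal from the excursion statistics that drive event counts and
  durations.
* **High excursions (97–100%)** — an alternating renewal overlay: a 90/10
  mixture of brief swings (10 + Exp(18) s) and prolonged high-saturation
  periods (60 + Exp(≈1900) s, as on supplemental oxygen). The long
  component carries most of the above-96 time; the short component carries
  most of the event count. Within an excursion, values follow a run
  process over 97–100 whose marginal is the printed high-end split (36%
  at 100, 20% at 99, 22% at 98, 22% at 97).
* **Desaturations (< 85%)** — flat dips to a drawn nadir: a 55/45 mixture
  of brief shallow dips (6 + Exp(8) s, mostly sub-alarm) and sustained
  events (16 + Exp(36) s). The nadir law is split at 80% (so the
  below-80.2% mass is right by construction, SpO2 being integer) and at
  75% (the rapid-desaturation zone at default settings).
* **PR** — a rounded truncated-normal run process on 100–200 bpm plus
  bradycardia (level ≈ N(80, 7), 10 + Exp(20) s) and tachycardia
  (level ≈ N(206, 6)) overlays. A quarter of deep desaturations trigger a
  coupled bradycardia, reflecting the bradycardic response to hypoxemia;
  the coupling is deliberately weak and the independent rate is reduced so
  the total bradycardia load stays calibrated.
* **Artifacts** — Poisson segments (1.33/h, 30 + Exp(240) s) typed as
  sensor-off, low-perfusion or cable-disconnect; cells inside are invalid
  with type-specific probabilities (tuned so ~75% of excluded cells have
  null SpO2) or carry noisy values, low-perfusion segments force `siq =
  "low"`; short random low-SIQ bursts occur elsewhere. Artifacts are
  placed independently of clinical episodes and may overlap them — uniform
  placement keeps the pooled valid-sample marginals unbiased, and sensor
  trouble is not independent of motion in reality either.
* **Annotations** — alarm tokens are written by running the package's own
  alarm state machine at default settings on the finished values, so
  annotations are reproducible from the trace by construction; each event
  is audible with probability 0.72 (otherwise "(Silenced)", visual-only),
  which puts the audible share of the doubled modality count near the
  reported 44%.
* **Heterogeneity** — per-neonate lognormal factors (sd 0.10 on the log)
  on episode rates and a N(0, 2.5 bpm) PR baseline shift. The printed
  summaries constrain only pooled marginals; this mild heterogeneity is a
  choice, and stronger per-neonate structure (e.g. a chronically hypoxemic
  subgroup) would satisfy the same constraints.

### Calibration: derived, not assigned

`default_calibration()` converts printed pooled statistics into process
parameters:

* time fractions → rates: a target fraction $f$ with mean episode dwell
  $\bar{D}$ gives rate $f \cdot 3600 / \bar{D}$ per hour. The
  desaturation rate follows from the 5.78% below-85 mass; the long-high
  mean dwell follows from the 44.22% above-96 mass at the chosen
  excursion rate.
* the nadir law's sub-80 share is the ratio 3.4 / 5.78 of the two printed
  tail masses;
* the PR baseline location/scale and the tachycardia fraction are solved
  by deterministic moment matching of the exact discrete mixture
  (baseline + overlays, including rounding, truncation and the
  between-neonate shift) against mean 158, SD 19.87, 0.92% below 90 and
  1.08% above 200;
* feasibility of the median: with 44.22% of mass above 96 and a median at
  96, the point mass at exactly 96 must be at least 0.5 − 0.4422 ≈ 5.8%;
  the shipped in-range marginal places 24% of the in-range mass (12%
  overall) there, keeping $P(\le 95) \approx 0.44$ so the median cannot
  slip.

Two event-shape constants are not identified by any printed marginal: the
high-excursion rate (6.8/h) and the short-dwell shapes. They were fixed by
matching the emergent event statistics — the 57.4% high share of SpO2
alarm events and the 20 s median event duration — at the default cohort
size, then frozen; the test suite verifies the whole constraint set within
three Monte-Carlo standard errors (neonate-level bootstrap).

### Scale, determinism, and what passing does not show

The default cohort is 49 neonates with monitoring durations drawn from a
truncated lognormal with median 2 simulated days (range 2.9 h – 7.3 days)
— about a 5.6-fold scale-down of the unit's durations (median 11.2 days,
range 16 h – 41 days), chosen so a full generate-filter-segment-summarize
cycle runs in well under a minute. Rates and marginals are per-hour
quantities and are unaffected by the scaling; *totals* (e.g. the unit's
565 413 alarms) are not reproduced at desk scale and are out of scope.
Per-neonate substreams are seeded from the cohort seed, so a spec is
reproduced byte for byte, independent of generation order.

The generator is a statistical stand-in, not a physiological model: it
plants flat-nadir desaturations (no ramps), leaves SpO2 and PR dynamics
otherwise uncoupled, has no diurnal structure, no care-event clustering
(handling, feeds), and no photoplethysmogram waveform. Passing the
calibration tests shows the pipeline computes the defined statistics
correctly on data with the reported pooled structure — it does not
validate clinical realism beyond those constraints.

## Degenerate inputs and tie-breaks

Empty traces yield zero monitored hours and empty event tables; a density
over zero hours is an error, as is a duration distribution over zero
events. An all-null averaging window is null; a violation interrupted by a
null or a timestamp gap restarts the delay. Unknown event tokens map to
category `other` with a warning and are never silently dropped. The
boundary conventions — 30 s merges / >30 s splits, value-equals-threshold
is in range, the ≤30 s duration bucket includes 30 s — are each pinned by
a dedicated test.

## Limitations

* The vendor's export schema, delay clocking, rapid-desaturation and
  averaging internals are unpublished; the documented dialect and state
  machine are explicit interpretations, adaptable via `trace_dialect()`
  and `alarm_settings()`.
* The six-way split of clinical alarm entries is a documented assumption
  (low/high × SpO2/PR, system, other), not a claim about the device.
* Modality (audible vs silenced) is operator behavior; the simulator
  cannot derive it from values and reports re-derived events as
  audio-visual.
* Cohort-level inference (subgroup comparisons, regression) is out of
  scope; the package stops at descriptive burden statistics and what-if
  recomputation.
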