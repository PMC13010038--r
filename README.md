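# neoalarm

Alarm-burden analysis for neonatal pulse-oximetry traces.

Continuous SpO2/pulse-rate monitoring of preterm neonates generates a
relentless stream of alarms, most of them brief and self-resolving. When
thresholds are not tailored to the patient, clinicians habituate (alarm
fatigue) and true deterioration risks being missed. `neoalarm` turns 0.5 Hz
pulse-oximeter trace exports into quantitative alarm-burden statistics and
lets you ask *what-if* questions about alternative alarm settings. It is
written for clinical researchers and biomedical engineers studying alarm
hygiene in newborn units.

## What it computes

* **Trace ingestion** (`read_trace_csv`, `write_trace_csv`): a documented
  CSV dialect for per-neonate traces (timestamp, SpO2, PR, perfusion
  index, signal quality, event tokens), with lossless handling of the
  device's invalid-entry tokens.
* **Quality filtering** (`apply_quality_rules`): excludes system-event
  segments (sensor off, low perfusion, cable disconnect) and invalid
  readings, removes alarm entries with low signal quality (SIQ), and
  accounts for everything in a quality report.
* **Event segmentation** (`segment_events`): groups per-cell alarm
  annotations into discrete alarm events — a new event starts when the
  alarm type changes or after a silence of more than 30 s — with

      duration_s = 2 × (number of active 2-second cells).

* **Burden metrics** (`per_neonate_burden`, `cohort_summary`): alarms per
  quality-passing hour, audible/visual densities, duration distributions
  ("30 seconds or less" buckets), per-neonate medians and IQRs.
* **Alarm-logic re-implementation** (`simulate_alarm_stream`,
  `what_if_sweep`): the monitor's alarm generation — trailing 8 s
  averaging, strict threshold check (defaults SpO2 85–96 %, PR 90–200
  bpm), 15 s alarm delay in whole 2 s cells, rapid-desaturation override
  (averaged SpO2 ≤ lower threshold − 10 points asserts immediately) — so
  alarm streams can be re-derived from raw values under alternative
  thresholds and delays.
* **Synthetic cohort generator** (`default_calibration`,
  `generate_cohort`): a calibrated stand-in for undeposited unit data —
  sticky integer SpO2 baseline, high-saturation excursions,
  desaturation dips, bradycardia/tachycardia overlays, sensor artifacts,
  and device annotations produced by the package's own alarm logic, with
  planted ground truth for validation.

## Worked example

```r
library(neoalarm)

# 1. a small synthetic cohort (or read_trace_csv() on real exports)
cohort <- generate_cohort(default_calibration(n_neonates = 4, seed = 7))
#> <synthetic_cohort> 4 neonates, 239 monitored hours, 3858 planted episodes

# 2. data-integrity filtering
filtered <- lapply(cohort$traces, apply_quality_rules)
print(filtered[[1]]$report)
#> <quality_report> neonate N01
#>   monitored: 78.68 h, excluded: 7.53 h (9.57%)
#>   invalid SpO2 cells: 10224; invalid PR cells: 10036
#>   alarm entries removed for low SIQ: 147; in excluded cells: 782
#>   system events (cells): Cable Disconnect=2261, Low Perfusion=5248, Sensor Off=6048
#>   null fraction in excluded cells: SpO2 75.4%, PR 74.0%
#>   density denominator downstream: quality-passing hours

# 3. alarm events under the 30 s gap rule
traces <- lapply(filtered, `[[`, "trace")
events <- do.call(rbind, lapply(traces, segment_events))

# 4. burden summary
hours <- vapply(traces, monitored_hours, numeric(1))
clinical <- events[events$category != "system", ]
cohort_summary(per_neonate_burden(clinical, hours), clinical)
#> <burden_summary> 4 neonates, 2452 alarm events
#>   alarms per neonate:        726 (IQR, 184)
#>   density per hour:          11.1 (IQR, 2.22)
#>   audible density per hour:  8.05 (IQR, 1.7)
#>   visual density per hour:   11.1 (IQR, 2.22)
#>   pooled median duration:    20 s (IQR, 38 s)
#>   duration buckets:  <=30s 64.4%, (30s,60s] 16.5%, (60s,120s] 7.7%, ...
#>   max hourly count: 24; max daily count: 279

# 5. what-if: shorter delays, a relaxed lower threshold
sweep <- what_if_sweep(traces, settings_grid(delay_s = c(0, 10, 15),
                                             spo2_low = c(80, 85)))
sweep[, c("spo2_low", "delay_s", "n_total", "act_total", "frac_spo2_below")]
#>   spo2_low delay_s n_total act_total frac_spo2_below
#> 1       80       0    2674      2842      0.02857026
#> 2       85       0    3296      3552      0.05650030
#> 3       80      10    2361      2472      0.02857026
#> 4       85      10    2949      3101      0.05650030
#> 5       80      15    1954      2006      0.02857026
#> 6       85      15    2457      2535      0.05650030
```

Reading the output: each neonate here averages about 11 alarm events per
monitored hour, all events are visual while ~72 % also sound
(`audible density < visual density`), and half of all events last 20 s or
less. The sweep shows the two standard alarm-hygiene levers acting
independently: a longer delay removes short activations
(`act_total` falls monotonically as `delay_s` grows), while lowering the
SpO2 threshold from 85 to 80 roughly halves the fraction of readings below
threshold (5.7 % → 2.9 %). `n_total` counts gap-merged events,
`act_total` counts alarm annunciations; the vignette explains why only the
latter is exactly monotone in the delay.

`run_analyze()` (or `inst/scripts/neoalarm-analyze.R` from a shell) runs
the whole pipeline — ingest, filter, segment, summarize, sweep — and
writes the quality report, event table, burden summary and sweep table to
an output directory.

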