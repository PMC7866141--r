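# ThermoTrack

Tracking and analysis for the **two-plate thermal place preference assay**
in mice — a behavioural readout of thermal pain sensitivity used to screen
analgesics against chemotherapy- (oxaliplatin-) induced cold
hypersensitivity.

In the assay a freely moving mouse chooses between two plates held at
different temperatures; nine 5-minute sessions tile 0–45 °C in 5 °C pairs
((0,5), (5,10), …, (40,45)), each animal is measured before oxaliplatin,
after oxaliplatin (*pre-drug*) and after a candidate analgesic
(*post-drug*), and the animal starts every session on the colder plate.
Healthy mice prefer the plate nearer their thermal preferendum (≈22–30 °C)
and avoid heat stress (> 34 °C). A drug's analgesic action is read out as
the **loss** of a previously significant plate preference or its
**reversal** toward the opposite plate.

ThermoTrack is written for behavioural pharmacology labs running this assay
(or building similar video-scored place preference tests) and provides the
full chain:

* **Tracker** — frame-differencing video analysis: per iteration, two
  consecutive frames are resized, grayscaled, median-filtered, subtracted,
  binarized and median-filtered again; white pixels are counted on each
  side of the arena midline and the larger count locates the animal. The
  mouse's zone occupancy is reported as % time per plate
  (`trackSession()`, `pctLeft + pctRight = 100` exactly). Iterations with
  no detectable motion (a stationary mouse is invisible to frame
  differencing) are resolved by carrying the last determined side forward.
* **Statistics** — per session: one-way repeated-measures ANOVA of
  `pct_colder` across the three timepoints; Tukey-adjusted plate-vs-plate
  comparisons within each timepoint (the `*` family, with the assay's
  strict star thresholds `* p<0.05 … **** p<0.0001`) and same-plate
  comparisons across timepoints (the `#` family); and the
  maintained / lost / reversed classification (`analyzeCohort()`).
* **Simulator** — a stochastic thermotaxis agent (Poisson crossing
  attempts, logistic plate choice on the comfort difference, stationary
  occupancy `plogis(β·Δcomfort)`) plus a grayscale video renderer with
  sensor noise, illumination drift, immobility episodes and per-frame
  ground truth, so every stage is testable without animal data
  (`simulateCohort()`, `simulateTrajectory()`, `renderFrames()`).

## Worked example

Simulate one (0, 5) °C session, render it to video, track it, and compare
with the simulator's ground truth:

```r
library(ThermoTrack)

pair <- PlatePair(0, 5, sessionId = 1)
tr  <- simulateTrajectory(pair, AgentParams(), durationS = 60, seed = 7)
fs  <- renderFrames(tr, RenderConfig(), seed = 7)
out <- trackSession(fs, TrackerConfig(), pair)
out$result
#> SessionResult [session 1: left 0 / right 5 degC]
#>   left 35.9% (21.5 s) | right 64.1% (38.4 s)
#>   colder 35.9% | warmer 64.1% | 178 unresolved iterations
mean(records(out$occupancy)$resolvedSide == trajectoryTruth(tr)$side[-1])
#> [1] 0.9949917
```

The animal spent 64% of the session on the warmer (5 °C) plate — the
expected cold-avoidance — and the tracker agrees with the ground-truth side
on 99.5% of iterations; the 178 "unresolved" iterations are immobility
episodes filled in by the carry-forward rule.

Simulate a full cohort (10 animals, 9 sessions, 3 timepoints) under a
cold-selective analgesic profile and classify the drug effect per session:

```r
sc <- simulateCohort(10, standardProtocol(),
                     effects = duloxetineProfile(), seed = 7)
cat(summaryReport(analyzeCohort(cohortTable(sc))), sep = "\n")
#> session  pair(degC)   pre-drug           post-drug          effect
#>       1     0-5       warmer (****)      none   (ns)        lost ####
#>       2     5-10      warmer (****)      colder (****)      reversed ####
#>       3    10-15      warmer (****)      warmer (****)      maintained ns
#>       4    15-20      warmer (****)      warmer (****)      maintained ns
#>       5    20-25      warmer (****)      warmer (****)      maintained ns
#>       6    25-30      colder (****)      colder (***)       maintained ns
#>       7    30-35      colder (****)      colder (****)      maintained ns
#>       8    35-40      colder (****)      colder (****)      maintained ns
#>       9    40-45      colder (****)      colder (****)      maintained ns
#> analgesia-indicating sessions (lost or reversed): 1, 2
```

The preference is lost at 0–5 °C and reversed at 5–10 °C (the analgesic
band) while cold-range preferences at 10–20 °C are untouched and
heat-avoidance above 30 °C stays intact.

A thin command-line wrapper over the same functions lives at
`inst/exec/thermotrack` (`simulate`, `track`, `analyze` subcommands);
`cmdSimulate()` / `cmdTrack()` / `cmdAnalyze()` are the equivalent R entry
points, each writing CSV/JSON outputs plus a provenance record (resolved
config, seed, package version).

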